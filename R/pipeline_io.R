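## File formats, validation and end-to-end orchestration. TSV is the
## canonical interchange; BED and VCF are accepted at the readers only.
## All written tables carry header comments stating column units.

.normalize_chrom <- function(x) sub("^[Cc]hr", "", as.character(x))

#' Write a TSV with unit header comments
#' @param df Data frame.
#' @param path Output path.
#' @param units Optional named character vector `column = unit` written as
#'   `#` comment lines.
#' @export
write_tsv_units <- function(df, path, units = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(units))
    writeLines(sprintf("# %s: %s", names(units), units), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by this package (or any plain TSV; `#` lines ignored)
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv_units <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a daily weather series from TSV
#'
#' Expects columns `date` (ISO-8601), `tmean`, `tmean_daylight`
#' (deg C) and optionally `photoperiod_hours`; when the photoperiod column
#' is absent it is computed from `latitude` with [daylength()].
#'
#' @param path TSV path.
#' @param latitude Latitude in degrees (required without a photoperiod
#'   column).
#' @return A [weather_series()].
#' @export
read_weather <- function(path, latitude = NULL) {
  d <- read_tsv_units(path)
  weather_series(d$date, d$tmean,
                 if (!is.null(d$tmean_daylight)) d$tmean_daylight else d$tmean,
                 photoperiod_hours = d$photoperiod_hours,
                 latitude = latitude)
}

#' Read an accession genotype TSV
#'
#' Columns `snp_id`, `chrom`, `pos`, then one 0/1/NA column per accession.
#'
#' @param path TSV path.
#' @return A [genotype_matrix()].
#' @export
read_genotypes_tsv <- function(path) {
  d <- read_tsv_units(path)
  snps <- data.frame(id = d$snp_id, chrom = .normalize_chrom(d$chrom),
                     pos = d$pos)
  calls <- t(as.matrix(d[, -(1:3), drop = FALSE]))
  genotype_matrix(calls, snps, accessions = rownames(calls))
}

#' Write an accession genotype TSV
#' @param G A [genotype_matrix()].
#' @param path Output path.
#' @export
write_genotypes_tsv <- function(G, path) {
  df <- cbind(data.frame(snp_id = G$snps$id, chrom = G$snps$chrom,
                         pos = G$snps$pos), as.data.frame(t(G$calls)))
  write_tsv_units(df, path, c(pos = "bp (1-based)", snp_id = "SNP id"))
}

#' Read biallelic genotypes from a VCF
#'
#' Accepts biallelic records with homozygous calls (inbred material);
#' heterozygous calls become missing with a warning. Requires the vcfR
#' package.
#'
#' @param path VCF path.
#' @return A [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"])
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  code <- function(x) {
    x <- sub("\\|", "/", x)
    out <- rep(NA_real_, length(x))
    out[x %in% c("0/0", "0")] <- 0
    out[x %in% c("1/1", "1")] <- 1
    het <- x %in% c("0/1", "1/0")
    if (any(het, na.rm = TRUE))
      warning(sum(het, na.rm = TRUE), " heterozygous calls set to missing")
    out
  }
  calls <- t(apply(gt, 2, code))
  dim(calls) <- c(ncol(gt), nrow(gt))
  rownames(calls) <- colnames(gt)
  snps <- data.frame(id = ifelse(fix[, "ID"] == "." | is.na(fix[, "ID"]),
                                 paste0(fix[, "CHROM"], "_", fix[, "POS"]),
                                 fix[, "ID"]),
                     chrom = .normalize_chrom(fix[, "CHROM"]),
                     pos = as.integer(fix[, "POS"]))
  genotype_matrix(calls, snps)
}

#' Read candidate genes from TSV or BED
#'
#' TSV needs columns `gene_id`, `chrom`, `start`, `end` (1-based inclusive).
#' BED (detected by the `.bed` extension, or `format = "bed"`) is 0-based
#' half-open and converted at the reader.
#'
#' @param path File path.
#' @param format `"auto"`, `"tsv"` or `"bed"`.
#' @param window_bp Window half-width passed to [gene_windows()].
#' @return A [gene_windows()] set.
#' @export
read_genes <- function(path, format = "auto", window_bp = 20000) {
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  if (format == "bed") {
    d <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = if (ncol(d) >= 4) d[[4]]
                        else sprintf("gene%03d", seq_len(nrow(d))),
                        chrom = .normalize_chrom(d[[1]]),
                        start = d[[2]] + 1L, end = d[[3]])
  } else {
    d <- read_tsv_units(path)
    genes <- data.frame(gene_id = d$gene_id,
                        chrom = .normalize_chrom(d$chrom),
                        start = d$start, end = d$end)
  }
  gene_windows(genes, window_bp)
}

#' Read a RIL family from its three TSV files
#'
#' @param geno_path Lines x markers table: first column `line_id`, then one
#'   A/B/H/NA column per marker.
#' @param map_path Marker map TSV: `marker`, `chrom`, `cM`, `bp`.
#' @param pheno_path Phenotype TSV: `line_id`, `trait_ptu`.
#' @param family_id,parents,recurrent_parent Passed to [ril_family()].
#' @return A [ril_family()].
#' @export
read_ril_family <- function(geno_path, map_path, pheno_path,
                            family_id = "fam", parents = c("A", "B"),
                            recurrent_parent = "A") {
  g <- read_tsv_units(geno_path)
  map <- read_tsv_units(map_path)
  map$chrom <- .normalize_chrom(map$chrom)
  ph <- read_tsv_units(pheno_path)
  geno <- as.matrix(g[, -1, drop = FALSE])
  geno[geno == ""] <- NA
  rownames(geno) <- g[[1]]
  y <- ph$trait_ptu[match(g[[1]], ph$line_id)]
  ril_family(geno, map, y, family_id = family_id, parents = parents,
             recurrent_parent = recurrent_parent)
}

#' Write a RIL family to its three TSV files
#' @param family A [ril_family()].
#' @param prefix Path prefix; writes `<prefix>_geno.tsv`, `<prefix>_map.tsv`,
#'   `<prefix>_pheno.tsv`.
#' @export
write_ril_family <- function(family, prefix) {
  calls <- family$prob_A
  geno <- matrix(NA_character_, nrow(calls), ncol(calls),
                 dimnames = dimnames(calls))
  geno[calls == 1] <- "A"; geno[calls == 0] <- "B"
  line_id <- sprintf("line%04d", seq_len(nrow(geno)))
  write_tsv_units(cbind(data.frame(line_id = line_id), as.data.frame(geno)),
                  paste0(prefix, "_geno.tsv"),
                  c(line_id = "RIL line id"))
  write_tsv_units(family$map, paste0(prefix, "_map.tsv"),
                  c(cM = "centimorgan", bp = "bp (1-based)"))
  write_tsv_units(data.frame(line_id = line_id,
                             trait_ptu = family$phenotype),
                  paste0(prefix, "_pheno.tsv"),
                  c(trait_ptu = "PTU (degC x daylight)"))
  invisible(prefix)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param genotypes Path to the accession genotype TSV.
#' @param trait Path to an accession trait TSV (`genotype_id`, `trait_ptu`).
#' @param families Optional list of lists with `geno`, `map`, `pheno` paths
#'   and `family_id`; `NULL` runs GWA-only.
#' @param genes Optional candidate-gene path (TSV or BED).
#' @param maf_threshold,window_bp,top_ns,n_perm,alpha Analysis parameters.
#' @param seed Integer seed covering every stochastic step.
#' @return List of class `run_config`.
#' @export
run_config <- function(genotypes, trait, families = NULL, genes = NULL,
                       maf_threshold = 0.10, window_bp = 20000,
                       top_ns = c(500, 200, 100, 50), n_perm = 200,
                       alpha = 0.05, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Load and cross-validate all pipeline inputs
#'
#' Reads every file named in the configuration and aggregates all
#' consistency failures (accession id agreement, chromosome naming, map
#' monotonicity) into a single error report.
#'
#' @param cfg A [run_config()].
#' @return Validated bundle: `G`, `trait` (named vector), `families`,
#'   `genes`.
#' @export
load_inputs <- function(cfg) {
  problems <- character(0)
  G <- tryCatch(read_genotypes_tsv(cfg$genotypes),
                error = function(e) {problems <<- c(problems, conditionMessage(e)); NULL})
  tr <- read_tsv_units(cfg$trait)
  trait <- setNames(tr$trait_ptu, tr$genotype_id)
  if (!is.null(G)) {
    missing_acc <- setdiff(names(trait), G$accessions)
    if (length(missing_acc))
      problems <- c(problems, paste0("phenotyped accessions absent from genotypes: ",
                                     paste(missing_acc, collapse = ", ")))
  }
  families <- NULL
  if (!is.null(cfg$families)) {
    families <- lapply(cfg$families, function(f)
      tryCatch(read_ril_family(f$geno, f$map, f$pheno,
                               family_id = f$family_id),
               error = function(e) {
                 problems <<- c(problems,
                                paste0("family ", f$family_id, ": ",
                                       conditionMessage(e)))
                 NULL
               }))
  }
  genes <- if (!is.null(cfg$genes))
    read_genes(cfg$genes, window_bp = cfg$window_bp) else NULL
  if (!is.null(G) && !is.null(genes)) {
    bad <- setdiff(unique(genes$chrom), unique(as.character(G$snps$chrom)))
    if (length(bad))
      problems <- c(problems, paste0("gene chromosomes absent from genotypes: ",
                                     paste(bad, collapse = ", ")))
  }
  if (length(problems))
    stop("input validation failed:\n  - ",
         paste(problems, collapse = "\n  - "))
  list(G = G, trait = trait, families = families, genes = genes)
}

#' Run the full dual-mapping pipeline
#'
#' Orchestrates the analysis in study order: MAF filtering, kinship, the two
#' GWA scans, per-family QTL models with permutation thresholds, SNP
#' annotation, the enrichment ladder, candidate classification and orphan
#' peaks. All outputs are written as unit-commented TSVs plus a provenance
#' JSON (parameters, seed, package version); the run is deterministic given
#' the configuration.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of result objects.
#' @export
run_all <- function(cfg, out_dir) {
  bundle <- load_inputs(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  G <- maf_filter(bundle$G, cfg$maf_threshold)
  y <- bundle$trait[G$accessions]
  if (anyNA(y)) stop("accessions without trait values: ",
                     paste(G$accessions[is.na(y)], collapse = ", "))
  K <- ibs_kinship(G)
  res_w <- wilcoxon_scan(G, y)
  res_m <- mixed_model_scan(G, y, K)
  scan_units <- c(pos = "bp (1-based)", p = "two-sided p-value", maf = "fraction")
  write_tsv_units(res_w, file.path(out_dir, "scan_wilcoxon.tsv"), scan_units)
  write_tsv_units(res_m, file.path(out_dir, "scan_mixed.tsv"), scan_units)

  qtl_tab <- NULL
  if (!is.null(bundle$families)) {
    qtl_tab <- do.call(rbind, lapply(seq_along(bundle$families), function(i) {
      fam <- bundle$families[[i]]
      thr <- permutation_threshold(fam, n_perm = cfg$n_perm,
                                   alpha = cfg$alpha, seed = cfg$seed + i)
      model <- forward_multiqtl(fam, thr)
      if (!nrow(model$qtl)) return(NULL)
      cbind(family = fam$family_id, model$qtl,
            model_r2 = model$model_r2, threshold = as.numeric(thr))
    }))
    if (!is.null(qtl_tab))
      write_tsv_units(qtl_tab, file.path(out_dir, "qtl_models.tsv"),
                      c(peak_cM = "centimorgan", ci_lo_bp = "bp",
                        additive_effect = "PTU (recurrent-parent allele)",
                        pve = "fraction of phenotypic variance"))
  }
  qtl_intervals <- NULL
  if (!is.null(qtl_tab))
    qtl_intervals <- data.frame(family = qtl_tab$family,
                                chrom = qtl_tab$chrom,
                                lo_bp = qtl_tab$ci_lo_bp,
                                hi_bp = qtl_tab$ci_hi_bp)

  results <- list(wilcoxon = res_w, mixed = res_m, qtl = qtl_tab)
  if (!is.null(bundle$genes)) {
    ann <- annotate_snps(res_m[, c("snp_id", "chrom", "pos")],
                         bundle$genes, qtl_intervals)
    flags <- if (is.null(qtl_intervals)) "candidate"
             else c("qtl", "candidate", "both")
    ladder <- enrichment_ladder(res_m, ann,
                                Ns = cfg$top_ns[cfg$top_ns <= nrow(res_m)],
                                flags = flags, B = 1000, seed = cfg$seed)
    write_tsv_units(ladder, file.path(out_dir, "enrichment.tsv"),
                    c(observed = "enrichment ratio"))
    n_class <- min(500, nrow(res_m))
    cls <- classify_candidates(select_top(res_m, n_class),
                               select_top(res_w, n_class), bundle$genes,
                               qtl_intervals,
                               select_top(res_m, min(50, nrow(res_m))))
    write_tsv_units(cls, file.path(out_dir, "candidate_classes.tsv"))
    orp <- orphan_peaks(res_m, bundle$genes, qtl_intervals)
    if (!is.null(qtl_intervals))
      write_tsv_units(orp, file.path(out_dir, "orphan_peaks.tsv"),
                      c(pos = "bp (1-based)"))
    results <- c(results, list(enrichment = ladder, classes = cls))
  }

  prov <- list(parameters = cfg[setdiff(names(cfg), "families")],
               seed = cfg$seed,
               package_version = as.character(utils::packageVersion("dualmap")))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
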