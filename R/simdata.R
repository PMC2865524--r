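## Seeded synthetic-data generators: structured accession panels with
## confounded traits, RIL families bred in silico (intercross + single-seed
## descent), field weather/layout with threshold-triggered flowering, and
## candidate-gene annotations. Every generator is a pure function of
## (config, seed) and ships a truth record for downstream recovery tests.

#' Simulation configuration
#'
#' Defaults emulate the study system at desk scale: a structured worldwide
#' panel of 184 accessions, five subpopulations at FST 0.3, five chromosomes
#' with A. thaliana-like physical and genetic lengths, RIL families of ~300
#' lines typed at ~82 markers bred by two intercross generations and six of
#' single-seed descent, and an autumn-sown field season at latitude 50.6 N
#' with three blocks and paired control accessions per array.
#'
#' @param seed Integer seed (mandatory).
#' @param n_accessions,n_snps,n_subpops,fst Panel dimensions and structure.
#' @param n_causal,effect_size Causal SNP count and per-allele effect (trait
#'   SD units).
#' @param h2_polygenic Variance fraction of the kinship-structured polygenic
#'   term.
#' @param confounding_strength Subpopulation mean shift (trait SD units).
#' @param chr_bp,chr_cM Chromosome lengths.
#' @param n_rils,n_markers,intercross_gens,selfing_gens RIL-family design.
#' @param latitude,mean_temp,amplitude,ar1_rho,noise_sd,daylight_offset
#'   Weather model: annual sinusoid (deg C) plus AR(1) noise; daylight mean
#'   is offset above the daily mean; photoperiod from [daylength()].
#' @param n_blocks,array_size Field design.
#' @param threshold_range PTU thresholds assigned to genotypes (range of the
#'   panel's flowering-time variation).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_accessions = 184, n_snps = 5000, n_subpops = 5,
                       fst = 0.3, n_causal = 0, effect_size = 1,
                       h2_polygenic = 0, confounding_strength = 0,
                       chr_bp = c(30.4e6, 19.7e6, 23.5e6, 18.6e6, 27.0e6),
                       chr_cM = c(120, 78, 90, 76, 105),
                       n_rils = 300, n_markers = 82,
                       intercross_gens = 2, selfing_gens = 6,
                       latitude = 50.6, mean_temp = 10, amplitude = 8,
                       ar1_rho = 0.6, noise_sd = 2, daylight_offset = 2,
                       n_blocks = 3, array_size = 24,
                       threshold_range = c(270, 580)) {
  if (missing(seed)) stop("seed is mandatory")
  if (fst <= 0 || fst >= 1) stop("fst must lie in (0, 1)")
  if (h2_polygenic < 0 || h2_polygenic > 1) stop("h2 must lie in [0, 1]")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a structured accession panel (Balding-Nichols)
#'
#' Ancestral allele frequencies are uniform on (0.05, 0.95); subpopulation
#' frequencies follow the Balding-Nichols Beta distribution at the
#' configured FST; inbred homozygous calls are Bernoulli draws. Each
#' subpopulation is assigned a latitude band so latitudinal clines can be
#' injected and recovered.
#'
#' @param cfg A [sim_config()].
#' @return List with `G` (a [genotype_matrix()]), `subpop` (labels),
#'   `latitudes`, `truth`.
#' @export
simulate_panel <- function(cfg) {
  set.seed(cfg$seed)
  m <- cfg$n_snps; n <- cfg$n_accessions; S <- cfg$n_subpops
  F <- cfg$fst
  p_anc <- runif(m, 0.05, 0.95)
  pop_freq <- vapply(seq_len(S), function(s)
    rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F), numeric(m))
  subpop <- sort(rep_len(seq_len(S), n))
  calls <- t(vapply(seq_len(n), function(i)
    rbinom(m, 1, pop_freq[, subpop[i]]), numeric(m)))
  chrom <- sort(rep_len(seq_along(cfg$chr_bp), m))
  pos <- unlist(lapply(seq_along(cfg$chr_bp), function(ch)
    sort(sample.int(cfg$chr_bp[ch], sum(chrom == ch)))))
  snps <- data.frame(id = sprintf("snp%05d", seq_len(m)),
                     chrom = chrom, pos = pos)
  lat_centre <- seq(38, 62, length.out = S)
  latitudes <- lat_centre[subpop] + runif(n, -2, 2)
  G <- genotype_matrix(calls, snps, sprintf("acc%03d", seq_len(n)))
  list(G = G, subpop = subpop, latitudes = latitudes,
       truth = list(seed = cfg$seed, fst = F, pop_freq = pop_freq,
                    p_anc = p_anc, subpop = subpop))
}

#' Simulate a trait on a panel
#'
#' \eqn{y = \sum_k \beta_k g_k + c \cdot shift(subpop) + u + e} with the
#' polygenic term drawn with covariance proportional to the realized IBS
#' kinship and scaled to the target variance fraction, and iid noise of unit
#' variance. Realized variance fractions are recorded in the truth record.
#'
#' @param panel Output of [simulate_panel()].
#' @param cfg A [sim_config()]; `n_causal`, `effect_size`, `h2_polygenic`
#'   and `confounding_strength` drive the architecture.
#' @param causal_ids Optional SNP ids to use as causal loci (overrides the
#'   random draw).
#' @return List with `y` and `truth` (causal ids/effects, realized variance
#'   fractions).
#' @export
simulate_trait <- function(panel, cfg, causal_ids = NULL) {
  set.seed(cfg$seed + 1L)
  G <- panel$G
  n <- nrow(G$calls)
  e <- rnorm(n)
  y <- e
  beta <- numeric(0); ids <- character(0)
  if (!is.null(causal_ids)) {
    ids <- causal_ids
  } else if (cfg$n_causal > 0) {
    ids <- sample(G$snps$id, cfg$n_causal)
  }
  if (length(ids)) {
    j <- match(ids, G$snps$id)
    beta <- rep_len(cfg$effect_size, length(j))
    y <- y + drop(G$calls[, j, drop = FALSE] %*% beta)
  }
  u <- rep(0, n)
  if (cfg$h2_polygenic > 0) {
    K <- ibs_kinship(G)
    L <- chol(K + diag(1e-6, n))
    u <- drop(crossprod(L, rnorm(n)))
    u <- u / sd(u) * sqrt(cfg$h2_polygenic / (1 - cfg$h2_polygenic))
    y <- y + u
  }
  shift <- rep(0, n)
  if (cfg$confounding_strength > 0) {
    shift <- cfg$confounding_strength * scale(panel$subpop)[, 1]
    y <- y + shift
  }
  vt <- var(y)
  truth <- list(causal_ids = ids, effects = beta,
                var_frac_causal = if (length(ids))
                  var(y - e - u - shift) / vt else 0,
                var_frac_polygenic = var(u) / vt,
                var_frac_confounding = var(shift) / vt,
                var_frac_noise = var(e) / vt)
  list(y = y, truth = truth)
}

## --- in-silico breeding -----------------------------------------------

## haplotype: list(starts, alleles); segment i covers [starts[i], starts[i+1])
.hap_const <- function(allele) list(starts = 0, alleles = allele)

.hap_query <- function(h, x) h$alleles[findInterval(x, h$starts)]

## recombine two haplotypes at sorted cut positions, starting from h1
.hap_recombine <- function(h1, h2, cuts, len) {
  if (!length(cuts)) return(h1)
  src <- list(h1, h2)
  cur <- 1L
  starts <- numeric(0); alleles <- numeric(0)
  bounds <- c(0, cuts)
  for (i in seq_along(bounds)) {
    lo <- bounds[i]
    hi <- if (i < length(bounds)) bounds[i + 1] else len
    h <- src[[cur]]
    inside <- h$starts > lo & h$starts < hi
    ss <- c(lo, h$starts[inside])
    aa <- c(.hap_query(h, lo), h$alleles[inside])
    starts <- c(starts, ss); alleles <- c(alleles, aa)
    cur <- 3L - cur
  }
  keep <- c(TRUE, diff(alleles) != 0)
  list(starts = starts[keep], alleles = alleles[keep])
}

## one gamete from a diploid (pair of haplotypes) on a chromosome of len cM
.gamete <- function(pair, len) {
  nco <- rpois(1, len / 100)
  first <- sample.int(2, 1)
  if (!nco) return(pair[[first]])
  cuts <- sort(runif(nco, 0, len))
  .hap_recombine(pair[[first]], pair[[3 - first]], cuts, len)
}

#' Breed a RIL family in silico and emit its marker data
#'
#' Starting from the F1 of two fully homozygous parents (A carries allele 1
#' everywhere, B allele 0), performs the configured intercross generations
#' (random mating within the family) followed by single-seed descent, with
#' crossovers Poisson in map length and uniform in cM (Haldane, no
#' interference). Marker genotypes are read off at equally spaced markers;
#' the genetic map handed to mapping is re-estimated from the simulated
#' recombinant fractions (inverse Haldane on RIL-expanded fractions), so
#' scan and simulation are internally consistent. The phenotype sums the
#' configured QTL effects (coded -a/+a for B/A homozygotes, 0 for residual
#' heterozygotes) plus Gaussian noise scaled to the target heritability.
#'
#' @param cfg A [sim_config()].
#' @param qtl Data frame `chrom`, `cM`, `effect` (additive effect `a` of the
#'   A allele, trait units); may be empty for a null family.
#' @param h2 Target broad-sense heritability of the line means (ignored if
#'   no QTL; then `noise_sd` is 1).
#' @param family_id Label.
#' @return List with `family` (a [ril_family()]), `truth` (true QTL
#'   positions/effects in estimated-map coordinates and bp, realized h2,
#'   true map).
#' @export
simulate_ril_family <- function(cfg, qtl = NULL, h2 = 0.8,
                                family_id = "fam1") {
  set.seed(cfg$seed + 2L)
  n_chr <- length(cfg$chr_cM)
  n <- cfg$n_rils
  mk_per_chr <- rep_len(ceiling(cfg$n_markers / n_chr), n_chr)
  marker_cM <- lapply(seq_len(n_chr), function(ch)
    seq(0, cfg$chr_cM[ch], length.out = mk_per_chr[ch]))

  ## population: list of individuals; individual = list over chromosomes of
  ## haplotype pairs
  f1 <- lapply(seq_len(n_chr), function(ch)
    list(.hap_const(1), .hap_const(0)))
  pop <- rep(list(f1), n)
  for (g in seq_len(cfg$intercross_gens)) {
    pop <- lapply(seq_len(n), function(i) {
      par <- sample.int(n, 2)
      lapply(seq_len(n_chr), function(ch)
        list(.gamete(pop[[par[1]]][[ch]], cfg$chr_cM[ch]),
             .gamete(pop[[par[2]]][[ch]], cfg$chr_cM[ch])))
    })
  }
  for (g in seq_len(cfg$selfing_gens)) {
    pop <- lapply(pop, function(ind)
      lapply(seq_len(n_chr), function(ch)
        list(.gamete(ind[[ch]], cfg$chr_cM[ch]),
             .gamete(ind[[ch]], cfg$chr_cM[ch]))))
  }

  ## marker genotypes
  geno <- do.call(cbind, lapply(seq_len(n_chr), function(ch) {
    t(vapply(pop, function(ind) {
      a1 <- .hap_query(ind[[ch]][[1]], marker_cM[[ch]])
      a2 <- .hap_query(ind[[ch]][[2]], marker_cM[[ch]])
      ifelse(a1 + a2 == 2, "A", ifelse(a1 + a2 == 0, "B", "H"))
    }, character(length(marker_cM[[ch]]))))
  }))
  n_mark <- vapply(marker_cM, length, integer(1))
  marker_chrom <- rep(seq_len(n_chr), n_mark)
  marker_names <- sprintf("m%d_%02d", marker_chrom,
                          unlist(lapply(n_mark, seq_len)))
  colnames(geno) <- marker_names

  ## re-estimate the genetic map from observed recombinant fractions
  num <- matrix(NA_real_, n, ncol(geno))
  num[geno == "A"] <- 1; num[geno == "B"] <- 0
  est_cM <- unlist(lapply(seq_len(n_chr), function(ch) {
    idx <- which(marker_chrom == ch)
    d <- vapply(seq_len(length(idx) - 1), function(k) {
      a <- num[, idx[k]]; b <- num[, idx[k + 1]]
      ok <- !is.na(a) & !is.na(b)
      .inverse_ril_map(mean(a[ok] != b[ok]))
    }, numeric(1))
    cumsum(c(0, d))
  }))
  bp <- unlist(lapply(seq_len(n_chr), function(ch)
    round(seq(1, cfg$chr_bp[ch], length.out = n_mark[ch]))))
  map <- data.frame(marker = marker_names, chrom = marker_chrom,
                    cM = est_cM, bp = bp)

  ## phenotype from QTL genotype scores
  gvals <- rep(0, n)
  if (!is.null(qtl) && nrow(qtl)) {
    for (k in seq_len(nrow(qtl))) {
      ch <- qtl$chrom[k]
      x <- vapply(pop, function(ind)
        .hap_query(ind[[ch]][[1]], qtl$cM[k]) +
          .hap_query(ind[[ch]][[2]], qtl$cM[k]) - 1, numeric(1))
      gvals <- gvals + qtl$effect[k] * x
    }
  }
  vg <- var(gvals)
  noise_sd <- if (vg > 0) sqrt(vg * (1 - h2) / h2) else 1
  pheno <- gvals + rnorm(n, 0, noise_sd)

  ## project true QTL cM (true map) onto the estimated map per chromosome
  truth_qtl <- NULL
  if (!is.null(qtl) && nrow(qtl)) {
    truth_qtl <- qtl
    truth_qtl$cM_est <- vapply(seq_len(nrow(qtl)), function(k) {
      ch <- qtl$chrom[k]
      approx(marker_cM[[ch]], est_cM[marker_chrom == ch],
             xout = qtl$cM[k], rule = 2)$y
    }, numeric(1))
    truth_qtl$bp <- vapply(seq_len(nrow(qtl)), function(k) {
      ch <- qtl$chrom[k]
      approx(marker_cM[[ch]], bp[marker_chrom == ch],
             xout = qtl$cM[k], rule = 2)$y
    }, numeric(1))
  }
  fam <- ril_family(geno, map, pheno, family_id = family_id,
                    parents = c("A", "B"), recurrent_parent = "A")
  list(family = fam,
       truth = list(qtl = truth_qtl, h2_target = h2,
                    h2_realized = if (vg > 0) vg / var(pheno) else 0,
                    noise_sd = noise_sd,
                    true_map = data.frame(marker = marker_names,
                                          chrom = marker_chrom,
                                          cM = unlist(marker_cM), bp = bp)))
}

#' Simulate field weather and the experimental layout
#'
#' Daily mean temperature is an annual sinusoid (coldest in mid January)
#' plus AR(1) noise; daylight mean adds a fixed offset; photoperiod comes
#' from [daylength()] at the configured latitude. Each genotype receives a
#' PTU threshold and flowers on the first day its accumulated PTU reaches
#' it. The layout replicates genotypes across blocks and arrays, injecting
#' block and array effects into the measured trait; each array carries the
#' two control accessions whose observed values become the array covariates.
#'
#' @param cfg A [sim_config()].
#' @param genotype_ids Genotypes to lay out (default 20 synthetic ids).
#' @param block_effects Per-block additive shifts (PTU); length `n_blocks`.
#' @param array_sd,plant_sd SDs of array effects and plant-level noise (PTU).
#' @param sow_date Germination date (common to all plants).
#' @param season_days Length of the simulated weather series.
#' @return List with `weather` (a [weather_series()]), `plants` (phenotype
#'   table: `genotype_id`, `block`, `array_id`, `germination_date`,
#'   `flowering_date`, `trait_ptu`, `control_cov_bg2`, `control_cov_lov5`),
#'   `truth` (thresholds, effects).
#' @export
simulate_weather_and_layout <- function(cfg, genotype_ids = sprintf("g%02d", 1:20),
                                        block_effects = rep(0, cfg$n_blocks),
                                        array_sd = 0, plant_sd = 0,
                                        sow_date = as.Date("2007-10-15"),
                                        season_days = 330) {
  set.seed(cfg$seed + 3L)
  dates <- sow_date + 0:(season_days - 1)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- cfg$mean_temp - cfg$amplitude * cos(2 * pi * (doy - 15) / 365.25)
  ar <- as.numeric(stats::filter(rnorm(season_days, 0, cfg$noise_sd),
                          cfg$ar1_rho, method = "recursive"))
  tmean <- seasonal + ar
  weather <- weather_series(dates, tmean, tmean + cfg$daylight_offset,
                            latitude = cfg$latitude)

  ## daily PTU increments and the first day each threshold is reached
  params <- phenology_params()
  inc <- ifelse(weather$tmean > params$gating_temp,
                pmax(0, weather$tmean_daylight - params$base_temp) *
                  weather$photoperiod_hours / 24, 0)
  cum <- cumsum(inc)
  thr <- runif(length(genotype_ids), cfg$threshold_range[1],
               min(cfg$threshold_range[2], max(cum) * 0.95))
  names(thr) <- genotype_ids
  flower_idx <- vapply(thr, function(t) which(cum >= t)[1], integer(1))

  rows <- list(); z <- 0
  controls <- c("Bg-2", "Lov-5")
  ctrl_thr <- setNames(runif(2, cfg$threshold_range[1], cfg$threshold_range[2]),
                       controls)
  for (b in seq_len(cfg$n_blocks)) {
    ids <- sample(genotype_ids)  # randomised within block
    n_arrays <- ceiling(length(ids) / cfg$array_size)
    arr <- rep(seq_len(n_arrays), each = cfg$array_size)[seq_along(ids)]
    for (a in seq_len(n_arrays)) {
      arr_eff <- rnorm(1, 0, array_sd)
      aid <- sprintf("b%d_a%d", b, a)
      cov_vals <- ctrl_thr + block_effects[b] + arr_eff +
        rnorm(2, 0, plant_sd)
      for (g in ids[arr == a]) {
        z <- z + 1
        rows[[z]] <- data.frame(
          genotype_id = g, block = b, array_id = aid,
          germination_date = sow_date,
          flowering_date = dates[flower_idx[g]],
          trait_ptu = thr[g] + block_effects[b] + arr_eff +
            rnorm(1, 0, plant_sd),
          control_cov_bg2 = cov_vals[1], control_cov_lov5 = cov_vals[2])
      }
    }
  }
  plants <- do.call(rbind, rows)
  rownames(plants) <- NULL
  list(weather = weather, plants = plants,
       truth = list(thresholds = thr, block_effects = block_effects,
                    control_thresholds = ctrl_thr))
}

#' Simulate a candidate-gene annotation
#'
#' Places decoy genes uniformly along the genome and, for a configurable
#' fraction of the causal SNPs, adds a gene containing the SNP, making
#' candidate-gene enrichment detectable downstream.
#'
#' @param cfg A [sim_config()].
#' @param snps SNP table (`id`, `chrom`, `pos`) of the panel.
#' @param causal_ids Causal SNP ids (possibly empty).
#' @param n_genes Total number of genes.
#' @param frac_causal_in_genes Fraction of causal SNPs that get a covering
#'   gene.
#' @param gene_bp Gene length (bp).
#' @return A [gene_windows()] set (20 kb windows).
#' @export
simulate_gene_annotation <- function(cfg, snps, causal_ids = character(0),
                                     n_genes = 100,
                                     frac_causal_in_genes = 1,
                                     gene_bp = 3000) {
  set.seed(cfg$seed + 4L)
  n_chr <- length(cfg$chr_bp)
  chrom <- sample.int(n_chr, n_genes, replace = TRUE,
                      prob = cfg$chr_bp / sum(cfg$chr_bp))
  start <- vapply(chrom, function(ch)
    sample.int(cfg$chr_bp[ch] - gene_bp, 1), integer(1))
  genes <- data.frame(gene_id = sprintf("gene%03d", seq_len(n_genes)),
                      chrom = chrom, start = start, end = start + gene_bp)
  n_cov <- round(frac_causal_in_genes * length(causal_ids))
  if (n_cov > 0) {
    cov_ids <- causal_ids[seq_len(n_cov)]
    j <- match(cov_ids, snps$id)
    repl <- seq_len(n_cov)  # first decoys become causal-covering genes
    genes$chrom[repl] <- snps$chrom[j]
    genes$start[repl] <- pmax(1, snps$pos[j] - round(gene_bp / 2))
    genes$end[repl] <- genes$start[repl] + gene_bp
  }
  gene_windows(genes[order(genes$chrom, genes$start), ])
}
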