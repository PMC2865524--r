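## Integration of GWA and QTL maps: candidate-gene windows, SNP annotation,
## enrichment of top SNPs with a resampled null, per-gene classification,
## orphan association peaks, and in/out-QTL p-value contrasts.

#' Build candidate-gene windows
#'
#' Extends each gene interval by a symmetric window (default 20 kb, a
#' conservative span given that linkage disequilibrium in selfing
#' A. thaliana decays over roughly 10 kb), clipped at position 1. Strand is
#' ignored; coordinates are 1-based inclusive.
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @param window_bp Window half-width in bp.
#' @return The input with `win_start`, `win_end` columns, class
#'   `gene_windows`.
#' @export
gene_windows <- function(genes, window_bp = 20000) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$end < genes$start)) stop("gene end precedes start")
  genes$win_start <- pmax(1, genes$start - window_bp)
  genes$win_end <- genes$end + window_bp
  class(genes) <- c("gene_windows", "data.frame")
  genes
}

## distance from position to a 1-based inclusive interval (0 if inside)
.interval_dist <- function(pos, lo, hi) {
  pmax(0, pmax(lo - pos, pos - hi))
}

#' Annotate SNPs with candidate-window and QTL-interval membership
#'
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos`.
#' @param windows A [gene_windows()] set (may be `NULL`).
#' @param qtl_intervals Data frame `family`, `chrom`, `lo_bp`, `hi_bp`
#'   (may be `NULL`). Intervals are pooled across families for the `in_qtl`
#'   flag; per-family ids are retained.
#' @return The input plus `near_candidate`, `in_qtl`, `both`, `nearest_gene`
#'   (gene whose interval is closest among covering windows), `qtl_families`
#'   (comma-separated ids). Membership is inclusive of endpoints.
#' @export
annotate_snps <- function(snps, windows = NULL, qtl_intervals = NULL) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)))
  n <- nrow(snps)
  near <- logical(n); nearest <- rep(NA_character_, n)
  if (!is.null(windows) && nrow(windows)) {
    unknown <- setdiff(windows$chrom, snps$chrom)
    for (ch in unique(windows$chrom)) {
      w <- windows[windows$chrom == ch, ]
      i <- which(snps$chrom == ch)
      if (!length(i)) next
      for (k in seq_len(nrow(w))) {
        hit <- i[snps$pos[i] >= w$win_start[k] & snps$pos[i] <= w$win_end[k]]
        if (!length(hit)) next
        d_new <- .interval_dist(snps$pos[hit], w$start[k], w$end[k])
        d_old <- ifelse(is.na(nearest[hit]), Inf, vapply(seq_along(hit),
          function(z) {
            g <- windows[windows$gene_id == nearest[hit[z]], ][1, ]
            .interval_dist(snps$pos[hit[z]], g$start, g$end)
          }, numeric(1)))
        upd <- d_new < d_old
        nearest[hit[upd]] <- w$gene_id[k]
        near[hit] <- TRUE
      }
    }
  }
  inq <- logical(n); fams <- rep("", n)
  if (!is.null(qtl_intervals) && nrow(qtl_intervals)) {
    bad <- setdiff(qtl_intervals$chrom, unique(snps$chrom))
    if (length(bad))
      stop("QTL intervals on chromosomes absent from the SNP set: ",
           paste(bad, collapse = ", "))
    for (k in seq_len(nrow(qtl_intervals))) {
      q <- qtl_intervals[k, ]
      hit <- snps$chrom == q$chrom & snps$pos >= q$lo_bp & snps$pos <= q$hi_bp
      inq <- inq | hit
      fams[hit] <- ifelse(fams[hit] == "", as.character(q$family),
                          paste(fams[hit], q$family, sep = ","))
    }
  }
  out <- snps
  out$near_candidate <- near
  out$in_qtl <- inq
  out$both <- near & inq
  out$nearest_gene <- nearest
  out$qtl_families <- fams
  out
}

#' Select the top-N SNPs of an association scan
#'
#' @param res An `association_result`.
#' @param N Top-set size, `0 < N <=` SNP count.
#' @return The N rows with smallest p, ties broken by `(chrom, pos)` for
#'   determinism, ordered by increasing p.
#' @export
select_top <- function(res, N) {
  if (N <= 0) stop("N must be positive")
  if (N > nrow(res)) stop("N exceeds the number of SNPs")
  ord <- order(res$p, res$chrom, res$pos)
  res[ord[seq_len(N)], , drop = FALSE]
}

.flag_col <- function(ann, flag) {
  switch(flag,
         qtl = ann$in_qtl,
         candidate = ann$near_candidate,
         both = ann$both,
         stop("unknown flag: ", flag))
}

#' Enrichment ratio of a flag among top SNPs
#'
#' @param top,background Annotated SNP sets (see [annotate_snps()]); the
#'   background is the full tested SNP universe.
#' @param flag One of `"qtl"`, `"candidate"`, `"both"`.
#' @return Ratio of the flagged fraction in `top` to that in `background`.
#' @export
enrichment_ratio <- function(top, background, flag) {
  bg <- mean(.flag_col(background, flag))
  if (bg == 0) stop("background fraction for flag '", flag,
                    "' is zero: enrichment undefined")
  mean(.flag_col(top, flag)) / bg
}

#' Resampled null distribution of the enrichment ratio
#'
#' Draws `B` random top-sets of size `N` uniformly without replacement from
#' the background and recomputes the enrichment ratio for each, giving the
#' null mean and central 95% interval of enrichment under no association.
#'
#' @param background Annotated SNP set.
#' @param N Top-set size (<= background size).
#' @param flag One of `"qtl"`, `"candidate"`, `"both"`.
#' @param B Number of draws.
#' @param seed Integer seed.
#' @return List with `null_mean`, `ci` (2.5 and 97.5 percentiles), `B`,
#'   `seed`, `draws`.
#' @export
enrichment_null <- function(background, N, flag, B = 1000, seed) {
  m <- nrow(background)
  if (N > m) stop("N exceeds the background size")
  fl <- .flag_col(background, flag)
  bg_frac <- mean(fl)
  if (bg_frac == 0) stop("background fraction is zero: enrichment undefined")
  set.seed(seed)
  draws <- vapply(seq_len(B), function(b)
    mean(fl[sample.int(m, N)]) / bg_frac, numeric(1))
  list(null_mean = mean(draws),
       ci = unname(quantile(draws, c(0.025, 0.975), type = 7)),
       B = B, seed = seed, draws = draws)
}

#' Enrichment ladder over progressively more selective top-SNP sets
#'
#' For each top-set size and flag, the observed enrichment ratio, the
#' resampled null mean and 95% interval, and a significance mark when the
#' observed ratio falls outside the interval.
#'
#' @param res An `association_result`.
#' @param annotations Output of [annotate_snps()] on the same SNP universe.
#' @param Ns Ladder of top-set sizes (sorted descending internally).
#' @param flags Flags to evaluate.
#' @param B Null draws per cell.
#' @param seed Integer seed (each cell derives its own stream).
#' @return Data frame: `N`, `flag`, `observed`, `null_mean`, `ci_lo`,
#'   `ci_hi`, `significant`.
#' @export
enrichment_ladder <- function(res, annotations,
                              Ns = c(3000, 2000, 1000, 500, 400, 300, 200, 100, 50),
                              flags = c("qtl", "candidate", "both"),
                              B = 1000, seed = 1) {
  if (max(Ns) > nrow(res)) stop("largest top-set exceeds the SNP count")
  Ns <- sort(unique(Ns), decreasing = TRUE)
  akey <- paste(annotations$chrom, annotations$pos)
  empty <- vapply(flags, function(fl) !any(.flag_col(annotations, fl)),
                  logical(1))
  if (any(empty)) {
    warning("no background SNP carries flag(s) ",
            paste(flags[empty], collapse = ", "), "; skipped")
    flags <- flags[!empty]
  }
  rows <- list(); z <- 0
  for (N in Ns) {
    top <- select_top(res, N)
    top_ann <- annotations[match(paste(top$chrom, top$pos), akey), ]
    for (fl in flags) {
      z <- z + 1
      obs <- enrichment_ratio(top_ann, annotations, fl)
      nul <- enrichment_null(annotations, N, fl, B = B, seed = seed + z)
      rows[[z]] <- data.frame(N = N, flag = fl, observed = obs,
                              null_mean = nul$null_mean,
                              ci_lo = nul$ci[1], ci_hi = nul$ci[2],
                              significant = obs < nul$ci[1] | obs > nul$ci[2])
    }
  }
  do.call(rbind, rows)
}

#' Rank contrast of association p-values inside versus outside QTL intervals
#'
#' Kruskal-Wallis test (two groups) of scan p-values for SNPs inside the
#' pooled QTL confidence intervals against those outside.
#'
#' @param res An `association_result`.
#' @param qtl_intervals Data frame `family`, `chrom`, `lo_bp`, `hi_bp`.
#' @return List with `kw_stat`, `p`, `n_in`, `n_out`, `median_in`,
#'   `median_out`.
#' @export
pvalue_in_out_qtl <- function(res, qtl_intervals) {
  ann <- annotate_snps(res[, c("snp_id", "chrom", "pos")],
                       qtl_intervals = qtl_intervals)
  if (!any(ann$in_qtl) || all(ann$in_qtl))
    stop("need SNPs both inside and outside QTL intervals")
  kw <- kruskal.test(res$p, factor(ann$in_qtl))
  list(kw_stat = unname(kw$statistic), p = kw$p.value,
       n_in = sum(ann$in_qtl), n_out = sum(!ann$in_qtl),
       median_in = median(res$p[ann$in_qtl]),
       median_out = median(res$p[!ann$in_qtl]))
}

#' Classify candidate genes by dual-mapping support
#'
#' A gene is "detected" by a method when any of that method's top SNPs lies
#' within the gene's window; it is QTL-overlapped when the gene interval
#' intersects any family's confidence interval. Classes follow the
#' dual-mapping logic: `confirmed` (both methods + QTL), `emma_only_qtl`,
#' `wilcoxon_only_qtl` (potential mixed-model false negatives), `no_qtl`
#' (detected but unsupported, potential false positives), `undetected`.
#'
#' @param top_emma,top_wilcoxon Top SNP sets (rows of the scan results,
#'   typically the top 500 of each method over the same filtered universe).
#' @param windows A [gene_windows()] set.
#' @param qtl_intervals Data frame `family`, `chrom`, `lo_bp`, `hi_bp`.
#' @param top50_emma Optional more-stringent top set used for a `top50` mark.
#' @return Data frame per gene: `gene_id`, `detected_emma`,
#'   `detected_wilcoxon`, `qtl_overlap`, `qtl_families`, `top50`, `class`.
#' @export
classify_candidates <- function(top_emma, top_wilcoxon, windows,
                                qtl_intervals, top50_emma = NULL) {
  hit_genes <- function(top) {
    if (is.null(top) || !nrow(top)) return(character(0))
    hits <- character(0)
    for (k in seq_len(nrow(windows))) {
      w <- windows[k, ]
      if (any(top$chrom == w$chrom & top$pos >= w$win_start &
                top$pos <= w$win_end))
        hits <- c(hits, w$gene_id)
    }
    hits
  }
  e_hits <- hit_genes(top_emma)
  w_hits <- hit_genes(top_wilcoxon)
  t50 <- hit_genes(top50_emma)
  out <- lapply(seq_len(nrow(windows)), function(k) {
    g <- windows[k, ]
    fams <- character(0)
    if (!is.null(qtl_intervals) && nrow(qtl_intervals)) {
      ov <- qtl_intervals$chrom == g$chrom &
        qtl_intervals$hi_bp >= g$start & qtl_intervals$lo_bp <= g$end
      fams <- unique(as.character(qtl_intervals$family[ov]))
    }
    de <- g$gene_id %in% e_hits
    dw <- g$gene_id %in% w_hits
    qo <- length(fams) > 0
    cls <- if (de && dw && qo) "confirmed"
    else if (de && qo) "emma_only_qtl"
    else if (dw && qo) "wilcoxon_only_qtl"
    else if (de || dw) "no_qtl"
    else "undetected"
    data.frame(gene_id = g$gene_id, detected_emma = de,
               detected_wilcoxon = dw, qtl_overlap = qo,
               qtl_families = paste(fams, collapse = ","),
               top50 = g$gene_id %in% t50, class = cls)
  })
  do.call(rbind, out)
}

#' Orphan association peaks inside QTL intervals
#'
#' Association peaks supported by a QTL but with no candidate gene within
#' `window_bp` of the top SNP: among the `rank_cut` best SNPs, those inside
#' pooled QTL intervals and farther than `window_bp` from every candidate
#' gene interval are greedily grouped into peaks at least `merge_bp` apart
#' (closer hits merge into the stronger peak).
#'
#' @param res An `association_result`.
#' @param windows A [gene_windows()] set (gene bodies are used for the
#'   distance rule; may be `NULL` for none).
#' @param qtl_intervals Data frame `family`, `chrom`, `lo_bp`, `hi_bp`.
#' @param rank_cut Number of top SNPs examined.
#' @param window_bp Candidate-free radius around the top SNP.
#' @param merge_bp Minimum spacing between reported peaks.
#' @return Data frame of peaks: `snp_id`, `chrom`, `pos`, `p`.
#' @export
orphan_peaks <- function(res, windows, qtl_intervals, rank_cut = 500,
                         window_bp = 20000, merge_bp = 100000) {
  top <- select_top(res, min(rank_cut, nrow(res)))
  ann <- annotate_snps(top[, c("snp_id", "chrom", "pos")],
                       qtl_intervals = qtl_intervals)
  cand <- top[ann$in_qtl, , drop = FALSE]
  if (!is.null(windows) && nrow(windows) && nrow(cand)) {
    far <- vapply(seq_len(nrow(cand)), function(i) {
      w <- windows[windows$chrom == cand$chrom[i], ]
      if (!nrow(w)) return(TRUE)
      all(.interval_dist(cand$pos[i], w$start, w$end) > window_bp)
    }, logical(1))
    cand <- cand[far, , drop = FALSE]
  }
  if (!nrow(cand))
    return(data.frame(snp_id = character(0), chrom = character(0),
                      pos = numeric(0), p = numeric(0)))
  cand <- cand[order(cand$p, cand$chrom, cand$pos), ]
  peaks <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    if (!nrow(peaks) ||
        all(peaks$chrom != cand$chrom[i] |
              abs(peaks$pos - cand$pos[i]) >= merge_bp))
      peaks <- rbind(peaks, cand[i, ])
  }
  rownames(peaks) <- NULL
  peaks[, c("snp_id", "chrom", "pos", "p")]
}
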