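## QTL mapping in RIL families: map algebra, conditional genotype
## probabilities, Haley-Knott interval scan, permutation thresholds,
## forward multi-QTL model, epistasis scan, genetic->physical projection.

#' Map functions for selfing-derived RILs
#'
#' Haldane recombination fraction for a map distance and its expansion to
#' the recombinant fraction observed between fixed RIL genotypes:
#' \eqn{r = 0.5(1 - e^{-2d/100})} and \eqn{R = 2r/(1 + 2r)}.
#'
#' @param d_cM Map distance in centimorgans, >= 0.
#' @return List with `r` and `R_ril`, each the length of `d_cM`.
#' @export
map_functions <- function(d_cM) {
  if (any(d_cM < 0)) stop("map distance must be non-negative")
  r <- 0.5 * (1 - exp(-2 * d_cM / 100))
  list(r = r, R_ril = 2 * r / (1 + 2 * r))
}

## Inverse of the RIL expansion + Haldane: observed fraction R -> cM.
.inverse_ril_map <- function(R) {
  R <- pmin(R, 0.4999)
  r <- R / (2 - 2 * R)
  -50 * log(1 - 2 * r)
}

#' Construct a marker map
#'
#' @param map Data frame with columns `marker`, `chrom`, `cM`, `bp`. Within
#'   each chromosome `cM` must be non-decreasing and `bp` strictly
#'   increasing (co-monotone genetic and physical orders).
#' @return The validated data frame, class `marker_map`.
#' @export
marker_map <- function(map) {
  stopifnot(all(c("marker", "chrom", "cM", "bp") %in% names(map)))
  for (ch in unique(map$chrom)) {
    m <- map[map$chrom == ch, ]
    if (any(diff(m$cM) < 0))
      stop("cM positions decrease within chromosome ", ch)
    if (any(diff(m$bp) <= 0))
      stop("bp positions must strictly increase within chromosome ", ch)
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Construct a RIL family
#'
#' @param geno Character matrix, lines x markers, calls in `A`/`B`/`H`/`NA`.
#'   `A` is the recurrent-parent allele. Heterozygous calls (residual after
#'   selfing) are treated as missing.
#' @param map A [marker_map()] whose markers match `colnames(geno)`.
#' @param phenotype Per-line trait values (PTU LS means); `NA` allowed.
#' @param family_id,parents,recurrent_parent Identifiers carried through to
#'   reports.
#' @return List of class `ril_family` with `prob_A` (numeric A-allele
#'   indicator, `NA` for missing/het), `map`, `phenotype`, ids.
#' @export
ril_family <- function(geno, map, phenotype, family_id = "fam",
                       parents = c("A", "B"), recurrent_parent = "A") {
  map <- marker_map(as.data.frame(map))
  geno <- as.matrix(geno)
  if (!all(colnames(geno) == map$marker))
    stop("genotype columns must match map markers in order")
  if (nrow(geno) != length(phenotype))
    stop("phenotype length must equal line count")
  bad <- !(geno %in% c("A", "B", "H") | is.na(geno))
  if (any(bad)) stop("genotype calls must be A/B/H/NA")
  num <- matrix(NA_real_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  num[geno == "A"] <- 1
  num[geno == "B"] <- 0
  structure(list(prob_A = num, map = map, phenotype = as.numeric(phenotype),
                 family_id = family_id, parents = parents,
                 recurrent_parent = recurrent_parent),
            class = "ril_family")
}

#' Conditional A-genotype probabilities at arbitrary map positions
#'
#' For each line, the probability of carrying the A (recurrent-parent)
#' genotype at each query position, conditional on the nearest informative
#' flanking markers, using RIL-expanded Haldane transition probabilities.
#' At a typed marker the probability is 0 or 1; with no informative flank
#' the prior 0.5 is returned. Positions outside the map are clamped to the
#' terminal markers with a warning.
#'
#' @param family A [ril_family()].
#' @param chrom Chromosome id.
#' @param positions_cM Numeric vector of query positions.
#' @return Matrix lines x positions of P(A).
#' @export
genotype_probs <- function(family, chrom, positions_cM) {
  sel <- family$map$chrom == chrom
  if (!any(sel)) stop("unknown chromosome: ", chrom)
  mcm <- family$map$cM[sel]
  span <- range(mcm)
  if (any(positions_cM < span[1] - 1e-9 | positions_cM > span[2] + 1e-9))
    warning("positions outside the map span clamped to terminal markers")
  pos <- pmin(pmax(positions_cM, span[1]), span[2])
  calls <- family$prob_A[, sel, drop = FALSE]
  n <- nrow(calls)
  out <- matrix(0.5, n, length(pos))
  for (i in seq_len(n)) {
    typed <- which(!is.na(calls[i, ]))
    if (!length(typed)) next
    tm <- mcm[typed]
    tv <- calls[i, typed]           # 1 = A, 0 = B
    li <- findInterval(pos, tm)     # left typed flank (0 = none)
    ri <- li + 1L                   # right typed flank
    hasL <- li >= 1L
    hasR <- ri <= length(tm)
    pLA <- rep(0.5, length(pos)); pRA <- rep(0.5, length(pos))
    if (any(hasL)) {
      tL <- map_functions(pos[hasL] - tm[li[hasL]])$R_ril
      pLA[hasL] <- ifelse(tv[li[hasL]] == 1, 1 - tL, tL)
    }
    if (any(hasR)) {
      tR <- map_functions(tm[ri[hasR]] - pos[hasR])$R_ril
      pRA[hasR] <- ifelse(tv[ri[hasR]] == 1, 1 - tR, tR)
    }
    num <- pLA * pRA
    den <- num + (1 - pLA) * (1 - pRA)
    out[i, ] <- ifelse(den > 0, num / den, 0.5)
  }
  out
}

## Scan grid and P(A) design for a family; shared by scan/permutations.
.scan_grid <- function(family, step_cM) {
  chroms <- unique(family$map$chrom)
  grid <- do.call(rbind, lapply(chroms, function(ch) {
    span <- range(family$map$cM[family$map$chrom == ch])
    cm <- unique(c(seq(span[1], span[2], by = step_cM), span[2]))
    data.frame(chrom = ch, cM = cm)
  }))
  keep <- !is.na(family$phenotype)
  P <- do.call(cbind, lapply(chroms, function(ch)
    genotype_probs(family, ch, grid$cM[grid$chrom == ch])))
  list(grid = grid, P = P[keep, , drop = FALSE],
       y = family$phenotype[keep])
}

## Haley-Knott LOD for every column of P against every column of Y,
## optionally conditioning on cofactor columns C (residualised out first).
.hk_lod <- function(P, Y, C = NULL) {
  n <- nrow(P)
  Y <- as.matrix(Y)
  if (!is.null(C)) {
    C1 <- cbind(1, C)
    qC <- qr(C1)
    Y <- qr.resid(qC, Y)
    P <- qr.resid(qC, P)
  } else {
    Y <- sweep(Y, 2, colMeans(Y))
    P <- sweep(P, 2, colMeans(P))
  }
  syy <- colSums(Y^2)
  sxx <- colSums(P^2)
  sxy <- crossprod(P, Y)                  # npos x nperm
  prop <- sxy^2 / outer(pmax(sxx, 1e-12), syy)
  prop[sxx < 1e-10, ] <- 0
  (n / 2) * (-log10(1 - pmin(prop, 1 - 1e-12)))
}

#' Single-QTL Haley-Knott genome scan
#'
#' Regresses the phenotype on the expected A-genotype dosage at each grid
#' position; \eqn{LOD = (n/2)\log_{10}(RSS_0/RSS_1)}.
#'
#' @param family A [ril_family()] with >= 30 phenotyped lines (smaller
#'   families are scanned with a warning).
#' @param step_cM Grid step (walk speed), default 0.5 cM; 0.1 supported but
#'   slower.
#' @return Data frame of class `qtl_scan`: `chrom`, `cM`, `lod`; attribute
#'   `n` = phenotyped lines.
#' @export
interval_scan <- function(family, step_cM = 0.5) {
  sg <- .scan_grid(family, step_cM)
  if (length(sg$y) < 30)
    warning("fewer than 30 phenotyped lines; scan may be unreliable")
  if (all(apply(sg$P, 2, function(x) var(x) < 1e-12)))
    warning("no segregating marker information: LOD is identically zero")
  lod <- drop(.hk_lod(sg$P, sg$y))
  scan <- data.frame(chrom = sg$grid$chrom, cM = sg$grid$cM, lod = lod)
  attr(scan, "n") <- length(sg$y)
  attr(scan, "step_cM") <- step_cM
  class(scan) <- c("qtl_scan", "data.frame")
  scan
}

#' Genome-wide LOD threshold by phenotype permutation
#'
#' Permutes phenotypes against whole genotype rows (preserving marker LD),
#' rescans, and returns the `1 - alpha` quantile of the genome-wide maximum
#' LOD.
#'
#' @param family A [ril_family()].
#' @param n_perm Number of permutations (>= 100; >= 1000 recommended for
#'   final thresholds).
#' @param alpha Genome-wide type-I error rate.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param step_cM Grid step.
#' @return Threshold LOD (scalar) with attribute `max_lods`.
#' @export
permutation_threshold <- function(family, n_perm = 1000, alpha = 0.05, seed,
                                  step_cM = 0.5) {
  if (n_perm < 100) stop("use at least 100 permutations")
  sg <- .scan_grid(family, step_cM)
  set.seed(seed)
  n <- length(sg$y)
  Y <- vapply(seq_len(n_perm), function(b) sg$y[sample.int(n)], numeric(n))
  lods <- .hk_lod(sg$P, Y)
  max_lods <- apply(lods, 2, max)
  thr <- unname(quantile(max_lods, 1 - alpha, type = 7))
  attr(thr, "max_lods") <- max_lods
  thr
}

#' LOD-drop support interval around a scan peak
#'
#' Widest contiguous grid interval around the peak whose LOD stays within
#' `lod_drop` of the peak LOD, extended by one grid point on each side.
#'
#' @param scan A `qtl_scan` (or any data frame with `chrom`, `cM`, `lod`).
#' @param chrom,peak_cM Peak location (must lie on the scan grid).
#' @param lod_drop LOD drop defining the interval; default 1.5.
#' @return Numeric `c(lo, hi)` in cM.
#' @export
support_interval <- function(scan, chrom, peak_cM, lod_drop = 1.5) {
  s <- scan[scan$chrom == chrom, ]
  i <- which.min(abs(s$cM - peak_cM))
  if (abs(s$cM[i] - peak_cM) > 1e-6) stop("peak is not on the scan grid")
  keep <- s$lod >= s$lod[i] - lod_drop
  lo <- i; hi <- i
  while (lo > 1 && keep[lo - 1]) lo <- lo - 1
  while (hi < nrow(s) && keep[hi + 1]) hi <- hi + 1
  c(s$cM[max(1, lo - 1)], s$cM[min(nrow(s), hi + 1)])
}

#' Project a genetic interval onto physical coordinates
#'
#' Piecewise-linear interpolation of cM to bp between flanking mapped
#' markers; endpoints beyond the map clamp to the terminal markers.
#'
#' @param map A [marker_map()].
#' @param chrom Chromosome id.
#' @param interval_cM Numeric vector of cM positions (often `c(lo, hi)`).
#' @return bp positions, same length.
#' @export
project_cm_to_bp <- function(map, chrom, interval_cM) {
  m <- map[map$chrom == chrom, ]
  if (!nrow(m)) stop("unknown chromosome: ", chrom)
  if (nrow(m) == 1) return(rep(m$bp, length(interval_cM)))
  round(approx(m$cM, m$bp, xout = interval_cM, rule = 2, ties = mean)$y)
}

#' Forward multi-QTL model with cofactor masking
#'
#' Iterative forward search: scan conditionally on accepted QTLs (their
#' expected genotype dosages enter as cofactors), mask a window around each
#' accepted peak, and accept the highest unmasked exceedance of the
#' threshold until none remains. The final joint linear model yields, per
#' QTL, the additive effect (half the fitted difference between homozygote
#' classes, signed as the effect of the recurrent-parent allele), the
#' drop-one variance explained, a conditional-scan LOD-drop support
#' interval, and the model \eqn{R^2 = V(G)/V(P)}.
#'
#' @param family A [ril_family()].
#' @param threshold LOD threshold, e.g. from [permutation_threshold()].
#' @param step_cM Scan grid step.
#' @param mask_cM Half-width of the cofactor mask around accepted peaks.
#' @param lod_drop LOD drop for support intervals.
#' @param max_qtl Safety cap on model size.
#' @return List of class `qtl_model`: `qtl` (data frame `chrom`, `peak_cM`,
#'   `ci_lo_cM`, `ci_hi_cM`, `ci_lo_bp`, `ci_hi_bp`, `additive_effect`,
#'   `pve`, `lod`), `model_r2`, `n`, `threshold`.
#' @export
forward_multiqtl <- function(family, threshold, step_cM = 0.5, mask_cM = 10,
                             lod_drop = 1.5, max_qtl = 10) {
  sg <- .scan_grid(family, step_cM)
  grid <- sg$grid; P <- sg$P; y <- sg$y
  peaks <- integer(0)
  repeat {
    C <- if (length(peaks)) P[, peaks, drop = FALSE] else NULL
    lod <- drop(.hk_lod(P, y, C))
    masked <- rep(FALSE, nrow(grid))
    for (pk in peaks)
      masked <- masked | (grid$chrom == grid$chrom[pk] &
                            abs(grid$cM - grid$cM[pk]) <= mask_cM)
    lod[masked] <- -Inf
    i <- which.max(lod)
    if (lod[i] <= threshold || length(peaks) >= max_qtl) break
    peaks <- c(peaks, i)
  }
  n <- length(y)
  if (!length(peaks)) {
    return(structure(list(
      qtl = data.frame(chrom = character(0), peak_cM = numeric(0),
                       ci_lo_cM = numeric(0), ci_hi_cM = numeric(0),
                       ci_lo_bp = numeric(0), ci_hi_bp = numeric(0),
                       additive_effect = numeric(0), pve = numeric(0),
                       lod = numeric(0)),
      model_r2 = 0, n = n, threshold = threshold), class = "qtl_model"))
  }

  ## refine each peak and its support interval conditional on the others
  refined <- peaks
  ci <- matrix(NA_real_, length(peaks), 2)
  lods <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    C <- if (length(peaks) > 1) P[, peaks[-k], drop = FALSE] else NULL
    lod_k <- drop(.hk_lod(P, y, C))
    ch <- grid$chrom[peaks[k]]
    on_ch <- which(grid$chrom == ch)
    j <- on_ch[which.max(lod_k[on_ch])]
    refined[k] <- j
    lods[k] <- lod_k[j]
    cond_scan <- data.frame(chrom = grid$chrom[on_ch], cM = grid$cM[on_ch],
                            lod = lod_k[on_ch])
    ci[k, ] <- support_interval(cond_scan, ch, grid$cM[j], lod_drop)
  }

  X <- P[, refined, drop = FALSE]
  fit <- lm(y ~ X)
  cf <- coef(fit)[-1]
  sign_flip <- if (identical(family$recurrent_parent, family$parents[2])) -1 else 1
  r2_full <- summary(fit)$r.squared
  pve <- vapply(seq_along(refined), function(k) {
    r2_red <- if (length(refined) > 1)
      summary(lm(y ~ X[, -k, drop = FALSE]))$r.squared else 0
    r2_full - r2_red
  }, numeric(1))
  ci_bp <- t(vapply(seq_along(refined), function(k)
    project_cm_to_bp(family$map, grid$chrom[refined[k]], ci[k, ]),
    numeric(2)))

  qtl <- data.frame(chrom = grid$chrom[refined], peak_cM = grid$cM[refined],
                    ci_lo_cM = ci[, 1], ci_hi_cM = ci[, 2],
                    ci_lo_bp = ci_bp[, 1], ci_hi_bp = ci_bp[, 2],
                    additive_effect = sign_flip * unname(cf) / 2,
                    pve = pve, lod = lods)
  qtl <- qtl[order(qtl$chrom, qtl$peak_cM), ]
  rownames(qtl) <- NULL
  structure(list(qtl = qtl, model_r2 = r2_full, n = n, threshold = threshold),
            class = "qtl_model")
}

#' Two-locus epistasis scan
#'
#' Tests the interaction term of `y ~ g1 + g2 + g1:g2` on expected genotype
#' dosages for every pair of grid positions separated by at least `min_sep`
#' cM (all inter-chromosome pairs included). Genome-wide significance comes
#' from permutations of the maximum interaction F statistic.
#'
#' @param family A [ril_family()] (>= 100 lines recommended).
#' @param grid_step Grid step in cM, default 5.
#' @param min_sep Minimum within-chromosome separation, default 10 cM.
#' @param n_perm Permutations for the genome-wide null of max F (0 skips).
#' @param alpha Genome-wide significance level.
#' @param seed Integer seed, required when `n_perm > 0`.
#' @return List with `pairs` (data frame `chrom1`, `cM1`, `chrom2`, `cM2`,
#'   `f_stat`, `interaction_effect`, `p_nominal`, and `significant` when
#'   permuted), `threshold_f` (or `NA`), `n_perm`.
#' @export
epistasis_scan <- function(family, grid_step = 5, min_sep = 10, n_perm = 0,
                           alpha = 0.05, seed = NULL) {
  sg <- .scan_grid(family, grid_step)
  grid <- sg$grid; P <- sg$P; y <- sg$y
  n <- length(y)
  npos <- nrow(grid)
  pr <- which(upper.tri(matrix(0, npos, npos)), arr.ind = TRUE)
  sep_ok <- grid$chrom[pr[, 1]] != grid$chrom[pr[, 2]] |
    abs(grid$cM[pr[, 1]] - grid$cM[pr[, 2]]) >= min_sep
  pr <- pr[sep_ok, , drop = FALSE]

  test_pairs <- function(yy) {
    ## returns F stats (and effects for the observed y)
    vapply(seq_len(nrow(pr)), function(k) {
      g1 <- P[, pr[k, 1]]; g2 <- P[, pr[k, 2]]
      X0 <- cbind(1, g1, g2)
      X1 <- cbind(X0, g1 * g2)
      f0 <- lm.fit(X0, yy); f1 <- lm.fit(X1, yy)
      rss0 <- sum(f0$residuals^2); rss1 <- sum(f1$residuals^2)
      df2 <- n - 4
      if (rss1 <= 1e-12 || f1$rank < 4) return(c(0, 0))
      c((rss0 - rss1) / (rss1 / df2), unname(f1$coefficients[4]))
    }, numeric(2))
  }

  obs <- test_pairs(y)
  f_stat <- obs[1, ]; eff <- obs[2, ]
  p_nom <- pf(f_stat, 1, n - 4, lower.tail = FALSE)
  pairs <- data.frame(chrom1 = grid$chrom[pr[, 1]], cM1 = grid$cM[pr[, 1]],
                      chrom2 = grid$chrom[pr[, 2]], cM2 = grid$cM[pr[, 2]],
                      f_stat = f_stat, interaction_effect = eff,
                      p_nominal = p_nom)
  thr <- NA_real_
  if (n_perm > 0) {
    if (is.null(seed)) stop("seed required for permutations")
    set.seed(seed)
    Y <- vapply(seq_len(n_perm), function(b) y[sample.int(n)], numeric(n))
    max_f <- rep(-Inf, n_perm)
    df2 <- n - 4
    for (k in seq_len(nrow(pr))) {
      g1 <- P[, pr[k, 1]]; g2 <- P[, pr[k, 2]]
      q0 <- qr(cbind(1, g1, g2))
      q1 <- qr(cbind(1, g1, g2, g1 * g2))
      if (q1$rank < 4) next
      rss0 <- colSums(qr.resid(q0, Y)^2)
      rss1 <- pmax(colSums(qr.resid(q1, Y)^2), 1e-12)
      max_f <- pmax(max_f, (rss0 - rss1) / (rss1 / df2))
    }
    thr <- unname(quantile(max_f, 1 - alpha, type = 7))
    pairs$significant <- pairs$f_stat > thr
  }
  list(pairs = pairs, threshold_f = thr, n_perm = n_perm)
}
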