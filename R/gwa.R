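## Genome-wide association in inbred accession panels: MAF filtering, IBS
## kinship, Wilcoxon rank-sum scan, EMMA-style mixed-model scan, diagnostics.

#' Construct a genotype matrix for an inbred panel
#'
#' @param calls Numeric matrix, accessions in rows, SNPs in columns, coded
#'   0/1 (homozygous calls of a selfing species) with `NA` for missing.
#' @param snps Data frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   one row per column of `calls`. Positions must be strictly increasing
#'   within each chromosome.
#' @param accessions Accession ids (default from rownames).
#' @return List of class `genotype_matrix` with elements `calls`, `snps`,
#'   `accessions`.
#' @export
genotype_matrix <- function(calls, snps, accessions = rownames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(accessions)) accessions <- paste0("acc", seq_len(nrow(calls)))
  stopifnot(all(c("id", "chrom", "pos") %in% names(snps)),
            nrow(snps) == ncol(calls))
  vals <- calls[!is.na(calls)]
  if (!all(vals %in% c(0, 1)))
    stop("calls must be coded 0/1/NA (biallelic, inbred)")
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (any(diff(p) <= 0))
      stop("SNP positions must be strictly increasing within chromosome ", ch)
  }
  rownames(calls) <- accessions
  colnames(calls) <- snps$id
  structure(list(calls = calls, snps = as.data.frame(snps),
                 accessions = accessions),
            class = "genotype_matrix")
}

#' Minor-allele-frequency vector of a genotype matrix
#' @param G A `genotype_matrix`.
#' @return Per-SNP MAF among non-missing calls, in `[0, 0.5]`.
#' @export
snp_maf <- function(G) {
  p <- colMeans(G$calls, na.rm = TRUE)
  pmin(p, 1 - p)
}

#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs whose MAF among non-missing calls is strictly greater than
#' the threshold.
#'
#' @param G A `genotype_matrix`.
#' @param threshold MAF threshold in `[0, 0.5)`; default 0.10.
#' @return The filtered `genotype_matrix`.
#' @export
maf_filter <- function(G, threshold = 0.10) {
  if (threshold < 0 || threshold >= 0.5) stop("threshold must lie in [0, 0.5)")
  keep <- snp_maf(G) > threshold
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warning("MAF filter removed every SNP")
  genotype_matrix(G$calls[, keep, drop = FALSE],
                  G$snps[keep, , drop = FALSE], G$accessions)
}

#' Identity-by-state kinship matrix
#'
#' Genotype-similarity matrix used as the covariance structure of the
#' polygenic random effect: `K[i, j]` is the fraction of SNPs non-missing in
#' both accessions at which the calls are identical; the diagonal is 1.
#'
#' @param G A `genotype_matrix` with at least 2 accessions and 1 SNP.
#' @return An n x n symmetric matrix of class `matrix`, values in `[0, 1]`.
#' @export
ibs_kinship <- function(G) {
  calls <- G$calls
  if (nrow(calls) < 2 || ncol(calls) < 1)
    stop("need at least 2 accessions and 1 SNP")
  one <- calls; one[is.na(one)] <- 0          # indicator of call == 1
  zero <- (1 - calls); zero[is.na(zero)] <- 0 # indicator of call == 0
  obs <- 1 * !is.na(calls)
  same <- tcrossprod(one) + tcrossprod(zero)
  overlap <- tcrossprod(obs)
  if (any(overlap == 0)) {
    idx <- which(overlap == 0, arr.ind = TRUE)[1, ]
    stop("accessions ", G$accessions[idx[1]], " and ", G$accessions[idx[2]],
         " share no genotyped SNP")
  }
  K <- same / overlap
  diag(K) <- 1
  dimnames(K) <- list(G$accessions, G$accessions)
  K
}

## Exact two-sided rank-sum p-value by enumeration of all assignments of the
## smaller class's size among the pooled ranks (handles ties via midranks).
.wilcox_exact_enum <- function(y1, y2) {
  n1 <- length(y1); n <- n1 + length(y2)
  r <- rank(c(y1, y2))
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  w_all <- colSums(matrix(r[combs], nrow = n1))
  eps <- 1e-9
  p_le <- mean(w_all <= w_obs + eps)
  p_ge <- mean(w_all >= w_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

## Rank-sum p for one SNP: exact enumeration for small classes, else normal
## approximation with tie and continuity correction.
.wilcox_p <- function(y, g, exact_max = 10) {
  y1 <- y[g == 1]; y0 <- y[g == 0]
  n1 <- length(y1); n0 <- length(y0)
  if (n1 == 0 || n0 == 0) return(c(stat = NA_real_, p = 1))
  r <- rank(c(y1, y0))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U
  if (max(n0, n1) <= exact_max) {
    p <- .wilcox_exact_enum(y1, y0)
  } else {
    n <- n0 + n1
    ties <- table(r)
    mu <- n1 * n0 / 2
    sigma2 <- (n1 * n0 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(c(stat = w, p = 1))  # all values tied
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  c(stat = w, p = p)
}

#' Wilcoxon rank-sum association scan
#'
#' Tests each SNP for a phenotype difference between its two genotype classes
#' with a two-sided rank-sum test: exact enumeration when the larger class has
#' at most `exact_max` accessions, otherwise the normal approximation with tie
#' and continuity corrections. Monomorphic SNPs get `p = 1` and are flagged.
#'
#' @param G A `genotype_matrix` (usually MAF-filtered).
#' @param y Trait values aligned with `G$accessions`; must be finite.
#' @param exact_max Largest class size for which the exact enumeration is
#'   used (both classes must satisfy it).
#' @return Data frame of class `association_result`: `snp_id`, `chrom`, `pos`,
#'   `maf`, `stat` (Mann-Whitney U), `p`, `n_used`, `monomorphic`, and
#'   attribute `method = "wilcoxon"`.
#' @export
wilcoxon_scan <- function(G, y, exact_max = 10) {
  if (any(!is.finite(y))) stop("trait values must be finite")
  if (length(y) != nrow(G$calls)) stop("trait length != accession count")
  m <- ncol(G$calls)
  stat <- p <- numeric(m); n_used <- integer(m); mono <- logical(m)
  for (j in seq_len(m)) {
    g <- G$calls[, j]
    ok <- !is.na(g)
    n_used[j] <- sum(ok)
    if (length(unique(g[ok])) < 2) {
      stat[j] <- NA_real_; p[j] <- 1; mono[j] <- TRUE
    } else {
      wp <- .wilcox_p(y[ok], g[ok], exact_max)
      stat[j] <- wp["stat"]; p[j] <- wp["p"]
    }
  }
  res <- data.frame(snp_id = G$snps$id, chrom = G$snps$chrom,
                    pos = G$snps$pos, maf = snp_maf(G), stat = stat, p = p,
                    n_used = n_used, monomorphic = mono, row.names = NULL)
  attr(res, "method") <- "wilcoxon"
  class(res) <- c("association_result", "data.frame")
  res
}

## EMMA-style restricted log-likelihood in delta = sigma2_e / sigma2_g,
## given eigenvalues lambda of S K S (nonzero part) and eta = U' y.
.reml_ll <- function(delta, lambda, eta2) {
  q <- length(lambda)
  0.5 * (q * log(q / (2 * pi)) - q -
           q * log(sum(eta2 / (lambda + delta))) -
           sum(log(lambda + delta)))
}

#' REML variance components under a kinship covariance
#'
#' Fits \eqn{y = X\beta + u + e}, \eqn{u \sim N(0, \sigma^2_g K)},
#' \eqn{e \sim N(0, \sigma^2_e I)} by restricted maximum likelihood. The
#' likelihood is profiled on the variance ratio \eqn{\delta = \sigma^2_e /
#' \sigma^2_g} via the eigendecomposition of the kinship projected on the
#' orthocomplement of the fixed effects, maximised on a log10 grid and
#' polished locally.
#'
#' @param y Trait vector.
#' @param X Fixed-effect design matrix (include the intercept); default
#'   intercept only.
#' @param K Kinship matrix (symmetric, positive semi-definite after jitter).
#' @param grid_pts,grid_range Grid for log10(delta); defaults 100 points on
#'   `[-5, 5]`.
#' @return List with `sigma2_g`, `sigma2_e`, `delta`, `logLik`, plus the
#'   projected spectrum (`lambda`, `eta2`) reused by [mixed_model_scan()].
#' @export
reml_variance_components <- function(y, X = matrix(1, length(y), 1), K,
                                     grid_pts = 100, grid_range = c(-5, 5)) {
  n <- length(y)
  X <- as.matrix(X)
  p <- qr(X)$rank
  if (n < p + 2) stop("need n >= p + 2 observations")
  if (max(abs(K - t(K))) > 1e-8) stop("K must be symmetric")
  K <- (K + t(K)) / 2
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  es <- eigen(S %*% K %*% S, symmetric = TRUE)
  lambda <- es$values[seq_len(n - p)]
  if (any(lambda < -1e-6)) stop("projected kinship is not positive semi-definite")
  lambda <- pmax(lambda, 0)
  U <- es$vectors[, seq_len(n - p), drop = FALSE]
  eta2 <- drop(crossprod(U, y))^2

  logd <- seq(grid_range[1], grid_range[2], length.out = grid_pts)
  ll <- vapply(10^logd, .reml_ll, numeric(1), lambda = lambda, eta2 = eta2)
  i <- which.max(ll)
  lo <- logd[max(1, i - 1)]; hi <- logd[min(grid_pts, i + 1)]
  opt <- optimize(function(ld) .reml_ll(10^ld, lambda, eta2),
                  c(lo, hi), maximum = TRUE)
  delta <- 10^opt$maximum
  if (opt$objective < ll[i]) delta <- 10^logd[i]
  sigma2_g <- sum(eta2 / (lambda + delta)) / (n - p)
  list(sigma2_g = sigma2_g, sigma2_e = delta * sigma2_g, delta = delta,
       logLik = max(opt$objective, ll[i]), lambda = lambda, eta2 = eta2)
}

## GLS F-test of one SNP on a subset of accessions (handles missing calls).
.gls_single <- function(y, X0, g, K, delta) {
  n <- length(y)
  V <- K + delta * diag(n)
  R <- chol(V)
  ys <- backsolve(R, y, transpose = TRUE)
  X0s <- backsolve(R, X0, transpose = TRUE)
  gs <- backsolve(R, g, transpose = TRUE)
  f0 <- lm.fit(X0s, ys)
  f1 <- lm.fit(cbind(X0s, gs), ys)
  rss0 <- sum(f0$residuals^2); rss1 <- sum(f1$residuals^2)
  df2 <- n - ncol(X0) - 1
  if (df2 < 1 || rss1 <= 0) return(c(NA_real_, 1))
  Fst <- (rss0 - rss1) / (rss1 / df2)
  c(unname(f1$coefficients[ncol(X0) + 1]), pf(Fst, 1, df2, lower.tail = FALSE))
}

#' Kinship-corrected mixed-model association scan
#'
#' Per-SNP test of the fixed locus effect \eqn{\beta} in
#' \eqn{y = X\beta + u + e} with polygenic background
#' \eqn{u \sim N(0, \sigma^2_g K)}. The variance ratio is estimated once on
#' the null model by [reml_variance_components()] and reused for every SNP
#' (generalised least squares after rotating by the eigenvectors of K), or
#' refitted per SNP when `per_snp_reml = TRUE` (slower, fully faithful REML).
#' With `K = diag(n)` the test reduces exactly to the ordinary regression
#' F-test. SNPs with missing calls are tested by casewise deletion.
#'
#' @param G A `genotype_matrix` (MAF-filtered).
#' @param y Trait values aligned with `G$accessions`.
#' @param K Kinship matrix, e.g. from [ibs_kinship()].
#' @param covariates Optional numeric matrix of additional fixed covariates
#'   (e.g. a candidate-gene functional class); the intercept is always
#'   included.
#' @param per_snp_reml Refit the variance ratio for each SNP.
#' @return An `association_result` data frame (`snp_id`, `chrom`, `pos`,
#'   `maf`, `stat` = estimated allelic effect, `p`, `n_used`, `monomorphic`)
#'   with attributes `method = "mixed"`, `sigma2_g`, `sigma2_e`, `delta`.
#' @export
mixed_model_scan <- function(G, y, K, covariates = NULL,
                             per_snp_reml = FALSE) {
  if (any(!is.finite(y))) stop("trait values must be finite")
  n <- nrow(G$calls)
  if (length(y) != n || nrow(K) != n) stop("dimension mismatch")
  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)
  null <- reml_variance_components(y, X0, K)
  delta <- null$delta
  m <- ncol(G$calls)
  beta <- rep(NA_real_, m); p <- rep(1, m)
  n_used <- integer(m); mono <- logical(m)

  miss <- colSums(is.na(G$calls)) > 0
  poly <- vapply(seq_len(m), function(j) {
    g <- G$calls[, j]
    length(unique(g[!is.na(g)])) >= 2
  }, logical(1))
  mono <- !poly
  n_used <- colSums(!is.na(G$calls))

  complete <- which(!miss & poly)
  if (length(complete)) {
    ## rotate once by the eigenvectors of K; GLS becomes weighted LS
    ek <- eigen((K + t(K)) / 2, symmetric = TRUE)
    w <- 1 / (pmax(ek$values, 0) + delta)
    Ut <- t(ek$vectors)
    ys <- drop(Ut %*% y)
    X0s <- Ut %*% X0
    ## weighted residuals of y and of each SNP on the null design
    wX0 <- X0s * w
    XtX <- crossprod(X0s, wX0)
    ey <- ys - X0s %*% solve(XtX, crossprod(wX0, ys))
    rss0 <- sum(w * ey^2)
    Gs <- Ut %*% G$calls[, complete, drop = FALSE]
    EG <- Gs - X0s %*% solve(XtX, crossprod(wX0, Gs))
    sgy <- drop(crossprod(EG, w * ey))
    sgg <- colSums(w * EG^2)
    ok <- sgg > 1e-12
    b <- ifelse(ok, sgy / sgg, NA_real_)
    rss1 <- pmax(rss0 - ifelse(ok, sgy^2 / sgg, 0), 0)
    df2 <- n - ncol(X0) - 1
    Fst <- (rss0 - rss1) / (rss1 / df2)
    pj <- ifelse(ok, pf(Fst, 1, df2, lower.tail = FALSE), 1)
    if (per_snp_reml) {
      for (idx in seq_along(complete)) {
        j <- complete[idx]
        g <- G$calls[, j]
        fitj <- reml_variance_components(y, cbind(X0, g), K)
        bp <- .gls_single(y, X0, g, K, fitj$delta)
        beta[j] <- bp[1]; p[j] <- bp[2]
      }
    } else {
      beta[complete] <- b; p[complete] <- pj
    }
  }

  for (j in which(miss & poly)) {
    ok <- !is.na(G$calls[, j])
    g <- G$calls[ok, j]
    dj <- if (per_snp_reml) {
      reml_variance_components(y[ok], cbind(X0[ok, , drop = FALSE], g),
                               K[ok, ok])$delta
    } else delta
    bp <- .gls_single(y[ok], X0[ok, , drop = FALSE], g, K[ok, ok], dj)
    beta[j] <- bp[1]; p[j] <- bp[2]
  }

  res <- data.frame(snp_id = G$snps$id, chrom = G$snps$chrom,
                    pos = G$snps$pos, maf = snp_maf(G), stat = beta, p = p,
                    n_used = n_used, monomorphic = mono, row.names = NULL)
  attr(res, "method") <- "mixed"
  attr(res, "sigma2_g") <- null$sigma2_g
  attr(res, "sigma2_e") <- null$sigma2_e
  attr(res, "delta") <- delta
  class(res) <- c("association_result", "data.frame")
  res
}

#' Genomic diagnostics of an association scan
#'
#' Genomic-control inflation factor (median association chi-square over its
#' null median), QQ coordinates on the -log10 scale, and the p-value
#' distribution stratified by MAF bins, mirroring the standard checks that
#' population-structure confounding and rare alleles leave on a scan.
#'
#' @param res An `association_result`.
#' @param maf_breaks Bin edges for the MAF stratification.
#' @return List with `lambda_gc`, `qq_pairs` (data frame `expected`,
#'   `observed`, both -log10, ascending), `p_by_maf` (data frame of per-bin
#'   median p and counts).
#' @export
genomic_diagnostics <- function(res, maf_breaks = c(0, 0.1, 0.2, 0.3, 0.4, 0.5)) {
  p <- res$p[!res$monomorphic]
  if (length(p) < 100) stop("need at least 100 tested SNPs for diagnostics")
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- median(chisq) / qchisq(0.5, df = 1)
  m <- length(p)
  qq <- data.frame(expected = -log10((m:1) / (m + 1)),
                   observed = sort(-log10(p)))
  maf <- res$maf[!res$monomorphic]
  bin <- cut(maf, maf_breaks, include.lowest = TRUE)
  p_by_maf <- data.frame(bin = levels(bin),
                         n = as.integer(table(bin)),
                         median_p = as.numeric(tapply(p, bin, median)),
                         frac_below_01 = as.numeric(tapply(p <= 0.01, bin, mean)),
                         row.names = NULL)
  list(lambda_gc = lambda, qq_pairs = qq, p_by_maf = p_by_maf)
}

#' Pairwise linkage disequilibrium between two SNPs
#'
#' On inbred homozygous calls the genotype vectors are haplotype-like, so
#' \eqn{r^2 = (p_{AB} - p_A p_B)^2 / (p_A(1-p_A) p_B(1-p_B))} is computed
#' directly from joint call frequencies, with a Fisher exact test on the
#' 2 x 2 haplotype table.
#'
#' @param g1,g2 0/1/NA call vectors over the same accessions.
#' @return List with `r2`, `fisher_p`, `n` (accessions used).
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 4) stop("need at least 4 accessions typed at both SNPs")
  a <- g1[ok]; b <- g2[ok]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    stop("monomorphic SNP: r2 undefined")
  pab <- mean(a == 1 & b == 1)
  r2 <- (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
  tab <- table(factor(a, c(0, 1)), factor(b, c(0, 1)))
  list(r2 = r2, fisher_p = fisher.test(tab)$p.value, n = sum(ok))
}
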