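test_that("map functions follow Haldane and the RIL expansion", {
  expect_equal(unlist(map_functions(0)), c(r = 0, R_ril = 0))
  far <- map_functions(1e5)
  expect_equal(far$r, 0.5, tolerance = 1e-10)
  expect_equal(far$R_ril, 0.5, tolerance = 1e-10)
  m10 <- map_functions(10)
  expect_equal(m10$r, 0.5 * (1 - exp(-0.2)), tolerance = 1e-12)
  expect_equal(m10$R_ril, 2 * m10$r / (1 + 2 * m10$r), tolerance = 1e-12)
  expect_equal(m10$r, 0.0906, tolerance = 1e-3)
  expect_equal(m10$R_ril, 0.1535, tolerance = 1e-3)
  expect_error(map_functions(-1), "non-negative")
})

test_that("genotype probabilities honour typed markers and symmetry", {
  fam <- make_marker_family(n_lines = 10, seed = 20)
  ## at a typed marker, probability is the call itself
  p <- genotype_probs(fam$family, 1, fam$map$cM)
  expect_equal(p, fam$g + 0, ignore_attr = TRUE)
  ## midpoint between opposite flanks is exactly 0.5
  geno <- matrix(c("A", "B"), 1, 2,
                 dimnames = list(NULL, c("m1_01", "m1_02")))
  map1 <- data.frame(marker = colnames(geno), chrom = 1, cM = c(0, 20),
                     bp = c(1, 2e6))
  f1 <- ril_family(geno, map1, 5)
  expect_equal(drop(genotype_probs(f1, 1, 10)), 0.5)
  expect_warning(genotype_probs(f1, 1, 25), "clamped")
})

test_that("genotype probabilities match a two-flank Bayes enumeration", {
  ## independent oracle: enumerate q in {A, B}, multiply flank transition
  ## probabilities computed from first principles
  oracle <- function(left_call, right_call, dl, dr) {
    trans <- function(d) {
      r <- 0.5 * (1 - exp(-2 * d / 100))
      2 * r / (1 + 2 * r)
    }
    pq <- c(A = 0.5, B = 0.5)
    for (q in c("A", "B")) {
      if (!is.na(left_call))
        pq[q] <- pq[q] * (if (left_call == q) 1 - trans(dl) else trans(dl))
      if (!is.na(right_call))
        pq[q] <- pq[q] * (if (right_call == q) 1 - trans(dr) else trans(dr))
    }
    unname(pq["A"] / sum(pq))
  }
  cases <- expand.grid(l = c("A", "B", NA), r = c("A", "B", NA),
                       pos = c(3, 11.5), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    geno <- matrix(c(cases$l[i], cases$r[i]), 1, 2,
                   dimnames = list(NULL, c("m1_01", "m1_02")))
    map1 <- data.frame(marker = colnames(geno), chrom = 1, cM = c(0, 18),
                       bp = c(1, 2e6))
    f <- ril_family(geno, map1, 1)
    expect_equal(drop(genotype_probs(f, 1, cases$pos[i])),
                 oracle(cases$l[i], cases$r[i], cases$pos[i],
                        18 - cases$pos[i]),
                 tolerance = 1e-12,
                 label = paste("case", i))
  }
})

test_that("scan peak at a typed marker equals single-marker regression", {
  fam <- make_marker_family(n_lines = 150, qtl_marker = 6, effect = 1,
                            seed = 21)
  scan <- interval_scan(fam$family, step_cM = 0.5)
  at_marker <- scan[abs(scan$cM - fam$map$cM[6]) < 1e-9, ]
  n <- 150
  f1 <- lm(fam$y ~ fam$g[, 6])
  f0 <- lm(fam$y ~ 1)
  lod_oracle <- (n / 2) * log10(sum(resid(f0)^2) / sum(resid(f1)^2))
  expect_equal(at_marker$lod, lod_oracle, tolerance = 1e-9)
})

test_that("LOD is invariant under affine phenotype transforms", {
  fam <- make_marker_family(n_lines = 100, qtl_marker = 4, effect = 0.8,
                            seed = 22)
  s1 <- interval_scan(fam$family)
  fam2 <- fam$family
  fam2$phenotype <- 2.5 * fam2$phenotype - 40
  s2 <- interval_scan(fam2)
  expect_equal(s1$lod, s2$lod, tolerance = 1e-9)
})

test_that("halving the scan step moves the peak by less than the step", {
  fam <- make_marker_family(n_lines = 200, qtl_marker = 5, effect = 1,
                            seed = 23)
  peak_at <- function(step) {
    s <- interval_scan(fam$family, step_cM = step)
    s$cM[which.max(s$lod)]
  }
  expect_lt(abs(peak_at(1) - peak_at(0.5)), 1)
  expect_lt(abs(peak_at(0.5) - peak_at(0.25)), 0.5)
})

test_that("permutation thresholds are stable, convergent and seeded", {
  fam <- make_marker_family(n_lines = 120, seed = 24)
  t1 <- permutation_threshold(fam$family, 1000, seed = 1)
  t2 <- permutation_threshold(fam$family, 1000, seed = 2)
  expect_lt(abs(t1 - t2), 0.15)
  t3 <- permutation_threshold(fam$family, 2000, seed = 3)
  expect_lt(abs(as.numeric(t1) - as.numeric(t3)), 0.15)
  ## same seed reproduces exactly
  expect_equal(as.numeric(t1),
               as.numeric(permutation_threshold(fam$family, 1000, seed = 1)))
  ## alpha = 1 gives the minimum of the max-LOD distribution
  tmin <- permutation_threshold(fam$family, 100, alpha = 1, seed = 4)
  expect_equal(as.numeric(tmin), min(attr(tmin, "max_lods")))
  expect_error(permutation_threshold(fam$family, 50, seed = 1), "100")
})

test_that("forward model recovers two unlinked QTLs with correct signs", {
  cfg <- sim_config(seed = 31, n_rils = 350, n_markers = 80)
  qtl <- data.frame(chrom = c(1, 3), cM = c(40, 50), effect = c(1, -0.7))
  sim <- simulate_ril_family(cfg, qtl = qtl, h2 = 0.5)
  thr <- permutation_threshold(sim$family, 200, seed = 5)
  mod <- forward_multiqtl(sim$family, thr)
  expect_gte(nrow(mod$qtl), 2)
  q1 <- mod$qtl[mod$qtl$chrom == 1, ][1, ]
  q3 <- mod$qtl[mod$qtl$chrom == 3, ][1, ]
  expect_equal(sign(q1$additive_effect), 1)
  expect_equal(sign(q3$additive_effect), -1)
  truth <- sim$truth$qtl
  expect_lt(abs(q1$peak_cM - truth$cM_est[1]), 10)
  expect_lt(abs(q3$peak_cM - truth$cM_est[2]), 10)
  ## per-QTL variance shares sum to at most the model R2 (plus slack)
  expect_lte(sum(mod$qtl$pve), mod$model_r2 + 0.02)
})

test_that("noiseless marker-coincident QTL data give a perfect joint model", {
  set.seed(32)
  f1 <- make_marker_family(n_lines = 250, n_mark = 8, len_cM = 70, seed = 32)
  f2 <- make_marker_family(n_lines = 250, n_mark = 8, len_cM = 70, seed = 33)
  y <- 1.0 * (2 * f1$g[, 4] - 1) + 0.6 * (2 * f2$g[, 6] - 1)
  geno <- cbind(matrix(c("B", "A")[f1$g + 1], 250, 8),
                matrix(c("B", "A")[f2$g + 1], 250, 8))
  colnames(geno) <- c(sprintf("m1_%02d", 1:8), sprintf("m2_%02d", 1:8))
  map <- data.frame(marker = colnames(geno), chrom = rep(1:2, each = 8),
                    cM = rep(seq(0, 70, by = 10), 2),
                    bp = rep(round(seq(1, 15e6, length.out = 8)), 2))
  fam <- ril_family(geno, map, y)
  mod <- forward_multiqtl(fam, threshold = 3)
  expect_equal(nrow(mod$qtl), 2)
  expect_gt(mod$model_r2, 0.999)
  expect_equal(sort(mod$qtl$peak_cM), c(30, 50))
  expect_equal(mod$qtl$additive_effect[order(mod$qtl$chrom)], c(1, 0.6),
               tolerance = 1e-6)
})

test_that("null families yield empty models at the permutation threshold", {
  empties <- 0
  for (seed in 1:25) {
    fam <- make_marker_family(n_lines = 200, n_mark = 30, seed = 400 + seed)
    thr <- permutation_threshold(fam$family, 200, seed = seed)
    mod <- forward_multiqtl(fam$family, thr)
    if (nrow(mod$qtl) == 0) empties <- empties + 1
  }
  expect_gte(empties / 25, 0.84)
})

test_that("support intervals span plateaus and collapse at zero drop", {
  scan <- data.frame(chrom = 1, cM = 0:10,
                     lod = c(0, 1, 3, 3, 3, 3, 3, 1, 0.5, 0.2, 0))
  ## flat top: interval spans the plateau plus one flanking point each side
  expect_equal(support_interval(scan, 1, 4, lod_drop = 1.5), c(1, 7))
  expect_equal(support_interval(scan, 1, 4, lod_drop = 0), c(1, 7))
  scan2 <- data.frame(chrom = 1, cM = 0:10,
                      lod = c(0, 0.5, 1, 2, 5, 9, 5, 2, 1, 0.5, 0))
  expect_equal(support_interval(scan2, 1, 5, lod_drop = 0), c(4, 6))
})

test_that("cM to bp projection interpolates linearly and clamps", {
  map <- marker_map(data.frame(marker = c("a", "b", "c"), chrom = 1,
                               cM = c(0, 10, 20), bp = c(1, 1e6, 2e6)))
  expect_equal(project_cm_to_bp(map, 1, c(10, 20)), c(1e6, 2e6))
  expect_equal(project_cm_to_bp(map, 1, 15), 1.5e6)
  expect_equal(project_cm_to_bp(map, 1, c(-5, 50)), c(1, 2e6))  # clamped
  ## property: projections always fall inside the flanking-marker bp range
  set.seed(25)
  for (i in 1:1000) {
    x <- runif(1, 0, 20)
    b <- project_cm_to_bp(map, 1, x)
    expect_gte(b, 1); expect_lte(b, 2e6)
  }
  expect_error(marker_map(data.frame(marker = c("a", "b"), chrom = 1,
                                     cM = c(0, 10), bp = c(100, 50))),
               "strictly increase")
})

test_that("epistasis scan detects a pure interaction and stays null otherwise", {
  make_epi_family <- function(seed, interaction = 0, n_lines = 350) {
    set.seed(seed)
    f <- make_marker_family(n_lines = n_lines, n_mark = 8, len_cM = 70,
                            seed = seed)
    g2 <- matrix(0L, n_lines, 8)
    g2[, 1] <- rbinom(n_lines, 1, 0.5)
    R <- map_functions(10)$R_ril
    for (j in 2:8)
      g2[, j] <- ifelse(rbinom(n_lines, 1, R) == 1, 1L - g2[, j - 1], g2[, j - 1])
    y <- rnorm(n_lines) +
      interaction * (2 * f$g[, 4] - 1) * (2 * g2[, 4] - 1)
    geno <- cbind(matrix(c("B", "A")[f$g + 1], n_lines, 8),
                  matrix(c("B", "A")[g2 + 1], n_lines, 8))
    colnames(geno) <- c(sprintf("m1_%02d", 1:8), sprintf("m2_%02d", 1:8))
    map <- data.frame(marker = colnames(geno), chrom = rep(1:2, each = 8),
                      cM = rep(seq(0, 70, by = 10), 2),
                      bp = rep(round(seq(1, 15e6, length.out = 8)), 2))
    ril_family(geno, map, y)
  }
  ## sign of a strong interaction is recovered
  fam <- make_epi_family(1, interaction = 2)
  ep <- epistasis_scan(fam, grid_step = 10, n_perm = 60, seed = 6)
  best <- ep$pairs[which.max(ep$pairs$f_stat), ]
  expect_true(best$significant)
  expect_equal(best$chrom1, 1); expect_equal(best$chrom2, 2)
  expect_lte(abs(best$cM1 - 30), 10); expect_lte(abs(best$cM2 - 30), 10)
  ## interaction coded on dosage products: positive generating coefficient
  expect_gt(best$interaction_effect, 0)

  ## additive-only null: few genome-wide significant pairs across seeds
  fp <- 0
  for (seed in 1:15) {
    famN <- make_epi_family(100 + seed, interaction = 0, n_lines = 200)
    epN <- epistasis_scan(famN, grid_step = 10, n_perm = 60, seed = seed)
    if (any(epN$pairs$significant)) fp <- fp + 1
  }
  expect_lte(fp, 3)

  ## moderate interaction (about 10% PVE) is found in most seeds
  det <- 0
  for (seed in 1:15) {
    famP <- make_epi_family(200 + seed, interaction = 0.33)
    epP <- epistasis_scan(famP, grid_step = 10, n_perm = 60, seed = seed)
    sig <- epP$pairs[epP$pairs$significant, ]
    if (nrow(sig) && any(sig$chrom1 != sig$chrom2)) det <- det + 1
  }
  expect_gte(det / 15, 0.6)
})

test_that("recurrent-parent effect signs aggregate like dispersed alleles", {
  ## two families bred with antagonistic allele effects: pooled effect signs
  ## must reproduce the generating mixture (bimodal in sign, not averaged)
  effects <- c()
  for (seed in c(61, 62)) {
    cfg <- sim_config(seed = seed, n_rils = 300, n_markers = 60)
    qtl <- data.frame(chrom = c(1, 4), cM = c(50, 30),
                      effect = c(1, -1) * c(1, 0.8))
    sim <- simulate_ril_family(cfg, qtl = qtl, h2 = 0.6)
    mod <- forward_multiqtl(sim$family, threshold = 3.2)
    effects <- c(effects, mod$qtl$additive_effect)
  }
  expect_gte(sum(effects > 0), 1)
  expect_gte(sum(effects < 0), 1)
})
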