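make_snps <- function(n = 200, chrom = 1, spacing = 10000) {
  data.frame(snp_id = sprintf("c%d_s%03d", chrom, 1:n), chrom = chrom,
             pos = seq_len(n) * spacing)
}

test_that("gene windows are symmetric, inclusive and clipped at 1", {
  g <- gene_windows(data.frame(gene_id = c("g1", "g2"), chrom = 1,
                               start = c(5000, 100000), end = c(6000, 103000)))
  expect_equal(g$win_start, c(1, 80000))
  expect_equal(g$win_end, c(26000, 123000))
  expect_error(gene_windows(data.frame(gene_id = "x", chrom = 1,
                                       start = 10, end = 5)), "precedes")
})

test_that("SNP annotation flags are inclusive at the 20 kb boundary", {
  snps <- data.frame(snp_id = c("a", "b", "c"), chrom = 1,
                     pos = c(123000, 123001, 50))
  w <- gene_windows(data.frame(gene_id = "g1", chrom = 1, start = 100000,
                               end = 103000))
  ann <- annotate_snps(snps, w)
  expect_equal(ann$near_candidate, c(TRUE, FALSE, FALSE))  # 123000 inclusive

  qi <- data.frame(family = c("f1", "f2"), chrom = 1,
                   lo_bp = c(100000, 120000), hi_bp = c(130000, 140000))
  ann2 <- annotate_snps(snps, w, qi)
  expect_true(ann2$both[1])
  expect_equal(ann2$qtl_families[1], "f1,f2")
  expect_error(annotate_snps(snps, qtl_intervals = data.frame(
    family = "f", chrom = 9, lo_bp = 1, hi_bp = 2)), "absent")
})

test_that("annotation equals a brute-force membership oracle and is idempotent", {
  set.seed(30)
  snps <- make_snps(300)
  starts <- sort(sample.int(3e6, 15))
  w <- gene_windows(data.frame(gene_id = sprintf("g%02d", 1:15), chrom = 1,
                               start = starts, end = starts + 2000))
  qi <- data.frame(family = c("f1", "f2"), chrom = 1,
                   lo_bp = c(2e5, 1.5e6), hi_bp = c(6e5, 2.2e6))
  ann <- annotate_snps(snps, w, qi)
  for (i in seq_len(nrow(snps))) {
    near_o <- FALSE; in_o <- FALSE
    for (k in seq_len(nrow(w)))
      if (snps$pos[i] >= w$win_start[k] && snps$pos[i] <= w$win_end[k])
        near_o <- TRUE
    for (k in seq_len(nrow(qi)))
      if (snps$pos[i] >= qi$lo_bp[k] && snps$pos[i] <= qi$hi_bp[k])
        in_o <- TRUE
    expect_equal(ann$near_candidate[i], near_o)
    expect_equal(ann$in_qtl[i], in_o)
    expect_equal(ann$both[i], near_o && in_o)
  }
  ## idempotent and order-independent
  ann_shuf <- annotate_snps(snps[sample.int(300), ], w, qi)
  m <- match(ann$snp_id, ann_shuf$snp_id)
  expect_equal(ann$near_candidate, ann_shuf$near_candidate[m])
  expect_equal(ann$in_qtl, ann_shuf$in_qtl[m])
})

test_that("top-SNP selection is a deterministic partial sort", {
  set.seed(31)
  res <- make_snps(100)
  res$p <- runif(100)
  names(res)[1] <- "snp_id"
  expect_equal(nrow(select_top(res, 100)), 100)
  top <- select_top(res, 10)
  expect_equal(top$snp_id, res$snp_id[order(res$p)][1:10])
  ## ties at the cut break by position
  res$p <- rep(c(0.001, 0.5), c(20, 80))
  top5 <- select_top(res, 5)
  expect_equal(top5$pos, sort(res$pos[res$p == 0.001])[1:5])
  expect_error(select_top(res, 0), "positive")
  expect_error(select_top(res, 101), "exceeds")
})

test_that("enrichment ratio follows flagged fractions", {
  bg <- data.frame(near_candidate = rep(c(TRUE, FALSE), c(10, 90)),
                   in_qtl = FALSE, both = FALSE)
  top <- data.frame(near_candidate = rep(c(TRUE, FALSE), c(5, 5)),
                    in_qtl = FALSE, both = FALSE)
  expect_equal(enrichment_ratio(top, bg, "candidate"), 5.0)
  all_flag <- data.frame(near_candidate = rep(TRUE, 10), in_qtl = FALSE,
                         both = FALSE)
  expect_equal(enrichment_ratio(all_flag, bg, "candidate"), 10.0)
  ## the full set has enrichment exactly 1 for every available flag
  expect_equal(enrichment_ratio(bg, bg, "candidate"), 1.0)
  expect_error(enrichment_ratio(top, bg, "qtl"), "zero")
})

test_that("resampled enrichment null is centred at 1, seeded and degenerate at full N", {
  set.seed(32)
  bg <- data.frame(near_candidate = runif(500) < 0.2, in_qtl = FALSE,
                   both = FALSE)
  nul <- enrichment_null(bg, 50, "candidate", B = 2000, seed = 9)
  mc_se <- sd(nul$draws) / sqrt(2000)
  expect_lt(abs(nul$null_mean - 1), 3 * mc_se + 0.02)
  expect_identical(nul$draws,
                   enrichment_null(bg, 50, "candidate", B = 2000, seed = 9)$draws)
  full <- enrichment_null(bg, 500, "candidate", B = 50, seed = 1)
  expect_equal(unname(diff(full$ci)), 0)
  expect_equal(full$null_mean, 1)
  expect_error(enrichment_null(bg, 501, "candidate", seed = 1), "exceeds")
})

test_that("enrichment ladder reports descending N and marks exceedances", {
  set.seed(33)
  res <- make_snps(400)
  names(res)[1] <- "snp_id"
  res$p <- runif(400)
  ## plant candidates under the best SNPs so enrichment must trigger
  best <- order(res$p)[1:20]
  w <- gene_windows(data.frame(gene_id = sprintf("g%02d", 1:20), chrom = 1,
                               start = res$pos[best], end = res$pos[best]),
                    window_bp = 1000)
  ann <- annotate_snps(res[, c("snp_id", "chrom", "pos")], w)
  lad <- enrichment_ladder(res, ann, Ns = c(50, 200, 100), flags = "candidate",
                           B = 300, seed = 4)
  expect_equal(lad$N, c(200, 100, 50))
  expect_true(all(lad$observed > 1))
  expect_true(lad$significant[lad$N == 50])
})

test_that("in/out-QTL p-value contrast matches a rank-sum oracle", {
  set.seed(34)
  res <- make_snps(300)
  names(res)[1] <- "snp_id"
  qi <- data.frame(family = "f1", chrom = 1, lo_bp = 1, hi_bp = 1e6)
  inside <- res$pos <= 1e6
  res$p <- runif(300)
  res$p[inside] <- res$p[inside]^2  # stochastically smaller inside
  out <- pvalue_in_out_qtl(res, qi)
  expect_lt(out$p, 0.01)
  expect_lt(out$median_in, out$median_out)
  ## two-group Kruskal-Wallis equals the tie-corrected rank-sum chi-square
  kw_oracle <- kruskal.test(res$p ~ inside)
  expect_equal(out$kw_stat, unname(kw_oracle$statistic))
  z <- wilcox.test(res$p[inside], res$p[!inside], exact = FALSE,
                   correct = FALSE)
  expect_equal(kw_oracle$p.value, z$p.value, tolerance = 1e-10)
})

test_that("candidate classification reproduces the rule table", {
  w <- gene_windows(data.frame(gene_id = sprintf("g%d", 1:8), chrom = 1,
                               start = (1:8) * 1e6, end = (1:8) * 1e6 + 1000),
                    window_bp = 10000)
  hit <- function(k) data.frame(snp_id = paste0("t", k), chrom = 1,
                                pos = k * 1e6 + 500, p = 1e-5)
  ## genes 1-4 have a QTL; membership pattern enumerates the rule table
  qi <- data.frame(family = "f1", chrom = 1, lo_bp = 0.5e6, hi_bp = 4.5e6)
  top_e <- rbind(hit(1), hit(2), hit(5), hit(6))   # EMMA hits
  top_w <- rbind(hit(1), hit(3), hit(5), hit(7))   # Wilcoxon hits
  cls <- classify_candidates(top_e, top_w, w, qi, top50_emma = hit(1))
  expect_equal(cls$class,
               c("confirmed", "emma_only_qtl", "wilcoxon_only_qtl",
                 "undetected", "no_qtl", "no_qtl", "no_qtl", "undetected"))
  expect_true(cls$top50[1])
  expect_equal(cls$qtl_families[1], "f1")
  ## oracle: recompute every gene class from first principles
  for (k in 1:8) {
    de <- k %in% c(1, 2, 5, 6); dw <- k %in% c(1, 3, 5, 7); qo <- k <= 4
    expected <- if (de && dw && qo) "confirmed" else if (de && qo)
      "emma_only_qtl" else if (dw && qo) "wilcoxon_only_qtl" else
        if (de || dw) "no_qtl" else "undetected"
    expect_equal(cls$class[k], expected)
  }
})

test_that("orphan peaks require QTL support, candidate-free windows and spacing", {
  set.seed(35)
  res <- make_snps(500, spacing = 5000)   # 2.5 Mb of SNPs
  names(res)[1] <- "snp_id"
  res$p <- runif(500, 0.5, 1)
  qi <- data.frame(family = "f1", chrom = 1, lo_bp = 1.45e6, hi_bp = 1.55e6)
  ## candidate gene at 0.4 Mb; an injected association at 1.5 Mb (500 kb away
  ## from any gene), inside the QTL interval, is the single orphan peak:
  ## weaker in-interval SNPs merge into it
  w <- gene_windows(data.frame(gene_id = "g1", chrom = 1, start = 4e5,
                               end = 4.01e5))
  res$p[res$pos == 1.5e6] <- 1e-6
  op <- orphan_peaks(res, w, qi, rank_cut = 100)
  expect_equal(nrow(op), 1)
  expect_equal(op$pos, 1.5e6)
  ## a second association near the gene is not orphan
  res$p[res$pos == 4.05e5] <- 1e-7
  op2 <- orphan_peaks(res, w, qi, rank_cut = 100)
  expect_false(4.05e5 %in% op2$pos)
  ## two strong SNPs 50 kb apart merge into one peak
  res$p[res$pos == 1.55e6] <- 5e-6
  op3 <- orphan_peaks(res, w, qi, rank_cut = 100)
  expect_equal(sum(op3$pos %in% c(1.5e6, 1.55e6)), 1)
  ## all top SNPs near candidates: empty result
  w_all <- gene_windows(data.frame(gene_id = "gbig", chrom = 1, start = 1,
                                   end = 2.5e6))
  expect_equal(nrow(orphan_peaks(res, w_all, qi, rank_cut = 100)), 0)
})
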