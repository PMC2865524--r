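# Fixture builders shared across test files. All are pure functions of the
# seed so frozen expectations stay stable.

make_weather <- function(n_days = 30, seed = 1, start = as.Date("2020-03-01"),
                         tmean = NULL) {
  set.seed(seed)
  if (is.null(tmean)) tmean <- runif(n_days, -5, 20)
  weather_series(start + seq_len(n_days) - 1, tmean,
                 tmean_daylight = tmean + runif(n_days, 0, 5),
                 photoperiod_hours = runif(n_days, 8, 16))
}

make_genotypes <- function(n = 20, m = 30, seed = 1, miss = 0) {
  set.seed(seed)
  calls <- matrix(rbinom(n * m, 1, runif(m, 0.2, 0.8)[rep(1:m, each = n)]),
                  n, m)
  if (miss > 0) calls[sample(length(calls), round(miss * length(calls)))] <- NA
  genotype_matrix(calls,
                  data.frame(id = sprintf("s%03d", 1:m),
                             chrom = sort(rep_len(1:2, m)),
                             pos = rep(seq_len(ceiling(m / 2)) * 1000, 2)[1:m]))
}

# 1-chromosome RIL family with evenly spaced markers, built directly (not via
# the breeding simulator) for deterministic scan tests
make_marker_family <- function(n_lines = 120, n_mark = 11, len_cM = 100,
                               qtl_marker = NULL, effect = 0, sd = 1,
                               seed = 1) {
  set.seed(seed)
  cm <- seq(0, len_cM, length.out = n_mark)
  R <- map_functions(diff(cm))$R_ril
  g <- matrix(0L, n_lines, n_mark)
  g[, 1] <- rbinom(n_lines, 1, 0.5)
  for (j in 2:n_mark)
    g[, j] <- ifelse(rbinom(n_lines, 1, R[j - 1]) == 1, 1L - g[, j - 1], g[, j - 1])
  y <- rnorm(n_lines, 0, sd)
  if (!is.null(qtl_marker)) y <- y + effect * (2 * g[, qtl_marker] - 1)
  geno <- matrix(c("B", "A")[g + 1], n_lines, n_mark,
                 dimnames = list(NULL, sprintf("m1_%02d", 1:n_mark)))
  map <- data.frame(marker = colnames(geno), chrom = 1, cM = cm,
                    bp = round(seq(1, 20e6, length.out = n_mark)))
  list(family = ril_family(geno, map, y), g = g, map = map, y = y)
}
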