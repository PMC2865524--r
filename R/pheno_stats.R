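## Field-design statistics: block model and least-square means, broad-sense
## heritability, transgressive segregation, latitude cline, NIL contrasts.

#' Fit the field-design fixed-effects model and extract least-square means
#'
#' Fits `trait ~ block + genotype (+ block:genotype) + covariates` with all
#' factors fixed, the covariates being the per-array trait values of the two
#' control accessions which absorb array effects within blocks. Least-square
#' means are adjusted genotype means: model predictions averaged over blocks
#' with covariates held at their global means.
#'
#' @param table Data frame with columns `genotype_id`, `block`, `trait_ptu`,
#'   and any covariate columns named in `covariates`.
#' @param covariates Character vector of numeric covariate column names
#'   (default the two control-accession covariates); missing columns are
#'   silently dropped from the model.
#' @param interaction Include a `block:genotype` term (used for parental
#'   lines and NILs, which are replicated within blocks).
#' @return List of class `block_model_fit` with `ls_means` (data frame
#'   `genotype_id`, `ls_mean`, `se`), `anova` (per-term `df`/`mean_sq` plus
#'   residual), and the underlying `fit`.
#' @export
fit_block_model <- function(table,
                            covariates = c("control_cov_bg2", "control_cov_lov5"),
                            interaction = FALSE) {
  stopifnot(all(c("genotype_id", "block", "trait_ptu") %in% names(table)))
  covariates <- intersect(covariates, names(table))
  df <- data.frame(trait = table$trait_ptu,
                   genotype = factor(table$genotype_id),
                   block = factor(table$block))
  for (cv in covariates) df[[cv]] <- table[[cv]]
  ## single-level factors carry no contrast; drop them from the formula
  rhs <- c(if (nlevels(df$block) > 1) "block",
           if (nlevels(df$genotype) > 1) "genotype",
           if (interaction && nlevels(df$block) > 1 &&
                 nlevels(df$genotype) > 1) "block:genotype",
           covariates)
  if (!length(rhs)) rhs <- "1"
  fml <- as.formula(paste("trait ~", paste(rhs, collapse = " + ")))
  fit <- lm(fml, data = df)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient field design; aliased terms: ",
         paste(bad, collapse = ", "))
  }

  ## LS means: average prediction over blocks, covariates at global means
  genos <- levels(df$genotype)
  blocks <- levels(df$block)
  tt <- delete.response(terms(fit))
  V <- vcov(fit)
  cov_means <- lapply(covariates, function(cv) mean(df[[cv]]))
  names(cov_means) <- covariates
  ls <- vapply(genos, function(g) {
    nd <- data.frame(genotype = factor(g, levels = genos),
                     block = factor(blocks, levels = blocks))
    for (cv in covariates) nd[[cv]] <- cov_means[[cv]]
    X <- model.matrix(tt, nd)
    L <- colMeans(X)
    c(sum(L * coef(fit)), sqrt(drop(t(L) %*% V %*% L)))
  }, numeric(2))
  ls_means <- data.frame(genotype_id = genos, ls_mean = ls[1, ], se = ls[2, ],
                         row.names = NULL)

  an <- anova(fit)
  terms_tab <- data.frame(term = rownames(an), df = an$Df,
                          mean_sq = an$`Mean Sq`, row.names = NULL)
  structure(list(ls_means = ls_means, anova = terms_tab, fit = fit),
            class = "block_model_fit")
}

#' Broad-sense heritability from mean squares
#'
#' Lynch & Walsh-style estimator from the genotype and residual mean squares
#' of the fixed-effects field model:
#' \eqn{\sigma^2_G = \max(0, (MS_G - MS_E)/r)} and
#' \eqn{H^2 = \sigma^2_G / (\sigma^2_G + MS_E)}, with `r` replicates per
#' genotype.
#'
#' @param ms_genotype,ms_error Genotype and residual mean squares, or pass a
#'   `block_model_fit` via `fit` to extract them.
#' @param r Replicates per genotype (the median replicate count in unbalanced
#'   designs). Must be >= 2.
#' @param fit Optional `block_model_fit`; overrides `ms_genotype`/`ms_error`.
#' @return List with `H2` (clipped to `[0, 1]`), `sigma2_G`, `sigma2_E`,
#'   `replicates_used`.
#' @export
broad_sense_heritability <- function(ms_genotype = NULL, ms_error = NULL, r,
                                     fit = NULL) {
  if (!is.null(fit)) {
    an <- fit$anova
    ms_genotype <- an$mean_sq[an$term == "genotype"]
    ms_error <- an$mean_sq[an$term == "Residuals"]
  }
  if (r < 2) stop("heritability undefined with fewer than 2 replicates")
  sigma2_G <- max(0, (ms_genotype - ms_error) / r)
  H2 <- sigma2_G / (sigma2_G + ms_error)
  list(H2 = min(1, max(0, H2)), sigma2_G = sigma2_G, sigma2_E = ms_error,
       replicates_used = r)
}

#' Transgressive segregation flags and intensity
#'
#' A family segregates transgressively when the most extreme RIL mean lies
#' beyond the more extreme parent by more than two parental standard
#' deviations. Intensity is the RIL phenotypic range divided by the absolute
#' parental difference.
#'
#' @param ril_means Genotypic means of the RILs (>= 2).
#' @param parentA_reps,parentB_reps Replicate values for each parent (>= 2
#'   each; the SD is taken across replicate plants).
#' @return List with `transgressive_low`, `transgressive_high`, `intensity`.
#' @export
transgression_stats <- function(ril_means, parentA_reps, parentB_reps) {
  if (length(ril_means) < 2) stop("need at least 2 RIL means")
  if (length(parentA_reps) < 2 || length(parentB_reps) < 2)
    stop("need at least 2 replicate values per parent")
  mA <- mean(parentA_reps); sA <- sd(parentA_reps)
  mB <- mean(parentB_reps); sB <- sd(parentB_reps)
  if (mA == mB) stop("identical parental means: transgression intensity undefined")
  low_bound <- min(mA - 2 * sA, mB - 2 * sB)
  high_bound <- max(mA + 2 * sA, mB + 2 * sB)
  list(transgressive_low = min(ril_means) < low_bound,
       transgressive_high = max(ril_means) > high_bound,
       intensity = (max(ril_means) - min(ril_means)) / abs(mA - mB))
}

#' Regression of transgression intensity on parental relatedness
#'
#' @param intensities Per-family transgression intensities.
#' @param kinships Per-family kinship coefficients between the parents.
#' @return List with `slope`, `p`, `n`.
#' @export
relatedness_vs_transgression <- function(intensities, kinships) {
  if (length(intensities) < 3) stop("need at least 3 families")
  fit <- lm(intensities ~ kinships)
  sm <- summary(fit)$coefficients
  if (nrow(sm) < 2)  # constant predictor
    return(list(slope = NA_real_, p = NA_real_, n = length(intensities)))
  list(slope = unname(sm[2, 1]), p = unname(sm[2, 4]), n = length(intensities))
}

#' Latitudinal cline in a panel trait
#'
#' Per-group OLS of trait on latitude of origin, with an optional latitude
#' exclusion filter (e.g. removing low-latitude outliers).
#'
#' @param trait Genotypic means (e.g. PTU LS means).
#' @param latitudes Latitudes of origin (degrees).
#' @param groups Optional grouping labels (e.g. FRI functional class); `NULL`
#'   fits a single group.
#' @param min_latitude Optional lower cutoff; accessions below it are dropped.
#' @return Data frame with one row per fitted group: `group`, `slope`, `se`,
#'   `p`, `n`. Groups with fewer than 3 members are skipped with a warning.
#' @export
latitude_cline <- function(trait, latitudes, groups = NULL,
                           min_latitude = NULL) {
  if (is.null(groups)) groups <- rep("all", length(trait))
  keep <- is.finite(trait) & is.finite(latitudes)
  if (!is.null(min_latitude)) keep <- keep & latitudes >= min_latitude
  trait <- trait[keep]; latitudes <- latitudes[keep]; groups <- groups[keep]
  out <- lapply(unique(groups), function(g) {
    i <- groups == g
    if (sum(i) < 3) {
      warning("group '", g, "' has fewer than 3 accessions; skipped")
      return(NULL)
    }
    sm <- summary(lm(trait[i] ~ latitudes[i]))$coefficients
    data.frame(group = g, slope = sm[2, 1], se = sm[2, 2], p = sm[2, 4],
               n = sum(i))
  })
  do.call(rbind, out)
}

#' Allele contrasts within heterogeneous inbred families
#'
#' For each HIF (a NIL pair segregating only at one genomic region), contrasts
#' the two allele classes with a pooled-variance two-sample t test. Effects of
#' opposite sign across HIFs validating one QTL are reported per HIF, never
#' averaged.
#'
#' @param nil_table Data frame with columns `hif_id`, `allele` (two classes)
#'   and `trait_ptu`.
#' @return Data frame with one row per HIF: `hif_id`, `allele_effect_ptu`
#'   (second allele class minus first, classes in sort order), `t_stat`, `p`,
#'   `n1`, `n2`. HIFs with a single class present are skipped with a warning.
#' @export
hif_contrast <- function(nil_table) {
  stopifnot(all(c("hif_id", "allele", "trait_ptu") %in% names(nil_table)))
  out <- lapply(split(nil_table, nil_table$hif_id), function(d) {
    classes <- sort(unique(as.character(d$allele)))
    if (length(classes) < 2) {
      warning("HIF '", d$hif_id[1], "' has a single allele class; skipped")
      return(NULL)
    }
    y1 <- d$trait_ptu[d$allele == classes[1]]
    y2 <- d$trait_ptu[d$allele == classes[2]]
    if (length(y1) < 2 || length(y2) < 2) {
      warning("HIF '", d$hif_id[1], "' has < 2 replicates in a class; skipped")
      return(NULL)
    }
    tt <- t.test(y2, y1, var.equal = TRUE)
    data.frame(hif_id = d$hif_id[1],
               allele_effect_ptu = mean(y2) - mean(y1),
               t_stat = unname(tt$statistic), p = tt$p.value,
               n1 = length(y1), n2 = length(y2))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
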