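## Phenology scaling: calendar flowering dates -> photothermal units (PTU)
## and accumulated chilling degrees, from a daily weather series.

#' Default phenology parameters
#'
#' @param base_temp Base temperature (deg C) subtracted from the daylight mean
#'   before accumulation. Default 3, the base temperature for the
#'   developmental rate of the Col-0 reference accession.
#' @param gating_temp Daily-mean temperature (deg C) a day must strictly
#'   exceed to contribute photothermal units. Default 3.
#' @param vern_threshold Temperature (deg C) below which a day accumulates
#'   chilling (vernalizing) degrees. Default 6.
#' @return A list of class `phenology_params`.
#' @export
phenology_params <- function(base_temp = 3, gating_temp = 3, vern_threshold = 6) {
  if (base_temp > vern_threshold)
    stop("base_temp must not exceed vern_threshold")
  structure(list(base_temp = base_temp, gating_temp = gating_temp,
                 vern_threshold = vern_threshold),
            class = "phenology_params")
}

#' Construct and validate a daily weather series
#'
#' @param date Vector of `Date`s, strictly increasing and contiguous
#'   (one row per calendar day, no gaps).
#' @param tmean Daily mean temperature (deg C).
#' @param tmean_daylight Mean temperature during daylight hours (deg C).
#' @param photoperiod_hours Hours of daylight, in `[0, 24]`. May be `NULL`,
#'   in which case `latitude` must be given and photoperiod is computed with
#'   [daylength()].
#' @param latitude Latitude in degrees, used only when `photoperiod_hours`
#'   is missing.
#' @return A `data.frame` of class `weather_series` with columns `date`,
#'   `tmean`, `tmean_daylight`, `photoperiod_hours`.
#' @export
weather_series <- function(date, tmean, tmean_daylight = tmean,
                           photoperiod_hours = NULL, latitude = NULL) {
  date <- as.Date(date)
  n <- length(date)
  if (n == 0) stop("empty weather series")
  if (any(diff(as.integer(date)) != 1L))
    stop("weather dates must be strictly increasing and contiguous (daily)")
  if (is.null(photoperiod_hours)) {
    if (is.null(latitude))
      stop("either photoperiod_hours or latitude must be supplied")
    photoperiod_hours <- daylength(latitude, as.integer(format(date, "%j")))
  }
  if (any(photoperiod_hours < 0 | photoperiod_hours > 24))
    stop("photoperiod_hours must lie in [0, 24]")
  if (any(!is.finite(tmean)) || any(!is.finite(tmean_daylight)))
    stop("temperatures must be finite")
  out <- data.frame(date = date, tmean = as.numeric(tmean),
                    tmean_daylight = as.numeric(tmean_daylight),
                    photoperiod_hours = as.numeric(photoperiod_hours))
  class(out) <- c("weather_series", "data.frame")
  out
}

#' Astronomical daylength
#'
#' Hours between sunrise and sunset from the standard solar-declination
#' formula (Forsythe et al. 1995 CBM model, horizon at the solar centre).
#'
#' @param latitude_deg Latitude in degrees, in `[-90, 90]`.
#' @param day_of_year Integer day of year, 1--366. Recycled against latitude.
#' @return Daylength in hours, in `[0, 24]` (0 or 24 inside polar circles).
#' @export
daylength <- function(latitude_deg, day_of_year) {
  if (any(latitude_deg < -90 | latitude_deg > 90))
    stop("latitude must lie in [-90, 90]")
  if (any(day_of_year < 1 | day_of_year > 366))
    stop("day_of_year must lie in [1, 366]")
  ## revolution angle and declination (radians)
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (day_of_year - 186)))
  decl <- asin(0.39795 * cos(theta))
  lat <- latitude_deg * pi / 180
  cosH <- -tan(lat) * tan(decl)
  cosH <- pmin(1, pmax(-1, cosH))  # polar day/night clamp
  (24 / pi) * acos(cosH)
}

.window_rows <- function(series, start, end, what = "requested window") {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("end date precedes start date")
  idx <- which(series$date >= start & series$date <= end)
  n_expected <- as.integer(end - start) + 1L
  if (length(idx) != n_expected)
    stop(sprintf("weather series does not cover %s [%s, %s] without gaps",
                 what, format(start), format(end)))
  idx
}

#' Accumulate photothermal units over a plant's life
#'
#' Sums, over every day from germination to flowering (both inclusive) whose
#' daily mean temperature strictly exceeds the gating temperature, the product
#' of the above-base daylight temperature and the photoperiod expressed as a
#' fraction of 24 h:
#' \deqn{PTU = \sum_i \max(0, \mu_i - \mu_b)\,\lambda_i}
#' where \eqn{\mu_i} is the daylight mean, \eqn{\mu_b} the base temperature
#' and \eqn{\lambda_i} the daily photoperiod as a proportion of 24 h. The
#' increment is floored at zero so cold daylight spells never subtract units.
#'
#' @param series A [weather_series()] covering the plant's lifespan.
#' @param germination_date,flowering_date Calendar dates (coerced with
#'   `as.Date`); flowering must not precede germination.
#' @param params A [phenology_params()] list.
#' @return Accumulated PTU (deg C x daylight), a non-negative scalar.
#' @export
accumulate_ptu <- function(series, germination_date, flowering_date,
                           params = phenology_params()) {
  idx <- .window_rows(series, germination_date, flowering_date,
                      "germination-to-flowering span")
  d <- series[idx, , drop = FALSE]
  keep <- d$tmean > params$gating_temp
  sum(pmax(0, d$tmean_daylight[keep] - params$base_temp) *
        d$photoperiod_hours[keep] / 24)
}

#' Accumulate chilling degrees over a window
#'
#' Sums `vern_threshold - tmean` over all days in `[start, end]` whose daily
#' mean temperature is strictly below the vernalization threshold.
#'
#' @inheritParams accumulate_ptu
#' @param start,end Window boundaries (inclusive).
#' @return Chilling degrees (deg C x day), non-negative.
#' @export
accumulate_chilling <- function(series, start, end,
                                params = phenology_params()) {
  idx <- .window_rows(series, start, end, "chilling window")
  d <- series[idx, , drop = FALSE]
  cold <- d$tmean < params$vern_threshold
  sum(params$vern_threshold - d$tmean[cold])
}

#' Year-to-year regression of paired genotype phenologies
#'
#' Ordinary least squares of year-2 values on year-1 values for genotypes
#' measured in both years. A slope of 1 indicates that the phenology scale
#' fully reproduces flowering across years.
#'
#' @param ptu_year1,ptu_year2 Numeric vectors, same genotype order.
#' @param conf_level Confidence level for the slope interval.
#' @return List with `slope`, `intercept`, `slope_ci` (length-2), `r_squared`,
#'   `n`.
#' @export
year_comparison <- function(ptu_year1, ptu_year2, conf_level = 0.95) {
  ok <- is.finite(ptu_year1) & is.finite(ptu_year2)
  x <- ptu_year1[ok]; y <- ptu_year2[ok]
  if (length(x) < 3) stop("need at least 3 paired genotypes")
  fit <- lm(y ~ x)
  ci <- confint(fit, "x", level = conf_level)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       slope_ci = as.numeric(ci), r_squared = summary(fit)$r.squared,
       n = length(x))
}

#' Coverage of one phenotypic range by another
#'
#' Fraction (as a percentage) of a full range spanned by a sub-range, e.g.
#' how much of the variation among natural accessions is covered by the
#' parents of a set of RIL families.
#'
#' @param sub_min,sub_max Range of the subset (e.g. RIL parents).
#' @param full_min,full_max Range of the full panel.
#' @return Coverage in percent: `100 * (sub_max - sub_min) / (full_max - full_min)`.
#' @export
range_coverage <- function(sub_min, sub_max, full_min, full_max) {
  if (sub_max < sub_min || full_max <= full_min)
    stop("ranges must be non-degenerate and ordered")
  100 * (sub_max - sub_min) / (full_max - full_min)
}
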