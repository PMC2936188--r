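#' Test-retest summary of a measurement series
#'
#' Mean, sample standard deviation (n - 1 denominator) and coefficient of
#' variation (COV = SD / mean) of a longitudinal volume series. For a
#' volumetrically stable organ measured repeatedly, the COV is the relative
#' precision of the measurement process itself.
#'
#' @param volumes Numeric vector of volumes (cm^3), one per scan, or an
#'   object of class `organ_series` (see [simulate_longitudinal_series()]).
#' @return An object of class `precision_summary`: list with `n`, `mean`,
#'   `sd`, `cov`.
#' @export
#' @examples
#' series_summary(c(1, 2, 3)) # mean 2, sd 1, cov 0.5
series_summary <- function(volumes) {
  if (inherits(volumes, "organ_series")) volumes <- volumes$volume_cm3
  if (!is.numeric(volumes))
    stop_validation("`volumes` must be numeric")
  if (length(volumes) < 2L)
    stop_validation("a precision summary needs at least 2 measurements (got %d)",
                    length(volumes))
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop_validation("all volumes must be finite and > 0")
  m <- mean(volumes)
  s <- stats::sd(volumes)
  structure(list(n = length(volumes), mean = m, sd = s, cov = s / m),
            class = "precision_summary")
}

#' @export
print.precision_summary <- function(x, ...) {
  cat(sprintf("<precision_summary> n=%d  mean=%.2f cm^3  sd=%.2f cm^3  COV=%.1f%%\n",
              x$n, x$mean, x$sd, 100 * x$cov))
  invisible(x)
}

#' Cohort aggregation of per-patient COVs
#'
#' Unweighted mean and sample SD of a set of per-series coefficients of
#' variation. Each series' COV already pools all of that patient's scans, so
#' the cohort summary deliberately weights patients equally rather than by
#' scan count.
#'
#' @param per_patient_covs Numeric vector of COVs (fractions or percents;
#'   the result is in the same unit).
#' @return List with `n`, `mean`, `sd` (`sd` is `NA` for a single value).
#' @export
cohort_cov_summary <- function(per_patient_covs) {
  if (!is.numeric(per_patient_covs) || length(per_patient_covs) == 0L)
    stop_validation("`per_patient_covs` must be a non-empty numeric vector")
  if (any(!is.finite(per_patient_covs)))
    stop_validation("all COVs must be finite")
  list(n = length(per_patient_covs),
       mean = mean(per_patient_covs),
       sd = if (length(per_patient_covs) >= 2L) stats::sd(per_patient_covs)
            else NA_real_)
}

#' Inter-observer mean percent difference
#'
#' Mean over paired measurements of the difference between two observers'
#' volumes relative to their pairwise mean, `|V1 - V2| / ((V1 + V2)/2)`.
#' The absolute value is taken by default (the conventional positive
#' reporting); set `signed = TRUE` for the signed version, whose mean can
#' reveal a systematic offset between observers.
#'
#' The statistic is symmetric in the two observers (up to sign) and bounded
#' by 2 for positive volumes.
#'
#' @param volumes_obs1,volumes_obs2 Equal-length numeric vectors of paired
#'   volumes (cm^3) from the two observers.
#' @param signed Keep the sign of `observer 1 - observer 2`? Default FALSE.
#' @return Mean (absolute) percent difference as a fraction.
#' @export
interobserver_mean_percent_difference <- function(volumes_obs1, volumes_obs2,
                                                  signed = FALSE) {
  if (!is.numeric(volumes_obs1) || !is.numeric(volumes_obs2))
    stop_validation("observer volumes must be numeric")
  if (length(volumes_obs1) != length(volumes_obs2))
    stop_validation("observer series differ in length (%d vs %d)",
                    length(volumes_obs1), length(volumes_obs2))
  if (length(volumes_obs1) < 1L)
    stop_validation("need at least one measurement pair")
  if (any(!is.finite(volumes_obs1)) || any(!is.finite(volumes_obs2)) ||
      any(volumes_obs1 <= 0) || any(volumes_obs2 <= 0))
    stop_validation("all volumes must be finite and > 0")
  d <- (volumes_obs1 - volumes_obs2) / ((volumes_obs1 + volumes_obs2) / 2)
  if (!signed) d <- abs(d)
  mean(d)
}

#' Squared correlation of paired measurement series
#'
#' Squared Pearson correlation (coefficient of determination, r^2) between
#' two time-matched volume series — for instance the left and right organ of
#' a pair, matched scan by scan. A low r^2 across a cohort indicates that
#' volume fluctuations are measurement noise rather than shared physiology.
#'
#' @param series_a,series_b Equal-length numeric vectors (n >= 3), matched
#'   by scan order.
#' @return r^2 in `[0, 1]`.
#' @export
paired_series_r2 <- function(series_a, series_b) {
  if (!is.numeric(series_a) || !is.numeric(series_b))
    stop_validation("series must be numeric")
  if (length(series_a) != length(series_b))
    stop_validation("paired series differ in length (%d vs %d)",
                    length(series_a), length(series_b))
  if (length(series_a) < 3L)
    stop_validation("r^2 needs at least 3 matched pairs")
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0)
    stop_validation("correlation is undefined for a constant series")
  stats::cor(series_a, series_b)^2
}

#' Trend of measurement COV against object volume
#'
#' Ordinary least-squares fit of per-series COV on mean volume (or on log
#' volume). Measurement precision improves with object size — larger objects
#' span more slices and a fixed-length boundary error is relatively smaller —
#' so the fitted slope is expected to be negative.
#'
#' @param volume_cm3 Numeric vector of per-series mean volumes.
#' @param cov Numeric vector of per-series COVs (fraction or percent).
#' @param form `"linear"` regresses COV on volume; `"log-volume"` on
#'   `log(volume)`.
#' @return List with `slope`, `intercept`, `r_squared`, `form`.
#' @export
cov_volume_trend <- function(volume_cm3, cov,
                             form = c("linear", "log-volume")) {
  form <- match.arg(form)
  if (!is.numeric(volume_cm3) || !is.numeric(cov))
    stop_validation("trend inputs must be numeric")
  if (length(volume_cm3) != length(cov))
    stop_validation("`volume_cm3` and `cov` differ in length")
  if (length(volume_cm3) < 3L)
    stop_validation("trend fit needs at least 3 points")
  if (any(!is.finite(volume_cm3)) || any(!is.finite(cov)) ||
      any(volume_cm3 <= 0))
    stop_validation("volumes must be positive and all inputs finite")
  if (stats::sd(volume_cm3) == 0)
    stop_validation("volumes must not all be equal")
  x <- if (form == "linear") volume_cm3 else log(volume_cm3)
  fit <- stats::lm(cov ~ x)
  r2 <- if (stats::sd(cov) == 0) 1 else stats::cor(x, cov)^2
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2,
       form = form)
}
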