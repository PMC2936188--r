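#' Precision report for a longitudinal volume series file
#'
#' Runs the full precision analysis over a cohort of longitudinal volume
#' series: per-patient/per-organ mean volumes and COVs with cohort
#' aggregates, paired-organ r^2 per patient, the COV-versus-volume trend,
#' and the minimal detectable change for every series. Organs with fewer
#' than 2 scans are excluded with a warning (precision is undefined for a
#' single measurement). The report is a pure function of its inputs:
#' rerunning on the same data yields byte-identical files.
#'
#' All rounding to display precision (volumes and percents to 1 decimal)
#' happens only in the human-readable summary; the CSV outputs carry full
#' precision alongside the display columns.
#'
#' @param series A data.frame in the series-CSV layout (columns
#'   `patient_id, scan_id, organ_label, volume_cm3`, optional `scan_date`)
#'   or a path to such a CSV.
#' @param out_dir Optional output directory; when given, the tables are
#'   written as CSV plus a plain-text `summary.txt`.
#' @param alpha Significance level for the detectable-change computation.
#' @param trend_form Trend regressor for [cov_volume_trend()]: `"linear"`
#'   (default) or `"log-volume"`.
#' @param config Optional named list recorded in the bundle metadata.
#' @return An object of class `report_bundle`: list with `volume_table`,
#'   `cov_table`, `r2_table`, `trend`, `detectable`, `metadata`.
#' @export
run_report <- function(series, out_dir = NULL, alpha = 0.05,
                       trend_form = c("linear", "log-volume"),
                       config = list()) {
  trend_form <- match.arg(trend_form)
  if (is.character(series) && length(series) == 1L)
    series <- read_series(series)
  missing_cols <- setdiff(series_csv_columns, names(series))
  if (length(missing_cols) > 0L)
    stop_format("series input is missing required column(s): %s",
                paste(missing_cols, collapse = ", "))
  if (nrow(series) == 0L)
    stop_validation("series input is empty")
  if (!is.numeric(series$volume_cm3) || any(!is.finite(series$volume_cm3)) ||
      any(series$volume_cm3 <= 0))
    stop_validation("all volumes must be finite and > 0")

  key <- interaction(series$patient_id, series$organ_label, drop = TRUE)
  groups <- split(series, key)
  small <- vapply(groups, nrow, integer(1)) < 2L
  if (any(small)) {
    warning(sprintf("excluding organ series with < 2 scans: %s",
                    paste(names(groups)[small], collapse = ", ")),
            call. = FALSE)
    groups <- groups[!small]
  }
  if (length(groups) == 0L)
    stop_validation("no organ series with >= 2 scans")

  per_organ <- do.call(rbind, lapply(groups, function(g) {
    s <- series_summary(g$volume_cm3)
    data.frame(patient_id = g$patient_id[1L],
               organ_label = g$organ_label[1L],
               n_scans = s$n, mean_cm3 = s$mean, sd_cm3 = s$sd, cov = s$cov,
               stringsAsFactors = FALSE)
  }))
  per_organ <- per_organ[order(per_organ$patient_id, per_organ$organ_label), ,
                         drop = FALSE]
  rownames(per_organ) <- NULL

  cohort_by_organ <- do.call(rbind, lapply(
    split(per_organ, per_organ$organ_label), function(g) {
      cs <- cohort_cov_summary(g$cov)
      data.frame(organ_label = g$organ_label[1L], n_patients = cs$n,
                 mean_volume_cm3 = mean(g$mean_cm3),
                 sd_volume_cm3 = if (nrow(g) >= 2L) stats::sd(g$mean_cm3) else NA_real_,
                 mean_cov = cs$mean, sd_cov = cs$sd,
                 stringsAsFactors = FALSE)
    }))
  rownames(cohort_by_organ) <- NULL

  # paired-organ r^2: patients with exactly two organ series of equal length,
  # matched by scan order
  r2_rows <- lapply(split(per_organ, per_organ$patient_id), function(g) {
    if (nrow(g) != 2L) return(NULL)
    a <- groups[[paste(g$patient_id[1L], g$organ_label[1L], sep = ".")]]
    b <- groups[[paste(g$patient_id[1L], g$organ_label[2L], sep = ".")]]
    if (is.null(a) || is.null(b) || nrow(a) != nrow(b) || nrow(a) < 3L)
      return(NULL)
    r2 <- tryCatch(paired_series_r2(a$volume_cm3, b$volume_cm3),
                   volprec_error = function(e) NA_real_)
    data.frame(patient_id = g$patient_id[1L],
               organ_a = g$organ_label[1L], organ_b = g$organ_label[2L],
               n_pairs = nrow(a), r_squared = r2, stringsAsFactors = FALSE)
  })
  r2_table <- do.call(rbind, r2_rows[!vapply(r2_rows, is.null, logical(1))])
  r2_summary <- if (!is.null(r2_table) && sum(!is.na(r2_table$r_squared)) > 0L)
    cohort_cov_summary(r2_table$r_squared[!is.na(r2_table$r_squared)])
  else NULL

  trend <- if (nrow(per_organ) >= 3L && stats::sd(per_organ$mean_cm3) > 0)
    cov_volume_trend(per_organ$mean_cm3, per_organ$cov, form = trend_form)
  else NULL

  detectable <- do.call(rbind, lapply(seq_len(nrow(per_organ)), function(i) {
    d <- min_detectable_volume_change(per_organ$mean_cm3[i],
                                      per_organ$sd_cm3[i],
                                      per_organ$n_scans[i], alpha)
    data.frame(patient_id = per_organ$patient_id[i],
               organ_label = per_organ$organ_label[i],
               alpha = alpha,
               min_detectable_volume_fraction = d$min_detectable_volume_fraction,
               equivalent_linear_fraction = d$equivalent_linear_fraction,
               stringsAsFactors = FALSE)
  }))

  bundle <- structure(
    list(volume_table = per_organ,
         cohort_table = cohort_by_organ,
         r2_table = r2_table,
         r2_summary = r2_summary,
         trend = trend,
         detectable = detectable,
         metadata = list(alpha = alpha, trend_form = trend_form,
                         n_measurements = nrow(series),
                         config = config,
                         package_version = as.character(utils::packageVersion("volprec")))),
    class = "report_bundle")

  if (!is.null(out_dir)) write_report_files(bundle, out_dir)
  bundle
}

# CSV tables with full-precision and display (1 d.p.) columns, plus a
# plain-text summary mirroring the usual mean-volume / COV / r^2 layout.
write_report_files <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vt <- bundle$volume_table
  vt$mean_cm3_display <- round_half_up(vt$mean_cm3, 1)
  vt$cov_pct_display <- round_half_up(100 * vt$cov, 1)
  utils::write.csv(vt, file.path(out_dir, "mean_volumes.csv"),
                   row.names = FALSE, quote = FALSE)
  ct <- bundle$cohort_table
  ct$mean_cov_pct_display <- round_half_up(100 * ct$mean_cov, 1)
  utils::write.csv(ct, file.path(out_dir, "cohort_cov.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(bundle$r2_table))
    utils::write.csv(bundle$r2_table, file.path(out_dir, "paired_r2.csv"),
                     row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(bundle$trend))
    utils::write.csv(as.data.frame(bundle$trend),
                     file.path(out_dir, "cov_volume_trend.csv"),
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$detectable,
                   file.path(out_dir, "detectable_change.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(format_report_summary(bundle), file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

format_report_summary <- function(bundle) {
  vt <- bundle$volume_table
  out <- c("Longitudinal volume precision report", "")
  out <- c(out, "Per-organ series (mean volume cm^3 / COV %):")
  out <- c(out, sprintf("  %-12s %-16s n=%2d  mean=%5.1f  COV=%5.1f%%",
                        vt$patient_id, vt$organ_label, vt$n_scans,
                        round_half_up(vt$mean_cm3, 1),
                        round_half_up(100 * vt$cov, 1)))
  ct <- bundle$cohort_table
  out <- c(out, "", "Cohort aggregates by organ:")
  out <- c(out, sprintf("  %-16s n=%2d  mean volume=%5.1f cm^3  mean COV=%5.1f%%",
                        ct$organ_label, ct$n_patients,
                        round_half_up(ct$mean_volume_cm3, 1),
                        round_half_up(100 * ct$mean_cov, 1)))
  if (!is.null(bundle$r2_table)) {
    out <- c(out, "", "Paired-organ r^2 (scan-order matched):")
    out <- c(out, sprintf("  %-12s %s vs %s: r^2=%.3f",
                          bundle$r2_table$patient_id, bundle$r2_table$organ_a,
                          bundle$r2_table$organ_b, bundle$r2_table$r_squared))
    if (!is.null(bundle$r2_summary))
      out <- c(out, sprintf("  cohort mean r^2=%.3f (sd %.3f)",
                            bundle$r2_summary$mean, bundle$r2_summary$sd))
  }
  if (!is.null(bundle$trend))
    out <- c(out, "", sprintf(
      "COV-volume trend (%s): slope=%.4f per cm^3, intercept=%.4f, r^2=%.3f",
      bundle$trend$form, bundle$trend$slope, bundle$trend$intercept,
      bundle$trend$r_squared))
  dt <- bundle$detectable
  out <- c(out, "", sprintf("Minimal detectable volume change (alpha=%g):",
                            bundle$metadata$alpha))
  out <- c(out, sprintf("  %-12s %-16s dV=%5.1f%%  (linear %4.1f%%)",
                        dt$patient_id, dt$organ_label,
                        round_half_up(100 * dt$min_detectable_volume_fraction, 1),
                        round_half_up(100 * dt$equivalent_linear_fraction, 1)))
  out
}

#' @export
print.report_bundle <- function(x, ...) {
  writeLines(format_report_summary(x))
  invisible(x)
}

#' Simulate-and-analyze pipeline
#'
#' One-command end-to-end run: simulate a longitudinal phantom series,
#' compute its volumes, and produce the precision report. The master seed
#' is recorded in the bundle metadata; the whole pipeline is a pure
#' function of the phantom specification.
#'
#' @param spec A [phantom_spec()] with `seed` set.
#' @param out_dir Optional output directory for the simulated CSVs and the
#'   report files.
#' @param alpha Significance level for the detectable-change computation.
#' @return A `report_bundle` (see [run_report()]) with the simulated
#'   `organ_series` attached as `$series`.
#' @export
run_end_to_end <- function(spec, out_dir = NULL, alpha = 0.05) {
  if (!inherits(spec, "phantom_spec"))
    stop_validation("`spec` must be a phantom_spec")
  series <- simulate_longitudinal_series(spec, out_dir = out_dir)
  bundle <- run_report(as.data.frame(series), out_dir = out_dir, alpha = alpha,
                       config = list(shape = spec$shape, seed = spec$seed,
                                     n_scans = spec$n_scans,
                                     slice_thickness_mm = spec$slice_thickness_mm))
  bundle$series <- series
  bundle
}
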