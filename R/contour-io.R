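#' Planar ROI contour on one CT slice
#'
#' A contour is an ordered list of in-plane vertices (mm) delineating one
#' organ's cross-section on one CT slice. The polygon is implicitly closed:
#' the last vertex connects back to the first. An explicitly repeated first
#' vertex (the other common export convention of freehand ROI tools) is
#' tolerated and removed.
#'
#' @param patient_id,scan_id,organ_label Identifiers (character scalars).
#' @param slice_index Integer position of the slice within the stack.
#' @param z_mm Through-plane position of the slice center, mm.
#' @param vertices Two-column numeric matrix (or data.frame) of in-plane
#'   `x, y` coordinates in mm, ordered along the boundary.
#' @param slice_thickness_mm Nominal thickness of this slice, mm. Thickness
#'   is carried per contour so that scans with mixed section thickness
#'   (e.g. 5 and 10 mm) are representable.
#'
#' @return An object of class `ct_contour`.
#' @seealso [polygon_area()], [slice_stack()]
#' @export
#' @examples
#' sq <- contour("p1", "s1", "left_adrenal", 1, 0,
#'               cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), 5)
#' polygon_area(sq) # 1 cm^2
contour <- function(patient_id, scan_id, organ_label, slice_index, z_mm,
                    vertices, slice_thickness_mm) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 2L)
    stop_validation("contour vertices must have two columns (x_mm, y_mm)")
  n <- nrow(vertices)
  if (n >= 2L && all(vertices[1L, ] == vertices[n, ]))
    vertices <- vertices[-n, , drop = FALSE]
  if (nrow(vertices) < 3L)
    stop_validation("invalid contour (%s/%s/%s slice %s): fewer than 3 vertices",
                    patient_id, scan_id, organ_label, slice_index)
  if (!all(is.finite(vertices)))
    stop_validation("invalid contour (%s/%s/%s slice %s): non-finite coordinate",
                    patient_id, scan_id, organ_label, slice_index)
  if (!is.finite(z_mm))
    stop_validation("contour z position must be finite")
  check_positive_scalar(slice_thickness_mm, "slice_thickness_mm")
  structure(
    list(patient_id = as.character(patient_id),
         scan_id = as.character(scan_id),
         organ_label = as.character(organ_label),
         slice_index = as.integer(slice_index),
         z_mm = as.numeric(z_mm),
         slice_thickness_mm = as.numeric(slice_thickness_mm),
         vertices = unname(vertices)),
    class = "ct_contour")
}

#' @export
print.ct_contour <- function(x, ...) {
  cat(sprintf("<ct_contour> %s/%s/%s slice %d @ z=%.2f mm, %d vertices, %.3f cm^2\n",
              x$patient_id, x$scan_id, x$organ_label, x$slice_index,
              x$z_mm, nrow(x$vertices), polygon_area(x)))
  invisible(x)
}

#' Enclosed area of a planar contour (shoelace formula)
#'
#' Absolute area of the implicitly closed polygon, computed by the shoelace
#' (Gauss) formula and converted from mm^2 to cm^2. The result is independent
#' of vertex orientation (clockwise vs counter-clockwise), of which vertex
#' the boundary starts at, and of translation of the slice coordinate frame.
#'
#' A degenerate (zero-area) polygon returns 0 with a warning; downstream
#' volume computation treats zero-area contours as a hard validation error
#' so they can never silently contribute an empty slice.
#'
#' @param x A [contour()] object, or a two-column matrix of vertices in mm.
#' @return Area in cm^2.
#' @export
polygon_area <- function(x) {
  v <- if (inherits(x, "ct_contour")) x$vertices else {
    v <- as.matrix(x)
    if (ncol(v) != 2L) stop_validation("vertex matrix must have two columns")
    n <- nrow(v)
    if (n >= 2L && all(v[1L, ] == v[n, ])) v <- v[-n, , drop = FALSE]
    v
  }
  if (nrow(v) < 3L)
    stop_validation("invalid contour: fewer than 3 vertices")
  if (!all(is.finite(v)))
    stop_validation("invalid contour: non-finite coordinate")
  xx <- v[, 1L]; yy <- v[, 2L]
  xn <- c(xx[-1L], xx[1L]); yn <- c(yy[-1L], yy[1L])
  area_mm2 <- abs(sum(xx * yn - xn * yy)) / 2
  if (area_mm2 == 0)
    warning("degenerate contour: enclosed area is zero", call. = FALSE)
  area_mm2 / 100
}

#' Stack of contours for one organ in one scan
#'
#' Collects all contours of one organ in one scan, ordered by through-plane
#' position. One slice-summation volume is computed from each stack.
#'
#' @param contours List of [contour()] objects sharing patient, scan and
#'   organ identifiers.
#' @param slice_thickness_mm Stack-level nominal thickness, mm. Defaults to
#'   the modal per-contour thickness.
#' @return An object of class `ct_slice_stack`.
#' @seealso [validate_stack()], [volume_from_stack()]
#' @export
slice_stack <- function(contours, slice_thickness_mm = NULL) {
  if (!is.list(contours) || length(contours) == 0L ||
      !all(vapply(contours, inherits, logical(1), "ct_contour")))
    stop_validation("`contours` must be a non-empty list of ct_contour objects")
  ids <- unique(t(vapply(contours, function(ct)
    c(ct$patient_id, ct$scan_id, ct$organ_label), character(3))))
  if (nrow(ids) != 1L)
    stop_validation("all contours in a stack must share patient, scan and organ")
  z <- vapply(contours, function(ct) ct$z_mm, numeric(1))
  contours <- contours[order(z)]
  if (is.null(slice_thickness_mm)) {
    th <- vapply(contours, function(ct) ct$slice_thickness_mm, numeric(1))
    tab <- table(th)
    slice_thickness_mm <- as.numeric(names(tab)[which.max(tab)])
  }
  check_positive_scalar(slice_thickness_mm, "slice_thickness_mm")
  structure(
    list(patient_id = ids[1L, 1L], scan_id = ids[1L, 2L],
         organ_label = ids[1L, 3L],
         slice_thickness_mm = as.numeric(slice_thickness_mm),
         contours = contours),
    class = "ct_slice_stack")
}

#' @export
print.ct_slice_stack <- function(x, ...) {
  cat(sprintf("<ct_slice_stack> %s/%s/%s: %d slices @ t=%.1f mm\n",
              x$patient_id, x$scan_id, x$organ_label,
              length(x$contours), x$slice_thickness_mm))
  invisible(x)
}

#' Validate a slice stack
#'
#' Checks the structural invariants of a stack and reports, rather than
#' throws: strictly increasing z positions with at most one contour per z,
#' inter-slice spacing an integer multiple of the slice thickness (within
#' 1e-6 mm), and positive enclosed area on every slice.
#'
#' A partial-coverage warning is raised when the first or last contour's
#' area exceeds `edge_area_fraction` of the maximum contour area: an organ
#' fully covered by the scan should taper off at both ends, so a thick
#' outermost slice suggests the scan clipped the organ (such scans are
#' conventionally excluded from precision series).
#'
#' @param stack A [slice_stack()].
#' @param edge_area_fraction Fraction of the maximum contour area above
#'   which an outermost contour triggers the partial-coverage warning.
#'   Default 0.5.
#' @return A list with elements `valid` (logical), `violations` and
#'   `warnings` (character vectors).
#' @export
validate_stack <- function(stack, edge_area_fraction = 0.5) {
  if (!inherits(stack, "ct_slice_stack"))
    stop_validation("`stack` must be a ct_slice_stack")
  violations <- character()
  warnings <- character()
  lab <- sprintf("%s/%s/%s", stack$patient_id, stack$scan_id, stack$organ_label)
  t <- stack$slice_thickness_mm
  if (!is.finite(t) || t <= 0)
    violations <- c(violations, sprintf("%s: slice thickness must be > 0", lab))
  z <- vapply(stack$contours, function(ct) ct$z_mm, numeric(1))
  if (anyDuplicated(z))
    violations <- c(violations,
                    sprintf("%s: more than one contour at z = %g mm", lab,
                            z[duplicated(z)][1L]))
  if (length(z) > 1L && is.finite(t) && t > 0) {
    dz <- diff(sort(z))
    bad <- abs(dz - round(dz / t) * t) > 1e-6 | round(dz / t) < 1
    if (any(bad[dz > 0]))
      violations <- c(violations,
                      sprintf("%s: slice spacing %g mm is not an integer multiple of thickness %g mm",
                              lab, dz[dz > 0][bad[dz > 0]][1L], t))
  }
  areas <- vapply(stack$contours, function(ct) {
    suppressWarnings(polygon_area(ct))
  }, numeric(1))
  if (any(areas <= 0))
    violations <- c(violations,
                    sprintf("%s: zero-area contour at z = %g mm", lab,
                            z[areas <= 0][1L]))
  if (length(areas) >= 1L && all(areas > 0)) {
    amax <- max(areas)
    if (areas[1L] > edge_area_fraction * amax ||
        areas[length(areas)] > edge_area_fraction * amax)
      warnings <- c(warnings,
                    sprintf("%s: possible partial coverage (outermost contour area > %.0f%% of maximum)",
                            lab, 100 * edge_area_fraction))
  }
  list(valid = length(violations) == 0L,
       violations = violations, warnings = warnings)
}

contour_csv_columns <- c("patient_id", "scan_id", "organ_label", "slice_index",
                         "z_mm", "slice_thickness_mm", "vertex_index",
                         "x_mm", "y_mm")

#' Read contours from a contour CSV file
#'
#' The contour CSV holds one vertex per row with columns `patient_id,
#' scan_id, organ_label, slice_index, z_mm, slice_thickness_mm, vertex_index,
#' x_mm, y_mm` (UTF-8, header required, decimal point). Rows are grouped by
#' `(patient_id, scan_id, organ_label)` into slice stacks, vertices ordered
#' by `vertex_index`, and all stack invariants are enforced.
#'
#' @param path Path to a contour CSV file.
#' @return A list of [slice_stack()] objects, ordered by patient, scan and
#'   organ identifiers.
#' @export
read_contours <- function(path) {
  if (!file.exists(path))
    stop_io("contour file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(contour_csv_columns, names(df))
  if (length(missing_cols) > 0L)
    stop_format("contour file %s is missing required column(s): %s",
                path, paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  key <- paste(df$patient_id, df$scan_id, df$organ_label, df$z_mm,
               df$vertex_index, sep = "\r")
  if (anyDuplicated(key))
    stop_format("contour file %s: duplicate (scan, organ, z, vertex_index) row: %s",
                path, gsub("\r", "/", key[duplicated(key)][1L]))
  df <- df[order(df$patient_id, df$scan_id, df$organ_label,
                 df$slice_index, df$vertex_index), , drop = FALSE]
  stack_key <- paste(df$patient_id, df$scan_id, df$organ_label, sep = "\r")
  stacks <- lapply(split(df, factor(stack_key, levels = unique(stack_key))),
                   function(sdf) {
    contours <- lapply(split(sdf, sdf$slice_index), function(cdf) {
      contour(cdf$patient_id[1L], cdf$scan_id[1L], cdf$organ_label[1L],
              cdf$slice_index[1L], cdf$z_mm[1L],
              cbind(cdf$x_mm, cdf$y_mm), cdf$slice_thickness_mm[1L])
    })
    slice_stack(unname(contours))
  })
  stacks <- unname(stacks)
  for (st in stacks) {
    rep <- validate_stack(st)
    if (!rep$valid)
      stop_validation("invalid contour data in %s: %s",
                      path, rep$violations[1L])
  }
  stacks
}

#' Write contours to a contour CSV file
#'
#' Writes stacks in the deterministic row order (patient, scan, organ,
#' slice_index, vertex_index); the output round-trips bit-exactly through
#' [read_contours()].
#'
#' @param stacks A list of [slice_stack()] objects (may be empty: a
#'   header-only file is written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(stacks, path) {
  if (inherits(stacks, "ct_slice_stack")) stacks <- list(stacks)
  rows <- lapply(stacks, function(st) {
    do.call(rbind, lapply(st$contours, function(ct) {
      n <- nrow(ct$vertices)
      data.frame(patient_id = ct$patient_id, scan_id = ct$scan_id,
                 organ_label = ct$organ_label, slice_index = ct$slice_index,
                 z_mm = ct$z_mm, slice_thickness_mm = ct$slice_thickness_mm,
                 vertex_index = seq_len(n),
                 x_mm = ct$vertices[, 1L], y_mm = ct$vertices[, 2L],
                 stringsAsFactors = FALSE)
    }))
  })
  df <- if (length(rows) > 0L) do.call(rbind, rows) else
    as.data.frame(stats::setNames(rep(list(character(0)), length(contour_csv_columns)),
                                  contour_csv_columns))
  if (nrow(df) > 0L)
    df <- df[order(df$patient_id, df$scan_id, df$organ_label,
                   df$slice_index, df$vertex_index), , drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io("cannot write contour file: %s", path)
  invisible(path)
}

series_csv_columns <- c("patient_id", "scan_id", "organ_label", "volume_cm3")

#' Read or write a longitudinal volume series CSV
#'
#' The series CSV holds one volume measurement per row with columns
#' `patient_id, scan_id, scan_date (ISO-8601, optional), organ_label,
#' volume_cm3`.
#'
#' @param path Path to a series CSV file.
#' @return `read_series()`: a data.frame of measurements in file order.
#' @export
read_series <- function(path) {
  if (!file.exists(path))
    stop_io("series file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(series_csv_columns, names(df))
  if (length(missing_cols) > 0L)
    stop_format("series file %s is missing required column(s): %s",
                path, paste(missing_cols, collapse = ", "))
  if (!"scan_date" %in% names(df)) df$scan_date <- NA_character_
  if (nrow(df) > 0L && (!is.numeric(df$volume_cm3) || any(!is.finite(df$volume_cm3)) ||
                        any(df$volume_cm3 <= 0)))
    stop_validation("series file %s: all volumes must be finite and > 0", path)
  df[, c("patient_id", "scan_id", "scan_date", "organ_label", "volume_cm3")]
}

#' @param series Data.frame with the series CSV columns.
#' @rdname read_series
#' @return `write_series()`: `path`, invisibly.
#' @export
write_series <- function(series, path) {
  missing_cols <- setdiff(series_csv_columns, names(series))
  if (length(missing_cols) > 0L)
    stop_format("series is missing required column(s): %s",
                paste(missing_cols, collapse = ", "))
  if (!"scan_date" %in% names(series)) series$scan_date <- NA_character_
  series <- series[, c("patient_id", "scan_id", "scan_date", "organ_label",
                       "volume_cm3")]
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
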