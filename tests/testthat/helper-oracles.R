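# Independent oracles and fixture builders used across the test files.

# Brute-force polygon area: even-odd point-in-polygon counting on a grid of
# cell centers (pitch h mm). Deliberately shares no code with the shoelace
# implementation.
rasterized_polygon_area <- function(vertices, h = 0.05) {
  v <- as.matrix(vertices)
  xr <- range(v[, 1]); yr <- range(v[, 2])
  gx <- seq(xr[1] - h / 2, xr[2] + h, by = h)
  gy <- seq(yr[1] - h / 2, yr[2] + h, by = h)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  sum(inside) * h^2 / 100  # cm^2
}

# Random simple (star-shaped) polygon: radii drawn at sorted angles.
random_star_polygon <- function(n, r_min = 3, r_max = 10) {
  theta <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, r_min, r_max)
  cbind(r * cos(theta), r * sin(theta))
}

# Two-pass summary statistics, written independently of series_summary().
brute_force_summary <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  list(n = n, mean = m, sd = s, cov = s / m)
}

# Regular polygon contour approximating a circle of radius r_mm at height z.
circle_contour <- function(r_mm, z_mm, slice_index = 1L, n = 128L,
                           thickness_mm = 5, patient = "p1", scan = "s1",
                           organ = "o1") {
  theta <- (seq_len(n) - 1L) * 2 * pi / n
  contour(patient, scan, organ, slice_index, z_mm,
          cbind(r_mm * cos(theta), r_mm * sin(theta)), thickness_mm)
}

# Stack of polygon contours with EXACTLY the given areas (cm^2) at spacing
# t: the circumradius is inflated so the inscribed polygon hits the target.
stack_with_areas <- function(areas_cm2, thickness_mm = 5, n = 128L, ...) {
  radii <- sqrt(areas_cm2 * 100 / ((n / 2) * sin(2 * pi / n)))
  contours <- lapply(seq_along(radii), function(i)
    circle_contour(radii[i], (i - 1) * thickness_mm, slice_index = i,
                   thickness_mm = thickness_mm, ...))
  slice_stack(contours, slice_thickness_mm = thickness_mm)
}

# Noise-free discretized sphere: circle contours at slice centers
# z = -r + (k + 1/2) t.
sphere_stack <- function(diameter_mm, thickness_mm, n_vertices = 128L) {
  r <- diameter_mm / 2
  z <- seq(-r + thickness_mm / 2, r, by = thickness_mm)
  z <- z[abs(z) < r]
  contours <- lapply(seq_along(z), function(i)
    circle_contour(sqrt(r^2 - z[i]^2), z[i], slice_index = i,
                   n = n_vertices, thickness_mm = thickness_mm))
  slice_stack(contours, slice_thickness_mm = thickness_mm)
}

# Published reference tables (shipped as plain-text fixtures).
fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "volprec")
  if (nzchar(p)) p else file.path("..", "..", "inst", "extdata", name)
}

table2 <- function() utils::read.csv(fixture_path("table2_mean_volumes.csv"))
table3 <- function() utils::read.csv(fixture_path("table3_covs.csv"))
table4 <- function() utils::read.csv(fixture_path("table4_r2.csv"))

# Two-point series with an exact target mean and COV (sample SD, n = 2).
two_point_series <- function(mean, cov) {
  s <- mean * cov
  c(mean - s / sqrt(2), mean + s / sqrt(2))
}

# Exhaustive slice-alignment sweep: attainable noiseless slice-summation
# volumes of a sphere for all grid offsets (independent of simulate_scan).
sphere_alignment_volumes <- function(diameter_mm, thickness_mm,
                                     du = 0.01) {
  r <- diameter_mm / 2
  u_grid <- seq(0, thickness_mm, by = du)
  vapply(u_grid, function(u) {
    k <- ceiling((-r - u) / thickness_mm):floor((r - u) / thickness_mm)
    z <- u + k * thickness_mm
    z <- z[abs(z) < r]
    sum(pi * (r^2 - z^2) * thickness_mm) / 1000
  }, numeric(1))
}

# Display rounding (half away from zero), for comparing to printed values.
round_digits <- function(x, d) sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d
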