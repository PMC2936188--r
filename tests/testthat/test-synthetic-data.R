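spec_sphere <- function(d = 20, ...) phantom_spec("sphere", diameter_mm = d, ...)

noiseless <- function(spec) {
  spec$radial_noise_sd <- 0
  spec$boundary_noise_sd_mm <- 0
  spec$scale_noise_sd <- 0
  spec$pixel_quantization <- 0
  spec
}

test_that("analytic cross-sections match the closed forms", {
  sp <- spec_sphere(20)
  expect_equal(cross_section_area(sp, 0), pi * 100 / 100, tolerance = 1e-12)
  expect_equal(cross_section_area(sp, 10), 0)
  expect_equal(cross_section_area(sp, -10), 0)
  expect_equal(cross_section_area(sp, 6), pi * (100 - 36) / 100,
               tolerance = 1e-12)

  el <- phantom_spec("ellipsoid", semi_axes_mm = c(12, 8, 15))
  expect_equal(cross_section_area(el, 0), pi * 12 * 8 / 100, tolerance = 1e-12)
  expect_equal(cross_section_area(el, 9), pi * 12 * 8 * (1 - 81 / 225) / 100,
               tolerance = 1e-12)
  expect_equal(cross_section_area(el, 15), 0)
})

test_that("bilobed cross-section degenerates to the larger lobe when nested", {
  bi <- phantom_spec("bilobed",
                     lobes = list(c(12, 9, 10), c(6, 5, 6)),
                     lobe_offset_mm = c(0, 0, 0))
  big <- phantom_spec("ellipsoid", semi_axes_mm = c(12, 9, 10))
  for (z in c(0, 3, -5))
    expect_equal(cross_section_area(bi, z), cross_section_area(big, z),
                 tolerance = 0.005)
})

test_that("offset bilobed union area exceeds either lobe and respects rasterization", {
  bi <- phantom_spec("bilobed",
                     lobes = list(c(10, 8, 9), c(10, 8, 9)),
                     lobe_offset_mm = c(8, 0, 0))
  a_union <- cross_section_area(bi, 0)
  a_lobe <- pi * 10 * 8 / 100
  expect_gt(a_union, a_lobe)
  expect_lt(a_union, 2 * a_lobe)
  # the traced noise-free boundary polygon encloses (nearly) the same area
  ct <- generate_contour(noiseless(bi), 0)
  expect_equal(polygon_area(ct), a_union, tolerance = 0.01)
})

test_that("noise-free contour of a circle has the inscribed-polygon area", {
  sp <- noiseless(spec_sphere(20))
  ct <- generate_contour(sp, 0)
  n <- sp$n_vertices
  r <- 10
  expect_equal(polygon_area(ct), (n / 2) * r^2 * sin(2 * pi / n) / 100,
               tolerance = 1e-12)
  # empty cross-section signals "no contour"
  expect_null(generate_contour(sp, 10.5))
})

test_that("contour generation is deterministic under a fixed seed", {
  sp <- spec_sphere(18.7)
  set.seed(99); c1 <- generate_contour(sp, 2)
  set.seed(99); c2 <- generate_contour(sp, 2)
  expect_identical(c1$vertices, c2$vertices)
})

test_that("per-vertex tracing jitter propagates to area as ~2 sigma/sqrt(n)", {
  sp <- spec_sphere(20, radial_noise_sd = 0.05, boundary_noise_sd_mm = 0,
                    scale_noise_sd = 0, pixel_quantization = 0)
  set.seed(123)
  areas <- replicate(4000, polygon_area(generate_contour(sp, 0)))
  a0 <- (sp$n_vertices / 2) * 100 * sin(2 * pi / sp$n_vertices) / 100
  expect_equal(mean(areas), a0, tolerance = 0.005)
  # first-order shoelace propagation for i.i.d. radial noise
  expect_equal(stats::sd(areas) / mean(areas), 2 * 0.05 / sqrt(sp$n_vertices),
               tolerance = 0.1)
})

test_that("a simulated scan covers the lesion and matches the alignment sweep", {
  sp <- noiseless(spec_sphere(20, slice_thickness_mm = 5))
  sp$n_vertices <- 256L
  attainable <- sphere_alignment_volumes(20, 5)
  set.seed(31)
  for (i in 1:25) {
    st <- simulate_scan(sp)
    expect_true(validate_stack(st)$valid)
    n_slices <- length(st$contours)
    expect_gte(n_slices, 3L)
    expect_lte(n_slices, 5L)
    v <- volume_from_stack(st)$volume_cm3
    # within the attainable noiseless range (small slack for polygon bias)
    expect_gte(v, min(attainable) * 0.995)
    expect_lte(v, max(attainable) * 1.005)
  }
  expect_gte(min(attainable), 3.4)
  expect_lte(max(attainable), 4.9)
})

test_that("fine slicing makes the scan volume converge to the sphere volume", {
  sp <- noiseless(spec_sphere(20, slice_thickness_mm = 0.1))
  sp$n_vertices <- 256L
  v <- volume_from_stack(simulate_scan(sp, seed = 5))$volume_cm3
  expect_equal(v, sphere_volume(20), tolerance = 0.005)
})

test_that("a lesion thinner than one slice yields a single-slice stack with warning", {
  sp <- noiseless(spec_sphere(3, slice_thickness_mm = 5))
  # offset chosen so no slice center falls inside the 3 mm lesion
  found_warning <- FALSE
  for (s in 1:50) {
    res <- withCallingHandlers(
      simulate_scan(sp, seed = s),
      warning = function(w) {
        found_warning <<- TRUE
        invokeRestart("muffleWarning")
      })
    expect_gte(length(res$contours), 1L)
  }
  expect_true(found_warning)
})

test_that("simulated scans are reproducible and longitudinal series deterministic", {
  sp <- spec_sphere(18.7, n_scans = 4, seed = 77)
  s1 <- simulate_scan(sp, seed = 123)
  s2 <- simulate_scan(sp, seed = 123)
  expect_equal(s1, s2)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- simulate_longitudinal_series(sp, out_dir = d1)
  r2 <- simulate_longitudinal_series(sp, out_dir = d2)
  expect_equal(r1$volume_cm3, r2$volume_cm3)
  # byte-identical output files under the same master seed
  expect_identical(readLines(file.path(d1, "contours.csv")),
                   readLines(file.path(d2, "contours.csv")))
  expect_identical(readLines(file.path(d1, "series.csv")),
                   readLines(file.path(d2, "series.csv")))
  # emitted files are valid module inputs
  stacks <- read_contours(file.path(d1, "contours.csv"))
  expect_length(stacks, 4L)
  back <- read_series(file.path(d1, "series.csv"))
  expect_equal(back$volume_cm3, r1$volume_cm3, tolerance = 1e-6)
})

test_that("earlier scans are unchanged when the series is extended", {
  s5 <- simulate_longitudinal_series(spec_sphere(18.7, n_scans = 5, seed = 42))
  s9 <- simulate_longitudinal_series(spec_sphere(18.7, n_scans = 9, seed = 42))
  expect_equal(s9$volume_cm3[1:5], s5$volume_cm3)
})

test_that("noise-free fine-sliced series has vanishing COV and unbiased mean", {
  sp <- noiseless(spec_sphere(20, slice_thickness_mm = 0.2, n_scans = 8,
                              seed = 9))
  sp$n_vertices <- 128L
  s <- simulate_longitudinal_series(sp)
  summ <- series_summary(s$volume_cm3)
  expect_lt(summ$cov, 0.001)
  expect_equal(summ$mean, sphere_volume(20), tolerance = 0.002)
})

test_that("measurement COV decreases as phantom volume grows", {
  # paired replicates (same child seeds across sizes) over a reduced grid;
  # the full 5-size x 200-replicate sweep runs with the acceptance checks
  sizes <- c(1, 4, 16)
  meds <- sapply(sizes, function(V) {
    covs <- sapply(1:40, function(r) {
      sp <- spec_sphere(equivalent_sphere_diameter(V), n_scans = 13,
                        seed = 5000 + r)
      series_summary(simulate_longitudinal_series(sp)$volume_cm3)$cov
    })
    median(covs)
  })
  expect_true(all(diff(meds) < 0))
})

test_that("equivalent-diameter COV follows the delta method (COV/3)", {
  covs_v <- numeric(30); covs_d <- numeric(30)
  for (r in 1:30) {
    sp <- spec_sphere(18.7, n_scans = 13, seed = 800 + r)
    v <- simulate_longitudinal_series(sp)$volume_cm3
    covs_v[r] <- series_summary(v)$cov
    covs_d[r] <- series_summary(equivalent_sphere_diameter(v))$cov
  }
  expect_lt(max(covs_v), 0.32)
  expect_equal(mean(covs_d), mean(covs_v) / 3, tolerance = 0.15)
})

test_that("phantom specification rejects invalid parameters", {
  expect_error(phantom_spec("sphere"), class = "volprec_domain_error")
  expect_error(phantom_spec("sphere", diameter_mm = -1),
               class = "volprec_domain_error")
  expect_error(phantom_spec("ellipsoid", semi_axes_mm = c(1, 2)),
               class = "volprec_domain_error")
  expect_error(phantom_spec("sphere", diameter_mm = 10, n_vertices = 4),
               class = "volprec_domain_error")
  expect_error(simulate_longitudinal_series(spec_sphere(10, n_scans = 5)),
               "seed", class = "volprec_validation_error")
})
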