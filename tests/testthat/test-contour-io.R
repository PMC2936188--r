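test_that("shoelace area handles the canonical cases", {
  sq <- contour("p", "s", "o", 1, 0, cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), 5)
  expect_equal(polygon_area(sq), 1.00)

  # collinear points enclose nothing and are flagged
  degen <- contour("p", "s", "o", 1, 0, cbind(c(0, 5, 10), c(0, 0, 0)), 5)
  expect_warning(a <- polygon_area(degen), "degenerate")
  expect_equal(a, 0)

  expect_error(polygon_area(cbind(c(0, 1), c(0, 1))), "fewer than 3")
  expect_error(contour("p", "s", "o", 1, 0, cbind(c(0, 1), c(0, 1)), 5),
               "fewer than 3")
  expect_error(contour("p", "s", "o", 1, 0,
                       cbind(c(0, NA, 1), c(0, 1, 0)), 5), "non-finite")
})

test_that("regular n-gon areas match the closed form exactly", {
  for (n in c(8L, 17L, 64L, 200L)) {
    for (r in c(2, 9.35, 30)) {
      theta <- (seq_len(n) - 1) * 2 * pi / n
      v <- cbind(r * cos(theta), r * sin(theta))
      expect_equal(polygon_area(v), (n / 2) * r^2 * sin(2 * pi / n) / 100,
                   tolerance = 1e-12)
    }
  }
})

test_that("area is invariant to vertex rotation, translation and orientation", {
  set.seed(101)
  for (rep in 1:20) {
    v <- random_star_polygon(sample(5:25, 1))
    a <- polygon_area(v)
    k <- sample(nrow(v), 1)
    rotated <- v[c(k:nrow(v), seq_len(k - 1)), , drop = FALSE]
    translated <- sweep(v, 2, stats::runif(2, -50, 50), "+")
    reversed <- v[rev(seq_len(nrow(v))), , drop = FALSE]
    expect_equal(polygon_area(rotated), a, tolerance = 1e-9)
    expect_equal(polygon_area(translated), a, tolerance = 1e-9)
    expect_equal(polygon_area(reversed), a, tolerance = 1e-9)
  }
})

test_that("shoelace area agrees with the rasterization oracle on a seeded 20-gon", {
  set.seed(7)
  v <- random_star_polygon(20, r_min = 4, r_max = 9)
  expect_equal(polygon_area(v), rasterized_polygon_area(v, h = 0.05),
               tolerance = 0.005)
})

test_that("an explicitly closed polygon is deduplicated on construction", {
  open_sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  closed_sq <- rbind(open_sq, open_sq[1, ])
  ct <- contour("p", "s", "o", 1, 0, closed_sq, 5)
  expect_equal(nrow(ct$vertices), 4L)
  expect_equal(polygon_area(ct), 1.00)
})

test_that("contour CSV round trip preserves stacks", {
  stacks <- list(
    stack_with_areas(c(1, 3, 4), organ = "left_adrenal"),
    stack_with_areas(c(2, 5, 3), organ = "right_adrenal"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_contours(stacks, path)
  back <- read_contours(path)
  expect_length(back, 2L)
  expect_equal(vapply(back, function(s) length(s$contours), integer(1)),
               c(3L, 3L))
  # organs come back sorted; match by label
  labs <- vapply(back, function(s) s$organ_label, character(1))
  for (st in stacks) {
    got <- back[[match(st$organ_label, labs)]]
    for (i in seq_along(st$contours))
      expect_equal(got$contours[[i]]$vertices, st$contours[[i]]$vertices,
                   tolerance = 1e-6)
  }
})

test_that("contour CSV format errors are reported by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_contours(list(stack_with_areas(c(1, 2))), path)
  df <- utils::read.csv(path)
  df$z_mm <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  expect_error(read_contours(path2), "z_mm", class = "volprec_format_error")

  df2 <- utils::read.csv(path)
  df2 <- rbind(df2, df2[1, ])  # duplicate (scan, organ, z, vertex) row
  utils::write.csv(df2, path2, row.names = FALSE)
  expect_error(read_contours(path2), "duplicate",
               class = "volprec_format_error")

  expect_error(read_contours(file.path(tempdir(), "no-such-file.csv")),
               "not found", class = "volprec_io_error")
})

test_that("writing an empty stack list yields a header-only file", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_contours(list(), path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_match(lines, "patient_id")
  expect_length(read_contours(path), 0L)
})

test_that("validate_stack reports completeness and structural problems", {
  # sphere-like taper: fine
  ok <- validate_stack(stack_with_areas(c(1, 3, 4, 3, 1)))
  expect_true(ok$valid)
  expect_length(ok$warnings, 0L)

  # thick first slice: organ probably clipped by the scan range
  clipped <- validate_stack(stack_with_areas(c(4, 3, 1)))
  expect_true(clipped$valid)
  expect_match(clipped$warnings, "partial coverage")

  # two contours at the same z
  dup <- slice_stack(list(circle_contour(5, 0, 1), circle_contour(5, 0, 2)))
  expect_false(validate_stack(dup)$valid)
  expect_match(validate_stack(dup)$violations, "more than one contour")

  # spacing not a multiple of the slice thickness
  odd <- slice_stack(list(circle_contour(5, 0, 1), circle_contour(5, 7.3, 2)),
                     slice_thickness_mm = 5)
  expect_false(validate_stack(odd)$valid)
  expect_match(validate_stack(odd)$violations, "integer multiple")
})

test_that("series CSV round trip and validation", {
  df <- data.frame(patient_id = "p1", scan_id = c("s1", "s2"),
                   scan_date = NA_character_, organ_label = "left_adrenal",
                   volume_cm3 = c(4.2, 5.0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(df, path)
  back <- read_series(path)
  expect_equal(back$volume_cm3, df$volume_cm3)
  expect_equal(back$organ_label, df$organ_label)

  bad <- df; bad$volume_cm3[1] <- -1
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_series(path2), class = "volprec_validation_error")
})
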