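test_that("line_through produces normalized lines satisfied by both points", {
  # horizontal, vertical, diagonal
  l1 <- line_through(c(0, 0), c(0, 10))
  expect_equal(unclass(l1), c(a = 0, b = 1, c = 0))
  l2 <- line_through(c(0, 0), c(10, 0))
  expect_equal(unclass(l2), c(a = 1, b = 0, c = 0))
  l3 <- line_through(c(0, 0), c(10, 10))
  expect_equal(abs(l3[["a"]]), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(l3[["a"]] + l3[["b"]], 0, tolerance = 1e-12)
  for (l in list(l1, l2, l3)) expect_equal(sum(l[1:2]^2), 1, tolerance = 1e-12)
  # both defining points lie on the line
  set.seed(1)
  for (i in 1:20) {
    p1 <- runif(2, -50, 50); p2 <- runif(2, -50, 50)
    l <- line_through(p1, p2)
    expect_lt(point_line_distance(p1, l), 1e-9)
    expect_lt(point_line_distance(p2, l), 1e-9)
    expect_gte(l[["a"]], 0)
  }
  expect_error(line_through(c(3, 4), c(3, 4)), "coincident")
})

test_that("point_line_distance matches axis-aligned and brute-force cases", {
  l <- line_through(c(0, 0), c(0, 10))       # the row = 0 line
  expect_equal(point_line_distance(c(5, 0), l), 5)
  expect_equal(point_line_distance(c(0, 7), l), 0)
  ld <- line_through(c(0, 0), c(10, 10))
  expect_equal(point_line_distance(c(3, 4), ld), 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(point_line_distance(c(3, 4), ld),
               brute_point_line(c(3, 4), c(0, 0), c(10, 10)),
               tolerance = 1e-6)
})

test_that("point_line_distance agrees with the two-point cross-product formula", {
  set.seed(7)
  for (i in 1:200) {
    p1 <- sample(-50:50, 2); p2 <- sample(-50:50, 2)
    if (all(p1 == p2)) next
    p0 <- sample(-50:50, 2)
    l <- line_through(p1, p2)
    ref <- abs((p2[2] - p1[2]) * (p1[1] - p0[1]) -
                 (p1[2] - p0[2]) * (p2[1] - p1[1])) /
      sqrt(sum((p2 - p1)^2))
    expect_equal(point_line_distance(p0, l), ref, tolerance = 1e-9)
  }
})

test_that("corneal apex localization picks the documented extremal pixel", {
  m <- disc_mask(200, 240, c(100, 120), 30)
  expect_equal(corneal_apex_sagittal(m), c(100, 90))
  expect_equal(corneal_apex_sagittal(matrix(c(FALSE, TRUE), 2, 1)), c(2, 1))
  expect_error(corneal_apex_sagittal(matrix(FALSE, 4, 4)), "no eye")

  m2 <- disc_mask(200, 256, c(100, 64), 30) | disc_mask(200, 256, c(100, 192), 30)
  ap <- corneal_apex_axial(m2)
  expect_equal(ap$left_eye, c(70, 64))
  expect_equal(ap$right_eye, c(70, 192))
  # spurious third component is dropped with a warning
  m3 <- m2; m3[190:192, 10:12] <- TRUE
  expect_warning(ap3 <- corneal_apex_axial(m3), "keeping the 2 largest")
  expect_equal(ap3$left_eye, ap$left_eye)
  # merged single component errors
  expect_error(corneal_apex_axial(disc_mask(64, 64, c(32, 32), 10)),
               "expected two eyes, found 1")
})

test_that("true_distance validates landmarks and matches closed form", {
  lms <- landmark_set("sagittal", c(50, 30), c(50, 220),
                      list(eye = c(20, 125)))
  expect_equal(unname(true_distance(lms)), 30)
  # apex on the line
  on_line <- landmark_set("sagittal", c(0, 0), c(10, 10), list(eye = c(5, 5)))
  expect_equal(unname(true_distance(on_line)), 0)
  ax <- landmark_set("axial", c(0, 0), c(0, 10),
                     list(left_eye = c(0, 5), right_eye = c(-3, 8)))
  expect_equal(unname(true_distance(ax)), c(0, 3))
  expect_error(landmark_set("axial", c(1, 1), c(1, 1),
                            list(left_eye = c(0, 0), right_eye = c(0, 1))),
               "must differ")
  expect_error(landmark_set("sagittal", c(0, 0), c(1, 1),
                            list(left_eye = c(0, 0))),
               "corneal apexes named")
  expect_error(true_distance(tibble::tibble(landmark = "rim_apex_a",
                                            row = 0, col = 0)),
               "rim_apex")
})

test_that("measure_slice recovers phantom truth and converts units", {
  s <- fixture_corpus("sagittal", 1, seed = 41)[[1]]
  m <- measure_slice(s$slice, s$eye_mask_true)
  expect_s3_class(m, "exo_measurement")
  expect_equal(nrow(m$distances), 1)
  expect_lt(abs(m$distances$distance_px - s$distance_true_px), 1.5)
  expect_equal(m$distances$distance_mm, m$distances$distance_px * 0.5)
  td <- tidy(m)
  expect_named(td, c("source_id", "view", "eye", "distance_px", "distance_mm"))
})

test_that("measurement is invariant under whole-image translation", {
  sp <- random_phantom_spec("axial", seed = 9, noise_sd = 0)
  shift <- function(spec, dr, dc) {
    spec$globe_centers <- lapply(spec$globe_centers, `+`, c(dr, dc))
    spec$bone_arcs <- lapply(spec$bone_arcs, function(a) {
      a$center <- a$center + c(dr, dc); a
    })
    spec$rim_apex_true <- lapply(spec$bone_arcs, exoct:::arc_apex)
    spec
  }
  s0 <- render_phantom(sp)
  s1 <- render_phantom(shift(sp, 7, 11))
  expect_equal(s1$distance_true_px, s0$distance_true_px, tolerance = 1e-9)
  m0 <- measure_slice(s0$slice, s0$eye_mask_true)
  m1 <- measure_slice(s1$slice, s1$eye_mask_true)
  expect_equal(m1$distances$distance_px, m0$distances$distance_px,
               tolerance = 1e-9)
})

test_that("missing or anisotropic spacing is handled as documented", {
  s <- fixture_corpus("axial", 1, seed = 42)[[1]]
  sl <- s$slice
  sl$pixel_spacing_mm <- NULL
  expect_warning(m <- measure_slice(sl, s$eye_mask_true), "px only")
  expect_true(all(is.na(m$distances$distance_mm)))
  sl$pixel_spacing_mm <- c(row = 0.5, col = 0.7)
  expect_error(measure_slice(sl, s$eye_mask_true), "anisotropic")
})
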