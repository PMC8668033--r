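test_that("movement fraction maps the endpoint arc onto 0..100", {
  fr <- make_frames(angles = c(-40, -5, 30))
  expect_equal(movement_fraction(fr), c(0, 50, 100))
  # translation invariance
  fr2 <- make_frames(angles = c(-40, -5, 30) + 17.3)
  expect_equal(movement_fraction(fr2), movement_fraction(fr))
  # out-of-arc intermediate frames are clamped with a warning
  fr3 <- make_frames(angles = c(-40, -45, 30))
  expect_warning(f3 <- movement_fraction(fr3),
                 class = "biokin_fraction_clamped")
  expect_equal(f3, c(0, 0, 100))
  expect_error(movement_fraction(make_frames(angles = c(10, 10, 10))),
               class = "biokin_zero_arc")
  expect_error(movement_fraction(fr[1]), class = "biokin_incomplete_curve")
})

test_that("RoM curves collect areas over fractions, sorted with duplicates averaged", {
  fr <- make_frames(areas = c(120, 100, 85), angles = c(-40, -1.5, 30))
  cv <- build_rom_curve(fr, "C5-C6")
  expect_s3_class(cv, "motion_curve")
  expect_equal(cv$s_max, 120)
  expect_equal(cv$s_min, 85)
  expect_equal(cv$fraction[c(1, 3)], c(0, 100))
  # shuffled input frames yield the same curve
  cv2 <- build_rom_curve(fr[c(3, 1, 2)], "C5-C6")
  expect_equal(cv2$fraction, cv$fraction)
  expect_equal(cv2$area, cv$area)
  # duplicate fractions averaged
  fr4 <- make_frames(areas = c(120, 100, 90, 85), angles = c(-40, -5, -5, 30),
                     phases = c("inclination", "neutral", "intermediate",
                                "reclination"))
  cv4 <- build_rom_curve(fr4, "C5-C6")
  expect_equal(length(cv4$fraction), 3L)
  expect_equal(cv4$area[2], 95)
  expect_error(build_rom_curve(fr, "L1-L2"), class = "biokin_incomplete_level")
  expect_error(build_rom_curve(fr[2], "C5-C6"),
               class = "biokin_incomplete_curve")
})

test_that("monotone cubic interpolation reproduces knots without overshoot", {
  kn <- motion_curve("C5-C6", c(0, 50, 100), c(120, 100, 85))
  dense <- interpolate_curve(kn, 101)
  expect_equal(dense$source, "interpolated")
  expect_equal(dense$area[c(1, 51, 101)], c(120, 100, 85))
  expect_true(all(dense$area <= 120 & dense$area >= 85))
  # linear knots reproduce the line exactly
  lin <- interpolate_curve(motion_curve("x", c(0, 50, 100), c(10, 20, 30)), 41)
  expect_lt(max(abs(lin$area - (10 + 0.2 * lin$fraction))), 1e-9)
  # refinement consistency: n and 2n-1 grids agree at shared fractions
  a <- interpolate_curve(kn, 51)
  b <- interpolate_curve(kn, 101)
  expect_lt(max(abs(a$area - b$area[seq(1, 101, by = 2)])), 1e-9)
  expect_error(interpolate_curve(motion_curve("x", c(0, 100), c(1, 2)), 11),
               class = "biokin_insufficient_knots")
})

test_that("conventional angular ROM is the signed endpoint angle difference", {
  fr <- make_frames(angles = c(-30, 0, 40))  # seg angles = angles / 5
  expect_equal(conventional_rom(fr, "C5-C6"), 14)
  # antisymmetric under swapping the endpoint poses
  fr_sw <- make_frames(angles = c(40, 0, -30))
  expect_equal(conventional_rom(fr_sw, "C5-C6"), -14)
  fr_no <- make_frames(phases = c("inclination", "neutral", "intermediate"))
  expect_error(conventional_rom(fr_no, "C5-C6"), class = "biokin_missing_pose")
})

test_that("motion surfaces locate the strongest curvature of sigmoid curves", {
  f <- seq(0, 100, length.out = 201)
  k <- 0.12
  fam <- lapply(c(-10, 0, 10), function(off)
    motion_curve("C5-C6", f, 100 / (1 + exp(-k * (f - 50 - off)))))
  names(fam) <- c(-10, 0, 10)
  surf <- motion_surface(fam, "C5-C6", n_grid = 201)
  expect_false(surf$indeterminate)
  # closed-form oracle: |S''| of the logistic peaks at 50 +- acosh-type offset;
  # compute it by dense differentiation of the closed form
  s <- 100 / (1 + exp(-k * (f - 50)))
  d2 <- diff(diff(s))
  oracle_locs <- f[2:200][order(-abs(d2))][1:2]
  expect_true(min(abs(surf$curvature_max_location - oracle_locs)) < 1.0)
  # the two curvature maxima are symmetric about 50
  expect_lt(abs(mean(oracle_locs) - 50), 1e-6)
  # flat and linear families are flagged indeterminate
  flat <- lapply(c(-5, 0, 5), function(o) motion_curve("x", f, rep(40, 201)))
  names(flat) <- c(-5, 0, 5)
  expect_true(motion_surface(flat, "x")$indeterminate)
  lin <- lapply(c(-5, 0, 5), function(o) motion_curve("x", f, 10 + f))
  names(lin) <- c(-5, 0, 5)
  expect_true(motion_surface(lin, "x")$indeterminate)
  expect_error(motion_surface(fam[1:2], "C5-C6"),
               class = "biokin_insufficient_family")
})
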