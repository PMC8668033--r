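test_that("segment signatures are the scale-invariant area range ratio", {
  cv <- motion_curve("C5-C6", c(0, 50, 100), c(100, 80, 60))
  sg <- segment_signature(cv)
  expect_equal(sg$delta_s, 40)
  expect_equal(sg$ratio, 0.4)
  # uniform area rescaling leaves the ratio unchanged
  sg2 <- segment_signature(motion_curve("C5-C6", c(0, 50, 100),
                                        2 * c(100, 80, 60)))
  expect_equal(sg2$ratio, sg$ratio)
  flat <- segment_signature(motion_curve("x", c(0, 100), c(50, 50)))
  expect_equal(flat$ratio, 0)
  zero <- segment_signature(motion_curve("x", c(0, 100), c(0, 0)))
  expect_equal(zero$ratio, 0)
  expect_true(zero$zero_smax)
})

test_that("spine signatures order the number series cranial to caudal", {
  lv <- section_levels("cervical")
  ratios <- c(0.3, 0.35, 0.4, 0.1, 0.3)
  curves <- lapply(seq_along(lv), function(i)
    motion_curve(lv[i], c(0, 50, 100), 100 * c(1, 1 - ratios[i] / 2,
                                               1 - ratios[i])))
  sig <- spine_signature(curves, "cervical")
  expect_equal(sig$level, lv)
  expect_equal(sig$ratio, ratios)
  # shuffled presentation gives the identical series
  sig2 <- spine_signature(curves[c(4, 1, 5, 2, 3)], "cervical")
  expect_equal(sig2$ratio, ratios)
  expect_error(spine_signature(curves[c(1, 1, 2, 3, 4)], "cervical"),
               class = "biokin_duplicate_level")
  expect_error(spine_signature(curves[1:4], "cervical"),
               class = "biokin_incomplete_section")
})

test_that("signature distance is a Euclidean metric on the ratio vectors", {
  lv <- section_levels("cervical")
  mk <- function(r) spine_signature(lapply(seq_along(lv), function(i)
    motion_curve(lv[i], c(0, 100), c(100, 100 * (1 - r[i])))), "cervical")
  a <- mk(c(0.3, 0.35, 0.4, 0.1, 0.3))
  b <- mk(c(0.3, 0.35, 0.4, 0.4, 0.3))
  expect_equal(signature_distance(a, a), 0)
  expect_equal(signature_distance(a, b), 0.3)
  expect_equal(signature_distance(a, b), signature_distance(b, a))
  lum <- spine_signature(lapply(section_levels("lumbar"), function(l)
    motion_curve(l, c(0, 100), c(100, 70))), "lumbar")
  expect_error(signature_distance(a, lum),
               class = "biokin_incompatible_signature")
})

test_that("Gaussian Bayes error matches closed forms", {
  # indistinguishable two-class problem: error ~ 0.5
  e1 <- gaussian_bayes_error(matrix(c(0, 0), 2, 1), 1, 2e4, seed = 1)
  expect_lt(abs(e1$error - 0.5), 0.02)
  # widely separated classes: error ~ 0
  e2 <- gaussian_bayes_error(matrix(c(0, 20), 2, 1), 1, 2e4, seed = 2)
  expect_lt(e2$error, 1e-3)
  # equal-sigma gap 2 sigma: Phi(-1)
  e3 <- gaussian_bayes_error(matrix(c(0, 2), 2, 1), 1, 1e5, seed = 3)
  expect_lt(abs(e3$error - pnorm(-1)), 0.01)
  expect_error(gaussian_bayes_error(matrix(0, 1, 1), 1),
               class = "biokin_insufficient_cohort")
  expect_error(gaussian_bayes_error(matrix(c(0, 1), 2, 1), 0),
               class = "biokin_invalid_covariance")
})

test_that("reproducibility reports satisfy the nearest-neighbour relation", {
  cfg <- spine_config("cervical", n_frames = 3, noise_sd_fraction = 0.002)
  sigs <- suppressWarnings(
    generate_fingerprint_cohort(cfg, n_subjects = 6, subject_ratio_sd = 0.05,
                                seed = 31))
  rep <- bayes_error_rate(sigs, n_draws = 2e4, seed = 32)
  expect_true(rep$bayes_error >= 0 && rep$bayes_error <= 1)
  expect_gte(rep$nn_error, rep$bayes_error - 3 * rep$bayes_se)
  expect_identical(rep$n_subjects, 6L)
  expect_error(bayes_error_rate(sigs[1]),
               class = "biokin_insufficient_cohort")
  expect_error(bayes_error_rate(lapply(sigs, `[`, 1)),
               class = "biokin_insufficient_cohort")
})

test_that("worst and best detection behave on exact and rescaled input", {
  cfg <- spine_config("cervical", noise_sd_fraction = 0)
  ref <- generate_reference_surrogate(cfg)
  an <- analyze_exam(generate_exam(cfg))
  # patient identical to reference: all deviations 0, tie flagged
  w <- detect_worst_segment(an$curves, ref)
  expect_lt(max(w$scores), 1e-9)
  expect_true(w$tie)
  # deviation invariant to uniform area rescaling
  scaled <- lapply(an$curves, function(cv)
    motion_curve(cv$level, cv$fraction, cv$area * 3.7, cv$source))
  names(scaled) <- names(an$curves)
  w2 <- detect_worst_segment(scaled, ref)
  expect_lt(max(abs(w2$scores - w$scores)), 1e-9)
  # a degenerated level separates worst from best
  deg <- data.frame(level = "C4-C5", height_loss_mm = 2, mobility_scale = 0.5)
  cfgd <- spine_config("cervical", noise_sd_fraction = 0, degeneration = deg)
  and <- analyze_exam(generate_exam(cfgd), ref)
  expect_equal(and$worst$level, "C4-C5")
  expect_false(and$best$level == and$worst$level)
  # w_h = 1 returns the max height ratio regardless of curves
  b1 <- detect_best_segment(and$curves, and$heights, ref, weights = c(1, 0))
  expect_equal(b1$level,
               names(which.max(and$heights / ref$heights)))
  expect_error(detect_best_segment(and$curves, and$heights, ref,
                                   exclude = section_levels("cervical")),
               class = "biokin_no_candidate")
  expect_error(detect_best_segment(and$curves, and$heights, ref,
                                   weights = c(0.7, 0.7)),
               class = "biokin_invalid_weights")
})
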