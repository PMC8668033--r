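test_that("device specifications validate their grid and mobility", {
  d <- device_spec("C", "cage", 0.8, c(4, 5, 6))
  expect_equal(d$mobility_factor, 0)  # cages are rigid by definition
  expect_error(device_spec("X", "prosthesis", 1.2, c(5, 6)),
               class = "biokin_invalid_device")
  expect_error(device_spec("X", "prosthesis", 0.5, c(6, 5)),
               class = "biokin_invalid_device")
  expect_error(device_spec("X", "prosthesis", 0.5, numeric(0)),
               class = "biokin_empty_grid")
})

test_that("virtual substitution transfers the donor shape at the right scale", {
  cfg <- spine_config("cervical", noise_sd_fraction = 0)
  ref <- generate_reference_surrogate(cfg)
  an <- analyze_exam(generate_exam(cfg))
  # donor substituted into a level with the same size ratio keeps s_max
  v <- virtual_substitution(an$curves, "C5-C6", "C6-C7", ref)
  expect_equal(v$source, "virtual")
  expect_equal(v$level, "C5-C6")
  q <- ref$size_ratios[["C5-C6"]] / ref$size_ratios[["C6-C7"]]
  expect_equal(v$s_max, an$curves[["C6-C7"]]$s_max * q)
  # the donor's delta-S/S_max ratio is transferred unchanged
  expect_equal(segment_signature(v)$ratio,
               segment_signature(an$curves[["C6-C7"]])$ratio)
  expect_error(virtual_substitution(an$curves, "C5-C6", "C5-C6", ref),
               class = "biokin_degenerate_substitution")
})

test_that("optimal device height scales the donor height and caps overcorrection", {
  cfg <- spine_config("cervical", noise_sd_fraction = 0)
  ref <- generate_reference_surrogate(cfg)
  h <- c("C5-C6" = 5.0, "C6-C7" = 7.0)
  # C5-C6 and C6-C7 share the reference height 7.0 and size ratio here
  res <- optimal_device_height(h, "C5-C6", "C6-C7", ref)
  expect_equal(res$height, 7.0)
  expect_false(res$no_change)
  # cap dominance: an inflated donor height is capped at the reference
  h2 <- c("C5-C6" = 5.0, "C6-C7" = 8.5)
  res2 <- optimal_device_height(h2, "C5-C6", "C6-C7", ref)
  expect_true(res2$capped)
  expect_equal(res2$height, ref$heights[["C5-C6"]])
  expect_error(optimal_device_height(c("C5-C6" = -1, "C6-C7" = 7),
                                     "C5-C6", "C6-C7", ref),
               class = "biokin_invalid_height")
})

test_that("device-grid mapping picks the nearest height, ties to the smaller", {
  p <- device_spec("P", "prosthesis", 0.8, c(5, 6, 7))
  m <- map_to_device_grid(4.5, p)
  expect_equal(m$grid_height, 5)
  expect_false(m$exact_available)
  m2 <- map_to_device_grid(5.0, p)
  expect_true(m2$exact_available)
  m3 <- map_to_device_grid(5.5, device_spec("P", "prosthesis", 0.8, c(5, 6)))
  expect_equal(m3$grid_height, 5)  # tie broken toward less distraction
})

test_that("post-implant prediction conserves and redistributes section motion", {
  cfg <- spine_config("cervical", noise_sd_fraction = 0)
  ref <- generate_reference_surrogate(cfg)
  an <- analyze_exam(generate_exam(cfg))
  rng <- function(cvs) vapply(cvs, function(cv) cv$s_max - cv$s_min,
                              numeric(1))
  tot <- sum(rng(an$curves))
  # identity device on an already-healthy spine changes nothing
  id <- predict_postop_curves(an$curves, "C5-C6",
                              device_spec("I", "prosthesis", 1, c(7)), ref)
  expect_lt(max(abs(rng(id$curves) - rng(an$curves))), 1e-9)
  # a cage zeroes the target range and conserves the section total
  cage <- predict_postop_curves(an$curves, "C5-C6",
                                device_spec("C", "cage", 0, c(7)), ref)
  expect_equal(rng(cage$curves)[["C5-C6"]], 0)
  expect_lt(abs(sum(rng(cage$curves)) - tot) / tot, 1e-9)
  # only the immediate neighbours change
  expect_equal(rng(cage$curves)[["C2-C3"]], rng(an$curves)[["C2-C3"]])
  # idempotence: re-applying the achieved configuration changes nothing
  again <- predict_postop_curves(cage$curves, "C5-C6",
                                 device_spec("C", "cage", 0, c(7)), ref)
  expect_lt(max(abs(rng(again$curves) - rng(cage$curves))), 1e-12)
  # boundary target flags single-neighbour redistribution
  bd <- predict_postop_curves(an$curves, "C6-C7",
                              device_spec("C", "cage", 0, c(7)), ref)
  expect_true(bd$single_neighbor)
  expect_lt(abs(sum(rng(bd$curves)) - tot) / tot, 1e-9)
})

test_that("adjacent delta-RoM decreases with device mobility", {
  cfg <- spine_config("cervical", noise_sd_fraction = 0)
  ref <- generate_reference_surrogate(cfg)
  an <- analyze_exam(generate_exam(cfg))
  adj <- vapply(seq(0, 1, by = 0.2), function(f) {
    d <- device_spec("X", if (f == 0) "cage" else "prosthesis", f, c(7))
    post <- predict_postop_curves(an$curves, "C5-C6", d, ref)
    mean(vapply(c("C4-C5", "C6-C7"), function(l)
      delta_rom(an$curves[[l]], post$curves[[l]])$delta_rom, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(adj) <= 1e-9))
  expect_true(all(adj[1] >= adj[-1]))
})

test_that("delta-RoM is the absolute range change, symmetric in its arguments", {
  pre <- motion_curve("C4-C5", c(0, 100), c(100, 60))
  post <- motion_curve("C4-C5", c(0, 100), c(100, 75))
  d <- delta_rom(pre, post)
  expect_equal(d$delta_rom, 15)
  expect_equal(delta_rom(post, pre)$delta_rom, 15)
  expect_equal(delta_rom(pre, pre)$delta_rom, 0)
  expect_error(delta_rom(pre, motion_curve("C5-C6", c(0, 100), c(9, 5))),
               class = "biokin_level_mismatch")
})

test_that("delta-RoM / outcome correlation handles exact and degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  worsening <- 2 * x  # relief = -worsening is perfectly anti-monotone
  res <- correlate_delta_rom_outcome(x, worsening, n_perm = 500, seed = 1)
  expect_equal(res$r, -1)
  expect_lt(res$p_value, 0.05)
  flat <- correlate_delta_rom_outcome(x, rep(1, 5), n_perm = 100, seed = 1)
  expect_true(flat$undefined)
  expect_error(correlate_delta_rom_outcome(1:2, 1:2),
               class = "biokin_insufficient_cohort")
})

test_that("implant plans chain detection, height choice and prediction", {
  set.seed(55)
  deg <- recovery_degeneration()
  cfg <- spine_config("cervical", noise_sd_fraction = 0, degeneration = deg)
  ref <- generate_reference_surrogate(spine_config("cervical"))
  an <- analyze_exam(generate_exam(cfg), ref)
  plan <- recommend_implant(an$curves, an$heights, ref,
                            device_spec("P1", "prosthesis", 0.8, c(5, 6, 7)))
  expect_s3_class(plan, "implant_plan")
  expect_equal(plan$target_level, "C5-C6")
  expect_equal(plan$best_level, "C6-C7")
  expect_lt(abs(plan$recommended_height - 7.0), 1e-6)
  expect_true(plan$grid_height %in% c(5, 6, 7))
  expect_equal(length(plan$delta_rom_per_level), 5L)
})
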