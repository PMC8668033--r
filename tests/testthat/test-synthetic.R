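test_that("configuration validates its parameters", {
  expect_error(spine_config("cervical", level_weights = rep(0.1, 5)),
               class = "biokin_config_error")
  expect_error(spine_config("cervical", ratios = c(0.3, 0.3, 0.3, 0.3, 1.2)),
               class = "biokin_config_error")
  expect_error(spine_config("cervical", n_frames = 2),
               class = "biokin_config_error")
  expect_error(spine_config("cervical", phase_offsets = c(0, 0, 0, 0, 30)),
               class = "biokin_config_error")
  cfg <- spine_config("lumbar")
  expect_equal(cfg$levels, section_levels("lumbar"))
})

test_that("the reference surrogate is deterministic and normalized", {
  cfg <- spine_config("cervical")
  r1 <- generate_reference_surrogate(cfg)
  r2 <- generate_reference_surrogate(cfg)
  expect_identical(r1, r2)
  expect_equal(unname(apply(r1$curves, 1, max)), rep(1, 5))
  expect_true(all(diff(r1$size_ratios) >= 0))
  # constant size ratios with equal heights/ratios collapse to one shape
  cfg2 <- spine_config("cervical", heights = rep(6, 5),
                       ratios = rep(0.35, 5), size_ratios = rep(1, 5),
                       phase_offsets = rep(0, 5))
  r3 <- generate_reference_surrogate(cfg2)
  expect_lt(max(apply(r3$curves, 2, function(col) diff(range(col)))), 1e-12)
})

test_that("exams are reproducible given a seed and noise-free by default path", {
  cfg <- spine_config("cervical", noise_sd_fraction = 0.03)
  e1 <- generate_exam(cfg, "S1", "a", seed = 7)
  e2 <- generate_exam(cfg, "S1", "a", seed = 7)
  expect_identical(e1$landmarks, e2$landmarks)
  e3 <- generate_exam(cfg, "S1", "b", seed = 8)
  expect_false(identical(e1$landmarks$x_px, e3$landmarks$x_px))
  # zero noise: two sessions are identical and signatures coincide
  cfg0 <- spine_config("cervical", noise_sd_fraction = 0)
  a <- analyze_exam(generate_exam(cfg0, "S1", "a"))$signature
  b <- analyze_exam(generate_exam(cfg0, "S1", "b"))$signature
  expect_equal(signature_distance(a, b), 0)
})

test_that("the pipeline recovers configured ratios, heights and arc exactly", {
  cfg <- spine_config("cervical", noise_sd_fraction = 0)
  an <- analyze_exam(generate_exam(cfg))
  expect_lt(max(abs(an$signature$ratio - unname(cfg$ratios))), 1e-9)
  # per-level arc contributions sum to the configured global arc
  expect_lt(abs(sum(an$conventional_rom) - cfg$global_arc), 1e-9)
  # disc heights recovered through the reference regression
  ref <- generate_reference_surrogate(cfg)
  h <- estimate_disc_heights(an, ref)
  expect_lt(max(abs(h - cfg$heights)), 1e-6)
  # halved mobility halves the recovered delta-S
  deg <- data.frame(level = "C4-C5", height_loss_mm = 0, mobility_scale = 0.5)
  cfg2 <- spine_config("cervical", noise_sd_fraction = 0, degeneration = deg)
  an2 <- analyze_exam(generate_exam(cfg2))
  expect_lt(abs(an2$signature$delta_s[3] / an$signature$delta_s[3] - 0.5),
            0.02)
})

test_that("area ranges scale linearly with configured disc heights", {
  base <- spine_config("cervical", noise_sd_fraction = 0)
  ds <- vapply(c(1, 1.5, 2), function(scal) {
    cfg <- spine_config("cervical", noise_sd_fraction = 0,
                        heights = base$heights * scal,
                        size_ratios = unname(base$size_ratios))
    analyze_exam(generate_exam(cfg))$signature$delta_s[2]
  }, numeric(1))
  expect_lt(max(abs(ds / ds[1] - c(1, 1.5, 2))), 1e-9)
})

test_that("session noise propagates monotonically into signature distances", {
  grid <- c(0, 0.01, 0.02, 0.05)
  mean_d <- vapply(grid, function(nf) {
    cfg <- spine_config("cervical", n_frames = 3, noise_sd_fraction = nf)
    mean(vapply(1:30, function(k) {
      a <- quiet_analyze(generate_exam(cfg, "S", "a", seed = 100 + k))$signature
      b <- quiet_analyze(generate_exam(cfg, "S", "b", seed = 900 + k))$signature
      signature_distance(a, b)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(mean_d[1], 0)
  expect_true(all(diff(mean_d) > 0))
})

test_that("cohorts are seed-reproducible with outcome law built in", {
  cfg <- spine_config("cervical", n_frames = 11)
  c1 <- generate_cohort(cfg, 4, seed = 21)
  c2 <- generate_cohort(cfg, 4, seed = 21)
  expect_identical(c1$outcomes, c2$outcomes)
  expect_identical(c1$subjects[[2]]$pre$landmarks,
                   c2$subjects[[2]]$pre$landmarks)
  expect_equal(nrow(c1$outcomes), 4L)
  expect_true(all(c1$outcomes$pre >= 0 & c1$outcomes$pre <= 1))
  # worsening tracks the true adjacent delta-RoM by construction
  truth <- vapply(c1$subjects, function(s)
    s$truth$mean_adjacent_delta_rom, numeric(1))
  expect_true(all(truth >= 0))
  expect_error(generate_cohort(cfg, 1), class = "biokin_insufficient_cohort")
  expect_error(generate_cohort(cfg, 4, outcome_model = list(slope = 1)),
               class = "biokin_config_error")
})
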