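# Shared fixtures: tiny frame sets and exam generators used across tests.

# analyze while silencing the expected clamp warnings of noisy exams
quiet_analyze <- function(...) suppressWarnings(analyze_exam(...))

# a minimal hand-built frame list: one level, phases at -40 / -5 / +30 deg
make_frames <- function(areas = c(120, 100, 85), level = "C5-C6",
                        angles = c(-40, -5, 30),
                        phases = c("inclination", "neutral", "reclination")) {
  lapply(seq_along(areas), function(i) {
    b <- 30
    tri <- list(structure(list(level = level, p1 = c(0, 0), p2 = c(b, 0),
                               p3 = c(20, 2 * areas[i] / b),
                               baseline_length = b, area = areas[i],
                               height = 2 * areas[i] / b, degenerate = FALSE),
                          class = "biokin_triangle"))
    names(tri) <- level
    motion_frame(i - 1L, phases[i], angles[i], tri,
                 seg_angles = stats::setNames(angles[i] / 5, level))
  })
}

# random rigid transform applied to a 2-column matrix of points
rigid_transform <- function(pts, theta, shift) {
  r <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  t(r %*% t(pts)) + matrix(shift, nrow(pts), 2, byrow = TRUE)
}

# degeneration table used by the recovery experiments: one severely
# degenerated target, mild wear elsewhere, the donor level left pristine
recovery_degeneration <- function(worst = "C5-C6", donor = "C6-C7",
                                  levels = section_levels("cervical")) {
  others <- setdiff(levels, c(worst, donor))
  rbind(data.frame(level = worst, height_loss_mm = 2, mobility_scale = 0.5),
        data.frame(level = others,
                   height_loss_mm = stats::runif(length(others), 0.3, 0.8),
                   mobility_scale = stats::runif(length(others), 0.85, 1)))
}
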