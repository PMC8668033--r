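# Seeded synthetic-spine generator: calibrated landmark trajectories of a
# cervical or lumbar section across an inclination -> neutral -> reclination
# sweep, with configurable degeneration, device effects, session noise and
# paired outcome scores.  The generator is the validation test bed standing
# in for patient radiographs; its numeric defaults are invented, synthetic
# values chosen for realism and clearly labelled as such.
#
# Motion model: every segment follows one shared sigmoid motion
# characteristic, each at its own phase offset within the section's global
# arc.  The apex (point 3) of level l sits at height
#     y_l(f) = h_l + a_l * (1 - g_l(f)),   a_l = h_l * rho_l / (1 - rho_l),
# above a fixed baseline of length B_l, where g_l is a normalized logistic
# in the movement percentage f and rho_l the healthy delta-S/S_max.  The
# triangle area B_l * y_l / 2 is then maximal in inclination, tracks disc
# height linearly, and reproduces rho_l exactly at zero noise.  Segmental
# rotations are weighted shares of the global arc with a correction term so
# that the section's endplate angles sum exactly to the global arc.

#' Synthetic spine configuration
#'
#' @param section "cervical" or "lumbar".
#' @param global_arc total inclination -> reclination arc of the section
#'   (degrees).
#' @param baselines per-level triangle baseline lengths (mm).
#' @param heights per-level neutral intersegmental disc heights (mm).
#' @param ratios per-level healthy delta-S/S_max values in (0, 1).
#' @param size_ratios per-level dimensionless size ratios, nondecreasing
#'   cranial -> caudal; default heights / heights\[1\].
#' @param level_weights simplex weights of each level's share of the global
#'   arc.
#' @param phase_offsets per-level phase offsets in percent of movement,
#'   within \[-20, 20\].
#' @param steepness logistic steepness of the shared motion characteristic
#'   (per percent of movement).
#' @param n_frames frames in the sweep (>= 3); 3 emulates the clinical
#'   three-pose exam, larger values a videofluoroscopic recording.
#' @param noise_sd_fraction session noise: landmark coordinate sd calibrated
#'   so the induced area sd is this fraction of a typical level's S_max.
#' @param ball_true_diameter_mm,ball_image_diameter_px calibration ball.
#' @param degeneration optional data.frame with columns `level`,
#'   `height_loss_mm`, `mobility_scale`.
#' @param device optional list `list(level, spec = device_spec,
#'   implanted_height_mm)` applied on top of any degeneration (post-op
#'   state, with adjacent-level motion redistribution).
#' @param seed integer seed for exam noise.
#' @return object of class `spine_config`.
#' @export
spine_config <- function(section = c("cervical", "lumbar"),
                         global_arc = NULL,
                         baselines = NULL, heights = NULL, ratios = NULL,
                         size_ratios = NULL, level_weights = NULL,
                         phase_offsets = NULL, steepness = 0.08,
                         n_frames = 101, noise_sd_fraction = 0.02,
                         ball_true_diameter_mm = 30,
                         ball_image_diameter_px = 150,
                         degeneration = NULL, device = NULL, seed = 1L) {
  section <- match.arg(section)
  levels <- section_levels(section)
  L <- length(levels)
  def <- if (section == "cervical") {
    list(arc = 70, B = c(15, 15.5, 16, 16.5, 17),
         h = c(5.5, 6, 6.5, 7, 7),
         rho = c(0.32, 0.35, 0.38, 0.40, 0.37))
  } else {
    list(arc = 60, B = c(30, 31, 32, 33, 34),
         h = c(8, 9, 10, 11, 11.5),
         rho = c(0.30, 0.33, 0.36, 0.38, 0.35))
  }
  if (is.null(global_arc)) global_arc <- def$arc
  if (is.null(baselines)) baselines <- def$B
  if (is.null(heights)) heights <- def$h
  if (is.null(ratios)) ratios <- def$rho
  if (is.null(size_ratios)) size_ratios <- heights / heights[1]
  if (is.null(level_weights)) level_weights <- rep(1 / L, L)
  if (is.null(phase_offsets)) phase_offsets <- seq(-10, 10, length.out = L)
  for (v in list(baselines, heights, ratios, size_ratios, level_weights,
                 phase_offsets)) {
    if (length(v) != L || any(!is.finite(v)))
      abort_biokin("per-level parameters must be finite and of section length",
                   "biokin_config_error")
  }
  if (abs(sum(level_weights) - 1) > 1e-12 || any(level_weights < 0))
    abort_biokin("level_weights must be a simplex (sum 1)", "biokin_config_error")
  if (any(heights <= 0) || any(baselines <= 0))
    abort_biokin("heights and baselines must be positive", "biokin_config_error")
  if (any(ratios <= 0 | ratios >= 1))
    abort_biokin("ratios must lie in (0, 1)", "biokin_config_error")
  if (any(diff(size_ratios) < 0))
    abort_biokin("size_ratios must be nondecreasing cranial -> caudal",
                 "biokin_config_error")
  if (any(abs(phase_offsets) > 20))
    abort_biokin("phase_offsets must lie in [-20, 20]", "biokin_config_error")
  if (n_frames < 3) abort_biokin("n_frames must be >= 3", "biokin_config_error")
  if (noise_sd_fraction < 0)
    abort_biokin("noise_sd_fraction must be >= 0", "biokin_config_error")
  if (!is.null(degeneration)) {
    degeneration <- as.data.frame(degeneration)
    if (!all(c("level", "height_loss_mm", "mobility_scale") %in%
             names(degeneration)) ||
        !all(degeneration$level %in% levels) ||
        any(degeneration$mobility_scale < 0 | degeneration$mobility_scale > 2))
      abort_biokin("invalid degeneration table", "biokin_config_error")
  }
  if (!is.null(device)) {
    if (!is.list(device) || !all(c("level", "spec") %in% names(device)) ||
        !(device$level %in% levels) || !inherits(device$spec, "device_spec"))
      abort_biokin("device must be list(level, spec, implanted_height_mm)",
                   "biokin_config_error")
    if (is.null(device$implanted_height_mm))
      device$implanted_height_mm <- heights[match(device$level, levels)]
  }
  names(baselines) <- names(heights) <- names(ratios) <-
    names(size_ratios) <- names(level_weights) <- names(phase_offsets) <- levels
  structure(list(section = section, levels = levels, global_arc = global_arc,
                 baselines = baselines, heights = heights, ratios = ratios,
                 size_ratios = size_ratios, level_weights = level_weights,
                 phase_offsets = phase_offsets, steepness = steepness,
                 n_frames = n_frames, noise_sd_fraction = noise_sd_fraction,
                 ball_true_diameter_mm = ball_true_diameter_mm,
                 ball_image_diameter_px = ball_image_diameter_px,
                 degeneration = degeneration, device = device,
                 seed = as.integer(seed)),
            class = "spine_config")
}

#' @export
print.spine_config <- function(x, ...) {
  cat(sprintf("Synthetic %s spine: %d levels, arc %g deg, %d frames, noise %.3g x S_max%s%s\n",
              x$section, length(x$levels), x$global_arc, x$n_frames,
              x$noise_sd_fraction,
              if (!is.null(x$degeneration)) ", degenerated" else "",
              if (!is.null(x$device)) paste0(", device@", x$device$level) else ""))
  invisible(x)
}

#' Normalized logistic motion progress of one level
#' @noRd
progress_curve <- function(fraction, offset, k) {
  s <- function(f) stats::plogis(k * (f - 50 - offset))
  (s(fraction) - s(0)) / (s(100) - s(0))
}

#' Per-level effective heights and motion amplitudes, degeneration and
#' device applied.  Amplitudes are in apex-height units (mm); area range of
#' level l is B_l * a_l / 2.
#' @noRd
build_profile <- function(config) {
  lv <- config$levels
  h_eff <- config$heights
  a_healthy <- config$heights * config$ratios / (1 - config$ratios)
  a_eff <- a_healthy
  if (!is.null(config$degeneration)) {
    for (i in seq_len(nrow(config$degeneration))) {
      d <- config$degeneration[i, ]
      j <- match(d$level, lv)
      h_eff[j] <- h_eff[j] - d$height_loss_mm
      if (h_eff[j] <= 0)
        abort_biokin("height loss exceeds disc height", "biokin_config_error")
      a_eff[j] <- a_eff[j] * d$mobility_scale
    }
  }
  adjacent_delta_area <- NULL
  if (!is.null(config$device)) {
    jt <- match(config$device$level, lv)
    B <- config$baselines
    a_post <- config$device$spec$mobility_factor * a_healthy[jt]
    removed_area <- B[jt] / 2 * (a_eff[jt] - a_post)
    a_eff[jt] <- a_post
    h_eff[jt] <- config$device$implanted_height_mm
    nb <- c(jt - 1L, jt + 1L)
    nb <- nb[nb >= 1L & nb <= length(lv)]
    nb_area <- B[nb] * a_eff[nb] / 2
    share <- if (sum(nb_area) > 0) nb_area / sum(nb_area)
             else rep(1 / length(nb), length(nb))
    gain <- removed_area * share
    a_eff[nb] <- pmax(a_eff[nb] + 2 * gain / B[nb], 0)
    adjacent_delta_area <- abs(gain)
    names(adjacent_delta_area) <- lv[nb]
  }
  list(h_eff = h_eff, a_eff = a_eff, a_healthy = a_healthy,
       adjacent_delta_area = adjacent_delta_area)
}

#' Reference surrogate implied by a healthy configuration
#'
#' Per-level normalized healthy RoM curves (shared sigmoid characteristic,
#' shifted by phase offset), neutral disc heights and level size ratios.
#' Deterministic: ignores degeneration, device and noise settings.
#'
#' @param config a [spine_config].
#' @param n_grid fraction grid resolution.
#' @return a [reference_surrogate].
#' @export
generate_reference_surrogate <- function(config, n_grid = 101) {
  stopifnot(inherits(config, "spine_config"))
  grid <- seq(0, 100, length.out = n_grid)
  a <- config$heights * config$ratios / (1 - config$ratios)
  m <- t(vapply(seq_along(config$levels), function(i) {
    g <- progress_curve(grid, config$phase_offsets[i], config$steepness)
    y <- config$heights[i] + a[i] * (1 - g)
    y / max(y)
  }, numeric(n_grid)))
  rownames(m) <- config$levels
  reference_surrogate(config$section, grid, m,
                      config$heights, config$size_ratios)
}

#' Generate one calibrated exam (landmark table + calibration)
#'
#' Emits per-frame landmark points (px) whose induced triangles reproduce
#' the configured per-level area curves exactly at zero noise; frames sweep
#' fractions 0 .. 100; an auxiliary endplate row for the most cranial
#' vertebra carries the section's cranial reference plate (points 1-2).
#' Session noise is isotropic Gaussian on the px coordinates.
#'
#' @param config a [spine_config].
#' @param subject_id,session_id identifiers written into the table.
#' @param seed optional integer seed for the session noise (local); when
#'   NULL the current RNG stream is used.
#' @return an `exam_bundle`: list with `landmarks` (data.frame with columns
#'   subject_id, session_id, frame_index, phase, level, point_id, x_px,
#'   y_px), `calibration`, `section`.
#' @export
generate_exam <- function(config, subject_id = "S01", session_id = "a",
                          seed = NULL) {
  stopifnot(inherits(config, "spine_config"))
  with_seed(seed, {
    lv <- config$levels
    L <- length(lv)
    B <- config$baselines
    w <- config$level_weights
    arc <- config$global_arc
    pr <- build_profile(config)
    n <- config$n_frames
    f <- seq(0, 100, length.out = n)
    phase <- rep("intermediate", n)
    phase[1] <- "inclination"; phase[n] <- "reclination"
    phase[which.min(abs(f - 50))] <- "neutral"
    # per-level motion progress and segmental rotations (degrees)
    G <- vapply(seq_len(L), function(i)
      progress_curve(f, config$phase_offsets[i], config$steepness),
      numeric(n))                                   # n x L
    Gbar <- as.numeric(G %*% w)
    alpha <- vapply(seq_len(L), function(i)
      w[i] * arc * (f / 100 - 0.5) + w[i] * arc * (G[, i] - Gbar),
      numeric(n))                                   # n x L, rowSums = arc*(f/100-.5)
    vb <- if (config$section == "cervical") 14 else 28  # vertebral body height
    scale <- config$ball_true_diameter_mm / config$ball_image_diameter_px
    # world angles of each baseline, caudal-most fixed horizontal:
    # psi[, L] = 0; psi[, l-1] = psi[, l] + alpha[, l]; aux = psi[,1]+alpha[,1]
    psi <- matrix(0, n, L)
    for (l in seq(L - 1L, 1L)) psi[, l] <- psi[, l + 1L] + alpha[, l + 1L]
    psi_aux <- psi[, 1L] + alpha[, 1L]
    rad <- pi / 180
    rows <- vector("list", L + 1L)
    # stack positions caudal -> cranial
    Px <- matrix(0, n, L); Py <- matrix(0, n, L)
    for (l in seq(L - 1L, 1L)) {
      dy <- vb + pr$h_eff[l + 1L]
      Px[, l] <- Px[, l + 1L] - sin(psi[, l] * rad) * dy
      Py[, l] <- Py[, l + 1L] + cos(psi[, l] * rad) * dy
    }
    for (l in seq_len(L)) {
      y3 <- pr$h_eff[l] + pr$a_eff[l] * (1 - G[, l])
      c_ <- cos(psi[, l] * rad); s_ <- sin(psi[, l] * rad)
      p1x <- Px[, l];                 p1y <- Py[, l]
      p2x <- Px[, l] + c_ * B[l];     p2y <- Py[, l] + s_ * B[l]
      x3 <- 0.75 * B[l]
      p3x <- Px[, l] + c_ * x3 - s_ * y3
      p3y <- Py[, l] + s_ * x3 + c_ * y3
      rows[[l]] <- data.frame(
        frame_index = rep(seq_len(n) - 1L, 3L),
        phase = rep(phase, 3L),
        level = lv[l],
        point_id = rep(1:3, each = n),
        x_mm = c(p1x, p2x, p3x), y_mm = c(p1y, p2y, p3y))
    }
    # auxiliary most-cranial endplate (points 1-2 only)
    dy <- vb + pr$h_eff[1L]
    ax <- Px[, 1L] - sin(psi_aux * rad) * dy
    ay <- Py[, 1L] + cos(psi_aux * rad) * dy
    bx <- ax + cos(psi_aux * rad) * B[1L]
    by <- ay + sin(psi_aux * rad) * B[1L]
    rows[[L + 1L]] <- data.frame(
      frame_index = rep(seq_len(n) - 1L, 2L),
      phase = rep(phase, 2L),
      level = section_top_plate(config$section),
      point_id = rep(1:2, each = n),
      x_mm = c(ax, bx), y_mm = c(ay, by))
    tab <- do.call(rbind, rows)
    if (config$noise_sd_fraction > 0) {
      c_geom <- sqrt(1 + 0.75^2 + 0.25^2)
      s_max_h <- B / 2 * (config$heights + pr$a_healthy)
      sd_mm <- config$noise_sd_fraction * mean(2 * s_max_h / B) / c_geom
      tab$x_mm <- tab$x_mm + stats::rnorm(nrow(tab), 0, sd_mm)
      tab$y_mm <- tab$y_mm + stats::rnorm(nrow(tab), 0, sd_mm)
    }
    landmarks <- data.frame(subject_id = subject_id, session_id = session_id,
                            frame_index = tab$frame_index, phase = tab$phase,
                            level = tab$level, point_id = tab$point_id,
                            x_px = tab$x_mm / scale, y_px = tab$y_mm / scale)
    o <- order(landmarks$frame_index, landmarks$level, landmarks$point_id)
    landmarks <- landmarks[o, ]
    rownames(landmarks) <- NULL
    new_exam_bundle(landmarks,
                    calibrate_scale(config$ball_true_diameter_mm,
                                    config$ball_image_diameter_px),
                    config$section)
  })
}

#' Generate a device cohort with paired outcome scores
#'
#' Per subject: randomized degeneration at a target level (plus mild random
#' wear elsewhere, sparing a preserved donor level), a pre-op exam, a
#' post-op exam with one of the supplied devices applied at the target, and
#' an outcome record on the neck-disability (NDI, 0-1 fraction) scale whose
#' worsening is `slope * mean adjacent delta-RoM + noise` -- the generative
#' law behind the delta-RoM / outcome correlation analyses.
#'
#' @param config a [spine_config] template (healthy anatomy, noise, frames).
#' @param n_subjects cohort size (>= 2).
#' @param devices list of [device_spec] cycled over subjects.
#' @param outcome_model list with `slope` (NDI worsening per mm^2 of mean
#'   adjacent delta-RoM) and `noise_sd`.
#' @param target_level implanted level (default mid-section, e.g. C5-C6).
#' @param best_level preserved donor level left pristine.
#' @param seed integer seed; the whole cohort is reproducible given it.
#' @return object of class `synthetic_cohort`: list with `subjects` (list of
#'   per-subject records: pre/post `exam_bundle`s, truth), `outcomes`
#'   (data.frame subject_id, score_name, pre, post, delta), `config`.
#' @export
generate_cohort <- function(config, n_subjects,
                            devices = default_devices(),
                            outcome_model = list(slope = 0.015,
                                                 noise_sd = 0.03),
                            target_level = NULL, best_level = NULL,
                            seed = 1L) {
  stopifnot(inherits(config, "spine_config"))
  if (n_subjects < 2)
    abort_biokin("n_subjects must be >= 2", "biokin_insufficient_cohort")
  if (!is.list(outcome_model) ||
      !all(c("slope", "noise_sd") %in% names(outcome_model)) ||
      !is_number(outcome_model$slope) || !is_number(outcome_model$noise_sd) ||
      outcome_model$noise_sd < 0)
    abort_biokin("outcome_model must be list(slope, noise_sd)",
                 "biokin_config_error")
  lv <- config$levels
  if (is.null(target_level)) target_level <- lv[ceiling(length(lv) / 2) + 1L]
  if (is.null(best_level)) best_level <- lv[length(lv)]
  if (target_level == best_level)
    abort_biokin("target and best level must differ", "biokin_config_error")
  with_seed(seed, {
    subjects <- vector("list", n_subjects)
    out <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      sid <- sprintf("S%03d", s)
      dev <- devices[[(s - 1L) %% length(devices) + 1L]]
      deg <- data.frame(level = target_level,
                        height_loss_mm = stats::runif(1, 1.5, 2.5),
                        mobility_scale = stats::runif(1, 0.4, 0.6))
      others <- setdiff(lv, c(target_level, best_level))
      if (length(others)) {
        deg <- rbind(deg, data.frame(
          level = others,
          height_loss_mm = stats::runif(length(others), 0, 0.5),
          mobility_scale = stats::runif(length(others), 0.85, 1)))
      }
      pre_cfg <- config; pre_cfg$degeneration <- deg
      implant_h <- config$heights[[target_level]]
      post_cfg <- pre_cfg
      post_cfg$device <- list(level = target_level, spec = dev,
                              implanted_height_mm = implant_h)
      pre <- generate_exam(pre_cfg, sid, "pre")
      post <- generate_exam(post_cfg, sid, "post")
      truth_adj <- build_profile(post_cfg)$adjacent_delta_area
      mean_adj <- mean(truth_adj)
      ndi_pre <- min(max(stats::rnorm(1, 0.38, 0.03), 0.05), 0.95)
      delta <- outcome_model$slope * mean_adj +
        stats::rnorm(1, 0, outcome_model$noise_sd)
      subjects[[s]] <- list(subject_id = sid, device = dev,
                            pre = pre, post = post,
                            truth = list(worst_level = target_level,
                                         best_level = best_level,
                                         degeneration = deg,
                                         implanted_height_mm = implant_h,
                                         adjacent_delta_rom = truth_adj,
                                         mean_adjacent_delta_rom = mean_adj))
      out[[s]] <- data.frame(subject_id = sid, score_name = "NDI",
                             pre = ndi_pre,
                             post = min(max(ndi_pre + delta, 0), 1),
                             delta = delta)
    }
    structure(list(subjects = subjects, outcomes = do.call(rbind, out),
                   config = config, target_level = target_level,
                   best_level = best_level, devices = devices, seed = seed),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s), target %s, devices {%s}\n",
              length(x$subjects), x$config$section, x$target_level,
              paste(vapply(x$devices, `[[`, character(1), "name"),
                    collapse = ", ")))
  invisible(x)
}

#' Default cervical device portfolio
#'
#' A rigid interbody cage and two prostheses of decreasing residual
#' mobility, with manufactured height grids starting at 5 mm for the
#' prostheses.
#'
#' @return named list of [device_spec].
#' @export
default_devices <- function() {
  list(C  = device_spec("C",  "cage",       0,   seq(4, 8, by = 0.5)),
       P1 = device_spec("P1", "prosthesis", 0.8, c(5, 6, 7)),
       P2 = device_spec("P2", "prosthesis", 0.4, c(5, 6, 7)))
}

#' Two-session signature cohort for the fingerprint reproducibility study
#'
#' Each subject gets an individual healthy motion profile (per-level
#' delta-S/S_max drawn around the section defaults) and two repeated
#' three-pose exams with independent session noise, mirroring the duplicate
#' functional-image protocol; signatures are recovered through the full
#' landmark pipeline.
#'
#' @param config a [spine_config] template; its `n_frames`/noise apply.
#' @param n_subjects number of subjects (>= 2).
#' @param subject_ratio_sd between-subject sd of each level's ratio.
#' @param seed integer seed.
#' @return list over subjects, each a list of two `spine_signature`s
#'   (input shape for [bayes_error_rate]).
#' @export
generate_fingerprint_cohort <- function(config, n_subjects = 20,
                                        subject_ratio_sd = 0.05, seed = 1L) {
  stopifnot(inherits(config, "spine_config"))
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      cfg <- config
      cfg$ratios <- pmin(pmax(
        config$ratios + stats::rnorm(length(config$ratios), 0,
                                     subject_ratio_sd), 0.1), 0.8)
      lapply(c("a", "b"), function(ss) {
        ex <- generate_exam(cfg, sprintf("S%03d", s), ss)
        analyze_exam(ex)$signature
      })
    })
  })
}
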