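# Exam-level analysis: from a calibrated landmark table to triangles, RoM
# curves, conventional angles, signatures and worst/best detection.

#' Construct an exam bundle
#' @noRd
new_exam_bundle <- function(landmarks, calibration, section,
                            subject_id = NULL, session_id = NULL) {
  structure(list(
    landmarks = landmarks, calibration = calibration, section = section,
    subject_id = subject_id %||% landmarks$subject_id[1],
    session_id = session_id %||% landmarks$session_id[1]
  ), class = "exam_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.exam_bundle <- function(x, ...) {
  cat(sprintf("Exam %s/%s (%s): %d frames, %d landmark rows\n",
              x$subject_id, x$session_id, x$section,
              length(unique(x$landmarks$frame_index)), nrow(x$landmarks)))
  invisible(x)
}

#' Reshape an exam's landmark table into per-frame/per-level arrays (mm)
#' @noRd
exam_arrays <- function(bundle) {
  if (is.null(bundle$calibration))
    abort_biokin("exam bundle has no calibration record",
                 "biokin_invalid_calibration")
  tab <- bundle$landmarks
  s <- bundle$calibration$scale_mm_per_px
  lv <- section_levels(bundle$section)
  seg <- tab[tab$level %in% lv, ]
  missing_lv <- setdiff(lv, unique(seg$level))
  if (length(missing_lv))
    abort_biokin(paste("section level(s) missing from exam:",
                       paste(missing_lv, collapse = ", ")),
                 "biokin_incomplete_section")
  frames <- sort(unique(tab$frame_index))
  nf <- length(frames); nl <- length(lv)
  X <- array(NA_real_, c(nf, nl, 3L))
  Y <- array(NA_real_, c(nf, nl, 3L))
  i <- match(seg$frame_index, frames)
  j <- match(seg$level, lv)
  X[cbind(i, j, seg$point_id)] <- seg$x_px * s
  Y[cbind(i, j, seg$point_id)] <- seg$y_px * s
  if (anyNA(X) || anyNA(Y)) {
    hole <- which(is.na(X), arr.ind = TRUE)[1, ]
    abort_biokin(sprintf("point %d of level %s missing in frame %s",
                         hole[3], lv[hole[2]], frames[hole[1]]),
                 "biokin_incomplete_frame")
  }
  phase <- tab$phase[match(frames, tab$frame_index)]
  # auxiliary most-cranial endplate, if present
  aux_lab <- section_top_plate(bundle$section)
  aux <- tab[tab$level == aux_lab, ]
  aux_dir <- NULL
  if (nrow(aux) > 0) {
    a1 <- aux[aux$point_id == 1, ]; a2 <- aux[aux$point_id == 2, ]
    if (nrow(a1) == nf && nrow(a2) == nf) {
      a1 <- a1[match(frames, a1$frame_index), ]
      a2 <- a2[match(frames, a2$frame_index), ]
      aux_dir <- atan2(a2$y_px - a1$y_px, a2$x_px - a1$x_px) * 180 / pi
    }
  }
  list(X = X, Y = Y, frames = frames, phase = phase, levels = lv,
       aux_dir = aux_dir)
}

#' Full kinematic analysis of one exam
#'
#' Computes, per frame and level, the biokinemetric triangle (baseline,
#' area, apex height), the whole-section inclination angle and movement
#' percentage, per-level RoM curves and delta-S/S_max signatures, and the
#' conventional angle-based ROM.  With a reference surrogate, additionally
#' estimates intersegmental disc heights and detects the worst and best
#' segments.
#'
#' @param bundle an `exam_bundle` (from [generate_exam] or
#'   [read_landmark_table]).
#' @param reference optional [reference_surrogate].
#' @param weights best-segment weights `c(w_h, w_c)`.
#' @param monotone_sweep stabilize the whole-section angle by isotonic
#'   regression over acquisition order before computing movement
#'   percentages (the functional exam sweeps monotonically from
#'   inclination to reclination, so a non-monotone angle sequence is
#'   annotation noise).  Applied to recordings of five or more frames;
#'   three-pose exams are left untouched.
#' @return object of class `biokin_analysis`: list with `curves`,
#'   `signature`, `fraction`, `global_angle`, `phase`, `conventional_rom`,
#'   `baselines`, and (given a reference) `heights`, `worst`, `best`.
#' @export
analyze_exam <- function(bundle, reference = NULL, weights = c(0.5, 0.5),
                         monotone_sweep = TRUE) {
  ar <- exam_arrays(bundle)
  nf <- length(ar$frames); lv <- ar$levels; nl <- length(lv)
  X <- ar$X; Y <- ar$Y
  area <- 0.5 * abs((X[, , 2] - X[, , 1]) * (Y[, , 3] - Y[, , 1]) -
                    (X[, , 3] - X[, , 1]) * (Y[, , 2] - Y[, , 1]))
  base_len <- sqrt((X[, , 2] - X[, , 1])^2 + (Y[, , 2] - Y[, , 1])^2)
  if (any(base_len == 0))
    abort_biokin("degenerate baseline in at least one frame",
                 "biokin_degenerate_baseline")
  base_dir <- atan2(Y[, , 2] - Y[, , 1], X[, , 2] - X[, , 1]) * 180 / pi
  dim(area) <- dim(base_len) <- dim(base_dir) <- c(nf, nl)
  # whole-section angle: most cranial plate (aux if available) vs most caudal
  top_dir <- if (!is.null(ar$aux_dir)) ar$aux_dir else base_dir[, 1]
  global_angle <- wrap_angle(top_dir - base_dir[, nl])
  i_inc <- which(ar$phase == "inclination")[1]
  i_rec <- which(ar$phase == "reclination")[1]
  if (is.na(i_inc) || is.na(i_rec))
    abort_biokin("exam must contain inclination and reclination poses",
                 "biokin_missing_pose")
  angle_for_frac <- global_angle
  if (monotone_sweep && nf >= 5L) {
    # the exam is a smooth monotone sweep in acquisition order: denoise the
    # section-angle trajectory (cubic trend for dense recordings), then
    # project onto the monotone cone (pool-adjacent-violators)
    sgn <- sign(global_angle[i_rec] - global_angle[i_inc])
    if (sgn != 0) {
      a <- global_angle
      if (nf >= 9L) {
        idx <- seq_len(nf)
        a <- stats::fitted(stats::lm(a ~ stats::poly(idx, 3)))
      }
      angle_for_frac <- sgn * stats::isoreg(seq_len(nf), sgn * a)$yf
    }
  }
  arc <- angle_for_frac[i_rec] - angle_for_frac[i_inc]
  if (arc == 0) abort_biokin("zero movement arc", "biokin_zero_arc")
  frac <- 100 * (angle_for_frac - angle_for_frac[i_inc]) / arc
  if (any(frac < -1e-9 | frac > 100 + 1e-9))
    warn_biokin("frame(s) outside the endpoint arc clamped to [0, 100]",
                "biokin_fraction_clamped")
  frac <- pmin(pmax(frac, 0), 100)
  # segmental endplate angles: upper plate = plate of the level above
  upper_dir <- cbind(if (!is.null(ar$aux_dir)) ar$aux_dir else
                       rep(NA_real_, nf),
                     base_dir[, -nl, drop = FALSE])
  seg_angle <- wrap_angle(upper_dir - base_dir)
  conv_rom <- wrap_angle(seg_angle[i_rec, ] - seg_angle[i_inc, ])
  names(conv_rom) <- lv
  curves <- lapply(seq_len(nl), function(j) {
    agg <- tapply(area[, j], frac, mean)
    fr_u <- as.numeric(names(agg))
    o <- order(fr_u)
    motion_curve(lv[j], fr_u[o], as.numeric(agg)[o], "measured")
  })
  names(curves) <- lv
  res <- list(curves = curves,
              signature = spine_signature(curves, bundle$section),
              fraction = frac, global_angle = global_angle,
              phase = ar$phase, conventional_rom = conv_rom,
              baselines = colMeans(base_len), section = bundle$section,
              subject_id = bundle$subject_id, session_id = bundle$session_id)
  names(res$baselines) <- lv
  if (!is.null(reference)) {
    res$heights <- estimate_disc_heights(res, reference)
    res$worst <- detect_worst_segment(curves, reference)
    res$best <- detect_best_segment(curves, res$heights, reference,
                                    weights = weights,
                                    exclude = res$worst$level)
  }
  structure(res, class = "biokin_analysis")
}

#' @export
print.biokin_analysis <- function(x, ...) {
  cat(sprintf("Analysis %s/%s (%s): arc %.1f deg over %d frames\n",
              x$subject_id, x$session_id, x$section,
              abs(x$global_angle[length(x$global_angle)] - x$global_angle[1]),
              length(x$fraction)))
  cat("  dS/Smax series:", paste(sprintf("%.3f", x$signature$ratio),
                                 collapse = " "), "\n")
  if (!is.null(x$worst))
    cat(sprintf("  worst segment %s, best segment %s\n",
                x$worst$level, x$best$level))
  invisible(x)
}

#' Estimate neutral intersegmental disc heights from an exam
#'
#' A level's area trajectory is affine in the reference surrogate's
#' normalized curve (both are affine in the level's motion progress), so the
#' measured areas are regressed on the reference curve by least squares and
#' the disc height read off as twice the predicted area at the reference
#' curve's minimum (the pose where the motion term vanishes) divided by the
#' measured baseline length.
#'
#' @param analysis a `biokin_analysis`.
#' @param reference a [reference_surrogate].
#' @return named numeric vector of heights (mm), cranial -> caudal.
#' @export
estimate_disc_heights <- function(analysis, reference) {
  lv <- reference$levels
  h <- vapply(seq_along(lv), function(i) {
    cv <- analysis$curves[[lv[i]]]
    if (is.null(cv))
      abort_biokin(paste("level missing from analysis:", lv[i]),
                   "biokin_reference_gap")
    r <- stats::approx(reference$fraction, reference$curves[i, ],
                       xout = cv$fraction, rule = 2)$y
    b <- analysis$baselines[[lv[i]]]
    if (stats::sd(r) == 0) return(2 * mean(cv$area) / b)
    fit <- stats::lm.fit(cbind(1, r), cv$area)
    s_at_min <- sum(fit$coefficients * c(1, min(reference$curves[i, ])))
    2 * max(s_at_min, 0) / b
  }, numeric(1))
  names(h) <- lv
  h
}

#' Expand an exam into motion-frame objects
#'
#' The object-per-frame view of an exam used by the frame-level operations
#' ([build_rom_curve], [conventional_rom], [movement_fraction]); the
#' vectorized [analyze_exam] is the equivalent fast path.
#'
#' @param bundle an `exam_bundle`.
#' @return list of [motion_frame].
#' @export
exam_to_frames <- function(bundle) {
  ar <- exam_arrays(bundle)
  nf <- length(ar$frames); lv <- ar$levels; nl <- length(lv)
  base_dir <- atan2(ar$Y[, , 2] - ar$Y[, , 1],
                    ar$X[, , 2] - ar$X[, , 1]) * 180 / pi
  dim(base_dir) <- c(nf, nl)
  top_dir <- if (!is.null(ar$aux_dir)) ar$aux_dir else base_dir[, 1]
  upper_dir <- cbind(if (!is.null(ar$aux_dir)) ar$aux_dir else
                       rep(NA_real_, nf),
                     base_dir[, -nl, drop = FALSE])
  lapply(seq_len(nf), function(i) {
    tri <- lapply(seq_len(nl), function(j) {
      p <- lapply(1:3, function(k) c(ar$X[i, j, k], ar$Y[i, j, k]))
      d <- p[[2]] - p[[1]]
      b <- sqrt(sum(d^2))
      ct <- d[1] / b; st <- d[2] / b
      q <- p[[3]] - p[[1]]
      new_triangle(lv[j], c(0, 0), c(b, 0),
                   c(ct * q[1] + st * q[2], -st * q[1] + ct * q[2]))
    })
    names(tri) <- lv
    sa <- wrap_angle(upper_dir[i, ] - base_dir[i, ])
    names(sa) <- lv
    motion_frame(ar$frames[i], ar$phase[i],
                 wrap_angle(top_dir[i] - base_dir[i, nl]), tri, sa)
  })
}

#' Measured adjacent-level delta-RoM of a synthetic cohort
#'
#' Runs the full landmark pipeline on every subject's pre and post exams and
#' measures the delta-RoM of the levels adjacent to the implanted segment.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort].
#' @return data.frame with `subject_id`, `device`, `mean_adjacent_delta_rom`
#'   (mm^2) and per-neighbour columns `delta_rom_cranial`,
#'   `delta_rom_caudal` (NA at section boundaries).
#' @export
cohort_adjacent_delta_rom <- function(cohort) {
  lv <- cohort$config$levels
  it <- match(cohort$target_level, lv)
  nb <- c(it - 1L, it + 1L)
  nb <- nb[nb >= 1L & nb <= length(lv)]
  rows <- lapply(cohort$subjects, function(s) {
    pre <- analyze_exam(s$pre)
    post <- analyze_exam(s$post)
    dr <- vapply(lv[nb], function(l)
      delta_rom(pre$curves[[l]], post$curves[[l]])$delta_rom, numeric(1))
    data.frame(subject_id = s$subject_id, device = s$device$name,
               mean_adjacent_delta_rom = mean(dr),
               delta_rom_cranial = if (it > 1L) dr[[1L]] else NA_real_,
               delta_rom_caudal = if (it < length(lv)) dr[[length(dr)]]
                                  else NA_real_)
  })
  do.call(rbind, rows)
}
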