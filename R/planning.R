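# Virtual best-into-worst substitution, optimal device height with
# size-ratio scaling and device-grid mapping, prediction of post-implant
# adjacent-level motion redistribution, delta-RoM, and delta-RoM -- outcome
# correlation.

#' Device specification
#'
#' @param name device label.
#' @param kind "cage" (rigid fusion) or "prosthesis".
#' @param mobility_factor fraction of the healthy reference range the
#'   implanted segment retains, in \[0, 1\]; forced to 0 for cages.
#' @param available_heights strictly increasing vector of manufactured
#'   heights (mm).
#' @return object of class `device_spec`.
#' @export
device_spec <- function(name, kind = c("cage", "prosthesis"),
                        mobility_factor = 0, available_heights) {
  kind <- match.arg(kind)
  if (kind == "cage") mobility_factor <- 0
  if (!is_number(mobility_factor) || mobility_factor < 0 || mobility_factor > 1)
    abort_biokin("mobility_factor must be in [0, 1]", "biokin_invalid_device")
  if (length(available_heights) == 0)
    abort_biokin("available_heights must be nonempty", "biokin_empty_grid")
  if (any(diff(available_heights) <= 0) || any(available_heights <= 0))
    abort_biokin("available_heights must be positive and strictly increasing",
                 "biokin_invalid_device")
  structure(list(name = name, kind = kind,
                 mobility_factor = mobility_factor,
                 available_heights = as.numeric(available_heights)),
            class = "device_spec")
}

#' @export
print.device_spec <- function(x, ...) {
  cat(sprintf("Device %s (%s): mobility factor %.2f, heights {%s} mm\n",
              x$name, x$kind, x$mobility_factor,
              paste(x$available_heights, collapse = ", ")))
  invisible(x)
}

#' Virtually substitute the best segment's motion into the worst segment
#'
#' The best segment's self-normalized RoM curve is transplanted to the worst
#' level and rescaled to that level's reference maximum area times the level
#' size-ratio quotient, yielding the virtual healthy-like curve the worst
#' segment should recover.  The delta-S/S_max ratio is transferred unchanged
#' (it is scale invariant).
#'
#' @param patient_curves list of [motion_curve] per level.
#' @param worst,best distinct segment labels.
#' @param reference a [reference_surrogate].
#' @return a `motion_curve` at the worst level, `source = "virtual"`.
#' @export
virtual_substitution <- function(patient_curves, worst, best, reference) {
  if (identical(worst, best))
    abort_biokin("worst and best level must differ",
                 "biokin_degenerate_substitution")
  lv <- vapply(patient_curves, function(cv) cv$level, character(1))
  if (!all(c(worst, best) %in% lv))
    abort_biokin("worst and best levels must both be present",
                 "biokin_reference_gap")
  if (!all(c(worst, best) %in% reference$levels))
    abort_biokin("levels missing from the reference surrogate",
                 "biokin_reference_gap")
  bc <- patient_curves[[which(lv == best)]]
  if (bc$s_max <= 0)
    abort_biokin("best-level curve has zero area", "biokin_empty_curve")
  # reference s_max of the worst level in patient scale: patient best s_max
  # mapped through the level size ratios
  q <- reference$size_ratios[[worst]] / reference$size_ratios[[best]]
  target_smax <- bc$s_max * q
  motion_curve(worst, bc$fraction, bc$area / bc$s_max * target_smax, "virtual")
}

#' Optimal device height for the worst segment
#'
#' The intersegmental height the worst segment should be restored to: the
#' best (most preserved) segment's height scaled by the quotient of level
#' size ratios, capped at the worst level's reference neutral height to
#' prevent overcorrection.
#'
#' @param patient_heights named neutral intersegmental heights (mm).
#' @param worst,best segment labels.
#' @param reference a [reference_surrogate].
#' @return list with `height` (mm), `capped` flag, and `no_change` flag
#'   (TRUE when the recommendation does not exceed the current worst height).
#' @export
optimal_device_height <- function(patient_heights, worst, best, reference) {
  hb <- patient_heights[[best]]
  hw <- patient_heights[[worst]]
  if (!is_number(hb) || hb <= 0 || !is_number(hw) || hw <= 0)
    abort_biokin("patient heights must be positive and finite",
                 "biokin_invalid_height")
  q <- reference$size_ratios[[worst]] / reference$size_ratios[[best]]
  h <- hb * q
  cap <- reference$heights[[worst]]
  capped <- h > cap
  h <- min(h, cap)
  list(height = h, capped = capped, no_change = h <= hw)
}

#' Map a recommended height onto a device's manufactured grid
#'
#' Returns the nearest available height (ties toward the smaller height:
#' less distraction) and whether the recommendation is exactly available
#' (within 0.05 mm).
#'
#' @param h recommended height (mm).
#' @param device a [device_spec].
#' @return list with `grid_height`, `exact_available`.
#' @export
#' @examples
#' map_to_device_grid(4.5, device_spec("P", "prosthesis", 0.8, c(5, 6, 7)))
map_to_device_grid <- function(h, device) {
  g <- device$available_heights
  if (length(g) == 0) abort_biokin("empty device grid", "biokin_empty_grid")
  d <- abs(g - h)
  # ties toward the smaller height
  i <- which(d == min(d))[1]
  list(grid_height = g[i], exact_available = d[i] < 0.05)
}

curve_range <- function(cv) cv$s_max - cv$s_min

#' Rescale a curve's range about its maximum
#' @noRd
rescale_range <- function(cv, new_range, source = "virtual") {
  old <- curve_range(cv)
  if (old == 0) {
    if (new_range == 0) return(motion_curve(cv$level, cv$fraction, cv$area, source))
    abort_biokin("cannot expand a flat curve", "biokin_invalid_curve")
  }
  area <- cv$s_max - (cv$s_max - cv$area) * new_range / old
  motion_curve(cv$level, cv$fraction, pmax(area, 0), source)
}

#' Predict adjacent-level motion after implantation
#'
#' The implanted level's area range is set to mobility_factor times its
#' healthy reference range (reference ratio times the patient's s_max at
#' that level); the removed range is redistributed to the immediately
#' adjacent levels proportionally to their current ranges, conserving the
#' section's total range.  Non-adjacent levels are unchanged.  A boundary
#' target redistributes to its single neighbour (flagged).  This
#' redistribution rule is the package's model of intersegmental
#' communication, not a biomechanical simulation.
#'
#' @param patient_curves list of [motion_curve] per level, cranial -> caudal.
#' @param target implanted segment label.
#' @param device a [device_spec].
#' @param reference a [reference_surrogate].
#' @return list with `curves` (per level; changed ones `source = "virtual"`),
#'   `single_neighbor` flag.
#' @export
predict_postop_curves <- function(patient_curves, target, device, reference) {
  lv <- vapply(patient_curves, function(cv) cv$level, character(1))
  if (!(target %in% lv))
    abort_biokin("target level not present", "biokin_reference_gap")
  if (!inherits(device, "device_spec"))
    abort_biokin("device must be a device_spec", "biokin_invalid_device")
  ord <- match(reference$levels, lv)
  if (anyNA(ord))
    abort_biokin("patient curves must cover the full section",
                 "biokin_incomplete_section")
  patient_curves <- patient_curves[ord]
  lv <- reference$levels
  it <- which(lv == target)
  i_ref <- which(reference$levels == target)
  ref_ratio <- 1 - min(reference$curves[i_ref, ]) / max(reference$curves[i_ref, ])
  tc <- patient_curves[[it]]
  pre_range <- curve_range(tc)
  post_range <- device$mobility_factor * ref_ratio * tc$s_max
  removed <- pre_range - post_range
  nb <- c(it - 1L, it + 1L)
  nb <- nb[nb >= 1L & nb <= length(lv)]
  single <- length(nb) == 1L
  nb_ranges <- vapply(patient_curves[nb], curve_range, numeric(1))
  out <- patient_curves
  if (abs(removed) > 0) {
    out[[it]] <- rescale_range(tc, post_range)
    if (sum(nb_ranges) > 0) {
      share <- nb_ranges / sum(nb_ranges)
    } else {
      share <- rep(1 / length(nb), length(nb))
    }
    for (j in seq_along(nb)) {
      nr <- nb_ranges[j] + removed * share[j]
      if (nr < 0) nr <- 0  # cannot move less than nothing
      out[[nb[j]]] <- rescale_range(patient_curves[[nb[j]]], nr)
    }
  }
  list(curves = out, single_neighbor = single)
}

#' Change in a level's range of motion between two exams
#'
#' delta-RoM = |change of the triangle-area range| between the pre and post
#' curves of one level; the adjacent-segment effect measure.
#'
#' @param pre,post [motion_curve]s of the same level.
#' @return object of class `rom_change`: list with `level`, `pre_range`,
#'   `post_range`, `delta_rom` (mm^2).
#' @export
delta_rom <- function(pre, post) {
  if (!identical(pre$level, post$level))
    abort_biokin("pre and post curves are for different levels",
                 "biokin_level_mismatch")
  structure(list(level = pre$level,
                 pre_range = curve_range(pre), post_range = curve_range(post),
                 delta_rom = abs(curve_range(post) - curve_range(pre))),
            class = "rom_change")
}

#' @export
print.rom_change <- function(x, ...) {
  cat(sprintf("dRoM %s: %.2f -> %.2f mm^2 (|d| = %.2f)\n",
              x$level, x$pre_range, x$post_range, x$delta_rom))
  invisible(x)
}

#' Correlate adjacent-level delta-RoM with outcome change
#'
#' Pearson correlation between each subject's mean adjacent-level delta-RoM
#' and the outcome delta, with a two-sided permutation p-value.  With
#' `relief = TRUE` the outcome delta is negated (relief = -(post - pre)), so
#' that implants disturbing adjacent segments more show a negative
#' correlation with relief.
#'
#' @param delta_roms numeric vector, per-subject mean adjacent delta-RoM.
#' @param outcome_deltas numeric vector of outcome changes (post - pre).
#' @param relief correlate against relief (negated delta) instead.
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return list with `r`, `p_value`, `n`, `undefined` flag (zero variance).
#' @export
correlate_delta_rom_outcome <- function(delta_roms, outcome_deltas,
                                        relief = TRUE, n_perm = 1e4,
                                        seed = NULL) {
  n <- length(delta_roms)
  if (n != length(outcome_deltas) || n < 3)
    abort_biokin("at least three paired subjects required",
                 "biokin_insufficient_cohort")
  y <- if (relief) -outcome_deltas else outcome_deltas
  if (stats::sd(delta_roms) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = n, undefined = TRUE))
  r <- stats::cor(delta_roms, y)
  with_seed(seed, {
    perm <- replicate(n_perm, sample.int(n))
    xp <- matrix(delta_roms[perm], nrow = n)
    rp <- as.numeric(stats::cor(xp, y))
    p <- (1 + sum(abs(rp) >= abs(r))) / (1 + n_perm)
    list(r = r, p_value = p, n = n, undefined = FALSE)
  })
}

#' Recommend an implant for a patient exam
#'
#' Chains worst/best detection, virtual best-into-worst substitution,
#' optimal height computation, device-grid mapping, post-implant prediction
#' and per-level delta-RoM into one implant plan.
#'
#' @param patient_curves list of [motion_curve] per level.
#' @param patient_heights named neutral intersegmental heights (mm).
#' @param reference a [reference_surrogate].
#' @param device a [device_spec].
#' @param worst optional preselected target level (default: detected).
#' @return object of class `implant_plan`.
#' @export
recommend_implant <- function(patient_curves, patient_heights, reference,
                              device, worst = NULL) {
  det <- detect_worst_segment(patient_curves, reference)
  if (is.null(worst)) worst <- det$level
  best <- detect_best_segment(patient_curves, patient_heights, reference,
                              exclude = worst)$level
  oh <- optimal_device_height(patient_heights, worst, best, reference)
  grid <- map_to_device_grid(oh$height, device)
  vsub <- virtual_substitution(patient_curves, worst, best, reference)
  post <- predict_postop_curves(patient_curves, worst, device, reference)
  lv <- vapply(post$curves, function(cv) cv$level, character(1))
  pre_ord <- patient_curves[match(lv, vapply(patient_curves,
                                             function(cv) cv$level,
                                             character(1)))]
  changes <- lapply(seq_along(lv),
                    function(i) delta_rom(pre_ord[[i]], post$curves[[i]]))
  structure(list(target_level = worst, best_level = best,
                 worst_scores = det$scores,
                 recommended_height = oh$height, capped = oh$capped,
                 no_change = oh$no_change,
                 grid_height = grid$grid_height,
                 exact_available = grid$exact_available,
                 device = device,
                 virtual_substitute = vsub,
                 virtual_curves = post$curves,
                 delta_rom_per_level = changes),
            class = "implant_plan")
}

#' @export
print.implant_plan <- function(x, ...) {
  cat(sprintf("Implant plan: target %s (best donor %s)\n", x$target_level,
              x$best_level))
  cat(sprintf("  recommended height %.2f mm%s -> device %s height %.2f mm (%s)\n",
              x$recommended_height, if (x$capped) " [capped]" else "",
              x$device$name, x$grid_height,
              if (x$exact_available) "exact" else "nearest available"))
  adj <- vapply(x$delta_rom_per_level, function(d) d$delta_rom, numeric(1))
  lv <- vapply(x$delta_rom_per_level, function(d) d$level, character(1))
  cat("  predicted dRoM per level [mm^2]:\n")
  for (i in seq_along(lv)) cat(sprintf("    %-7s %8.3f\n", lv[i], adj[i]))
  invisible(x)
}
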