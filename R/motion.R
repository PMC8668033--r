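# Per-segment range-of-motion (RoM) curves: triangle area as a function of
# the percentage of the whole section's inclination -> reclination movement.
# Sparse 3-pose exams are densified by shape-preserving monotone cubic
# interpolation; the conventional angle-based ROM and the motion-surface
# curvature analysis live here too.

#' Construct a motion frame
#'
#' @param frame_index acquisition index (>= 0).
#' @param phase one of "inclination", "neutral", "reclination", "intermediate".
#' @param global_angle whole-section inclination/reclination angle (degrees):
#'   signed angle of the most cranial endplate relative to the most caudal.
#' @param triangles named list of [biokin_triangle][register_to_segment_frame],
#'   one per level.
#' @param seg_angles optional named vector of conventional segmental endplate
#'   angles (degrees) per level.
#' @return object of class `motion_frame`.
#' @export
motion_frame <- function(frame_index, phase, global_angle, triangles,
                         seg_angles = NULL) {
  phase <- match.arg(phase,
                     c("inclination", "neutral", "reclination", "intermediate"))
  stopifnot(is_number(global_angle), frame_index >= 0)
  structure(list(frame_index = frame_index, phase = phase,
                 global_angle = global_angle, triangles = triangles,
                 seg_angles = seg_angles),
            class = "motion_frame")
}

#' Percentage of section movement for each frame
#'
#' Maps each frame's whole-section angle onto 0 (inclination pose) .. 100
#' (reclination pose).  Intermediate frames outside the endpoint arc are
#' clamped with a warning.  Invariant to adding a constant to all angles.
#'
#' @param frames list of [motion_frame].
#' @return numeric vector of percentages in \[0, 100\].
#' @export
movement_fraction <- function(frames) {
  if (length(frames) < 2)
    abort_biokin("at least two frames are required", "biokin_incomplete_curve")
  th <- vapply(frames, function(f) f$global_angle, numeric(1))
  ph <- vapply(frames, function(f) f$phase, character(1))
  i_inc <- which(ph == "inclination")[1]
  i_rec <- which(ph == "reclination")[1]
  if (is.na(i_inc) || is.na(i_rec))
    abort_biokin("inclination and reclination poses are both required",
                 "biokin_missing_pose")
  arc <- th[i_rec] - th[i_inc]
  if (arc == 0)
    abort_biokin("identical endpoint angles: zero movement arc",
                 "biokin_zero_arc")
  f <- 100 * (th - th[i_inc]) / arc
  if (any(f < 0 | f > 100)) {
    warn_biokin("frame(s) outside the inclination-reclination arc clamped to [0, 100]",
                "biokin_fraction_clamped")
    f <- pmin(pmax(f, 0), 100)
  }
  f
}

#' Construct a motion curve
#'
#' @param level segment label.
#' @param fraction percentages of movement, strictly increasing in \[0, 100\].
#' @param area triangle areas (mm^2), same length as `fraction`.
#' @param source "measured", "interpolated" or "virtual".
#' @return object of class `motion_curve` with `s_max`, `s_min` fields.
#' @export
motion_curve <- function(level, fraction, area,
                         source = c("measured", "interpolated", "virtual")) {
  source <- match.arg(source)
  if (length(fraction) == 0 || length(fraction) != length(area))
    abort_biokin("fraction and area must be nonempty and equal length",
                 "biokin_empty_curve")
  if (any(diff(fraction) <= 0))
    abort_biokin("fraction must be strictly increasing", "biokin_invalid_curve")
  if (any(!is.finite(fraction)) || any(!is.finite(area)) || any(area < 0))
    abort_biokin("curve values must be finite, areas >= 0", "biokin_invalid_curve")
  structure(list(level = level, fraction = as.numeric(fraction),
                 area = as.numeric(area),
                 s_max = max(area), s_min = min(area), source = source),
            class = "motion_curve")
}

#' @export
print.motion_curve <- function(x, ...) {
  cat(sprintf("RoM curve %s (%s): %d points, S in [%.2f, %.2f] mm^2, dS/Smax %.3f\n",
              x$level, x$source, length(x$fraction), x$s_min, x$s_max,
              if (x$s_max > 0) (x$s_max - x$s_min) / x$s_max else 0))
  invisible(x)
}

#' Plot a RoM curve (area vs. percentage of movement)
#' @param x a `motion_curve`.
#' @param ... passed to [graphics::plot].
#' @export
plot.motion_curve <- function(x, ...) {
  graphics::plot(x$fraction, x$area, type = "b",
                 xlab = "movement [%]", ylab = "triangle area S [mm^2]",
                 main = paste("RoM", x$level), ...)
  invisible(x)
}

#' Build a segment's RoM curve from an exam's frames
#'
#' @param frames list of [motion_frame] covering the exam.
#' @param level segment label present in every frame.
#' @return a `motion_curve` (source "measured"), sorted by fraction with
#'   duplicate fractions averaged.
#' @export
build_rom_curve <- function(frames, level) {
  if (length(frames) < 2)
    abort_biokin("at least two frames are required", "biokin_incomplete_curve")
  ok <- vapply(frames, function(f) level %in% names(f$triangles), logical(1))
  if (!all(ok))
    abort_biokin(sprintf("level %s missing in frame(s) %s", level,
                         paste(which(!ok), collapse = ",")),
                 "biokin_incomplete_level")
  fr <- movement_fraction(frames)
  ar <- vapply(frames, function(f) f$triangles[[level]]$area, numeric(1))
  # average duplicate fractions, then sort numerically
  agg <- tapply(ar, fr, mean)
  fr_u <- as.numeric(names(agg))
  o <- order(fr_u)
  motion_curve(level, fr_u[o], as.numeric(agg)[o], "measured")
}

#' Interpolate a sparse RoM curve onto a uniform grid
#'
#' Clinical exams sample only three poses (inclination, neutral,
#' reclination); the curve is densified with a shape-preserving monotone
#' cubic (Fritsch-Carlson) interpolant, which passes through every knot and
#' cannot overshoot the knot range between adjacent knots.
#'
#' @param sparse a `motion_curve` with >= 3 knots.
#' @param n_points number of uniform grid points over the knot span.
#' @return a `motion_curve` with `source = "interpolated"`.
#' @export
interpolate_curve <- function(sparse, n_points = 101) {
  stopifnot(inherits(sparse, "motion_curve"))
  if (length(sparse$fraction) < 3)
    abort_biokin("at least three knots (inclination, neutral, reclination) required",
                 "biokin_insufficient_knots")
  if (n_points < 2) abort_biokin("n_points must be >= 2", "biokin_invalid_curve")
  fun <- stats::splinefun(sparse$fraction, sparse$area, method = "monoH.FC")
  g <- seq(min(sparse$fraction), max(sparse$fraction), length.out = n_points)
  motion_curve(sparse$level, g, pmax(fun(g), 0), "interpolated")
}

#' Resample a curve onto a given fraction grid
#' @noRd
resample_curve <- function(curve, grid) {
  if (length(curve$fraction) >= 3) {
    fun <- stats::splinefun(curve$fraction, curve$area, method = "monoH.FC")
  } else {
    fun <- stats::approxfun(curve$fraction, curve$area, rule = 2)
  }
  g <- pmin(pmax(grid, min(curve$fraction)), max(curve$fraction))
  pmax(fun(g), 0)
}

#' Conventional angle-based range of motion of a segment
#'
#' ROM = segmental endplate angle at reclination minus at inclination
#' (signed, degrees); the classical measure the triangle surrogate is
#' compared against.
#'
#' @param frames list of [motion_frame] with `seg_angles` populated.
#' @param level segment label.
#' @return signed ROM in degrees.
#' @export
conventional_rom <- function(frames, level) {
  ph <- vapply(frames, function(f) f$phase, character(1))
  i_inc <- which(ph == "inclination")[1]
  i_rec <- which(ph == "reclination")[1]
  if (is.na(i_inc) || is.na(i_rec))
    abort_biokin("inclination and reclination poses are both required",
                 "biokin_missing_pose")
  ang <- function(i) {
    a <- frames[[i]]$seg_angles
    if (is.null(a) || !(level %in% names(a)) || !is.finite(a[[level]]))
      abort_biokin(sprintf("segment angle for %s unavailable in frame %d",
                           level, i), "biokin_missing_pose")
    a[[level]]
  }
  wrap_angle(ang(i_rec) - ang(i_inc))
}

#' Relative segmental motion expressed as a surface
#'
#' Stacks a family of RoM curves acquired at distinct segmental phase
#' offsets into a surface S(fraction, offset) and locates the strongest
#' curvature of the zero-offset (or central) curve -- the locus where
#' adjacent-segment motion initiation is expected.
#'
#' @param curve_family named list of `motion_curve`, names are phase offsets
#'   (percent of movement, numeric strings).
#' @param level segment label.
#' @param n_grid fraction grid resolution.
#' @return object of class `motion_surface` with fields `grid` (matrix,
#'   offsets x fractions), `fraction`, `offsets`, `curvature_max_location`
#'   (NA with `indeterminate = TRUE` for flat/linear curves).
#' @export
motion_surface <- function(curve_family, level, n_grid = 101) {
  if (length(curve_family) < 3)
    abort_biokin("at least three curves at distinct phase offsets required",
                 "biokin_insufficient_family")
  offs <- as.numeric(names(curve_family))
  if (anyNA(offs) || anyDuplicated(offs))
    abort_biokin("curve_family names must be distinct numeric phase offsets",
                 "biokin_insufficient_family")
  o <- order(offs)
  offs <- offs[o]; curve_family <- curve_family[o]
  grid <- seq(0, 100, length.out = n_grid)
  m <- t(vapply(curve_family, resample_curve, numeric(n_grid), grid = grid))
  rownames(m) <- format(offs, trim = TRUE)
  # central curve: offset closest to zero
  ic <- which.min(abs(offs))
  s <- m[ic, ]
  h <- grid[2] - grid[1]
  d2 <- (s[-c(1, 2)] - 2 * s[-c(1, n_grid)] + s[-c(n_grid - 1, n_grid)]) / h^2
  span <- max(s) - min(s)
  indeterminate <- span == 0 || max(abs(d2)) < 1e-10 * max(span, 1)
  loc <- if (indeterminate) NA_real_ else grid[which.max(abs(d2)) + 1L]
  structure(list(level = level, grid = m, fraction = grid, offsets = offs,
                 curvature_max_location = loc, indeterminate = indeterminate),
            class = "motion_surface")
}

#' @export
print.motion_surface <- function(x, ...) {
  cat(sprintf("Motion surface %s: %d offsets x %d fractions; strongest curvature at %s%%\n",
              x$level, nrow(x$grid), ncol(x$grid),
              if (x$indeterminate) "indeterminate" else
                format(x$curvature_max_location)))
  invisible(x)
}
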