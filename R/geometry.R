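# Calibration, rigid registration to the segment frame, and
# biokinemetric-triangle construction and measurement.
#
# The biokinemetric triangle of a motion segment is spanned by three sagittal
# landmarks: the leading (anterior) edge of the lower vertebra on its upper
# endplate (point 1), the ascending facet posteriorly on the same endplate
# (point 2), and the rear edge of the upper vertebra at the roof of the
# neuroforamen (point 3).  Points 1-2 form a baseline fixed to the lower
# vertebra, so in the registered segment frame only the apex (point 3) moves
# and the triangle's height/area is the motion surrogate.

#' Calibrate the pixel-to-millimetre scale from a gauged marker ball
#'
#' Radiographs carry a radio-opaque ball of known diameter; the ratio of true
#' to imaged diameter gives a single scalar scale (projective magnification
#' gradients are ignored).
#'
#' @param ball_true_diameter true ball diameter in mm.
#' @param ball_image_diameter imaged ball diameter in px.
#' @return object of class `calibration_record` with fields
#'   `ball_true_diameter_mm`, `ball_image_diameter_px`, `scale_mm_per_px`.
#' @export
#' @examples
#' calibrate_scale(30, 60)$scale_mm_per_px  # 0.5
calibrate_scale <- function(ball_true_diameter, ball_image_diameter) {
  if (!is_number(ball_true_diameter) || !is_number(ball_image_diameter) ||
      ball_true_diameter <= 0 || ball_image_diameter <= 0) {
    abort_biokin("calibration diameters must be finite and > 0",
                 "biokin_invalid_calibration")
  }
  structure(list(
    ball_true_diameter_mm = ball_true_diameter,
    ball_image_diameter_px = ball_image_diameter,
    scale_mm_per_px = ball_true_diameter / ball_image_diameter
  ), class = "calibration_record")
}

#' @export
print.calibration_record <- function(x, ...) {
  cat(sprintf("Calibration: ball %.3g mm / %.3g px -> %.6g mm/px\n",
              x$ball_true_diameter_mm, x$ball_image_diameter_px,
              x$scale_mm_per_px))
  invisible(x)
}

#' Unsigned triangle area by the shoelace formula
#'
#' @param p1,p2,p3 numeric length-2 coordinates (mm).
#' @param warn_degenerate warn when the points are collinear.
#' @return area in mm^2 (>= 0); 0 with a degeneracy warning when collinear.
#' @export
#' @examples
#' triangle_area(c(0, 0), c(30, 0), c(12, 9))  # 135
triangle_area <- function(p1, p2, p3, warn_degenerate = TRUE) {
  a <- 0.5 * abs((p2[1] - p1[1]) * (p3[2] - p1[2]) -
                 (p3[1] - p1[1]) * (p2[2] - p1[2]))
  if (warn_degenerate && a == 0) {
    warn_biokin("collinear landmarks: degenerate triangle with zero area",
                "biokin_degenerate_triangle")
  }
  a
}

#' Construct a biokinemetric triangle from registered landmarks
#' @noRd
new_triangle <- function(level, p1, p2, p3, degenerate = FALSE) {
  b <- sqrt(sum((p2 - p1)^2))
  if (b == 0) abort_biokin("baseline |p2 - p1| is zero", "biokin_degenerate_baseline")
  a <- triangle_area(p1, p2, p3, warn_degenerate = FALSE)
  structure(list(
    level = level, p1 = p1, p2 = p2, p3 = p3,
    baseline_length = b, area = a, height = 2 * a / b,
    degenerate = a == 0
  ), class = "biokin_triangle")
}

#' @export
print.biokin_triangle <- function(x, ...) {
  cat(sprintf("Biokinemetric triangle %s: baseline %.2f mm, area %.2f mm^2, height %.2f mm\n",
              x$level, x$baseline_length, x$area, x$height))
  invisible(x)
}

#' Register per-frame landmark triples to the fixed-baseline segment frame
#'
#' Each frame's three landmarks are calibrated (px -> mm) and rigidly
#' transformed (rotation + translation, no further scaling) so that point 1
#' lies at the origin and point 2 on the positive first axis.  The baseline is
#' thereby fixed to the lower vertebra across frames and only the apex moves;
#' areas are unchanged by the rigid transform.
#'
#' @param raw_points_per_frame list of frames; each frame a data.frame or
#'   matrix-like with columns `point_id`, `x`, `y` (px) containing point ids
#'   1, 2, 3 exactly once.
#' @param calibration a `calibration_record`.
#' @param level segment label attached to the triangles.
#' @return list of `biokin_triangle`, one per frame.
#' @export
register_to_segment_frame <- function(raw_points_per_frame, calibration,
                                      level = "unknown") {
  if (!inherits(calibration, "calibration_record"))
    abort_biokin("calibration must be a calibration_record",
                 "biokin_invalid_calibration")
  s <- calibration$scale_mm_per_px
  lapply(seq_along(raw_points_per_frame), function(i) {
    fr <- as.data.frame(raw_points_per_frame[[i]])
    if (!all(c(1, 2, 3) %in% fr$point_id) || nrow(fr) < 3) {
      abort_biokin(sprintf("frame %d: landmark points 1,2,3 required", i),
                   "biokin_incomplete_frame")
    }
    pt <- function(id) {
      r <- fr[fr$point_id == id, , drop = FALSE][1, ]
      c(r$x, r$y) * s
    }
    p1 <- pt(1); p2 <- pt(2); p3 <- pt(3)
    if (!all(is.finite(c(p1, p2, p3))))
      abort_biokin(sprintf("frame %d: non-finite landmark coordinate", i),
                   "biokin_invalid_landmark")
    d <- p2 - p1
    b <- sqrt(sum(d^2))
    if (b == 0)
      abort_biokin(sprintf("frame %d: degenerate baseline", i),
                   "biokin_degenerate_baseline")
    # rotation taking the baseline direction onto +x
    ct <- d[1] / b; st <- d[2] / b
    rot <- function(p) {
      q <- p - p1
      c(ct * q[1] + st * q[2], -st * q[1] + ct * q[2])
    }
    new_triangle(level, c(0, 0), c(b, 0), rot(p3))
  })
}

#' Signed angle between two endplate directions
#'
#' Conventional angular motion analysis: the signed angle from the lower
#' endplate direction to the upper endplate direction, in (-180, 180],
#' zero when the plates are parallel.
#'
#' @param lower_plate_dir,upper_plate_dir numeric length-2 direction vectors.
#' @return angle in degrees.
#' @export
#' @examples
#' endplate_angle(c(1, 0), c(cos(pi / 18), sin(pi / 18)))  # +10
endplate_angle <- function(lower_plate_dir, upper_plate_dir) {
  wrap_angle(vector_angle(upper_plate_dir) - vector_angle(lower_plate_dir))
}
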