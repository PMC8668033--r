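# Readers and writers for the package's plain-text formats: landmark CSV
# tables, calibration / device / reference-surrogate JSON, curve and
# signature CSV exports, outcome tables and JSON analysis reports.

landmark_columns <- c("subject_id", "session_id", "frame_index", "phase",
                      "level", "point_id", "x_px", "y_px")
valid_phases <- c("inclination", "neutral", "reclination", "intermediate")

#' Read a landmark table into an exam bundle
#'
#' Comma-separated text with header
#' `subject_id,session_id,frame_index,phase,level,point_id,x_px,y_px`;
#' unknown columns are preserved but ignored.  For multi-subject or
#' multi-session tables use [read_exam_set].
#'
#' @param path file path.
#' @param calibration a `calibration_record` (or NULL; required later by
#'   [analyze_exam]).
#' @param section "cervical" or "lumbar"; inferred from the level labels
#'   when NULL.
#' @return an `exam_bundle`.
#' @export
read_landmark_table <- function(path, calibration = NULL, section = NULL) {
  if (!file.exists(path))
    abort_biokin(paste("no such file:", path), "biokin_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_landmarks(df, path)
  if (is.null(section)) section <- infer_section(df$level)
  if (length(unique(df$subject_id)) > 1 || length(unique(df$session_id)) > 1)
    abort_biokin("table contains several exams; use read_exam_set()",
                 "biokin_io_error")
  new_exam_bundle(df[landmark_columns], calibration, section)
}

#' Read a multi-exam landmark table, split by subject and session
#'
#' @inheritParams read_landmark_table
#' @return named list of `exam_bundle`s, names `subject_id/session_id`.
#' @export
read_exam_set <- function(path, calibration = NULL, section = NULL) {
  if (!file.exists(path))
    abort_biokin(paste("no such file:", path), "biokin_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_landmarks(df, path)
  if (is.null(section)) section <- infer_section(df$level)
  key <- paste(df$subject_id, df$session_id, sep = "/")
  lapply(split(df[landmark_columns], key), new_exam_bundle,
         calibration = calibration, section = section)
}

validate_landmarks <- function(df, path) {
  if (nrow(df) == 0)
    abort_biokin(paste("empty landmark table:", path), "biokin_empty_input")
  miss <- setdiff(landmark_columns, names(df))
  if (length(miss))
    abort_biokin(paste("landmark table missing required column(s):",
                       paste(miss, collapse = ", ")), "biokin_schema_error")
  for (col in c("frame_index", "point_id", "x_px", "y_px")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      abort_biokin(sprintf("non-numeric %s at data row %d", col, bad[1]),
                   "biokin_parse_error")
  }
  bad_ph <- which(!(df$phase %in% valid_phases))
  if (length(bad_ph))
    abort_biokin(sprintf("invalid phase '%s' at data row %d",
                         df$phase[bad_ph[1]], bad_ph[1]),
                 "biokin_schema_error")
  bad_pt <- which(!(df$point_id %in% 1:3))
  if (length(bad_pt))
    abort_biokin(sprintf("point_id outside {1,2,3} at data row %d",
                         bad_pt[1]), "biokin_schema_error")
  invisible(df)
}

infer_section <- function(levels) {
  if (any(levels %in% section_levels("cervical"))) return("cervical")
  if (any(levels %in% section_levels("lumbar"))) return("lumbar")
  abort_biokin("cannot infer spine section from level labels",
               "biokin_schema_error")
}

#' Write an exam bundle's landmark table
#' @param bundle an `exam_bundle`.
#' @param path output file.
#' @export
write_landmark_table <- function(bundle, path) {
  utils::write.csv(bundle$landmarks[landmark_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a calibration record (JSON)
#' @param path file path.
#' @return a `calibration_record`.
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("ball_true_diameter_mm", "ball_image_diameter_px") %in% names(j)))
    abort_biokin("calibration JSON must carry ball_true_diameter_mm and ball_image_diameter_px",
                 "biokin_invalid_calibration")
  calibrate_scale(j$ball_true_diameter_mm, j$ball_image_diameter_px)
}

#' @rdname read_calibration
#' @param calibration a `calibration_record`.
#' @export
write_calibration <- function(calibration, path) {
  jsonlite::write_json(list(
    ball_true_diameter_mm = calibration$ball_true_diameter_mm,
    ball_image_diameter_px = calibration$ball_image_diameter_px), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export motion curves as CSV (`level,fraction,area_mm2,source`)
#' @param curves list of [motion_curve].
#' @param path output file.
#' @export
write_curves <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(level = cv$level, fraction = cv$fraction,
               area_mm2 = cv$area, source = cv$source)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read motion curves from a CSV written by [write_curves]
#' @param path file path.
#' @return named list of [motion_curve].
#' @export
read_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("level", "fraction", "area_mm2", "source")
  if (!all(need %in% names(df)))
    abort_biokin("curve CSV missing required columns", "biokin_schema_error")
  out <- lapply(split(df, df$level), function(d)
    motion_curve(d$level[1], d$fraction, d$area_mm2, d$source[1]))
  out
}

#' Read / write a device specification (JSON)
#' @param path file path.
#' @return a [device_spec].
#' @export
read_device <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("name", "kind", "mobility_factor", "available_heights_mm")
  if (!all(need %in% names(j)))
    abort_biokin("device JSON must carry name, kind, mobility_factor, available_heights_mm",
                 "biokin_invalid_device")
  device_spec(j$name, j$kind, j$mobility_factor, j$available_heights_mm)
}

#' @rdname read_device
#' @param device a [device_spec].
#' @export
write_device <- function(device, path) {
  jsonlite::write_json(list(name = device$name, kind = device$kind,
                            mobility_factor = device$mobility_factor,
                            available_heights_mm = device$available_heights),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a reference surrogate (JSON)
#' @param path file path.
#' @return a [reference_surrogate].
#' @export
read_reference_surrogate <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- if (is.list(j$curves)) do.call(rbind, j$curves) else as.matrix(j$curves)
  rownames(m) <- j$levels
  reference_surrogate(j$section, j$fraction, m,
                      stats::setNames(unlist(j$heights_mm), j$levels),
                      stats::setNames(unlist(j$size_ratios), j$levels))
}

#' @rdname read_reference_surrogate
#' @param reference a [reference_surrogate].
#' @export
write_reference_surrogate <- function(reference, path) {
  jsonlite::write_json(list(
    section = reference$section, levels = reference$levels,
    fraction = reference$fraction,
    curves = lapply(seq_along(reference$levels),
                    function(i) unname(reference$curves[i, ])),
    heights_mm = as.list(reference$heights),
    size_ratios = as.list(reference$size_ratios)), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export spine signatures
#' (`subject_id,session_id,level,delta_s_mm2,s_max_mm2,ratio`)
#' @param signature a `spine_signature`.
#' @param subject_id,session_id identifiers for the exported rows.
#' @param path output file.
#' @export
write_signature <- function(signature, subject_id, session_id, path) {
  df <- data.frame(subject_id = subject_id, session_id = session_id,
                   level = signature$level,
                   delta_s_mm2 = signature$delta_s,
                   s_max_mm2 = signature$s_max, ratio = signature$ratio)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an outcome table (`subject_id,score_name,pre,post`)
#' @param path file path.
#' @return data.frame with a `delta` (post - pre) column added.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "score_name", "pre", "post")
  if (!all(need %in% names(df)))
    abort_biokin("outcome table must carry subject_id,score_name,pre,post",
                 "biokin_schema_error")
  df$delta <- df$post - df$pre
  df
}

#' @rdname read_outcomes
#' @param outcomes outcome data.frame.
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.csv(outcomes[c("subject_id", "score_name", "pre", "post")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON analysis / plan / reproducibility report
#'
#' Every report echoes the tool version and the seed so any run is
#' replayable.
#'
#' @param x a list-like result (coerced with unclass recursively).
#' @param path output file.
#' @param seed seed echoed into the report.
#' @param config optional configuration echo.
#' @export
write_report <- function(x, path, seed = NA, config = NULL) {
  strip <- function(v) {
    if (is.list(v)) lapply(unclass(v), strip) else v
  }
  payload <- list(tool = "biokin",
                  version = as.character(utils::packageVersion("biokin")),
                  seed = seed, config = strip(config), result = strip(x))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
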