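# Internal helpers shared across modules.

#' Signal a classed biokin error
#'
#' @param msg message text.
#' @param class condition subclass, e.g. "biokin_invalid_calibration".
#' @noRd
abort_biokin <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "biokin_error")))
}

#' Warn with a biokin condition subclass
#' @noRd
warn_biokin <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "biokin_warning")))
}

#' Evaluate an expression under a local RNG seed
#'
#' Restores (or removes) the caller's .Random.seed afterwards so that seeded
#' internals never disturb an outer simulation stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Wrap an angle in degrees to (-180, 180]
#' @noRd
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

#' Signed angle (degrees) of a 2-D direction vector
#' @noRd
vector_angle <- function(v) {
  if (all(v == 0)) abort_biokin("direction vector must be nonzero",
                                "biokin_invalid_direction")
  atan2(v[2], v[1]) * 180 / pi
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Canonical level labels of a spine section, cranial to caudal
#'
#' @param section "cervical" (C2-C3 ... C6-C7) or "lumbar" (L1-L2 ... L5-S1).
#' @return character vector of segment labels, most cranial first.
#' @export
#' @examples
#' section_levels("cervical")
section_levels <- function(section = c("cervical", "lumbar")) {
  section <- match.arg(section)
  if (section == "cervical") {
    v <- paste0("C", 2:7)
  } else {
    v <- c(paste0("L", 1:5), "S1")
  }
  paste(v[-length(v)], v[-1], sep = "-")
}

#' Most cranial vertebral plate label of a section
#'
#' The auxiliary endplate row (points 1-2 only) written by the generator for
#' the uppermost vertebra; used as the cranial reference of the whole-section
#' inclination angle and as the upper plate of the topmost segment.
#' @noRd
section_top_plate <- function(section = c("cervical", "lumbar")) {
  section <- match.arg(section)
  if (section == "cervical") "C2" else "L1"
}
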