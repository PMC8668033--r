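# Segment signatures (delta-S / S_max), spine number series, reproducibility
# pattern recognition via a Gaussian plug-in Bayes error rate, and worst/best
# segment detection against a reference surrogate of healthy motion geometry.

#' Segment signature: the area range over the motion relative to its maximum
#'
#' Each segment is condensed to the single number delta-S / S_max, the change
#' of the triangle's area over the movement divided by its maximum area.
#' The ratio is dimensionless and invariant to uniform rescaling of the
#' exam's coordinates.
#'
#' @param curve a [motion_curve].
#' @return object of class `segment_signature` with fields `level`,
#'   `delta_s`, `s_max`, `ratio` and a `zero_smax` flag.
#' @export
segment_signature <- function(curve) {
  if (!inherits(curve, "motion_curve")) abort_biokin("a motion_curve is required",
                                                     "biokin_empty_curve")
  ds <- curve$s_max - curve$s_min
  zero <- curve$s_max <= 0
  structure(list(level = curve$level, delta_s = ds, s_max = curve$s_max,
                 ratio = if (zero) 0 else ds / curve$s_max,
                 zero_smax = zero),
            class = "segment_signature")
}

#' Spine signature: the ordered number series of a spine section
#'
#' @param curves named list of [motion_curve] (names or `$level` give the
#'   segment labels), covering every level of the section.
#' @param section "cervical" or "lumbar".
#' @return object of class `spine_signature`: a data.frame with columns
#'   `level`, `delta_s`, `s_max`, `ratio`, ordered cranial -> caudal.
#' @export
spine_signature <- function(curves, section = c("cervical", "lumbar")) {
  section <- match.arg(section)
  lv <- vapply(curves, function(cv) cv$level, character(1))
  if (anyDuplicated(lv))
    abort_biokin("duplicate level in signature input", "biokin_duplicate_level")
  want <- section_levels(section)
  if (!all(want %in% lv))
    abort_biokin(paste("missing level(s):",
                       paste(setdiff(want, lv), collapse = ", ")),
                 "biokin_incomplete_section")
  curves <- curves[match(want, lv)]
  sig <- lapply(curves, segment_signature)
  df <- data.frame(level = want,
                   delta_s = vapply(sig, `[[`, numeric(1), "delta_s"),
                   s_max = vapply(sig, `[[`, numeric(1), "s_max"),
                   ratio = vapply(sig, `[[`, numeric(1), "ratio"),
                   row.names = NULL)
  structure(df, section = section, class = c("spine_signature", "data.frame"))
}

#' @export
print.spine_signature <- function(x, ...) {
  cat(sprintf("Spine signature (%s): series %s\n", attr(x, "section"),
              paste(sprintf("%.3f", x$ratio), collapse = " ")))
  NextMethod()
}

#' Euclidean distance between two spine signatures
#'
#' The number series of two exams are compared on the data level as the
#' Euclidean distance between their ratio vectors.
#'
#' @param a,b `spine_signature` objects over the same section and levels.
#' @return nonnegative scalar; 0 iff the series are identical.
#' @export
signature_distance <- function(a, b) {
  if (!identical(attr(a, "section"), attr(b, "section")) ||
      !identical(a$level, b$level))
    abort_biokin("signatures cover different sections or levels",
                 "biokin_incompatible_signature")
  sqrt(sum((a$ratio - b$ratio)^2))
}

#' Bayes error of a multi-class Gaussian problem by Monte Carlo
#'
#' Equiprobable classes with Gaussian class-conditional densities sharing a
#' diagonal covariance: draws are classified by the Bayes decision rule
#' (maximum density, i.e. minimum Mahalanobis distance) and the error rate
#' estimated.  The two-class equal-variance case has the closed form
#' Phi(-gap / (2 sigma)) against which the estimator can be checked.
#'
#' @param means numeric matrix, one row per class.
#' @param sd positive vector of per-dimension standard deviations (recycled).
#' @param n_draws Monte-Carlo sample size.
#' @param seed optional integer seed (local to this call).
#' @return list with `error`, `se` (binomial Monte-Carlo standard error) and
#'   `n_draws`.
#' @export
#' @examples
#' gaussian_bayes_error(matrix(c(0, 2), 2, 1), 1, 1e4, seed = 1)$error
gaussian_bayes_error <- function(means, sd, n_draws = 1e5, seed = NULL) {
  means <- as.matrix(means)
  k <- nrow(means); d <- ncol(means)
  if (k < 2) abort_biokin("at least two classes required", "biokin_insufficient_cohort")
  sd <- rep_len(sd, d)
  if (any(sd <= 0)) abort_biokin("sd must be positive", "biokin_invalid_covariance")
  with_seed(seed, {
    cls <- sample.int(k, n_draws, replace = TRUE)
    z <- matrix(stats::rnorm(n_draws * d), n_draws, d)
    x <- means[cls, , drop = FALSE] + sweep(z, 2, sd, `*`)
    # squared Mahalanobis distance to every class mean
    xs <- sweep(x, 2, sd, `/`)
    ms <- sweep(means, 2, sd, `/`)
    d2 <- outer(rowSums(xs^2), rowSums(ms^2), `+`) - 2 * xs %*% t(ms)
    pred <- max.col(-d2, ties.method = "first")
    err <- mean(pred != cls)
    list(error = err, se = sqrt(err * (1 - err) / n_draws), n_draws = n_draws)
  })
}

#' Reproducibility of the number series as a pattern-recognition problem
#'
#' Functional images are taken twice per subject; if the spine's number
#' series is an individual fingerprint, a classifier assigning series to
#' subjects should make few errors.  Per-subject Gaussian class-conditional
#' densities are fitted on the ratio vectors (class means = per-subject
#' session means; shared diagonal covariance estimated from within-subject
#' session differences), and the Bayes error of the equiprobable multi-class
#' problem is estimated by Monte Carlo.  A leave-one-session-out 1-nearest-
#' neighbour error is reported alongside as a distribution-free check.
#'
#' @param signatures list over subjects, each a list of exactly two
#'   `spine_signature` objects (the repeated sessions).
#' @param n_draws Monte-Carlo draws for the Bayes error.
#' @param seed optional integer seed.
#' @param ridge_fraction floor for near-zero within-subject variances, as a
#'   fraction of the largest variance (or of 1e-12 when all are zero);
#'   applied with a message.
#' @return object of class `reproducibility_report`: list with
#'   `bayes_error`, `bayes_se`, `nn_error`, `n_subjects`, `n_sessions`,
#'   `within_sd`, `ridged`.
#' @export
bayes_error_rate <- function(signatures, n_draws = 1e5, seed = NULL,
                             ridge_fraction = 1e-6) {
  n <- length(signatures)
  if (n < 2) abort_biokin("at least two subjects required",
                          "biokin_insufficient_cohort")
  bad <- vapply(signatures, function(s) length(s) != 2L, logical(1))
  if (any(bad)) abort_biokin("exactly two sessions per subject required",
                             "biokin_insufficient_cohort")
  x1 <- t(vapply(signatures, function(s) s[[1]]$ratio,
                 numeric(nrow(signatures[[1]][[1]]))))
  x2 <- t(vapply(signatures, function(s) s[[2]]$ratio,
                 numeric(nrow(signatures[[1]][[1]]))))
  d <- ncol(x1)
  means <- (x1 + x2) / 2
  v <- colMeans((x1 - x2)^2) / 2           # within-subject session variance
  ridged <- FALSE
  floor_v <- ridge_fraction * max(v, 1e-12)
  if (any(v < floor_v)) {
    v <- pmax(v, floor_v)
    ridged <- TRUE
    message("bayes_error_rate: near-singular within-subject covariance regularized")
  }
  be <- gaussian_bayes_error(means, sqrt(v), n_draws = n_draws, seed = seed)
  # leave-one-session-out 1-NN over all 2n session vectors
  xx <- rbind(x1, x2)
  subj <- rep(seq_len(n), 2L)
  dm <- as.matrix(stats::dist(xx))
  diag(dm) <- Inf
  nn <- apply(dm, 1, which.min)
  nn_error <- mean(subj[nn] != subj)
  structure(list(bayes_error = be$error, bayes_se = be$se,
                 nn_error = nn_error, n_subjects = n, n_sessions = 2L,
                 within_sd = sqrt(v), ridged = ridged),
            class = "reproducibility_report")
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat(sprintf(
    "Reproducibility: %d subjects x %d sessions; Bayes error %.4f (MC se %.4f), 1-NN error %.4f%s\n",
    x$n_subjects, x$n_sessions, x$bayes_error, x$bayes_se, x$nn_error,
    if (x$ridged) " [covariance ridged]" else ""))
  invisible(x)
}

#' Construct a reference surrogate of healthy segmental motion geometry
#'
#' Stores, per level of a section: the normalized healthy RoM curve
#' (S / S_max on a 0..100 fraction grid), the neutral intersegmental disc
#' height (mm), and the level size ratio (distal discs are larger than
#' proximal ones, so ratios are nondecreasing cranial -> caudal).
#'
#' @param section "cervical" or "lumbar".
#' @param fraction common fraction grid in \[0, 100\].
#' @param curves matrix (levels x fractions) of normalized areas, max 1.
#' @param heights named neutral disc heights (mm) per level.
#' @param size_ratios named dimensionless level size ratios, nondecreasing
#'   cranial -> caudal.
#' @return object of class `reference_surrogate`.
#' @export
reference_surrogate <- function(section, fraction, curves, heights,
                                size_ratios) {
  section <- match.arg(section, c("cervical", "lumbar"))
  levels <- section_levels(section)
  curves <- as.matrix(curves)
  if (!identical(rownames(curves), levels))
    abort_biokin("curve rows must be the section levels, cranial -> caudal",
                 "biokin_reference_gap")
  if (!all(levels %in% names(heights)) || !all(levels %in% names(size_ratios)))
    abort_biokin("heights and size_ratios must cover every level",
                 "biokin_reference_gap")
  if (any(heights[levels] <= 0))
    abort_biokin("reference heights must be positive", "biokin_invalid_height")
  if (any(diff(size_ratios[levels]) < 0))
    abort_biokin("size ratios must be nondecreasing cranial -> caudal",
                 "biokin_reference_gap")
  structure(list(section = section, levels = levels,
                 fraction = as.numeric(fraction), curves = curves,
                 heights = heights[levels], size_ratios = size_ratios[levels]),
            class = "reference_surrogate")
}

#' @export
print.reference_surrogate <- function(x, ...) {
  cat(sprintf("Reference surrogate (%s): %d levels, %d fraction points\n",
              x$section, length(x$levels), length(x$fraction)))
  invisible(x)
}

#' Normalized RMS deviation of patient curves from the reference
#'
#' Each patient curve is resampled onto the reference fraction grid and
#' projected onto the reference shape by least squares (area ~ a + b * ref);
#' the deviation is the RMS difference between the normalized fitted shape
#' and the reference curve, plus any residual shape excess beyond the
#' reference curve.  Normalizing through the fitted scale rather than the
#' pointwise maximum keeps the measure unbiased under dense noisy sampling;
#' it is invariant to uniform area rescaling of the patient exam.  The raw
#' fit residual (annotation noise plus any shape departure outside the
#' affine family) is not part of the score, since its magnitude differs
#' across levels with baseline length rather than with pathology.
#' @noRd
curve_deviations <- function(patient_curves, reference) {
  lv <- reference$levels
  have <- vapply(patient_curves, function(cv) cv$level, character(1))
  if (!all(lv %in% have))
    abort_biokin(paste("patient exam lacks level(s):",
                       paste(setdiff(lv, have), collapse = ", ")),
                 "biokin_reference_gap")
  patient_curves <- patient_curves[match(lv, have)]
  dev <- vapply(seq_along(lv), function(i) {
    cv <- patient_curves[[i]]
    rg <- reference$curves[i, ] / max(reference$curves[i, ])
    # reference shape evaluated at the measured fractions: the raw areas are
    # regressed on it directly, never interpolating through noisy points
    r <- stats::approx(reference$fraction, rg, xout = cv$fraction, rule = 2)$y
    if (cv$s_max <= 0) return(Inf)
    if (stats::sd(r) == 0)
      return(sqrt(mean((cv$area / cv$s_max - r)^2)))
    fit <- stats::lm.fit(cbind(1, r), cv$area)
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
    s_fit <- a + b                      # fitted area at the reference max
    if (!is.finite(s_fit) || s_fit <= 0 || b <= 0) {
      # degenerate fit: fall back to raw self-normalized comparison
      return(sqrt(mean((cv$area / cv$s_max - r)^2)))
    }
    sqrt(mean(((a + b * rg) / s_fit - rg)^2))
  }, numeric(1))
  names(dev) <- lv
  dev
}

#' Detect the worst (most pathologically altered) segment
#'
#' The worst segment is the one whose movement geometry deviates most from
#' the healthy geometry stored in the reference surrogate: the root-mean-
#' square difference between the patient's and the reference's self-
#' normalized RoM curves on a common fraction grid.  Ties are broken toward
#' the more caudal level (degeneration prevails caudally) with a tie flag.
#'
#' @param patient_curves list of [motion_curve], one per level.
#' @param reference a [reference_surrogate].
#' @return list with `level`, `scores` (named deviations, cranial -> caudal),
#'   `tie` flag.
#' @export
detect_worst_segment <- function(patient_curves, reference) {
  dev <- curve_deviations(patient_curves, reference)
  mx <- max(dev)
  at <- which(dev >= mx - 1e-12)   # float-tolerant tie detection
  list(level = reference$levels[at[length(at)]], scores = dev,
       tie = length(at) > 1L)
}

#' Detect the best (most preserved) segment
#'
#' The best segment has maintained the greatest intersegmental distance and
#' is most closely oriented to the healthy movement geometry:
#' score = w_h * (patient height / reference height) - w_c * curve deviation,
#' maximized over non-excluded levels.
#'
#' @param patient_curves list of [motion_curve], one per level.
#' @param patient_heights named neutral intersegmental heights (mm) per level,
#'   e.g. from [estimate_disc_heights].
#' @param reference a [reference_surrogate].
#' @param weights numeric `c(w_h, w_c)`, nonnegative, summing to 1.
#' @param exclude levels to skip (e.g. the implanted or worst level).
#' @return list with `level`, `scores` (named), `excluded`.
#' @export
detect_best_segment <- function(patient_curves, patient_heights, reference,
                                weights = c(0.5, 0.5), exclude = character()) {
  if (length(weights) != 2 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    abort_biokin("weights must be two nonnegative numbers summing to 1",
                 "biokin_invalid_weights")
  dev <- curve_deviations(patient_curves, reference)
  lv <- reference$levels
  if (!all(lv %in% names(patient_heights)))
    abort_biokin("patient_heights must cover every level", "biokin_reference_gap")
  hr <- patient_heights[lv] / reference$heights
  score <- weights[1] * hr - weights[2] * dev
  keep <- setdiff(lv, exclude)
  if (length(keep) == 0)
    abort_biokin("all levels excluded: no best-segment candidate",
                 "biokin_no_candidate")
  best <- keep[which.max(score[keep])]
  list(level = best, scores = score, excluded = exclude)
}
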