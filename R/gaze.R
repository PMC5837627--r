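# Behavioural labelling and descriptive statistics of gaze.
#
# Sign convention used throughout the package: gaze angles are in degrees,
# negative = leftward deviation, positive = rightward, 0 = midline, wrapped
# to (-180, 180].

#' Eligibility and recovery labels from gaze angles
#'
#' A patient is \emph{eligible} (abnormal gaze) when the first-time-point
#' gaze shows a leftward deviation of more than 12 degrees, i.e.
#' \code{gaze_t1 < -12} (strict: exactly -12 is not eligible).
#' \emph{Recovery} is a second-time-point deviation within 3 degrees of the
#' midline, i.e. \code{abs(gaze_t2) <= 3} (inclusive). Recovery is undefined
#' (\code{NA}) for non-eligible patients.
#'
#' @param gaze_t1_deg,gaze_t2_deg numeric vectors of gaze angles in degrees,
#'   in (-180, 180].
#' @return A data frame with logical columns \code{eligible} and
#'   \code{recovered} (\code{NA} where not eligible).
#' @export
classify_gaze <- function(gaze_t1_deg, gaze_t2_deg) {
  stopifnot(length(gaze_t1_deg) == length(gaze_t2_deg))
  eligible <- gaze_t1_deg < -12
  recovered <- ifelse(eligible, abs(gaze_t2_deg) <= 3, NA)
  data.frame(eligible = eligible, recovered = as.logical(recovered))
}

#' Circular mean of angles in degrees
#'
#' The direction of the resultant of unit vectors at each angle — the
#' appropriate average for angular data such as gaze. Returns a value in
#' (-180, 180]. When the resultant has (numerically) zero length the mean
#' direction is undefined and \code{NA_real_} is returned with a warning.
#'
#' @param angles_deg nonempty numeric vector of angles in degrees.
#' @return Mean direction in degrees, or \code{NA_real_}.
#' @export
circular_mean <- function(angles_deg) {
  if (length(angles_deg) == 0L) stop_therinf("circular_mean: empty input")
  rad <- angles_deg * pi / 180
  s <- mean(sin(rad)); c <- mean(cos(rad))
  if (sqrt(s^2 + c^2) < 1e-12) {
    warning("circular_mean: resultant length ~0, mean direction undefined",
            call. = FALSE)
    return(NA_real_)
  }
  wrap_angle(atan2(s, c) * 180 / pi)
}

#' Gaze-laterality curve
#'
#' Relates the admission direction of gaze to the laterality of damage:
#' patients are binned into \code{n_bins} equal-width bins over the observed
#' gaze range and the mean right-hemisphere damage ratio is reported per
#' bin. A linear model of the per-patient ratio on gaze angle (Gaussian
#' maximum likelihood, identity link) summarises the dependence; the fit is
#' to per-patient data, the bins are display-level summaries. Patients with
#' empty lesions are excluded (with a message).
#'
#' @param cohort a \code{cohort} (see \code{\link{generate_cohort}}).
#' @param n_bins number of gaze bins (default 7).
#' @return An object of class \code{gaze_laterality_curve}: a list with
#'   \code{bins} (data frame: bin midpoint, mean ratio, n; empty bins have
#'   \code{NA} mean), \code{slope}, \code{intercept}, \code{slope_z} (slope
#'   divided by its standard error) and \code{n_used}.
#' @export
gaze_laterality_curve <- function(cohort, n_bins = 7L) {
  stopifnot(inherits(cohort, "cohort"))
  ratio <- vapply(cohort$lesions, function(m) {
    if (sum(m$voxels) == 0L) NA_real_ else suppressWarnings(laterality_ratio(m))
  }, numeric(1))
  gaze <- cohort$covariates$gaze_t1_deg
  keep <- !is.na(ratio)
  if (sum(!keep) > 0L)
    message(sprintf("gaze_laterality_curve: excluded %d patient(s) with empty lesions",
                    sum(!keep)))
  ratio <- ratio[keep]; gaze <- gaze[keep]
  if (length(gaze) < 2L) stop_therinf("need at least 2 patients with lesions")

  rng <- range(gaze)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- cut(gaze, breaks = edges, include.lowest = TRUE, labels = FALSE)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  bins <- data.frame(
    bin = seq_len(n_bins),
    gaze_mid_deg = mids,
    mean_ratio = vapply(seq_len(n_bins), function(b) {
      if (any(bin == b)) mean(ratio[bin == b]) else NA_real_
    }, numeric(1)),
    n = vapply(seq_len(n_bins), function(b) sum(bin == b), numeric(1))
  )
  fit <- stats::lm(ratio ~ gaze)
  sm <- suppressWarnings(summary(fit))$coefficients # degenerate perfect fits
  structure(list(
    bins = bins,
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    slope_z = unname(sm["gaze", "Estimate"] / sm["gaze", "Std. Error"]),
    n_used = length(gaze)
  ), class = "gaze_laterality_curve")
}

#' @export
print.gaze_laterality_curve <- function(x, ...) {
  cat(sprintf("gaze-laterality curve (n = %d): slope %.4f per degree (z = %.2f)\n",
              x$n_used, x$slope, x$slope_z))
  print(x$bins, row.names = FALSE)
  invisible(x)
}
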