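# The therapeutic function: a monotone continuous fit to the per-effect-size
# detection probabilities, its 0.5 crossing (the therapeutic threshold: the
# minimum effect size at which half of simulated trials are positive, i.e.
# where a meta-analysis would only just identify the intervention as
# successful), and bootstrap confidence intervals for the threshold.

#' Monotone I-spline basis
#'
#' Evaluates an I-spline (integrated spline) basis on [0, 1]: each basis
#' function is non-decreasing, 0 at 0 and 1 at 1, so any non-negative
#' combination (plus a non-negative intercept) is non-decreasing. Built
#' from partial sums of a B-spline basis of order \code{degree + 1} with
#' the given interior knots.
#'
#' @param x evaluation points in [0, 1].
#' @param interior_knots knots strictly inside (0, 1).
#' @param degree polynomial degree of the underlying B-splines (default 3).
#' @return Matrix with one column per basis function.
#' @export
ispline_basis <- function(x, interior_knots = numeric(0), degree = 3L) {
  ord <- degree + 1L
  interior_knots <- sort(interior_knots[interior_knots > 0 & interior_knots < 1])
  knots <- c(rep(0, ord), interior_knots, rep(1, ord))
  B <- splines::splineDesign(knots, pmin(pmax(x, 0), 1), ord = ord,
                             outer.ok = TRUE)
  nb <- ncol(B)
  # I_j(x) = sum_{m >= j} B_m(x); drop j = 1 (constant 1)
  I <- t(apply(B, 1L, function(r) rev(cumsum(rev(r)))))
  if (length(x) == 1L) I <- matrix(I, nrow = 1L)
  I[, -1L, drop = FALSE]
}

# Weighted non-negative least squares via pracma::lsqnonneg. The basis has
# more columns than there are effect sizes, so a tiny Tikhonov augmentation
# keeps the active-set solves full rank without materially biasing the fit.
nnls_weighted <- function(A, y, w, ridge = 1e-6) {
  sw <- sqrt(w)
  Aa <- rbind(A * sw, diag(sqrt(ridge), ncol(A)))
  ya <- c(y * sw, rep(0, ncol(A)))
  pracma::lsqnonneg(Aa, ya)$x
}

#' Fit the therapeutic function
#'
#' Fits a monotone shape-constrained spline (I-spline basis with
#' non-negative coefficients and non-negative intercept, interior knots at
#' the observed effect sizes) to the mean detection probabilities, with
#' iteratively reweighted Huber loss for robustness to outlying points.
#' Fitted values are clipped to [0, 1]. The therapeutic threshold (smallest
#' effect size where the fitted curve reaches 0.5) is estimated by
#' bisection; when the curve never attains 0.5 on [0, 1] it is reported as
#' not reached (\code{NA}).
#'
#' @param points data frame with columns \code{effect_size} and
#'   \code{detection_probability} (at least 3 distinct effect sizes), e.g.
#'   one model kind's rows of a \code{\link{run_trial_batch}} table.
#' @param weights optional per-point weights.
#' @param robust apply Huber reweighting (default \code{TRUE}).
#' @param huber_k Huber tuning constant in residual-MAD units.
#' @param degree I-spline degree.
#' @return Object of class \code{therapeutic_function}: \code{coef}
#'   (intercept first), \code{knots}, \code{degree}, \code{points},
#'   \code{threshold} (\code{NA} if not reached), \code{threshold_reached}.
#' @export
fit_therapeutic_function <- function(points, weights = NULL, robust = TRUE,
                                     huber_k = 1.345, degree = 3L) {
  x <- points$effect_size
  y <- points$detection_probability
  if (length(unique(x)) < 3L)
    stop_therinf("need at least 3 distinct effect sizes")
  if (any(x < 0 | x > 1)) stop_therinf("effect sizes must lie in [0, 1]")
  w0 <- weights %||% rep(1, length(x))

  knots <- unique(x[x > 0 & x < 1])
  A <- cbind(1, ispline_basis(x, knots, degree))
  cf <- nnls_weighted(A, y, w0)
  if (robust) {
    for (iter in seq_len(30L)) {
      r <- y - as.vector(A %*% cf)
      s <- stats::mad(r)
      if (s < 1e-8) break
      wh <- ifelse(abs(r) <= huber_k * s, 1, huber_k * s / abs(r))
      cf_new <- nnls_weighted(A, y, w0 * wh)
      if (max(abs(cf_new - cf)) < 1e-9) { cf <- cf_new; break }
      cf <- cf_new
    }
  }
  tf <- structure(list(coef = cf, knots = knots, degree = degree,
                       points = points, threshold = NA_real_,
                       threshold_reached = FALSE),
                  class = "therapeutic_function")
  thr <- estimate_threshold(tf)
  tf$threshold <- thr
  tf$threshold_reached <- !is.na(thr)
  tf
}

#' Evaluate a fitted therapeutic function
#'
#' @param object a \code{therapeutic_function}.
#' @param x effect sizes in [0, 1].
#' @param ... unused.
#' @return Fitted detection probabilities, clipped to [0, 1].
#' @export
predict.therapeutic_function <- function(object, x, ...) {
  A <- cbind(1, ispline_basis(x, object$knots, object$degree))
  pmin(pmax(as.vector(A %*% object$coef), 0), 1)
}

#' Estimate the therapeutic threshold
#'
#' The smallest effect size in [0, 1] at which the fitted monotone curve
#' reaches a detection probability of 0.5, found by bisection to the given
#' tolerance. Returns \code{NA_real_} when the curve never attains 0.5
#' ("not reached").
#'
#' @param tf a \code{therapeutic_function}.
#' @param level probability level defining the threshold (default 0.5).
#' @param tol bisection tolerance (default 1e-4).
#' @return Threshold effect size, or \code{NA_real_}.
#' @export
estimate_threshold <- function(tf, level = 0.5, tol = 1e-4) {
  f <- function(z) predict(tf, z)
  if (f(1) < level) return(NA_real_)
  if (f(0) >= level) return(0)
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) >= level) hi <- mid else lo <- mid
  }
  hi
}

#' Bootstrap confidence interval for the therapeutic threshold
#'
#' Resamples the per-iteration trial outcomes within each effect size
#' (case resampling of the 0/1 positives), refits the therapeutic function
#' to the resampled means and re-estimates the threshold; the percentile
#' interval over replicates is returned. When more than 10\% of replicates
#' do not reach 0.5 the interval is reported as censored.
#'
#' @param curves a \code{detection_curves} object from
#'   \code{\link{run_trial_batch}}, or a named list of logical vectors of
#'   per-iteration positives keyed by effect size.
#' @param model_kind which model's raw outcomes to use (when \code{curves}
#'   is a \code{detection_curves}).
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @param ... passed to \code{\link{fit_therapeutic_function}}.
#' @return List of class \code{threshold_ci}: \code{low}, \code{high},
#'   \code{censored}, \code{prop_not_reached}, \code{thresholds}
#'   (replicate values).
#' @export
bootstrap_threshold_ci <- function(curves, model_kind = "low_dim",
                                   n_boot = 1000L, seed = 1L, level = 0.95,
                                   ...) {
  if (inherits(curves, "detection_curves")) {
    m <- curves$raw[[model_kind]]
    if (is.null(m)) stop_therinf("no raw outcomes for model kind ", model_kind)
    effects <- curves$effect_sizes
    outcome_list <- lapply(seq_along(effects), function(e) m[, e])
  } else {
    effects <- as.numeric(names(curves))
    outcome_list <- curves
  }
  n_eff <- length(effects)
  thresholds <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      phat <- vapply(outcome_list, function(v)
        mean(v[sample.int(length(v), replace = TRUE)]), numeric(1))
      tf <- fit_therapeutic_function(
        data.frame(effect_size = effects, detection_probability = phat), ...)
      tf$threshold
    }, numeric(1))
  })
  prop_nr <- mean(is.na(thresholds))
  censored <- prop_nr > 0.10
  qs <- stats::quantile(thresholds, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(list(low = qs[1], high = if (censored) NA_real_ else qs[2],
                 censored = censored, prop_not_reached = prop_nr,
                 thresholds = thresholds),
            class = "threshold_ci")
}

#' @export
print.therapeutic_function <- function(x, ...) {
  thr <- if (x$threshold_reached) sprintf("%.4f", x$threshold) else "not reached"
  cat(sprintf("therapeutic function: %d points, threshold %s\n",
              nrow(x$points), thr))
  invisible(x)
}

#' @export
print.threshold_ci <- function(x, ...) {
  if (x$censored)
    cat(sprintf("threshold 95%% CI: [%.4f, censored] (%.0f%% of replicates did not reach 0.5)\n",
                x$low, 100 * x$prop_not_reached))
  else
    cat(sprintf("threshold 95%% CI: [%.4f, %.4f]\n", x$low, x$high))
  invisible(x)
}

#' Monotonicity check of a detection curve
#'
#' Tests whether detection probabilities are non-decreasing in effect size
#' up to Monte-Carlo error: the isotonic violation statistic (sum of
#' squared deviations from the best non-decreasing fit, by
#' \code{\link[stats]{isoreg}}) is compared with its permutation
#' distribution over random orderings of the same values. The curve passes
#' when the observed statistic is below the 5th percentile of the permuted
#' statistics, i.e. more monotone than 95\% of random orderings.
#'
#' @param detection_probability per-effect-size detection probabilities, in
#'   increasing effect-size order.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return List: \code{statistic}, \code{bound} (permutation 5th
#'   percentile), \code{monotone} (logical), \code{p_greater} (fraction of
#'   permutations with a statistic at or below the observed).
#' @export
monotonicity_check <- function(detection_probability, n_perm = 1000L, seed = 1L) {
  viol <- function(p) sum((p - stats::isoreg(p)$yf)^2)
  obs <- viol(detection_probability)
  perms <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      viol(sample(detection_probability)), numeric(1))
  })
  bound <- stats::quantile(perms, 0.05, names = FALSE)
  list(statistic = obs, bound = bound,
       monotone = obs <= bound || obs < 1e-12,
       p_greater = mean(perms <= obs))
}
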