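# Iterated randomized hypothetical trials.
#
# Each iteration randomizes the eligible (gaze-deviated) patients into
# intervention and control arms, applies the hypothetical intervention to
# the treated arm, and fits a linear probability model of recovery on
# [intervention, age, sex, lesion volume], optionally augmented with the
# high-dimensional covariate: the recovery classifier's score on the
# pre-intervention lesion. A trial is positive when the two-sided p-value
# of the intervention coefficient is below alpha (0.05). The fraction of
# positive trials per effect size estimates the detection probability; no
# multiplicity correction is applied across iterations, which stand for
# independent trials in a meta-analytic frame.

#' Randomize eligible patients into intervention and control arms
#'
#' Seeded permutation split: the first \code{round(allocation * n)}
#' (round-half-up) patients of the permutation form the treated arm; arms
#' are disjoint and exhaustive.
#'
#' @param ids patient ids (length >= 2).
#' @param allocation treated fraction (default 0.5).
#' @param seed integer seed.
#' @return List with \code{treated} and \code{control} id vectors.
#' @export
randomize_arms <- function(ids, allocation = 0.5, seed = 1L) {
  n <- length(ids)
  if (n < 2L) stop_therinf("need at least 2 eligible patients to randomize")
  perm <- withr::with_seed(seed, sample(ids))
  n_treat <- round_half_up(allocation * n)
  list(treated = perm[seq_len(n_treat)], control = perm[-seq_len(n_treat)])
}

# OLS with treated-coefficient inference; returns NULL checks via ok flag.
ols_treated_test <- function(X, y, treated_col = 2L) {
  n <- nrow(X); p <- ncol(X)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < p) {
    return(list(ok = FALSE, message = "rank-deficient design matrix",
                coefficient = NA_real_, p_value = NA_real_))
  }
  rss <- sum(fit$residuals^2)
  df <- n - p
  if (df <= 0) return(list(ok = FALSE, message = "no residual degrees of freedom",
                           coefficient = NA_real_, p_value = NA_real_))
  sigma2 <- rss / df
  Qr <- fit$qr
  cov_unscaled <- chol2inv(Qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(diag(cov_unscaled) * sigma2)[order(Qr$pivot)]
  beta <- fit$coefficients
  tstat <- beta[treated_col] / se[treated_col]
  list(ok = TRUE, message = NULL,
       coefficient = unname(beta[treated_col]),
       p_value = unname(2 * stats::pt(-abs(tstat), df)))
}

#' Fit one trial's outcome model
#'
#' Ordinary least-squares linear probability model of binary recovery on
#' intercept, intervention, age, sex and lesion volume; the high-dimensional
#' variant adds the classifier score as a covariate. The intervention effect
#' is tested with a two-sided t-test on its coefficient. A logistic link is
#' available by configuration but the linear probability model is the
#' default. Rank-deficient designs are reported as failed (non-positive)
#' fits, not errors.
#'
#' @param outcomes data frame with columns \code{recovered} (logical/0-1),
#'   \code{treated} (logical/0-1), \code{age}, \code{sex}, \code{volume},
#'   and \code{score} when \code{model_kind = "high_dim"}.
#' @param model_kind \code{"low_dim"} or \code{"high_dim"}.
#' @param family \code{"lpm"} (default, OLS) or \code{"logistic"}.
#' @param alpha significance level (default 0.05).
#' @return Object of class \code{trial_model_result}: \code{coefficient},
#'   \code{p_value}, \code{positive}, \code{model_kind}, \code{ok},
#'   \code{message}.
#' @export
fit_trial_model <- function(outcomes, model_kind = c("low_dim", "high_dim"),
                            family = c("lpm", "logistic"), alpha = 0.05) {
  model_kind <- match.arg(model_kind)
  family <- match.arg(family)
  need <- c("recovered", "treated", "age", "sex", "volume")
  if (model_kind == "high_dim") need <- c(need, "score")
  miss <- setdiff(need, names(outcomes))
  if (length(miss)) stop_therinf("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(outcomes[need])) stop_therinf("missing values in model columns")

  y <- as.numeric(outcomes$recovered)
  X <- cbind(intercept = 1, treated = as.numeric(outcomes$treated),
             age = outcomes$age, sex = outcomes$sex, volume = outcomes$volume)
  if (model_kind == "high_dim") X <- cbind(X, score = outcomes$score)

  if (family == "lpm") {
    res <- ols_treated_test(X, y)
  } else {
    res <- tryCatch({
      fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
      if (fit$rank < ncol(X)) {
        list(ok = FALSE, message = "rank-deficient design matrix",
             coefficient = NA_real_, p_value = NA_real_)
      } else {
        sm <- summary(stats::glm(y ~ X - 1, family = stats::binomial()))$coefficients
        z <- sm[2, "z value"]
        list(ok = TRUE, message = NULL, coefficient = sm[2, "Estimate"],
             p_value = 2 * stats::pnorm(-abs(z)))
      }
    }, error = function(e) list(ok = FALSE, message = conditionMessage(e),
                                coefficient = NA_real_, p_value = NA_real_))
  }
  structure(list(coefficient = res$coefficient, p_value = res$p_value,
                 positive = isTRUE(res$ok) && !is.na(res$p_value) && res$p_value < alpha,
                 model_kind = model_kind, ok = res$ok, message = res$message),
            class = "trial_model_result")
}

#' Run an iterated-trial batch over a grid of effect sizes
#'
#' For each effect size, runs \code{n_iterations} randomized hypothetical
#' trials on the eligible patients outside the classifier training pool,
#' fitting the low- and/or high-dimensional outcome model on identical data
#' within each iteration (paired design: the only difference is the score
#' column). Per-iteration seeds are derived deterministically from
#' \code{master_seed} and the (effect size, iteration) indices, so any cell
#' is re-runnable in isolation.
#'
#' The recovery classifier is trained once on a held-out pool of eligible
#' patients (fraction \code{classifier_pool_fraction}, seeded split) and
#' never sees the trial pool or the randomization; this independence is
#' asserted before any trial runs.
#'
#' @param cohort a \code{cohort}.
#' @param kind \code{"non_altering"} or \code{"lesion_altering"}.
#' @param effect_sizes responder proportions or volume reductions
#'   (default 0.1 to 0.9 by 0.1; 0 is allowed for null calibration).
#' @param n_iterations randomizations per effect size (default 600).
#' @param model_kinds subset of \code{c("low_dim", "high_dim")}.
#' @param classifier optional pre-trained \code{recovery_classifier}; when
#'   \code{NULL} one is trained internally on the held-out pool.
#' @param trial_ids optional explicit trial pool (must be eligible and
#'   disjoint from the classifier's training ids).
#' @param classifier_pool_fraction fraction of eligible patients reserved
#'   for classifier training.
#' @param classifier_mode,cost passed to
#'   \code{\link{train_recovery_classifier}} (\code{cost = NULL}: nested-CV
#'   selection on the training pool).
#' @param control_rule control-arm outcome rule for lesion-altering
#'   interventions (see \code{\link{apply_lesion_altering}}).
#' @param hd_covariate form of the high-dimensional covariate: the
#'   classifier's predicted recovery label (\code{"label"}, default — the
#'   prediction of whether the patient would recover regardless of
#'   treatment) or the continuous decision score (\code{"score"}).
#' @param allocation treated-arm fraction.
#' @param alpha significance level for a positive trial.
#' @param family outcome model family (\code{"lpm"} default).
#' @param master_seed master integer seed.
#' @param max_failure_rate abort threshold for failed iterations per point.
#' @return Object of class \code{detection_curves}: \code{table} (one row
#'   per effect size x model kind: positives, detection probability, exact
#'   binomial 95\% CI), \code{raw} (list by model kind of logical
#'   iteration-by-effect matrices), the classifier, trial pool ids and call
#'   parameters.
#' @export
run_trial_batch <- function(cohort, kind = c("non_altering", "lesion_altering"),
                            effect_sizes = seq(0.1, 0.9, by = 0.1),
                            n_iterations = 600L,
                            model_kinds = c("low_dim", "high_dim"),
                            classifier = NULL, trial_ids = NULL,
                            classifier_pool_fraction = 0.5,
                            classifier_mode = "inductive", cost = NULL,
                            control_rule = "classifier_on_original",
                            hd_covariate = c("label", "score"),
                            allocation = 0.5, alpha = 0.05, family = "lpm",
                            master_seed = 1L, max_failure_rate = 0.05) {
  hd_covariate <- match.arg(hd_covariate)
  kind <- match.arg(kind)
  model_kinds <- match.arg(model_kinds, several.ok = TRUE)
  cv <- cohort$covariates
  eligible <- cv$id[cv$eligible]
  if (length(eligible) < 4L) stop_therinf("too few eligible patients")

  if (is.null(classifier)) {
    n_pool <- round_half_up(classifier_pool_fraction * length(eligible))
    pool <- withr::with_seed(mix_seed(master_seed, 10L),
                             sample(eligible, n_pool))
    x_pool <- lesion_matrix(cohort, pool)
    y_pool <- cv$recovered[match(pool, cv$id)]
    classifier <- train_recovery_classifier(x_pool, y_pool, mode = classifier_mode,
                                            cost = cost,
                                            seed = mix_seed(master_seed, 11L))
  }
  if (is.null(trial_ids)) {
    trial_ids <- setdiff(eligible, classifier$training_ids)
  } else {
    if (!all(trial_ids %in% eligible))
      stop_therinf("trial_ids must be eligible patients")
  }
  overlap <- intersect(trial_ids, classifier$training_ids)
  if (length(overlap) > 0L)
    stop_therinf("independence contract violated: classifier training pool ",
                 "overlaps the trial pool (", length(overlap), " patient(s))")
  n_trial <- length(trial_ids)
  if (n_trial < 4L) stop_therinf("too few trial-pool patients")

  row <- match(trial_ids, cv$id)
  age <- cv$age_years[row]; sex <- cv$sex[row]
  natural <- cv$recovered[row]
  volume <- vapply(cohort$lesions[trial_ids],
                   function(m) sum(m$voxels), numeric(1))
  x_trial <- lesion_matrix(cohort, trial_ids)
  score <- as.vector(x_trial %*% classifier$weights) + classifier$bias
  if (hd_covariate == "label") score <- as.numeric(score > 0)
  cache <- if (kind == "lesion_altering") erosion_cache(cohort, classifier, trial_ids) else NULL

  # per-cell seeds: one master-seeded draw of independent 31-bit seeds, so
  # iterations behave as independent replicates and any (level, iteration)
  # cell is re-runnable in isolation by regenerating the table
  seed_table <- withr::with_seed(master_seed,
    matrix(sample.int(2147483646L, length(effect_sizes) * n_iterations,
                      replace = TRUE),
           nrow = n_iterations, ncol = length(effect_sizes)))

  raw <- lapply(stats::setNames(model_kinds, model_kinds),
                function(mk) matrix(NA, nrow = n_iterations, ncol = length(effect_sizes)))
  failures <- matrix(0L, nrow = length(effect_sizes), ncol = length(model_kinds),
                     dimnames = list(NULL, model_kinds))

  for (e in seq_along(effect_sizes)) {
    eff <- effect_sizes[e]
    for (it in seq_len(n_iterations)) {
      seed_it <- seed_table[it, e]
      arms <- randomize_arms(trial_ids, allocation, seed = seed_it)
      treated_flag <- trial_ids %in% arms$treated
      if (kind == "non_altering") {
        out <- natural
        out[treated_flag] <- apply_non_altering(natural[treated_flag], eff,
                                                seed = mix_seed(seed_it, 1L))
      } else {
        tab <- apply_lesion_altering(cohort, arms$treated, arms$control, eff,
                                     classifier, rule = control_rule,
                                     seed = seed_it, cache = cache)
        out <- tab$outcome_recovered[match(trial_ids, tab$patient_id)]
      }
      df <- data.frame(recovered = out, treated = treated_flag, age = age,
                       sex = sex, volume = volume, score = score)
      for (mk in model_kinds) {
        res <- tryCatch(fit_trial_model(df, mk, family = family, alpha = alpha),
                        error = function(err) list(positive = FALSE, ok = FALSE,
                                                   message = conditionMessage(err)))
        raw[[mk]][it, e] <- res$positive
        if (!isTRUE(res$ok)) failures[e, mk] <- failures[e, mk] + 1L
      }
    }
    for (mk in model_kinds) {
      if (failures[e, mk] > max_failure_rate * n_iterations)
        stop_therinf(sprintf("effect size %.2f, %s: %d of %d iterations failed",
                             eff, mk, failures[e, mk], n_iterations))
    }
  }

  tab <- do.call(rbind, lapply(model_kinds, function(mk) {
    pos <- colSums(raw[[mk]])
    ci <- t(vapply(pos, function(k)
      stats::binom.test(k, n_iterations)$conf.int, numeric(2)))
    data.frame(kind = kind, model_kind = mk, effect_size = effect_sizes,
               n_iterations = n_iterations, positives = as.integer(pos),
               detection_probability = pos / n_iterations,
               ci_low = ci[, 1], ci_high = ci[, 2])
  }))
  structure(list(table = tab, raw = raw, kind = kind,
                 effect_sizes = effect_sizes, n_iterations = n_iterations,
                 model_kinds = model_kinds, classifier = classifier,
                 trial_ids = trial_ids, control_rule = control_rule,
                 hd_covariate = hd_covariate,
                 alpha = alpha, master_seed = master_seed,
                 failures = failures),
            class = "detection_curves")
}

#' @export
print.detection_curves <- function(x, ...) {
  cat(sprintf("detection curves (%s, %d iterations, %d trial patients):\n",
              x$kind, x$n_iterations, length(x$trial_ids)))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
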