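# Hypothetical interventions applied to the treated arm of a simulated
# trial.
#
# Lesion non-altering interventions (e.g. neurorehabilitation) normalize
# the outcome of a fixed proportion of the treated without touching the
# lesion. Lesion-altering interventions (e.g. thrombolysis) shrink each
# treated lesion by surface erosion; the counterfactual outcome is then
# read off the previously trained recovery classifier applied to the
# changed lesion.

#' Specification of a hypothetical intervention
#'
#' @param kind \code{"non_altering"} (responder proportion) or
#'   \code{"lesion_altering"} (fractional volume reduction by erosion).
#' @param effect_size value in [0, 1]: responder proportion, or fractional
#'   lesion volume reduction.
#' @param control_outcome_rule for lesion-altering interventions, how the
#'   control arm's outcome is obtained: \code{"classifier_on_original"}
#'   (default; the classifier applied to the unchanged lesion, so the
#'   zero-effect null is exactly calibrated) or \code{"natural"} (the
#'   observed natural outcome).
#' @return A list of class \code{intervention_spec}.
#' @export
intervention_spec <- function(kind = c("non_altering", "lesion_altering"),
                              effect_size,
                              control_outcome_rule = c("classifier_on_original", "natural")) {
  kind <- match.arg(kind)
  control_outcome_rule <- match.arg(control_outcome_rule)
  if (!is.numeric(effect_size) || any(effect_size < 0) || any(effect_size > 1))
    stop_therinf("effect_size must be in [0, 1]")
  structure(list(kind = kind, effect_size = effect_size,
                 control_outcome_rule = control_outcome_rule),
            class = "intervention_spec")
}

#' Apply a lesion non-altering intervention
#'
#' Forces recovery in exactly \code{round(p * n_treated)} (round-half-up)
#' treated patients, chosen uniformly at random with the given seed; the
#' remaining treated patients keep their natural outcome. A natural
#' recoverer selected as responder stays recovered, so the effective effect
#' is diluted by the natural recovery rate exactly as in a real trial.
#' \code{method = "bernoulli"} draws each treated patient independently
#' with probability \code{p} instead.
#'
#' @param natural logical vector: natural outcomes of the treated patients.
#' @param p responder proportion in [0, 1].
#' @param seed integer seed.
#' @param method \code{"exact"} (default) or \code{"bernoulli"}.
#' @return Logical vector of treated outcomes.
#' @export
apply_non_altering <- function(natural, p, seed = 1L, method = c("exact", "bernoulli")) {
  method <- match.arg(method)
  if (p < 0 || p > 1) stop_therinf("p must be in [0, 1]")
  n <- length(natural)
  out <- natural
  withr::with_seed(seed, {
    if (method == "exact") {
      n_resp <- round_half_up(p * n)
      if (n_resp > 0L) out[sample.int(n, n_resp)] <- TRUE
    } else {
      out[stats::runif(n) < p] <- TRUE
    }
  })
  out
}

# Precomputed erosion/score cache for one set of patients: per patient the
# erosion shells as in-mask vector positions, the classifier weight of each
# voxel, the original score and volume. Allows any (reduction, seed) to be
# evaluated by subtracting the removed voxels' weights from the original
# score, in exact agreement with erode_to_fraction + predict.
erosion_cache <- function(cohort, model, ids, connectivity = 6L) {
  grid <- cohort$grid
  pos_of <- integer(prod(grid$dims))
  pos_of[grid$mask_idx] <- seq_len(grid$n_in_mask)
  lapply(stats::setNames(ids, ids), function(id) {
    map <- cohort$lesions[[id]]
    shells_lin <- erosion_shells(map, connectivity)
    shells_pos <- lapply(shells_lin, function(s) pos_of[s])
    v <- vectorize(map)
    list(shells = shells_pos,
         shell_sizes = lengths(shells_pos),
         volume = sum(v),
         score0 = sum(model$weights[v == 1]) + model$bias)
  })
}

# Treated score and volume after eroding one cached lesion by `reduction`.
eroded_prediction <- function(entry, model, reduction, seed) {
  v0 <- entry$volume
  target <- round_half_up((1 - reduction) * v0)
  n_remove <- v0 - target
  score <- entry$score0
  if (n_remove > 0L) {
    left <- n_remove
    for (k in seq_along(entry$shells)) {
      sh <- entry$shells[[k]]
      if (left >= length(sh)) {
        score <- score - sum(model$weights[sh])
        left <- left - length(sh)
        if (left == 0L) break
      } else {
        part <- withr::with_seed(seed, sample(sh, left))
        score <- score - sum(model$weights[part])
        left <- 0L
        break
      }
    }
  }
  list(score = score, recovered = score > 0, volume = target)
}

#' Apply a lesion-altering intervention
#'
#' Each treated lesion is eroded to \code{(1 - reduction)} of its volume
#' (\code{\link{erode_to_fraction}}) and the treated outcome is the
#' recovery classifier's prediction on the changed lesion. Control outcomes
#' follow \code{rule}: the classifier applied to the unchanged lesion
#' (default) or the observed natural outcome. The classifier must have been
#' trained on patients disjoint from both arms; this independence contract
#' is asserted.
#'
#' @param cohort a \code{cohort}.
#' @param treated_ids,control_ids patient ids of the two arms.
#' @param reduction fractional volume reduction in [0, 1].
#' @param model a \code{recovery_classifier}.
#' @param rule control-arm outcome rule (see \code{\link{intervention_spec}}).
#' @param seed integer seed (partial-shell draws; per-patient seeds are
#'   derived deterministically).
#' @param cache optional precomputed cache from repeated use (internal).
#' @return Data frame: \code{patient_id}, \code{treated},
#'   \code{outcome_recovered}, \code{post_lesion_volume}, \code{score}.
#' @export
apply_lesion_altering <- function(cohort, treated_ids, control_ids, reduction,
                                  model, rule = c("classifier_on_original", "natural"),
                                  seed = 1L, cache = NULL) {
  rule <- match.arg(rule)
  if (reduction < 0 || reduction > 1) stop_therinf("reduction must be in [0, 1]")
  overlap <- intersect(model$training_ids, c(treated_ids, control_ids))
  if (length(overlap) > 0L)
    stop_therinf("independence contract violated: classifier was trained on ",
                 length(overlap), " trial patient(s), e.g. ", overlap[1])
  ids <- c(treated_ids, control_ids)
  if (is.null(cache)) cache <- erosion_cache(cohort, model, ids)

  res <- data.frame(patient_id = ids,
                    treated = rep(c(TRUE, FALSE), c(length(treated_ids), length(control_ids))),
                    outcome_recovered = NA, post_lesion_volume = NA_integer_,
                    score = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(treated_ids)) {
    id <- treated_ids[i]
    pr <- eroded_prediction(cache[[id]], model, reduction, mix_seed(seed, 5L, i))
    res$outcome_recovered[i] <- pr$recovered
    res$post_lesion_volume[i] <- pr$volume
    res$score[i] <- pr$score
  }
  ctrl_rows <- seq_along(control_ids) + length(treated_ids)
  if (rule == "classifier_on_original") {
    for (j in seq_along(control_ids)) {
      e <- cache[[control_ids[j]]]
      res$outcome_recovered[ctrl_rows[j]] <- e$score0 > 0
      res$post_lesion_volume[ctrl_rows[j]] <- e$volume
      res$score[ctrl_rows[j]] <- e$score0
    }
  } else {
    cv <- cohort$covariates
    nat <- cv$recovered[match(control_ids, cv$id)]
    res$outcome_recovered[ctrl_rows] <- nat
    res$post_lesion_volume[ctrl_rows] <-
      vapply(control_ids, function(id) cache[[id]]$volume, integer(1))
    res$score[ctrl_rows] <- vapply(control_ids, function(id) cache[[id]]$score0, numeric(1))
  }
  res
}
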