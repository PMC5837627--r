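# End-to-end orchestration: a single configuration fully determines an
# experiment — cohort generation (or loading), classifier training on a
# held-out pool, iterated trial batches for one or both intervention
# classes, therapeutic function fits with bootstrapped thresholds — and a
# manifest that makes the run reproducible.

#' Experiment presets
#'
#' \code{"paper_scale"}: 1172 patients on the full 5768-voxel grid, 9 effect
#' sizes (0.1-0.9), 600 iterations per level, 1000 bootstrap replicates.
#' \code{"desk"}: 300 patients on the desk grid, 5 effect sizes (0.1-0.9 by
#' 0.2), 100 iterations per level, 400 bootstrap replicates — sized for
#' interactive use.
#'
#' @param name preset name.
#' @return A configuration list for \code{\link{run_experiment}}.
#' @export
experiment_preset <- function(name = c("desk", "paper_scale")) {
  name <- match.arg(name)
  if (name == "paper_scale") {
    list(preset = "paper_scale", n_patients = 1172L, grid = "default",
         effect_sizes = seq(0.1, 0.9, by = 0.1), n_iterations = 600L,
         kinds = c("non_altering", "lesion_altering"),
         model_kinds = c("low_dim", "high_dim"),
         classifier_pool_fraction = 0.5, classifier_mode = "inductive",
         cost = "auto", control_rule = "classifier_on_original",
         allocation = 0.5, alpha = 0.05, family = "lpm",
         n_boot = 1000L, cv_folds = 10L, master_seed = 1L)
  } else {
    list(preset = "desk", n_patients = 300L, grid = "desk",
         effect_sizes = seq(0.1, 0.9, by = 0.2), n_iterations = 100L,
         kinds = c("non_altering", "lesion_altering"),
         model_kinds = c("low_dim", "high_dim"),
         classifier_pool_fraction = 0.5, classifier_mode = "inductive",
         cost = "auto", control_rule = "classifier_on_original",
         allocation = 0.5, alpha = 0.05, family = "lpm",
         n_boot = 400L, cv_folds = 5L, master_seed = 1L)
  }
}

validate_config <- function(config) {
  req <- c("n_patients", "grid", "effect_sizes", "n_iterations", "kinds",
           "model_kinds", "master_seed")
  miss <- setdiff(req, names(config))
  if (length(miss))
    stop_therinf("config is missing field(s): ", paste(miss, collapse = ", "))
  if (any(config$effect_sizes < 0 | config$effect_sizes > 1))
    stop_therinf("config: effect_sizes must lie in [0, 1]")
  bad <- setdiff(config$kinds, c("non_altering", "lesion_altering"))
  if (length(bad)) stop_therinf("config: unknown intervention kind ", bad[1])
  bad <- setdiff(config$model_kinds, c("low_dim", "high_dim"))
  if (length(bad)) stop_therinf("config: unknown model kind ", bad[1])
  invisible(config)
}

config_grid <- function(config) {
  g <- config$grid
  if (is.character(g)) {
    switch(g, default = default_brain_grid(), desk = desk_brain_grid(),
           stop_therinf("config: unknown grid preset '", g, "'"))
  } else {
    do.call(build_brain_grid, g)
  }
}

#' Run a full therapeutic-inference experiment
#'
#' Executes a configuration (see \code{\link{experiment_preset}}; a YAML
#' file path is also accepted): generates or loads the cohort, trains the
#' recovery classifier on a held-out pool of eligible patients, reports its
#' cross-validated sensitivity/specificity, runs the iterated-trial batches
#' for each requested intervention class, fits the therapeutic functions
#' and estimates thresholds with bootstrap confidence intervals. When
#' \code{out_dir} is given, result tables (TSV), classifier weight map
#' (NIfTI) and a manifest (JSON: configuration, seed, versions, config
#' hash) are written there.
#'
#' @param config configuration list or YAML file path.
#' @param cohort optional pre-built \code{cohort} (overrides generation).
#' @param classifier optional pre-trained classifier; its training ids must
#'   not overlap the trial pool.
#' @param out_dir optional output directory.
#' @return Object of class \code{experiment_result}: \code{config},
#'   \code{cohort}, \code{classifier_cv}, \code{curves} (per kind),
#'   \code{fits} (per kind and model kind), \code{thresholds} (data frame
#'   with bootstrap CIs), \code{gaze} (circular mean and laterality curve).
#' @export
run_experiment <- function(config = experiment_preset("desk"), cohort = NULL,
                           classifier = NULL, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- experiment_preset("desk")
  config <- utils::modifyList(defaults, config)
  validate_config(config)
  seed <- config$master_seed

  if (is.null(cohort)) {
    grid <- config_grid(config)
    cohort <- generate_cohort(n = config$n_patients, grid = grid,
                              gt_config = do.call(ground_truth_config,
                                                  config$gt_config %||% list()),
                              lesion_config = config$lesion_config %||% list(),
                              seed = mix_seed(seed, 100L))
  }
  cv <- cohort$covariates
  eligible <- cv$id[cv$eligible]
  cost <- config$cost %||% "auto"
  if (identical(cost, "auto")) cost <- NULL  # nested-CV selection

  # shared classifier pool so both intervention classes see the same split
  if (is.null(classifier)) {
    n_pool <- round_half_up((config$classifier_pool_fraction %||% 0.5) * length(eligible))
    pool <- withr::with_seed(mix_seed(seed, 10L), sample(eligible, n_pool))
    x_pool <- lesion_matrix(cohort, pool)
    y_pool <- cv$recovered[match(pool, cv$id)]
    classifier <- train_recovery_classifier(x_pool, y_pool,
                                            mode = config$classifier_mode %||% "inductive",
                                            cost = cost,
                                            seed = mix_seed(seed, 11L))
    classifier_cv <- cross_validate_classifier(x_pool, y_pool,
                                               k = config$cv_folds %||% 5L,
                                               cost = classifier$cost,
                                               seed = mix_seed(seed, 12L))
  } else classifier_cv <- NULL
  trial_ids <- setdiff(eligible, classifier$training_ids)
  overlap <- intersect(trial_ids, classifier$training_ids)
  if (length(overlap) > 0L)
    stop_therinf("independence contract violated: classifier pool overlaps trial pool")
  if (length(trial_ids) < 4L)
    stop_therinf("classifier training pool leaves too few trial patients")

  curves <- list(); fits <- list(); thr_rows <- list()
  for (kd in config$kinds) {
    curves[[kd]] <- run_trial_batch(
      cohort, kind = kd, effect_sizes = config$effect_sizes,
      n_iterations = config$n_iterations, model_kinds = config$model_kinds,
      classifier = classifier, trial_ids = trial_ids,
      control_rule = config$control_rule %||% "classifier_on_original",
      hd_covariate = config$hd_covariate %||% "label",
      allocation = config$allocation %||% 0.5,
      alpha = config$alpha %||% 0.05, family = config$family %||% "lpm",
      master_seed = mix_seed(seed, match(kd, c("non_altering", "lesion_altering"))))
    for (mk in config$model_kinds) {
      pts <- curves[[kd]]$table[curves[[kd]]$table$model_kind == mk, ]
      tf <- fit_therapeutic_function(pts)
      fits[[kd]][[mk]] <- tf
      ci <- bootstrap_threshold_ci(curves[[kd]], model_kind = mk,
                                   n_boot = config$n_boot %||% 400L,
                                   seed = mix_seed(seed, 20L + match(mk, c("low_dim", "high_dim"))))
      thr_rows[[paste(kd, mk)]] <- data.frame(
        kind = kd, model_kind = mk, threshold = tf$threshold,
        reached = tf$threshold_reached, ci_low = ci$low, ci_high = ci$high,
        ci_censored = ci$censored)
    }
  }

  gaze <- list(
    circular_mean_t1 = circular_mean(cv$gaze_t1_deg),
    laterality = gaze_laterality_curve(cohort)
  )
  result <- structure(list(
    config = config, cohort = cohort, classifier = classifier,
    classifier_cv = classifier_cv, curves = curves, fits = fits,
    thresholds = do.call(rbind, thr_rows), gaze = gaze
  ), class = "experiment_result")

  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

# Write tables, weight map and manifest for a result bundle.
write_experiment <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_curves <- do.call(rbind, lapply(result$curves, `[[`, "table"))
  utils::write.table(all_curves, file.path(out_dir, "detection_curves.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$thresholds, file.path(out_dir, "thresholds.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$gaze$laterality$bins,
                     file.path(out_dir, "gaze_laterality.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(result$classifier_cv)) {
    ccv <- result$classifier_cv
    utils::write.table(
      data.frame(k = ccv$k, sensitivity_mean = ccv$sensitivity_mean,
                 sensitivity_se = ccv$sensitivity_se,
                 specificity_mean = ccv$specificity_mean,
                 specificity_se = ccv$specificity_se),
      file.path(out_dir, "classifier_cv.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  export_weight_map(result$classifier, result$cohort$grid,
                    file.path(out_dir, "classifier_weights.nii.gz"))
  cfg_yaml <- yaml::as.yaml(result$config)
  cfg_file <- file.path(out_dir, "config.yaml")
  writeLines(cfg_yaml, cfg_file)
  manifest <- list(
    package = "therinf",
    package_version = as.character(utils::packageVersion("therinf")),
    r_version = as.character(getRversion()),
    master_seed = result$config$master_seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    n_patients = nrow(result$cohort$covariates),
    n_eligible = sum(result$cohort$covariates$eligible),
    n_trial_pool = length(setdiff(result$cohort$covariates$id[result$cohort$covariates$eligible],
                                  result$classifier$training_ids))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("therapeutic-inference experiment\n")
  if (!is.null(x$classifier_cv)) print(x$classifier_cv)
  cat(sprintf("cohort gaze circular mean: %.2f deg\n", x$gaze$circular_mean_t1))
  print(x$thresholds, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Render the standard figures for an experiment result
#'
#' Writes four PNG figures: the polar histogram of admission gaze with its
#' circular mean; the gaze-laterality curve (bin means and linear fit); the
#' paired therapeutic functions per intervention class (low-dimensional in
#' black, high-dimensional in red, with binomial error bars, threshold
#' markers and bootstrap CI bands); and an axial-slice montage of the
#' classifier weight map.
#'
#' @param result an \code{experiment_result}.
#' @param dir output directory.
#' @return Character vector of file paths, invisibly.
#' @export
make_figures <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  f <- file.path(dir, "gaze_polar.png")
  grDevices::png(f, width = 700, height = 700)
  plot_gaze_polar(result$cohort$covariates$gaze_t1_deg)
  grDevices::dev.off(); paths <- c(paths, f)

  f <- file.path(dir, "gaze_laterality.png")
  grDevices::png(f, width = 700, height = 500)
  plot_laterality(result$gaze$laterality)
  grDevices::dev.off(); paths <- c(paths, f)

  f <- file.path(dir, "therapeutic_functions.png")
  grDevices::png(f, width = 600 * length(result$curves), height = 520)
  graphics::par(mfrow = c(1, length(result$curves)))
  for (kd in names(result$curves))
    plot_therapeutic(result$curves[[kd]], result$fits[[kd]], main = kd)
  grDevices::dev.off(); paths <- c(paths, f)

  f <- file.path(dir, "classifier_weights.png")
  grDevices::png(f, width = 900, height = 700)
  plot_weight_montage(result$classifier, result$cohort$grid)
  grDevices::dev.off(); paths <- c(paths, f)

  invisible(paths)
}

plot_gaze_polar <- function(gaze_deg, n_bins = 36L) {
  br <- seq(-180, 180, length.out = n_bins + 1L)
  h <- graphics::hist(gaze_deg, breaks = br, plot = FALSE)
  r <- h$counts / max(h$counts, 1)
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = "Admission gaze (polar histogram)")
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE, fg = "grey70")
  # 0 deg = up (midline); negative (leftward) angles to the left
  ang <- (h$mids + 90) * pi / 180
  for (i in seq_along(r)) {
    graphics::segments(0, 0, r[i] * cos(ang[i]), r[i] * sin(ang[i]),
                       col = "steelblue", lwd = 4)
  }
  cm <- circular_mean(gaze_deg)
  graphics::arrows(0, 0, cos((cm + 90) * pi / 180), sin((cm + 90) * pi / 180),
                   col = "red", lwd = 2, length = 0.1)
  graphics::text(0, -1.08, sprintf("circular mean %.2f deg", cm))
}

plot_laterality <- function(curve) {
  b <- curve$bins[!is.na(curve$bins$mean_ratio), ]
  graphics::plot(b$gaze_mid_deg, b$mean_ratio, pch = 19, col = "steelblue",
                 ylim = c(0, 1), xlab = "gaze angle (deg, negative = leftward)",
                 ylab = "right-hemisphere damage ratio",
                 main = "Damage laterality by gaze")
  graphics::abline(curve$intercept, curve$slope, col = "red", lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = sprintf("slope %.4f/deg (z = %.1f)", curve$slope, curve$slope_z))
}

plot_therapeutic <- function(curves, fits, main = "") {
  tab <- curves$table
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "effect size", ylab = "detection probability",
                 main = paste("Therapeutic function:", main))
  graphics::abline(h = 0.5, col = "grey80", lty = 3)
  cols <- c(low_dim = "black", high_dim = "red")
  xs <- seq(0, 1, by = 0.01)
  for (mk in names(fits)) {
    sub <- tab[tab$model_kind == mk, ]
    graphics::arrows(sub$effect_size, sub$ci_low, sub$effect_size, sub$ci_high,
                     angle = 90, code = 3, length = 0.02, col = cols[mk])
    graphics::points(sub$effect_size, sub$detection_probability, pch = 19,
                     col = cols[mk])
    graphics::lines(xs, predict(fits[[mk]], xs), col = cols[mk], lwd = 2)
    if (fits[[mk]]$threshold_reached)
      graphics::abline(v = fits[[mk]]$threshold, col = cols[mk], lty = 2)
  }
  graphics::legend("bottomright", bty = "n", lwd = 2, col = cols,
                   legend = names(cols)[names(cols) %in% names(fits)])
}

plot_weight_montage <- function(classifier, grid, n_slices = 12L) {
  arr <- export_weight_map(classifier, grid)
  zs <- unique(round(seq(1, grid$dims[3], length.out = n_slices)))
  nc <- ceiling(sqrt(length(zs))); nr <- ceiling(length(zs) / nc)
  graphics::par(mfrow = c(nr, nc), mar = c(0.5, 0.5, 1.5, 0.5))
  lim <- max(abs(arr)) + 1e-12
  pal <- grDevices::colorRampPalette(c("darkred", "yellow", "white", "cyan", "darkblue"))(64)
  for (z in zs) {
    graphics::image(arr[, , z], zlim = c(-lim, lim), col = pal, axes = FALSE,
                    main = paste("z =", z), asp = grid$dims[2] / grid$dims[1])
  }
}
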