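# High-dimensional recovery classifier.
#
# A linear max-margin classifier (libsvm C-SVC via e1071, linear kernel,
# class-weighted for imbalance) maps the binary lesion vector to natural
# recovery of gaze. The fitted voxel weights and bias are extracted so that
# prediction on any lesion vector — including artificially eroded lesions —
# is a plain dot product. Sign convention: positive decision score favours
# recovery.
#
# Transductive mode augments the max-margin fit with seeded self-training
# on unlabelled vectors: label them with the current model, refit on the
# union, iterate to a fixed point (or a maximum number of rounds).

#' Train the lesion-to-recovery linear classifier
#'
#' @param x numeric matrix (patients x in-mask voxels) of lesion vectors;
#'   row names are used as training ids.
#' @param y logical (or 0/1) vector: natural recovery labels.
#' @param mode \code{"inductive"} (default) or \code{"transductive"}.
#' @param unlabelled optional matrix of unlabelled lesion vectors for
#'   transductive self-training.
#' @param cost SVM regularization parameter C. When \code{NULL}, chosen by
#'   nested cross-validation on the training pool over
#'   \code{cost_grid}.
#' @param cost_grid candidate costs for nested selection.
#' @param max_self_train maximum self-training rounds.
#' @param seed integer seed (nested CV folds and tie-breaking).
#' @return Object of class \code{recovery_classifier}: \code{weights}
#'   (length \code{ncol(x)}), \code{bias}, \code{training_ids},
#'   \code{transductive}, \code{cost}, \code{levels}.
#' @export
train_recovery_classifier <- function(x, y, mode = c("inductive", "transductive"),
                                      unlabelled = NULL, cost = NULL,
                                      cost_grid = 10^seq(-3, 1),
                                      max_self_train = 10L, seed = 1L) {
  mode <- match.arg(mode)
  y <- as.logical(y)
  if (any(is.na(y))) stop_therinf("training labels contain NA")
  if (length(unique(y)) < 2L) stop_therinf("training set has a single class")
  if (min(table(y)) < 2L) stop_therinf("need at least 2 patients per class")
  if (all(rowSums(x) == 0)) stop_therinf("all training lesion vectors are empty")
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))

  if (is.null(cost)) cost <- select_cost(x, y, cost_grid, seed = seed)

  fit <- svm_linear_fit(x, y, cost)
  n_rounds <- 0L
  if (mode == "transductive" && !is.null(unlabelled) && nrow(unlabelled) > 0L) {
    prev <- rep(NA, nrow(unlabelled))
    for (r in seq_len(max_self_train)) {
      pseudo <- as.vector(unlabelled %*% fit$w + fit$b) > 0
      if (identical(pseudo, prev)) break
      prev <- pseudo
      n_rounds <- r
      fit <- svm_linear_fit(rbind(x, unlabelled), c(y, pseudo), cost)
    }
  }
  structure(list(weights = fit$w, bias = fit$b, training_ids = ids,
                 transductive = (mode == "transductive"), cost = cost,
                 self_train_rounds = n_rounds,
                 levels = c("persist", "recover")),
            class = "recovery_classifier")
}

# Linear C-SVC with inverse-frequency class weights; returns weights/bias
# aligned so that score > 0 predicts y == TRUE.
svm_linear_fit <- function(x, y, cost) {
  yf <- factor(ifelse(y, "recover", "persist"), levels = c("persist", "recover"))
  cw <- length(y) / (2 * table(yf))
  m <- e1071::svm(x, yf, kernel = "linear", cost = cost, scale = FALSE,
                  class.weights = cw)
  w <- as.vector(crossprod(m$coefs, m$SV))
  b <- -m$rho
  # libsvm's decision-value sign favours the first class of the reported
  # pair; align so that a positive score predicts recovery.
  dv <- attr(stats::predict(m, x[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  if (strsplit(colnames(dv), "/")[[1]][1] != "recover") { w <- -w; b <- -b }
  list(w = w, b = b)
}

# Nested k-fold selection of the SVM cost on the training pool only, by
# balanced accuracy (mean of sensitivity and specificity), consistent with
# the class-weighted loss.
select_cost <- function(x, y, cost_grid, k = 5L, seed = 1L) {
  folds <- stratified_folds(y, k, seed)
  bal <- vapply(cost_grid, function(cc) {
    pred <- rep(NA, length(y))
    for (f in seq_len(k)) {
      te <- folds == f
      if (length(unique(y[!te])) < 2L) next
      fit <- svm_linear_fit(x[!te, , drop = FALSE], y[!te], cc)
      pred[te] <- as.vector(x[te, , drop = FALSE] %*% fit$w + fit$b) > 0
    }
    ok <- !is.na(pred)
    (mean(pred[ok & y]) + mean(!pred[ok & !y])) / 2
  }, numeric(1))
  cost_grid[which.max(bal)]
}

# Stratified fold assignment (1..k), seeded.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Predict recovery from lesion vectors
#'
#' Score is \code{x \%*\% weights + bias}; predicted recovery is
#' \code{score > 0}.
#'
#' @param object a \code{recovery_classifier}.
#' @param x lesion vector (length \code{length(weights)}) or matrix of
#'   vectors (rows = patients).
#' @param ... unused.
#' @return Data frame with \code{score} and \code{recovered}.
#' @export
predict.recovery_classifier <- function(object, x, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(object$weights))
    stop_therinf("lesion vector length ", ncol(x), " does not match classifier (",
                 length(object$weights), ")")
  score <- as.vector(x %*% object$weights) + object$bias
  data.frame(score = score, recovered = score > 0)
}

#' Cross-validated sensitivity and specificity
#'
#' Stratified k-fold cross-validation of the recovery classifier.
#' Sensitivity is the recovered-class true positive rate, specificity the
#' persistent-class true negative rate; means and standard errors are taken
#' over folds.
#'
#' @param x,y as in \code{\link{train_recovery_classifier}}.
#' @param k number of folds (default 10).
#' @param mode,cost,seed passed to the trainer; held-out fold vectors serve
#'   as the unlabelled set in transductive mode.
#' @return Object of class \code{cv_report}: \code{k},
#'   \code{sensitivity_mean}, \code{sensitivity_se}, \code{specificity_mean},
#'   \code{specificity_se} and the per-fold table.
#' @export
cross_validate_classifier <- function(x, y, k = 10L, mode = "inductive",
                                      cost = 1, seed = 1L) {
  y <- as.logical(y)
  if (k < 2L) stop_therinf("k must be >= 2")
  if (min(table(y)) < k) stop_therinf("a class is too small for ", k, "-fold stratification")
  folds <- stratified_folds(y, k, seed)
  per_fold <- data.frame(fold = seq_len(k), sensitivity = NA_real_,
                         specificity = NA_real_)
  for (f in seq_len(k)) {
    te <- folds == f
    model <- train_recovery_classifier(
      x[!te, , drop = FALSE], y[!te], mode = mode,
      unlabelled = if (mode == "transductive") x[te, , drop = FALSE] else NULL,
      cost = cost, seed = mix_seed(seed, f))
    pred <- predict(model, x[te, , drop = FALSE])$recovered
    per_fold$sensitivity[f] <- mean(pred[y[te]])
    per_fold$specificity[f] <- mean(!pred[!y[te]])
  }
  se <- function(v) stats::sd(v) / sqrt(length(v))
  structure(list(k = k,
                 sensitivity_mean = mean(per_fold$sensitivity),
                 sensitivity_se = se(per_fold$sensitivity),
                 specificity_mean = mean(per_fold$specificity),
                 specificity_se = se(per_fold$specificity),
                 per_fold = per_fold),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV: sensitivity %.2f%% (SE %.2f%%), specificity %.2f%% (SE %.2f%%)\n",
              x$k, 100 * x$sensitivity_mean, 100 * x$sensitivity_se,
              100 * x$specificity_mean, 100 * x$specificity_se))
  invisible(x)
}

#' Export classifier voxel weights as a volume
#'
#' Devectorizes the fitted weights onto the grid (zero outside the mask)
#' and optionally writes them as a float NIfTI volume.
#'
#' @param model a \code{recovery_classifier}.
#' @param grid the \code{brain_grid} the lesion vectors were taken from.
#' @param path optional NIfTI output path.
#' @return The 3D weight array, invisibly when writing.
#' @export
export_weight_map <- function(model, grid, path = NULL) {
  arr <- devectorize(model$weights, grid)
  if (!is.null(path)) {
    write_lesion(arr, path, grid = grid)
    return(invisible(arr))
  }
  arr
}
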