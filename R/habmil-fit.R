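# The user-facing fitting interface: one call trains a hierarchical
# attention MIL classifier on a cohort manifest and returns a classed
# object with the usual modelling methods.

#' Fit a hierarchical attention MIL classifier
#'
#' Trains the full pipeline (3-D instance encoder, positional encoding,
#' dynamic gated attention pooling, sigmoid bag head) on a cohort manifest
#' with a leakage-free subject-level split, and evaluates the selected
#' checkpoint on the held-out test partition.
#'
#' @param manifest cohort manifest data.frame (see [generate_cohort()] /
#'   [read_manifest()]) or a path to a manifest file.
#' @param config a [model_config()] describing the architecture.
#' @param train a [train_config()] describing the optimization protocol.
#' @param split a [make_splits()] plan, or NULL to build one from `seed`
#'   with the default 60/20/20 ratios.
#' @param seed master seed (overrides `train$seed` when given).
#' @return object of class `habmil`: the trained model, split plan,
#'   per-epoch history, validation and test metrics.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(6, 6, grid_shape = c(16, 16, 12), seed = 1)
#' cfg <- model_config(encoder_config(stage_channels = c(4, 8),
#'                                    pool_sizes = list(2, 2),
#'                                    embed_dim = 8,
#'                                    input_shape = c(16, 16, 12)),
#'                     lsvd_rank = 2)
#' fit <- habmil(cohort, cfg, train_config(epochs = 2, seed = 1))
#' print(fit)
#' }
#' @export
habmil <- function(manifest, config = model_config(),
                   train = train_config(), split = NULL, seed = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!is.null(seed)) train$seed <- as.integer(seed)
  if (is.null(split)) {
    split <- make_splits(manifest, k_folds = min(5L, max(2L, round(
      0.6 * length(unique(manifest$subject_id))))),
      seed = derive_seed(train$seed, "split"))
  }
  data <- load_dataset(manifest, config$encoder$input_shape,
                       train$modalities)
  fit <- train_model(NULL, manifest, split, train, config, data)
  test_ids <- split_subjects(split, "test")
  test_metrics <- NULL
  if (length(test_ids) > 0) {
    test_metrics <- evaluate_model(
      fit$model, manifest[manifest$subject_id %in% test_ids, ],
      dataset_subset(data, test_ids))
  }
  structure(list(model = fit$model, config = config, train = train,
                 split = split, history = fit$history,
                 val_metrics = fit$val_metrics,
                 test_metrics = test_metrics, manifest = manifest),
            class = "habmil")
}

#' @export
print.habmil <- function(x, ...) {
  cat("Hierarchical attention MIL classifier\n")
  cat(sprintf("  encoder: %s -> %s x %d instances; pos: %s; pooling: %s\n",
              paste(x$config$encoder$input_shape, collapse = "x"),
              paste(x$config$encoder$target_instance_grid, collapse = "x"),
              x$config$encoder$embed_dim, x$config$pos_encoding,
              x$config$pooling))
  cat(sprintf("  trained %d epochs on %d subjects (seed %d)\n",
              max(x$history$epoch),
              sum(x$split$assignment$partition == "train"), x$train$seed))
  if (!is.null(x$test_metrics)) {
    cat(sprintf("  test: AUC %.3f  ACC %.3f  SEN %.3f  SPE %.3f (n = %d)\n",
                x$test_metrics$auc, x$test_metrics$acc,
                x$test_metrics$sensitivity, x$test_metrics$specificity,
                x$test_metrics$n_test))
  }
  invisible(x)
}

#' @export
summary.habmil <- function(object, ...) {
  print(object)
  cat("\nPer-epoch history (last 5):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  if (!is.null(object$val_metrics)) {
    cat("\nValidation: ")
    print(object$val_metrics)
  }
  invisible(object)
}

#' Predict bag probabilities for new subjects
#'
#' @param object a fitted `habmil` object.
#' @param newdata manifest data.frame (or path); defaults to the held-out
#'   test partition of the fit.
#' @param ... unused.
#' @return data.frame with subject_id, probability, predicted_label.
#' @export
predict.habmil <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    ids <- split_subjects(object$split, "test")
    newdata <- object$manifest[object$manifest$subject_id %in% ids, ]
  }
  if (is.character(newdata)) newdata <- read_manifest(newdata)
  data <- load_dataset(newdata, object$config$encoder$input_shape,
                       object$train$modalities)
  probs <- score_dataset(object$model, data)
  data.frame(subject_id = vapply(data, function(d) d$subject_id,
                                 character(1)),
             probability = probs,
             predicted_label = as.integer(probs >= 0.5))
}

#' Plot training history and test ROC
#'
#' @param x a fitted `habmil` object.
#' @param which "history", "roc" or "both" (default).
#' @param ... passed to plotting functions.
#' @export
plot.habmil <- function(x, which = c("both", "history", "roc"), ...) {
  which <- match.arg(which)
  two <- which == "both" && !is.null(x$test_metrics) &&
    !is.null(x$test_metrics$roc)
  if (two) {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  if (which %in% c("both", "history")) {
    graphics::plot(x$history$epoch, x$history$train_loss, type = "l",
                   xlab = "epoch", ylab = "loss", main = "training", ...)
    if (any(is.finite(x$history$val_loss))) {
      graphics::lines(x$history$epoch, x$history$val_loss, lty = 2)
      graphics::legend("topright", legend = c("train", "val"),
                       lty = c(1, 2), bty = "n")
    }
  }
  if (which %in% c("both", "roc") && !is.null(x$test_metrics) &&
      !is.null(x$test_metrics$roc)) {
    r <- x$test_metrics$roc
    graphics::plot(r$fpr, r$tpr, type = "l", xlab = "FPR", ylab = "TPR",
                   main = sprintf("test ROC (AUC %.3f)", x$test_metrics$auc))
    graphics::abline(0, 1, lty = 3)
  }
  invisible(x)
}

#' Coefficients of the bag-level classification head
#'
#' @param object a fitted `habmil` object.
#' @param ... unused.
#' @return named numeric vector: the head weights (one per fused feature)
#'   and the intercept.
#' @export
coef.habmil <- function(object, ...) {
  w <- object$model$params$head$w
  stats::setNames(c(w, object$model$params$head$b),
                  c(paste0("z", seq_along(w)), "(intercept)"))
}

#' Residuals of the fitted bag probabilities
#'
#' @param object a fitted `habmil` object.
#' @param ... unused.
#' @return response residuals (label - probability) on the test partition.
#' @export
residuals.habmil <- function(object, ...) {
  if (is.null(object$test_metrics)) return(numeric(0))
  s <- attr(object$test_metrics, "scores")
  stats::setNames(s$label - s$score, s$subject_id)
}
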