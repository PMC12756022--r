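# Training loop (Adam, binary cross-entropy bag loss), evaluation metrics
# (trapezoidal ROC/AUC, accuracy, sensitivity, specificity), repeated
# K-fold cross-validation and the ablation harness.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with initial learning rate
#' 1e-4 and weight decay 1e-5, 100 epochs, batch size 2. Desk-scale
#' experiments typically override `epochs` and `learning_rate`.
#'
#' @param epochs training epochs (default 100).
#' @param batch_size bags per gradient step (default 2).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param weight_decay L2 weight decay (default 1e-5).
#' @param seed master seed for all randomness (init, shuffling, dropout,
#'   augmentation).
#' @param augment an [augment_policy()] (default: no augmentation).
#' @param modalities modality subset to keep (others are zeroed).
#' @param class_weighting inverse-prevalence loss weighting (default off).
#' @param clip_norm global gradient-norm clip (default 5).
#' @param select_best keep the checkpoint with the best validation AUC
#'   (default TRUE; FALSE keeps the final epoch).
#' @param verbose print per-epoch progress.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 2L,
                         learning_rate = 1e-4, weight_decay = 1e-5,
                         seed = 1L, augment = augment_policy(),
                         modalities = MODALITIES, class_weighting = FALSE,
                         clip_norm = 5, select_best = TRUE,
                         verbose = FALSE) {
  assert_that(is_count(epochs) && epochs >= 1, "epochs must be >= 1")
  assert_that(is_count(batch_size) && batch_size >= 1,
              "batch_size must be >= 1")
  assert_that(learning_rate > 0, "learning_rate must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 augment = augment, modalities = modalities,
                 class_weighting = class_weighting, clip_norm = clip_norm,
                 select_best = select_best, verbose = verbose),
            class = "train_config")
}

#' Mean binary cross-entropy bag loss
#'
#' @param predictions bag probabilities in (0,1) (values at exactly 0/1 are
#'   epsilon-clamped).
#' @param labels 0/1 bag labels, same length.
#' @param weights optional per-bag weights (default 1).
#' @return scalar loss.
#' @export
mil_loss <- function(predictions, labels, weights = NULL) {
  assert_that(length(predictions) == length(labels),
              "predictions and labels differ in length")
  p <- pmin(pmax(predictions, 1e-7), 1 - 1e-7)
  ll <- -(labels * log(p) + (1 - labels) * log(1 - p))
  if (is.null(weights)) mean(ll) else sum(weights * ll) / sum(weights)
}

# ---- metrics ---------------------------------------------------------------

#' ROC points for a score vector
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return data.frame with columns fpr, tpr (monotone, from (0,0) to
#'   (1,1)); ties in scores are collapsed to single points.
#' @export
roc_points <- function(scores, labels) {
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  assert_that(npos > 0 && nneg > 0,
              "ROC undefined: test set contains a single class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tied block
  data.frame(fpr = c(0, fp[keep] / nneg), tpr = c(0, tp[keep] / npos))
}

#' Area under the ROC curve by trapezoidal integration
#' @inheritParams roc_points
#' @return AUC in [0,1].
#' @export
auc_trapezoid <- function(scores, labels) {
  r <- roc_points(scores, labels)
  sum(diff(r$fpr) * (r$tpr[-1] + r$tpr[-nrow(r)]) / 2)
}

#' Evaluation metrics for bag scores
#'
#' @param scores bag probabilities.
#' @param labels 0/1 labels.
#' @param threshold decision threshold for accuracy/sensitivity/
#'   specificity (default 0.5).
#' @return object of class `eval_metrics`: auc, acc, sensitivity,
#'   specificity, roc (data.frame), n_test. AUC is NA (with a warning) on
#'   single-class test sets.
#' @export
eval_metrics <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  single <- length(unique(labels)) < 2L
  if (single) {
    warning("single-class test set: AUC undefined")
    auc <- NA_real_; roc <- NULL
  } else {
    auc <- auc_trapezoid(scores, labels)
    roc <- roc_points(scores, labels)
  }
  structure(list(auc = auc, acc = (tp + tn) / length(labels),
                 sensitivity = sen, specificity = spe, roc = roc,
                 n_test = length(labels)),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "eval_metrics (n = %d): AUC %.3f | ACC %.3f | SEN %.3f | SPE %.3f\n",
    x$n_test, x$auc, x$acc, x$sensitivity, x$specificity))
  invisible(x)
}

# ---- dataset handling ------------------------------------------------------

#' Load and standardize a whole cohort into memory
#'
#' Reads every subject of a manifest, standardizes to `input_shape` and
#' caches the stacked arrays; useful for passing one preloaded dataset to
#' several [train_model()] runs.
#'
#' @param manifest cohort manifest data.frame.
#' @param input_shape target volume shape (the encoder's `input_shape`).
#' @param modalities modality subset to keep (others zeroed).
#' @return list with one entry per subject: `subject_id`, `volume`
#'   (standardized `multimodal_volume`), `x` (stacked array), `label`.
#' @export
load_dataset <- function(manifest, input_shape, modalities = MODALITIES) {
  lapply(seq_len(nrow(manifest)), function(i) {
    vol <- load_volume(manifest[i, ])
    vol <- standardize(vol, input_shape)
    vol <- restrict_modalities(vol, modalities)
    list(subject_id = vol$subject_id, volume = vol,
         x = volume_to_array(vol), label = manifest$label[i])
  })
}

dataset_subset <- function(data, subject_ids) {
  ids <- vapply(data, function(d) d$subject_id, character(1))
  data[ids %in% subject_ids]
}

# Scores for a dataset under a model (eval mode).
score_dataset <- function(model, data) {
  vapply(data, function(d)
    model_forward(model, d$x, training = FALSE)$prob, numeric(1))
}

# ---- training --------------------------------------------------------------

#' Train a model on a cohort
#'
#' Seeded end-to-end: parameter initialization, shuffling, dropout and
#' augmentation all derive from `config$seed`. The checkpoint with the
#' best validation AUC is kept (validation loss breaks AUC ties).
#'
#' @param model a `habmil_model` from [model_init()] (or NULL to
#'   initialize from `config$seed`).
#' @param manifest cohort manifest data.frame.
#' @param split a [make_splits()] plan.
#' @param config a [train_config()].
#' @param model_cfg a [model_config()] (used when `model` is NULL).
#' @param data optional preloaded dataset (from an internal cache) to skip
#'   NIfTI reads.
#' @return list of class `habmil_fit_result`: `model` (best checkpoint),
#'   `history` (per-epoch data.frame), `val_metrics`.
#' @export
train_model <- function(model = NULL, manifest, split, config = train_config(),
                        model_cfg = model_config(), data = NULL) {
  if (is.null(model)) model <- model_init(model_cfg, seed = config$seed)
  input_shape <- model$config$encoder$input_shape
  if (is.null(data)) {
    data <- load_dataset(manifest, input_shape, config$modalities)
  }
  train_data <- dataset_subset(data, split_subjects(split, "train"))
  val_data <- dataset_subset(data, split_subjects(split, "val"))
  assert_that(length(train_data) >= 1, "no training subjects")
  labels <- vapply(train_data, function(d) d$label, numeric(1))
  wts <- NULL
  if (config$class_weighting) {
    prev <- mean(labels)
    wts <- ifelse(labels == 1, 1 / max(prev, 1e-3),
                  1 / max(1 - prev, 1e-3))
    wts <- wts / mean(wts)
  }
  opt <- adam_init(model$params, lr = config$learning_rate,
                   weight_decay = config$weight_decay)
  aug_on <- any(unlist(config$augment[c("flip", "affine", "intensity_scale",
                                        "jitter", "modality_dropout")]) > 0)
  history <- vector("list", config$epochs)
  best <- list(auc = -Inf, loss = Inf, params = model$params,
               state = model$state)
  set.seed(derive_seed(config$seed, "train-loop"))
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(length(train_data))
    losses <- numeric(0)
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(length(ord), i + config$batch_size - 1L)]
      gacc <- NULL
      for (j in batch) {
        d <- train_data[[j]]
        x <- if (aug_on) volume_to_array(augment(d$volume, config$augment))
             else d$x
        fw <- model_forward(model, x, training = TRUE)
        model$state <- fw$state
        w_j <- if (is.null(wts)) 1 else wts[j]
        losses <- c(losses, mil_loss(fw$prob, d$label))
        if (!is.finite(fw$logit)) {
          stop(sprintf("non-finite logit at epoch %d, subject %s",
                       epoch, d$subject_id))
        }
        dlogit <- w_j * (fw$prob - d$label) / length(batch)
        bw <- model_backward(model, fw, dlogit)
        gacc <- if (is.null(gacc)) bw$grads else param_add(gacc, bw$grads)
      }
      gn <- param_global_norm(gacc)
      if (is.finite(gn) && gn > config$clip_norm) {
        gacc <- param_scale(gacc, config$clip_norm / gn)
      }
      st <- adam_step(opt, model$params, gacc)
      opt <- st$opt
      model$params <- st$params
      i <- i + config$batch_size
    }
    ep_loss <- mean(losses)
    val_auc <- NA_real_; val_loss <- NA_real_
    if (length(val_data) > 0) {
      vs <- score_dataset(model, val_data)
      vy <- vapply(val_data, function(d) d$label, numeric(1))
      val_loss <- mil_loss(vs, vy)
      if (length(unique(vy)) > 1L) val_auc <- auc_trapezoid(vs, vy)
      better <- (!is.na(val_auc) && val_auc > best$auc) ||
        (!is.na(val_auc) && val_auc == best$auc && val_loss < best$loss) ||
        (is.na(val_auc) && val_loss < best$loss)
      if (better) {
        best <- list(auc = ifelse(is.na(val_auc), -Inf, val_auc),
                     loss = val_loss, params = model$params,
                     state = model$state)
      }
    }
    history[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss,
                                   val_loss = val_loss, val_auc = val_auc)
    if (config$verbose) {
      message(sprintf("epoch %3d  loss %.4f  val_loss %.4f  val_auc %s",
                      epoch, ep_loss, val_loss,
                      ifelse(is.na(val_auc), "NA", sprintf("%.3f", val_auc))))
    }
  }
  if (config$select_best && length(val_data) > 0 && best$auc > -Inf) {
    model$params <- best$params
    model$state <- best$state
  }
  history <- do.call(rbind, history)
  val_metrics <- NULL
  if (length(val_data) > 0) {
    vy <- vapply(val_data, function(d) d$label, numeric(1))
    if (length(unique(vy)) > 1L) {
      val_metrics <- eval_metrics(score_dataset(model, val_data), vy)
    }
  }
  structure(list(model = model, history = history,
                 val_metrics = val_metrics),
            class = "habmil_fit_result")
}

#' Evaluate a model on a held-out manifest
#'
#' @param model a `habmil_model`.
#' @param manifest manifest rows of the test subjects.
#' @param data optional preloaded dataset.
#' @param modalities modality subset.
#' @return an `eval_metrics` object (plus per-subject scores as
#'   attribute "scores").
#' @export
evaluate_model <- function(model, manifest, data = NULL,
                           modalities = MODALITIES) {
  if (is.null(data)) {
    data <- load_dataset(manifest, model$config$encoder$input_shape,
                         modalities)
  }
  scores <- score_dataset(model, data)
  labels <- vapply(data, function(d) d$label, numeric(1))
  m <- eval_metrics(scores, labels)
  attr(m, "scores") <- data.frame(
    subject_id = vapply(data, function(d) d$subject_id, character(1)),
    score = scores, label = labels)
  m
}

# ---- cross-validation ------------------------------------------------------

#' Repeated K-fold cross-validation
#'
#' Shuffles subjects into `k` folds (per repeat, with distinct derived
#' seeds), trains on k-1 folds and evaluates on the held-out fold. Within
#' CV the final-epoch model is evaluated (no inner validation split).
#'
#' @param manifest cohort manifest.
#' @param model_cfg a [model_config()].
#' @param config a [train_config()].
#' @param k folds (default 5).
#' @param repeats repeats (default 5).
#' @return list with `table` (per repeat x fold metrics) and `summary`
#'   (mean and sd per metric).
#' @export
cross_validate <- function(manifest, model_cfg = model_config(),
                           config = train_config(), k = 5L, repeats = 5L) {
  subjects <- unique(manifest$subject_id)
  assert_that(length(subjects) >= k, "fewer subjects than folds")
  data <- load_dataset(manifest, model_cfg$encoder$input_shape,
                       config$modalities)
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    rep_seed <- derive_seed(config$seed, "cv-repeat", rep_i)
    fold_of <- with_seed(rep_seed, {
      f <- rep_len(seq_len(k), length(subjects))
      stats::setNames(sample(f), sample(subjects))
    })
    for (fold in seq_len(k)) {
      test_ids <- names(fold_of)[fold_of == fold]
      train_ids <- setdiff(subjects, test_ids)
      plan <- structure(list(
        assignment = data.frame(
          subject_id = c(train_ids, test_ids),
          partition = rep(c("train", "test"),
                          c(length(train_ids), length(test_ids))),
          fold = NA_integer_, stringsAsFactors = FALSE),
        seed = rep_seed, k_folds = k), class = "split_plan")
      cfg_fold <- config
      cfg_fold$seed <- derive_seed(rep_seed, "fold", fold)
      cfg_fold$select_best <- FALSE
      fit <- train_model(NULL, manifest, plan, cfg_fold, model_cfg, data)
      m <- evaluate_model(fit$model,
                          manifest[manifest$subject_id %in% test_ids, ],
                          dataset_subset(data, test_ids))
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_i = rep_i, fold = fold, auc = m$auc, acc = m$acc,
        sensitivity = m$sensitivity, specificity = m$specificity,
        n_test = m$n_test)
    }
  }
  tab <- do.call(rbind, rows)
  metric_cols <- c("auc", "acc", "sensitivity", "specificity")
  summ <- data.frame(metric = metric_cols,
                     mean = vapply(tab[metric_cols], mean, 1, na.rm = TRUE),
                     sd = vapply(tab[metric_cols], stats::sd, 1,
                                 na.rm = TRUE))
  list(table = tab, summary = summ)
}

# ---- ablation harness ------------------------------------------------------

#' Standard ablation grid
#'
#' The four model variants contrasted in the ablation design: the plain
#' backbone (no positional encoding, plain attention pooling), the
#' backbone plus CLE, the backbone plus DGA, and the full model.
#' @return named list of (pos_encoding, pooling) pairs.
#' @export
ablation_variants <- function() {
  list(backbone = list(pos_encoding = "none", pooling = "attention"),
       cle = list(pos_encoding = "cle", pooling = "attention"),
       dga = list(pos_encoding = "none", pooling = "dga"),
       full = list(pos_encoding = "cle", pooling = "dga"))
}

#' Run an ablation / modality-combination grid
#'
#' Each grid cell fixes a model variant (positional encoding, pooling,
#' modality subset); each cell is trained and tested under the same set of
#' seeds so the contrasts are paired. A failing cell is recorded with NA
#' metrics and the run continues.
#'
#' @param manifest cohort manifest.
#' @param grid named list of cells, each a list with any of
#'   `pos_encoding`, `pooling`, `modalities`.
#' @param seeds integer vector of run seeds (one trained model per cell x
#'   seed).
#' @param model_cfg base [model_config()].
#' @param config base [train_config()].
#' @param ratios split ratios (default 0.6/0.2/0.2).
#' @return data.frame with one row per cell x seed and metric columns.
#' @export
run_ablation <- function(manifest, grid = ablation_variants(),
                         seeds = 1:5, model_cfg = model_config(),
                         config = train_config(),
                         ratios = c(0.6, 0.2, 0.2)) {
  base_data <- load_dataset(manifest, model_cfg$encoder$input_shape)
  rows <- list()
  for (cell_name in names(grid)) {
    cell <- grid[[cell_name]]
    cfg_m <- model_config(
      encoder = model_cfg$encoder,
      pos_encoding = cell$pos_encoding %||% model_cfg$pos_encoding,
      pooling = cell$pooling %||% model_cfg$pooling,
      d_pos = model_cfg$d_pos, pos_hidden = model_cfg$pos_hidden,
      n_freq = model_cfg$n_freq, att_hidden = model_cfg$att_hidden,
      lsvd_rank = model_cfg$lsvd_rank,
      att_dropout = model_cfg$att_dropout)
    mods <- cell$modalities %||% config$modalities
    for (seed in seeds) {
      res <- tryCatch({
        data <- if (identical(mods, MODALITIES)) base_data else
          lapply(base_data, function(d) {
            v <- restrict_modalities(d$volume, mods)
            list(subject_id = d$subject_id, volume = v,
                 x = volume_to_array(v), label = d$label)
          })
        plan <- make_splits(manifest, ratios, k_folds = 2L, seed = seed)
        cfg_t <- config
        cfg_t$seed <- seed
        cfg_t$modalities <- mods
        fit <- train_model(NULL, manifest, plan, cfg_t, cfg_m, data)
        test_ids <- split_subjects(plan, "test")
        m <- evaluate_model(fit$model,
                            manifest[manifest$subject_id %in% test_ids, ],
                            dataset_subset(data, test_ids))
        data.frame(cell = cell_name, seed = seed,
                   pos_encoding = cfg_m$pos_encoding,
                   pooling = cfg_m$pooling,
                   modalities = paste(mods, collapse = "+"),
                   auc = m$auc, acc = m$acc, sensitivity = m$sensitivity,
                   specificity = m$specificity, stringsAsFactors = FALSE)
      }, error = function(e) {
        warning(sprintf("ablation cell %s seed %d failed: %s", cell_name,
                        seed, conditionMessage(e)))
        data.frame(cell = cell_name, seed = seed,
                   pos_encoding = cfg_m$pos_encoding,
                   pooling = cfg_m$pooling,
                   modalities = paste(mods, collapse = "+"),
                   auc = NA_real_, acc = NA_real_, sensitivity = NA_real_,
                   specificity = NA_real_, stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}
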