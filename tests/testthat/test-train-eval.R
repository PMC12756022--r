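# Loss, metrics, the training loop contract, cross-validation and the
# ablation harness (full-scale training behavior is exercised in
# test-acceptance.R).

test_that("bag loss is mean binary cross-entropy", {
  expect_lt(mil_loss(c(0.999999, 1e-6), c(1, 0)), 1e-4)
  expect_equal(mil_loss(rep(0.5, 7), rep(c(0, 1), length.out = 7)), log(2))
  set.seed(1)
  p <- runif(20, 0.01, 0.99)
  y <- rbinom(20, 1, 0.5)
  oracle <- 0
  for (i in 1:20) oracle <- oracle - (y[i] * log(p[i]) +
                                        (1 - y[i]) * log(1 - p[i])) / 20
  expect_equal(mil_loss(p, y), oracle, tolerance = 1e-12)
  expect_error(mil_loss(c(0.2, 0.4), 1), "length")
  # exact 0/1 probabilities are clamped, not infinite
  expect_true(is.finite(mil_loss(c(0, 1), c(1, 0))))
})

test_that("AUC and confusion metrics match independent computations", {
  # perfect separation
  expect_equal(auc_trapezoid(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # hand-counted confusion at 0.5
  scores <- c(0.9, 0.6, 0.4, 0.3, 0.8, 0.2)
  labels <- c(1, 0, 1, 0, 1, 0)
  m <- eval_metrics(scores, labels)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$acc, 4 / 6)
  # ACC is recoverable from SEN, SPE and prevalence
  prev <- mean(labels)
  expect_equal(m$acc, m$sensitivity * prev + m$specificity * (1 - prev))
  # ROC is monotone
  expect_true(all(diff(m$roc$fpr) >= 0))
  expect_true(all(diff(m$roc$tpr) >= 0))
  # label-independent scores at large n: AUC near 1/2
  set.seed(2)
  s <- runif(500)
  y <- rbinom(500, 1, 0.5)
  expect_lt(abs(auc_trapezoid(s, y) - 0.5), 0.05)
  # single-class test set is flagged
  expect_warning(m1 <- eval_metrics(c(0.2, 0.8), c(1, 1)), "single-class")
  expect_true(is.na(m1$auc))
})

test_that("trapezoidal AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  for (rep in 1:5) {
    s <- rnorm(40)
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    ref <- suppressMessages(as.numeric(pROC::auc(y, s, direction = "<")))
    expect_equal(auc_trapezoid(s, y), ref, tolerance = 1e-10)
  }
})

test_that("a smoke training run completes, logs and is seed-reproducible", {
  man <- read_manifest(file.path(smoke_cohort_dir(), "manifest.tsv"))
  cfg <- smoke_model_config()
  tr <- train_config(epochs = 2L, learning_rate = 1e-3, seed = 5,
                     batch_size = 2L)
  split <- make_splits(man, c(0.5, 0.25, 0.25), k_folds = 2L, seed = 5)
  fit1 <- train_model(NULL, man, split, tr, cfg)
  expect_equal(nrow(fit1$history), 2L)
  expect_true(all(is.finite(fit1$history$train_loss)))
  fit2 <- train_model(NULL, man, split, tr, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)
})

test_that("the habmil S3 interface fits, prints and predicts", {
  man <- read_manifest(file.path(smoke_cohort_dir(), "manifest.tsv"))
  # the 8-subject smoke split can give a single-class test partition,
  # which eval_metrics legitimately warns about
  fit <- suppressWarnings(
    habmil(man, smoke_model_config(),
           train_config(epochs = 2L, learning_rate = 1e-3, seed = 1),
           split = make_splits(man, c(0.5, 0.25, 0.25), k_folds = 2L,
                               seed = 1)))
  expect_s3_class(fit, "habmil")
  expect_output(print(fit), "Hierarchical attention MIL")
  pr <- predict(fit)
  expect_equal(nrow(pr), 2L)   # the two test subjects
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  cf <- coef(fit)
  expect_equal(length(cf), fit$config$d_fused + 1L)
  expect_equal(length(residuals(fit)), 2L)
})

test_that("cross-validation keeps folds disjoint and aggregates correctly", {
  man <- read_manifest(file.path(smoke_cohort_dir(), "manifest.tsv"))
  cv <- cross_validate(man, smoke_model_config(),
                       train_config(epochs = 1L, learning_rate = 1e-3,
                                    seed = 2),
                       k = 2L, repeats = 2L)
  expect_equal(nrow(cv$table), 4L)   # 2 folds x 2 repeats
  # every subject tested exactly once per repeat
  expect_equal(sum(cv$table$n_test[cv$table$repeat_i == 1]), 8L)
  # aggregation matches an independent mean/sd
  expect_equal(cv$summary$mean[cv$summary$metric == "acc"],
               mean(cv$table$acc, na.rm = TRUE))
  expect_equal(cv$summary$sd[cv$summary$metric == "auc"],
               sd(cv$table$auc, na.rm = TRUE))
  expect_error(cross_validate(man[1:2, ], smoke_model_config(),
                              train_config(epochs = 1L), k = 5L),
               "fewer subjects")
})

test_that("the ablation harness runs a one-cell grid and restricts modalities", {
  man <- read_manifest(file.path(smoke_cohort_dir(), "manifest.tsv"))
  tab <- suppressWarnings(run_ablation(man, grid = list(flair_only = list(
    pos_encoding = "none", pooling = "mean", modalities = "flair")),
    seeds = 1L, model_cfg = smoke_model_config(),
    config = train_config(epochs = 1L, learning_rate = 1e-3),
    ratios = c(0.5, 0.25, 0.25)))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$modalities, "flair")
  expect_true(is.finite(tab$acc))
})
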