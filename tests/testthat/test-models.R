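# Base classifiers under the repeated stratified CV scheme, RMSE, and the
# dense embedding network.

test_that("rmse matches its closed forms and the recompute oracle", {
  expect_equal(rmse(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(rmse(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(rmse(c(0.5, 0.5), 1), "lengths")
  expect_error(rmse(c(-0.1, 0.5), c(0, 1)))
  set.seed(41)
  for (rep in 1:10) {
    p <- runif(30)
    y <- rbinom(30, 1, 0.5)
    expect_equal(rmse(p, y), oracle_rmse(p, y))
  }
})

test_that("a separable problem is solved perfectly by random forest", {
  set.seed(42)
  x <- rbind(matrix(rnorm(100, 0, 0.3), 50, 2),
             matrix(rnorm(100, 4, 0.3), 50, 2))
  colnames(x) <- c("d1", "d2")
  y <- rep(c("No", "Yes"), each = 50)
  r <- train_eval_classifier(x, y, "random-forest",
                             cv_config(folds = 5, repeats = 2, seed = 1))
  expect_equal(r$auc, 1)
  expect_equal(r$rates$tpr, c(1, 1))
  expect_equal(r$rates$fpr, c(0, 0))
  expect_lt(r$rmse_test, 0.2)
})

test_that("permuted labels give chance-level AUC", {
  set.seed(43)
  x <- matrix(rnorm(120 * 3), 120, 3, dimnames = list(NULL, letters[1:3]))
  aucs <- vapply(1:10, function(s) {
    y <- sample(rep(c("No", "Yes"), 60))
    train_eval_classifier(x, y, "naive-bayes",
                          cv_config(folds = 5, repeats = 1, seed = s))$auc
  }, 0)
  # null AUC standard error at the CV-build size, averaged over seeds
  n <- 120 * 0.7 / 2
  se_null <- sqrt((2 * n + 1) / (12 * n * n)) / sqrt(10)
  expect_lt(abs(mean(aucs) - 0.5), 3 * se_null + 0.01)
})

test_that("every classifier kind learns the planted lexicon signal", {
  feats <- shared_features()
  sel <- select_features(feats)
  x <- as.matrix(feats[, sel$selected, drop = FALSE])
  y <- feats$label
  cvq <- cv_config(folds = 5, repeats = 1, seed = 3)
  for (kind in c("naive-bayes", "random-forest", "svm", "adaboost",
                 "gaussian-process")) {
    r <- train_eval_classifier(x, y, kind, cvq)
    expect_gt(r$auc, 0.6)
    expect_true(r$rmse_train >= 0 && r$rmse_train <= 1)
    expect_true(r$rmse_test >= 0 && r$rmse_test <= 1)
  }
})

test_that("stratification failure on tiny folds is a clear error", {
  x <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  y <- c("Yes", rep("No", 5))
  expect_error(train_eval_classifier(x, y, "naive-bayes",
                                     cv_config(folds = 5, repeats = 1)),
               "stratification")
})

test_that("the network memorises a separable toy problem", {
  set.seed(44)
  x <- rbind(matrix(rnorm(60 * 8, -1, 0.5), 60, 8),
             matrix(rnorm(60 * 8, 1, 0.5), 60, 8))
  y <- rep(c(0, 1), each = 60)
  fit <- net_fit(x, y, net_config(hidden = c(16, 8), dropout = 0,
                                  epochs = 200, seed = 9))
  acc <- mean((predict(fit, x) >= 0.5) == y)
  expect_equal(acc, 1)
  expect_lt(tail(fit$loss_history, 1), 0.1)
})

test_that("extreme dropout degrades training accuracy", {
  set.seed(45)
  x <- rbind(matrix(rnorm(50 * 6, -1), 50, 6),
             matrix(rnorm(50 * 6, 1), 50, 6))
  y <- rep(c(0, 1), each = 50)
  f_low <- net_fit(x, y, net_config(hidden = c(16, 8), dropout = 0.2,
                                    epochs = 80, seed = 2))
  f_high <- net_fit(x, y, net_config(hidden = c(16, 8), dropout = 0.99,
                                     epochs = 80, seed = 2))
  acc <- function(f) mean((predict(f, x) >= 0.5) == y)
  expect_gt(acc(f_low), acc(f_high))
})

test_that("network training is deterministic given the seed", {
  set.seed(46)
  x <- matrix(rnorm(40 * 5), 40, 5)
  y <- rep(c(0, 1), 20)
  cfg <- net_config(hidden = c(8, 4), epochs = 30, seed = 5)
  f1 <- net_fit(x, y, cfg)
  f2 <- net_fit(x, y, cfg)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$W, f2$W)
})

test_that("the embedding-net pathway honours the shared evaluation contract", {
  set.seed(47)
  x <- rbind(matrix(rnorm(60 * 16, -0.5), 60, 16),
             matrix(rnorm(60 * 16, 0.5), 60, 16))
  y <- rep(c("No", "Yes"), each = 60)
  r <- train_eval_embedding_net(x, y,
                                net_config(hidden = c(8, 4), epochs = 40),
                                cv_config(folds = 4, repeats = 2, seed = 6))
  expect_s3_class(r, "somnia_model_result")
  expect_equal(r$approach, "embedding")
  expect_false(r$linear)
  expect_gt(r$auc, 0.8)
  expect_length(r$auc_by_repeat, 2)
  xna <- x; xna[1, 1] <- NA
  expect_error(train_eval_embedding_net(xna, y), "finite")
})

test_that("averaging over repeats stabilises the out-of-fold AUC", {
  set.seed(48)
  x <- rbind(matrix(rnorm(50 * 2, 0), 50, 2),
             matrix(rnorm(50 * 2, 0.8), 50, 2))
  colnames(x) <- c("a", "b")
  y <- rep(c("No", "Yes"), each = 50)
  r <- train_eval_classifier(x, y, "naive-bayes",
                             cv_config(folds = 5, repeats = 8, seed = 7))
  # repeats genuinely vary, and the repeat-averaged out-of-fold AUC sits
  # with (or above) the per-repeat AUCs rather than outside their spread
  expect_gt(sd(r$auc_by_repeat), 0)
  expect_gte(r$auc, min(r$auc_by_repeat))
  expect_lt(abs(r$auc - mean(r$auc_by_repeat)),
            3 * sd(r$auc_by_repeat) + 0.02)
  expect_equal(length(r$oof$prob), length(r$oof$y))
  expect_true(all(r$oof$prob >= 0 & r$oof$prob <= 1))
})
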