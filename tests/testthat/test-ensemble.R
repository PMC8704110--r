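# Double-weighted convex-combination ensemble.

test_that("weights derive from RMSE exactly", {
  expect_equal(model_weight(0), 1)
  expect_equal(model_weight(1), 0)
  expect_equal(model_weight(0.48), 0.52)
  expect_error(model_weight(1.2), "\\[0, 1\\]")
  expect_error(model_weight(-0.1), "\\[0, 1\\]")
})

test_that("split-weight combination is the convex form", {
  expect_equal(combine_split_weights(0.7, 0.3, 1), 0.7)
  expect_equal(combine_split_weights(0.7, 0.3, 0), 0.3)
  expect_equal(combine_split_weights(0.52, 0.38, 0.5), 0.45)
  for (lam in c(0, 0.25, 0.6, 1)) {
    expect_equal(combine_split_weights(0.41, 0.41, lam), 0.41)
  }
  expect_error(combine_split_weights(0.5, 0.5, 2))
})

test_that("ensemble prediction is the normalised weighted mean", {
  expect_equal(ensemble_predict(cbind(1, 1, 1), c(0.2, 0.5, 0.9))$score, 1)
  ep <- ensemble_predict(cbind(a = 0.9, b = 0.6, c = 0.3), c(1, 1, 1))
  expect_equal(ep$score, 0.6)
  expect_equal(ep$label, "Yes")
  set.seed(61)
  for (rep in 1:20) {
    Y <- matrix(runif(30), 10, 3)
    w <- runif(3)
    expect_equal(ensemble_predict(Y, w)$score, oracle_weighted_mean(Y, w))
  }
})

test_that("invalid component inputs are rejected by name", {
  expect_error(ensemble_predict(cbind(0.5, 0.5), c(0, 0)), "unusable")
  expect_error(ensemble_predict(cbind(0.5, NA), c(1, 1)), "missing")
  expect_error(ensemble_predict(cbind(1.2, 0.5), c(1, 1)), "probabilities")
  expect_error(ensemble_predict(cbind(0.5, 0.5), c(-1, 2)), "non-negative")
})

test_that("convexity, scaling, monotonicity and reduction hold on random draws", {
  set.seed(62)
  for (rep in 1:1000) {
    Y <- matrix(runif(9), 3, 3)
    w <- runif(3)
    s <- ensemble_predict(Y, w)$score
    expect_true(all(s >= apply(Y, 1, min) - 1e-12 &
                      s <= apply(Y, 1, max) + 1e-12))
    expect_equal(ensemble_predict(Y, 7.3 * w)$score, s)
  }
  set.seed(63)
  for (rep in 1:200) {
    Y <- matrix(runif(3), 1, 3)
    w <- runif(3) + 0.05
    s0 <- ensemble_predict(Y, w)$score
    Y2 <- Y
    Y2[2] <- min(1, Y2[2] + runif(1, 0, 1 - Y2[2]))
    expect_gte(ensemble_predict(Y2, w)$score, s0 - 1e-12)
    # one nonzero weight reduces to that component exactly
    expect_equal(ensemble_predict(Y, c(0, 1, 0))$score, Y[2])
  }
})

make_component_set <- function(y_train, y_test, wt_train, wt_test,
                               quality = c(1, 0, 0), seed = 1) {
  set.seed(seed)
  comp <- function(q, ap, kind) {
    noise_tr <- runif(length(y_train))
    noise_te <- runif(length(y_test))
    p_tr <- pmin(pmax(q * (0.98 * y_train + 0.01) + (1 - q) * noise_tr,
                      0), 1)
    p_te <- pmin(pmax(q * (0.98 * y_test + 0.01) + (1 - q) * noise_te,
                     0), 1)
    fake_result(ap, kind, p_tr, p_te, y_train, y_test, wt_train, wt_test)
  }
  list(lexicon = list(comp(quality[1], "lexicon", "naive-bayes")),
       embedding = list(comp(quality[2], "embedding", "embedding-net")),
       traits = list(comp(quality[3], "traits", "random-forest")))
}

test_that("one perfect component dominates the fitted ensemble", {
  set.seed(64)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  wt_train <- sort(sample.int(n, 180))
  wt_test <- setdiff(seq_len(n), wt_train)
  res <- make_component_set(y[wt_train], y[wt_test], wt_train, wt_test,
                            quality = c(1, 0, 0), seed = 64)
  ens <- fit_ensemble(res)
  a <- ensemble_auc(ens, y)
  perfect <- roc_auc(res$lexicon[[1]]$pred_test, y[wt_test])$auc
  expect_gte(a$auc_test, perfect - 0.02)
})

test_that("all-chance components give a chance-level ensemble", {
  set.seed(65)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  wt_train <- sort(sample.int(n, 240))
  wt_test <- setdiff(seq_len(n), wt_train)
  aucs <- vapply(1:10, function(s) {
    res <- make_component_set(y[wt_train], y[wt_test], wt_train, wt_test,
                              quality = c(0, 0, 0), seed = 600 + s)
    ensemble_auc(fit_ensemble(res), y)$auc_test
  }, 0)
  n1 <- sum(y[wt_test] == 1); n0 <- sum(y[wt_test] == 0)
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0)) / sqrt(10)
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.01)
})

test_that("mismatched weighting splits are an alignment error", {
  set.seed(66)
  y <- rbinom(100, 1, 0.5)
  res <- make_component_set(y[1:60], y[61:100], 1:60, 61:100)
  bad <- make_component_set(y[1:50], y[51:100], 1:50, 51:100)
  res$traits <- bad$traits
  expect_error(fit_ensemble(res), "alignment")
})

test_that("per-split best models and weights are assembled as documented", {
  set.seed(67)
  y <- rbinom(200, 1, 0.5)
  wt_train <- 1:120
  wt_test <- 121:200
  y_tr <- y[wt_train]; y_te <- y[wt_test]
  good_tr <- pmin(pmax(0.9 * y_tr + 0.05 + rnorm(120, 0, 0.02), 0), 1)
  bad_tr <- runif(120)
  good_te <- pmin(pmax(0.9 * y_te + 0.05 + rnorm(80, 0, 0.02), 0), 1)
  bad_te <- runif(80)
  # model A: good on train, bad on test; model B: the reverse
  a <- fake_result("lexicon", "naive-bayes", good_tr, bad_te,
                   y_tr, y_te, wt_train, wt_test)
  b <- fake_result("lexicon", "random-forest", bad_tr, good_te,
                   y_tr, y_te, wt_train, wt_test)
  other <- fake_result("traits", "svm", runif(120), runif(80),
                       y_tr, y_te, wt_train, wt_test)
  ens <- fit_ensemble(list(lexicon = list(a, b), traits = list(other)),
                      lambda = 0.5)
  w <- ens$weights[ens$weights$approach == "lexicon", ]
  expect_equal(w$model_train, "naive-bayes")
  expect_equal(w$model_test, "random-forest")
  expect_equal(w$w_train, 1 - a$rmse_train)
  expect_equal(w$w_test, 1 - b$rmse_test)
  expect_equal(w$w_combined,
               combine_split_weights(1 - a$rmse_train, 1 - b$rmse_test, 0.5))
})
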