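# Base-classifier suite and the validation scheme.
#
# Two split systems coexist, as in the study design: a 70/30 model-building
# holdout whose 70% side carries repeated stratified k-fold cross-validation
# (out-of-fold probabilities give AUC and per-class TPR/FPR), and an
# independent 60/40 "weighting" split on which each model's RMSE is measured
# per side to derive the ensemble weights W = 1 - RMSE. Both splits are
# functions of the labels and the CV seed only, so every feature family
# evaluated under the same configuration shares identical splits and the
# ensemble can align predictions user by user.

#' Cross-validation and split configuration
#'
#' @param folds number of CV folds (>= 2).
#' @param repeats CV repetitions.
#' @param holdout_fraction fraction held out of model building (default
#'   0.30: CV runs inside the remaining 70%).
#' @param weighting_split_fraction test-side fraction of the weighting split
#'   (default 0.40: weights derive from a 60/40 split).
#' @param seed RNG seed controlling all splits.
#' @return object of class `somnia_cv_config`.
#' @export
cv_config <- function(folds = 10, repeats = 10, holdout_fraction = 0.30,
                      weighting_split_fraction = 0.40, seed = 1) {
  stopifnot(folds >= 2, repeats >= 1,
            holdout_fraction > 0, holdout_fraction < 1,
            weighting_split_fraction > 0, weighting_split_fraction < 1)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 holdout_fraction = holdout_fraction,
                 weighting_split_fraction = weighting_split_fraction,
                 seed = as.integer(seed)),
            class = "somnia_cv_config")
}

#' Root-mean-square error of probabilistic predictions
#'
#' `sqrt(mean((p - y)^2))` for predicted positive-class probabilities
#' against binary labels; always in \[0, 1\], so `W = 1 - RMSE` is a valid
#' model weight.
#'
#' @param probs probabilities in \[0, 1\].
#' @param labels binary labels (0/1 or logical).
#' @return scalar RMSE.
#' @export
#' @examples
#' rmse(c(0.5, 0.5), c(0, 1))  # 0.5
rmse <- function(probs, labels) {
  labels <- as.numeric(labels)
  if (length(probs) != length(labels)) {
    stop("probs and labels have different lengths", call. = FALSE)
  }
  stopifnot(all(probs >= 0 & probs <= 1), all(labels %in% c(0, 1)))
  sqrt(mean((probs - labels)^2))
}

# stratified index sample: draw `fraction` of each class
stratified_sample <- function(y, fraction) {
  idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
    sample(ix, round(length(ix) * fraction))
  }), use.names = FALSE)
  sort(idx)
}

# fold assignment per repeat, stratified by class
stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (ix in split(seq_along(y), y)) {
    f[sample(ix)] <- rep_len(seq_len(folds), length(ix))
  }
  f
}

# All splits derive from cv$seed and the labels alone.
make_eval_plan <- function(y, cv) {
  set.seed(cv$seed)
  n <- length(y)
  build <- stratified_sample(y, 1 - cv$holdout_fraction)
  fold_ids <- lapply(seq_len(cv$repeats), function(r) {
    stratified_folds(y[build], cv$folds)
  })
  wt_train <- stratified_sample(y, 1 - cv$weighting_split_fraction)
  list(build = build, holdout = setdiff(seq_len(n), build),
       fold_ids = fold_ids, wt_train = wt_train,
       wt_test = setdiff(seq_len(n), wt_train))
}

linear_kinds <- function() {
  c("naive-bayes", "random-forest", "svm", "adaboost", "gaussian-process")
}

#' All supported base classifier kinds
#' @return character vector.
#' @export
classifier_kinds <- function() c(linear_kinds(), "embedding-net")

# fit/predict dispatch ------------------------------------------------------

fit_base <- function(x, y, kind, net = net_config(), seed = 1) {
  yf <- factor(ifelse(y == 1, "Yes", "No"), levels = c("No", "Yes"))
  df <- data.frame(x, check.names = FALSE)
  set.seed(seed)
  switch(kind,
    "naive-bayes" = e1071::naiveBayes(df, yf),
    "random-forest" = randomForest::randomForest(df, yf, ntree = 200),
    "svm" = e1071::svm(df, yf, probability = TRUE, kernel = "radial"),
    "adaboost" = ada_fit(x, y, rounds = 50),
    "gaussian-process" = {
      m <- NULL
      # gausspr narrates its kernel-width estimation; keep fits quiet
      utils::capture.output(m <- kernlab::gausspr(as.matrix(x), yf))
      m
    },
    "embedding-net" = net_fit(as.matrix(x), y,
                              within_seed(net, seed)),
    stop("unknown classifier kind: ", kind, call. = FALSE)
  )
}

within_seed <- function(net, seed) {
  net$seed <- as.integer(seed)
  net
}

predict_base <- function(model, x, kind) {
  df <- data.frame(x, check.names = FALSE)
  p <- switch(kind,
    "naive-bayes" = predict(model, df, type = "raw")[, "Yes"],
    "random-forest" = predict(model, df, type = "prob")[, "Yes"],
    "svm" = {
      pr <- predict(model, df, probability = TRUE)
      attr(pr, "probabilities")[, "Yes"]
    },
    "adaboost" = ada_predict(model, x),
    "gaussian-process" = kernlab::predict(model, as.matrix(x),
                                          type = "probabilities")[, "Yes", drop = TRUE],
    "embedding-net" = predict(model, as.matrix(x)),
    stop("unknown classifier kind: ", kind, call. = FALSE)
  )
  pmin(pmax(as.numeric(p), 0), 1)
}

# AdaBoost (SAMME with depth-one rpart stumps). Hand-rolled: weighted
# exponential-loss boosting of decision stumps, probability through the
# logistic of the additive margin.
ada_fit <- function(x, y, rounds = 50) {
  df <- data.frame(x, check.names = FALSE)
  df$.y <- factor(y, levels = c(0, 1))
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric()
  for (m in seq_len(rounds)) {
    fit <- rpart::rpart(.y ~ ., df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1,
                                                       minsplit = 2,
                                                       xval = 0))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y))
    if (err <= 1e-10) {
      stumps[[m]] <- fit
      alphas[m] <- 10
      break
    }
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit
    alphas[m] <- alpha
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
  }
  if (length(stumps) == 0) {
    # no stump beat chance: fall back to the prior
    return(structure(list(stumps = list(), alphas = numeric(),
                          prior = mean(y)), class = "somnia_ada"))
  }
  structure(list(stumps = stumps, alphas = alphas, prior = mean(y)),
            class = "somnia_ada")
}

ada_predict <- function(model, x) {
  df <- data.frame(x, check.names = FALSE)
  if (length(model$stumps) == 0) {
    return(rep(model$prior, nrow(df)))
  }
  score <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- as.integer(as.character(predict(model$stumps[[m]], df,
                                            type = "class")))
    score <- score + model$alphas[m] * (2 * pred - 1)
  }
  1 / (1 + exp(-2 * score))
}

# evaluation ----------------------------------------------------------------

classwise_rates <- function(probs, y, threshold = 0.5) {
  pos <- probs >= threshold
  data.frame(
    class = c("Yes", "No"),
    tpr = c(mean(pos[y == 1]), mean(!pos[y == 0])),
    fpr = c(mean(pos[y == 0]), mean(!pos[y == 1])),
    stringsAsFactors = FALSE
  )
}

#' Construct a model result
#'
#' The container shared by all evaluated models, and the unit the ensemble
#' consumes. Exposed so that externally produced predictions (another
#' toolchain, a reference model) can enter the ensemble under the same
#' contract.
#'
#' @param approach one of `"lexicon"`, `"embedding"`, `"traits"` (free-form
#'   allowed).
#' @param kind classifier kind.
#' @param auc out-of-fold AUC.
#' @param rates per-class TPR/FPR data.frame.
#' @param oof out-of-fold probability data.frame.
#' @param auc_by_repeat AUC per CV repeat.
#' @param rmse_train,rmse_test RMSE on the weighting-split sides.
#' @param pred_train,pred_test probabilities on the weighting-split sides.
#' @param wt_train,wt_test the weighting-split indices.
#' @param n sample size.
#' @return object of class `somnia_model_result`.
#' @export
model_result <- function(approach, kind, auc = NA_real_, rates = NULL,
                         oof = NULL, auc_by_repeat = NULL,
                         rmse_train, rmse_test,
                         pred_train, pred_test, wt_train, wt_test, n) {
  structure(list(approach = approach, kind = kind,
                 linear = kind %in% linear_kinds(),
                 auc = auc, rates = rates, oof = oof,
                 auc_by_repeat = auc_by_repeat,
                 rmse_train = rmse_train, rmse_test = rmse_test,
                 pred_train = pred_train, pred_test = pred_test,
                 wt_train = wt_train, wt_test = wt_test, n = n),
            class = "somnia_model_result")
}

#' @export
print.somnia_model_result <- function(x, ...) {
  cat("<model result> ", x$approach, " / ", x$kind,
      ": AUC ", round(x$auc, 3),
      ", RMSE train ", round(x$rmse_train, 3),
      " / test ", round(x$rmse_test, 3), "\n", sep = "")
  invisible(x)
}

#' Train and evaluate one base classifier
#'
#' Runs the full validation scheme on one feature family and classifier
#' kind: repeated stratified k-fold cross-validation inside the
#' model-building split (out-of-fold probabilities averaged over repeats
#' give the AUC and per-class TPR/FPR at threshold 0.5), then a single fit
#' on the 60% weighting side whose in-sample RMSE and held-out 40% RMSE
#' become the ensemble weight inputs.
#'
#' @param x numeric matrix or data.frame of (already selected) features.
#' @param y labels: "Yes"/"No", logical, or 0/1 (1 = insomniac).
#' @param kind one of [classifier_kinds()].
#' @param cv a [cv_config()].
#' @param net a [net_config()] (used when `kind = "embedding-net"`).
#' @param approach label recorded in the result.
#' @return a [model_result()].
#' @export
train_eval_classifier <- function(x, y, kind = "random-forest",
                                  cv = cv_config(), net = net_config(),
                                  approach = "lexicon") {
  kind <- match.arg(kind, classifier_kinds())
  if (is.data.frame(x)) {
    x <- as.matrix(x[, setdiff(names(x), c("user_id", "label")),
                     drop = FALSE])
  }
  y <- normalize_labels(y)
  stopifnot(nrow(x) == length(y))
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  plan <- make_eval_plan(y, cv)

  xb <- x[plan$build, , drop = FALSE]
  yb <- y[plan$build]
  oof <- matrix(NA_real_, length(yb), cv$repeats)
  auc_by_repeat <- numeric(cv$repeats)
  for (r in seq_len(cv$repeats)) {
    fid <- plan$fold_ids[[r]]
    for (k in seq_len(cv$folds)) {
      tr <- fid != k
      te <- fid == k
      if (length(unique(yb[tr])) < 2 || !any(te)) {
        stop("stratification failure: a fold lost a class (n too small ",
             "for ", cv$folds, " folds)", call. = FALSE)
      }
      fit <- fit_base(xb[tr, , drop = FALSE], yb[tr], kind, net,
                      seed = cv$seed + 1000L * r + k)
      oof[te, r] <- predict_base(fit, xb[te, , drop = FALSE], kind)
    }
    auc_by_repeat[r] <- roc_auc(oof[, r], yb)$auc
  }
  oof_mean <- rowMeans(oof)
  auc <- roc_auc(oof_mean, yb)$auc
  rates <- classwise_rates(oof_mean, yb)

  fit_w <- fit_base(x[plan$wt_train, , drop = FALSE], y[plan$wt_train],
                    kind, net, seed = cv$seed + 99991L)
  pred_train <- predict_base(fit_w, x[plan$wt_train, , drop = FALSE], kind)
  pred_test <- predict_base(fit_w, x[plan$wt_test, , drop = FALSE], kind)

  model_result(
    approach = approach, kind = kind, auc = auc, rates = rates,
    oof = data.frame(index = plan$build, prob = oof_mean, y = yb),
    auc_by_repeat = auc_by_repeat,
    rmse_train = rmse(pred_train, y[plan$wt_train]),
    rmse_test = rmse(pred_test, y[plan$wt_test]),
    pred_train = pred_train, pred_test = pred_test,
    wt_train = plan$wt_train, wt_test = plan$wt_test, n = length(y)
  )
}

#' Train and evaluate the embedding network
#'
#' The embedding pathway's counterpart of [train_eval_classifier()]:
#' validates the fixed-dimension input contract and runs the same scheme
#' with the dense network.
#'
#' @param embeddings numeric matrix of per-user embeddings (n x dimension).
#' @inheritParams train_eval_classifier
#' @return a [model_result()].
#' @export
train_eval_embedding_net <- function(embeddings, y, net = net_config(),
                                     cv = cv_config()) {
  stopifnot(is.matrix(embeddings))
  if (any(!is.finite(embeddings))) {
    stop("non-finite embedding input", call. = FALSE)
  }
  train_eval_classifier(embeddings, y, kind = "embedding-net", cv = cv,
                        net = net, approach = "embedding")
}

normalize_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    stopifnot(all(y %in% c("Yes", "No")))
    return(as.integer(y == "Yes"))
  }
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  y
}
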