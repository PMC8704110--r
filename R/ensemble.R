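# Double-weighted convex-combination ensemble.
#
# Each feature family (lexicon, embedding, traits) contributes the
# predictions of its best model, weighted by W = 1 - RMSE. Weights are
# computed on BOTH sides of the 60/40 weighting split — a model that shines
# in training but collapses out of sample is discounted — and the two
# split-wise weights are merged by a convex coefficient lambda. The final
# score is the weight-normalised linear combination
#   I_final = sum_m W_m Y_m / sum_m W_m,
# a probability in the convex hull of the component predictions, labelled
# "Yes" at the 0.5 threshold.

#' Model weight from RMSE
#'
#' `W = 1 - RMSE`. A perfect model (RMSE 0) carries weight 1; a maximally
#' wrong one carries 0.
#'
#' @param rmse_value RMSE in \[0, 1\].
#' @return weight in \[0, 1\].
#' @export
#' @examples
#' model_weight(0.48)  # 0.52
model_weight <- function(rmse_value) {
  stopifnot(is.numeric(rmse_value))
  if (any(rmse_value < 0 | rmse_value > 1)) {
    stop("rmse must lie in [0, 1]", call. = FALSE)
  }
  1 - rmse_value
}

#' Convex combination of split-wise weights
#'
#' `lambda * w_train + (1 - lambda) * w_test`.
#'
#' @param w_train,w_test weights from the training and test sides.
#' @param lambda convex coefficient in \[0, 1\]. The default 0.5 weighs both
#'   splits equally; 0.6 (the train-side split proportion) is the documented
#'   alternative.
#' @return combined weight.
#' @export
#' @examples
#' combine_split_weights(0.52, 0.38, 0.5)  # 0.45
combine_split_weights <- function(w_train, w_test, lambda = 0.5) {
  stopifnot(all(w_train >= 0 & w_train <= 1),
            all(w_test >= 0 & w_test <= 1),
            length(lambda) == 1, lambda >= 0, lambda <= 1)
  lambda * w_train + (1 - lambda) * w_test
}

#' Ensemble prediction from component probabilities
#'
#' Weight-normalised linear combination of the per-family predicted
#' probabilities, thresholded at 0.5. With normalised weights the score
#' always lies between the smallest and largest component prediction, and
#' scaling all weights by a positive constant leaves it unchanged.
#'
#' @param components numeric matrix, one column per approach (e.g.
#'   lexicon/embedding/traits), entries in \[0, 1\]; or a named list of
#'   equal-length probability vectors.
#' @param weights non-negative per-approach weights; must sum to a positive
#'   value.
#' @return list of class `somnia_ensemble_prediction`: `score`, `label`,
#'   `components`, `weights` (normalised).
#' @export
#' @examples
#' ensemble_predict(cbind(a = 0.9, b = 0.6, c = 0.3), c(1, 1, 1))$score
ensemble_predict <- function(components, weights) {
  if (is.list(components) && !is.data.frame(components)) {
    components <- do.call(cbind, components)
  }
  components <- as.matrix(components)
  stopifnot(is.numeric(components), is.numeric(weights),
            ncol(components) == length(weights))
  if (any(is.na(components))) {
    stop("missing component predictions", call. = FALSE)
  }
  if (any(components < 0 | components > 1)) {
    stop("component predictions must be probabilities in [0, 1]",
         call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  sw <- sum(weights)
  if (sw <= 0) {
    stop("unusable ensemble: all weights are zero", call. = FALSE)
  }
  w <- weights / sw
  score <- drop(components %*% w)
  structure(list(score = score,
                 label = ifelse(score >= 0.5, "Yes", "No"),
                 components = components, weights = w),
            class = "somnia_ensemble_prediction")
}

best_by <- function(results, field) {
  vals <- vapply(results, function(r) r[[field]], 0)
  # tie-break toward the linear model (then input order) for stability
  lin <- vapply(results, function(r) isTRUE(r$linear), TRUE)
  ord <- order(vals, !lin)
  ord[1]
}

#' Fit the double-weighted ensemble
#'
#' Consumes one or more evaluated [model_result()]s per approach, all from
#' the same weighting split. Per approach and split side, the best
#' (lowest-RMSE) model — linear or nonlinear, ties toward linear — supplies
#' that side's weight `W = 1 - RMSE` and predictions; the two weights merge
#' by [combine_split_weights()], and [ensemble_predict()] produces the final
#' scores on each side.
#'
#' @param results named list: approach name -> list of `somnia_model_result`
#'   (a bare `somnia_model_result` is accepted and wrapped).
#' @param lambda convex coefficient merging train- and test-side weights.
#' @return object of class `somnia_ensemble`: `weights` (data.frame per
#'   approach), `lambda`, per-side predictions (`train`, `test`), per-side
#'   ensemble AUC (`auc_train`, `auc_test`) and component AUCs
#'   (`component_auc`).
#' @export
fit_ensemble <- function(results, lambda = 0.5) {
  stopifnot(is.list(results), length(results) >= 2, !is.null(names(results)))
  results <- lapply(results, function(r) {
    if (inherits(r, "somnia_model_result")) list(r) else r
  })
  ok <- vapply(results, function(rl) {
    all(vapply(rl, inherits, TRUE, what = "somnia_model_result"))
  }, TRUE)
  if (!all(ok)) {
    stop("missing or invalid component results for approach: ",
         paste(names(results)[!ok], collapse = ", "), call. = FALSE)
  }

  ref <- results[[1]][[1]]
  for (ap in names(results)) {
    for (r in results[[ap]]) {
      if (!identical(r$wt_train, ref$wt_train) ||
          !identical(r$wt_test, ref$wt_test)) {
        stop("alignment error: approach '", ap,
             "' was evaluated on a different weighting split", call. = FALSE)
      }
    }
  }

  rows <- lapply(names(results), function(ap) {
    rl <- results[[ap]]
    bt <- best_by(rl, "rmse_train")
    be <- best_by(rl, "rmse_test")
    w_train <- model_weight(rl[[bt]]$rmse_train)
    w_test <- model_weight(rl[[be]]$rmse_test)
    data.frame(approach = ap,
               model_train = rl[[bt]]$kind, model_test = rl[[be]]$kind,
               rmse_train = rl[[bt]]$rmse_train,
               rmse_test = rl[[be]]$rmse_test,
               w_train = w_train, w_test = w_test,
               w_combined = combine_split_weights(w_train, w_test, lambda),
               stringsAsFactors = FALSE)
  })
  wdf <- do.call(rbind, rows)

  y_train <- vapply(names(results), function(ap) {
    results[[ap]][[best_by(results[[ap]], "rmse_train")]]$pred_train
  }, numeric(length(ref$pred_train)))
  y_test <- vapply(names(results), function(ap) {
    results[[ap]][[best_by(results[[ap]], "rmse_test")]]$pred_test
  }, numeric(length(ref$pred_test)))

  pred_train <- ensemble_predict(y_train, wdf$w_combined)
  pred_test <- ensemble_predict(y_test, wdf$w_combined)

  out <- list(weights = wdf, lambda = lambda,
              train = pred_train, test = pred_test,
              wt_train = ref$wt_train, wt_test = ref$wt_test)
  class(out) <- "somnia_ensemble"
  out
}

#' Evaluate an ensemble against labels
#'
#' AUCs of the ensemble and of each component on both weighting-split sides.
#'
#' @param ens a `somnia_ensemble`.
#' @param y full-cohort labels (the split indices stored in the ensemble
#'   select the relevant entries).
#' @return list: `auc_train`, `auc_test`, `component_auc_train`,
#'   `component_auc_test`.
#' @export
ensemble_auc <- function(ens, y) {
  y <- normalize_labels(y)
  y_tr <- y[ens$wt_train]
  y_te <- y[ens$wt_test]
  list(
    auc_train = roc_auc(ens$train$score, y_tr)$auc,
    auc_test = roc_auc(ens$test$score, y_te)$auc,
    component_auc_train = apply(ens$train$components, 2, function(p) {
      roc_auc(p, y_tr)$auc
    }),
    component_auc_test = apply(ens$test$components, 2, function(p) {
      roc_auc(p, y_te)$auc
    })
  )
}

#' @export
print.somnia_ensemble <- function(x, ...) {
  cat("<somnia_ensemble> lambda ", x$lambda, "\n", sep = "")
  print(x$weights, row.names = FALSE)
  invisible(x)
}
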