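# Independent brute-force oracles and shared fixtures. Oracles are written
# from the defining formulas, never by calling the implementation they check.

# AUC as the Mann-Whitney pair probability: P(score_pos > score_neg) with
# ties counted half, by explicit pair enumeration.
oracle_auc_pairs <- function(scores, y) {
  sp <- scores[y == 1]
  sn <- scores[y == 0]
  total <- 0
  for (a in sp) {
    total <- total + sum(a > sn) + 0.5 * sum(a == sn)
  }
  total / (length(sp) * length(sn))
}

oracle_rmse <- function(p, y) sqrt(sum((p - y)^2) / length(p))

oracle_fisher <- function(x, g) {
  lv <- unique(g)
  x1 <- x[g == lv[1]]
  x2 <- x[g == lv[2]]
  (mean(x1) - mean(x2))^2 /
    (sum((x1 - mean(x1))^2) / (length(x1) - 1) +
       sum((x2 - mean(x2))^2) / (length(x2) - 1))
}

oracle_maxmin <- function(x) (x - min(x)) / (max(x) - min(x))

oracle_weighted_mean <- function(Y, w) {
  out <- numeric(nrow(Y))
  for (i in seq_len(nrow(Y))) out[i] <- sum(Y[i, ] * w) / sum(w)
  out
}

# category percent score by naive double loop (handles trailing-* stems)
oracle_category_score <- function(tokens, words) {
  hits <- 0
  for (tok in tolower(tokens)) {
    matched <- FALSE
    for (w in words) {
      if (endsWith(w, "*")) {
        if (startsWith(tok, substr(w, 1, nchar(w) - 1))) matched <- TRUE
      } else if (tok == w) {
        matched <- TRUE
      }
      if (matched) break
    }
    hits <- hits + matched
  }
  100 * hits / length(tokens)
}

# shared small cohorts, generated once per test run
.fixture_env <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- generator_config(n_yes = 200, n_no = 200, seed = 42)
    .fixture_env$cohort <- generate_cohort(cfg)
  }
  .fixture_env$cohort
}

shared_preprocessed <- function() {
  if (is.null(.fixture_env$pp)) {
    .fixture_env$pp <- preprocess_corpus(shared_cohort()$docs)
  }
  .fixture_env$pp
}

shared_features <- function() {
  if (is.null(.fixture_env$feats)) {
    .fixture_env$feats <- lexicon_features(shared_preprocessed()$docs,
                                           shared_cohort()$users)
  }
  .fixture_env$feats
}

# tiny synthetic model-result builder for ensemble tests: all components
# share the same weighting split by construction
fake_result <- function(approach, kind, pred_train, pred_test,
                        y_train, y_test, wt_train, wt_test) {
  model_result(
    approach = approach, kind = kind,
    rmse_train = rmse(pred_train, y_train),
    rmse_test = rmse(pred_test, y_test),
    pred_train = pred_train, pred_test = pred_test,
    wt_train = wt_train, wt_test = wt_test,
    n = length(wt_train) + length(wt_test)
  )
}
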