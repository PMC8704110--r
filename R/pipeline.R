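# End-to-end pipeline: cohort -> preprocessing -> three feature families ->
# selection -> base models -> double-weighted ensemble.

#' Run the full insomnia-prediction pipeline
#'
#' Convenience wrapper chaining every stage on one cohort: preprocess and
#' seed-strip the documents, build lexicon category features (Fisher
#' selection then collinearity pruning), trait features (Fisher selection,
#' falling back to all five traits if none passes), and per-user hashed
#' embeddings; evaluate the requested classifiers per family and the dense
#' network on the embeddings; fit the double-weighted ensemble.
#'
#' @param cohort a `somnia_cohort` with documents, or a `somnia_config`
#'   (a cohort is then generated).
#' @param cv a [cv_config()].
#' @param net a [net_config()].
#' @param lex a `somnia_lexicon`.
#' @param classifiers classifier kinds evaluated on the lexicon and trait
#'   features.
#' @param backend embedding backend.
#' @param lambda ensemble convex coefficient.
#' @param fisher_threshold Fisher admission cutoff.
#' @param r_threshold collinearity cutoff.
#' @return list of class `somnia_pipeline`: cohort, preprocessing stats,
#'   feature objects, selection objects, per-family model results, the
#'   fitted ensemble and its AUCs.
#' @export
#' @examples
#' \donttest{
#' cfg <- generator_config(n_yes = 60, n_no = 60, max_docs_per_user = 10,
#'                         seed = 7)
#' pl <- run_insomnia_pipeline(cfg, cv = cv_config(folds = 5, repeats = 2),
#'                             net = net_config(epochs = 30))
#' pl$auc
#' }
run_insomnia_pipeline <- function(cohort,
                                  cv = cv_config(),
                                  net = net_config(),
                                  lex = default_lexicon(),
                                  classifiers = c("naive-bayes",
                                                  "random-forest"),
                                  backend = hashing_backend(),
                                  lambda = 0.5,
                                  fisher_threshold = 1.0,
                                  r_threshold = 0.7) {
  if (inherits(cohort, "somnia_config")) cohort <- generate_cohort(cohort)
  stopifnot(inherits(cohort, "somnia_cohort"), !is.null(cohort$docs))
  users <- cohort$users
  pp <- preprocess_corpus(cohort$docs)

  feats <- lexicon_features(pp$docs, users, lex)
  if (!identical(feats$user_id, users$user_id)) {
    keep <- users$user_id %in% feats$user_id
    users <- users[keep, , drop = FALSE]
  }
  y <- users$label

  sel <- select_features(feats, threshold = fisher_threshold)
  lex_cols <- sel$selected
  prune <- NULL
  if (length(lex_cols) >= 2) {
    prune <- collinearity_prune(
      as.matrix(feats[, lex_cols, drop = FALSE]), labels = y,
      r_threshold = r_threshold)
    lex_cols <- prune$retained
  }
  if (length(lex_cols) == 0) {
    warning("no lexicon feature survived selection; using all categories")
    lex_cols <- setdiff(names(feats), c("user_id", "label"))
  }
  x_lex <- as.matrix(feats[, lex_cols, drop = FALSE])

  trait_names <- c("openness", "conscientiousness", "extraversion",
                   "agreeableness", "neuroticism")
  x_traits_all <- as.matrix(users[, trait_names])
  sel_tr <- select_features(x_traits_all, labels = y,
                            threshold = fisher_threshold)
  tr_cols <- if (length(sel_tr$selected)) sel_tr$selected else trait_names
  x_traits <- x_traits_all[, tr_cols, drop = FALSE]

  emb <- embed_users(pp$docs, users, backend)

  res_lex <- lapply(classifiers, function(kind) {
    train_eval_classifier(x_lex, y, kind, cv, approach = "lexicon")
  })
  res_traits <- lapply(classifiers, function(kind) {
    train_eval_classifier(x_traits, y, kind, cv, approach = "traits")
  })
  res_emb <- list(train_eval_embedding_net(emb, y, net, cv))

  results <- list(lexicon = res_lex, embedding = res_emb,
                  traits = res_traits)
  ens <- fit_ensemble(results, lambda = lambda)
  auc <- ensemble_auc(ens, y)

  structure(list(cohort = cohort, users = users,
                 preprocess_stats = pp$stats,
                 features = feats, selection = sel, pruning = prune,
                 lexicon_columns = lex_cols, trait_columns = tr_cols,
                 embeddings = emb, results = results,
                 ensemble = ens, auc = auc),
            class = "somnia_pipeline")
}

#' @export
print.somnia_pipeline <- function(x, ...) {
  cat("<somnia_pipeline> ", nrow(x$users), " users\n", sep = "")
  cat("  lexicon features: ", paste(x$lexicon_columns, collapse = ", "),
      "\n", sep = "")
  cat("  trait features: ", paste(x$trait_columns, collapse = ", "),
      "\n", sep = "")
  cat("  ensemble AUC: train ", round(x$auc$auc_train, 3), ", test ",
      round(x$auc$auc_test, 3), "\n", sep = "")
  comp <- round(x$auc$component_auc_test, 3)
  cat("  component test AUC: ",
      paste(names(comp), comp, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
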