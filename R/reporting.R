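# Evaluation metrics and descriptive analyses: empirical ROC/AUC,
# Pearson chi-square on 2x2 contingency tables, fixed-bin trait
# distributions, and collapsed-Gibbs LDA topic models for subgroup corpora.

#' Empirical ROC curve and AUC
#'
#' AUC is computed as the Mann-Whitney pair statistic with midranks (exactly
#' the trapezoidal area over the tie-grouped empirical ROC), so it is
#' invariant under strictly monotone transformations of the scores and
#' equals 0.5 for constant scores.
#'
#' @param scores numeric scores, larger = more "Yes".
#' @param labels binary labels (1/"Yes" = positive); both classes required.
#' @return list: `auc`, `roc` (data.frame `fpr`, `tpr` over score
#'   thresholds), `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc  # 1
roc_auc <- function(scores, labels) {
  y <- normalize_labels(labels)
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  r <- rank(scores)  # midranks
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  grp <- cumsum(!duplicated(ss))
  tp <- cumsum(ys)
  fp <- cumsum(1 - ys)
  last <- !duplicated(grp, fromLast = TRUE)
  roc <- data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
  list(auc = auc, roc = roc, n_pos = n1, n_neg = n0)
}

#' Pearson chi-square test on a 2x2 table
#'
#' `X^2 = sum (O - E)^2 / E` with `df = 1` and an upper-tail p-value.
#' Continuity correction is off by default.
#'
#' @param table 2x2 matrix of non-negative counts; no zero marginals.
#' @param correct apply the Yates continuity correction.
#' @return list: `statistic`, `df`, `p_value`, `expected`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(309, 363, 511, 391), 2, byrow = TRUE))
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) {
    stop("a 2x2 table is required", call. = FALSE)
  }
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero marginal: expected counts undefined", call. = FALSE)
  }
  expected <- outer(rs, cs) / sum(table)
  dev <- abs(table - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  list(statistic = stat, df = 1L,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       expected = expected)
}

#' Fixed-bin trait distribution
#'
#' Bins trait scores into the five canonical ranges 0-0.2, 0.2-0.4, 0.4-0.6,
#' 0.6-0.8, 0.8-1.0. Bins are left-closed right-open with the last bin
#' closed, so a printed boundary such as 0.4 belongs to the upper range.
#'
#' @param values numeric vector in \[0, 1\].
#' @return data.frame: `bin`, `count`, `percent`; counts sum to
#'   `length(values)`.
#' @export
#' @examples
#' trait_bin_distribution(c(0.1, 0.5, 0.9, 0.95))
trait_bin_distribution <- function(values) {
  stopifnot(is.numeric(values), length(values) > 0)
  if (any(!is.finite(values)) || any(values < 0 | values > 1)) {
    stop("trait values must lie in [0, 1]", call. = FALSE)
  }
  # comparison against the literal edges, not division: 0.6/0.2 is not an
  # exact 3 in floating point
  idx <- findInterval(values, c(0, 0.2, 0.4, 0.6, 0.8, 1),
                      rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = 5L)
  data.frame(
    bin = c("0.0-0.2", "0.2-0.4", "0.4-0.6", "0.6-0.8", "0.8-1.0"),
    count = counts,
    percent = 100 * counts / length(values),
    stringsAsFactors = FALSE
  )
}

#' Latent Dirichlet allocation topics by collapsed Gibbs sampling
#'
#' Fits a k-topic LDA model to a corpus of cleaned documents with a
#' collapsed Gibbs sampler (compiled), deterministic given the seed.
#' Documents are tokenised on whitespace; the vocabulary is the set of
#' observed tokens and must contain at least `k` distinct words.
#'
#' @param texts character vector of documents (at least `k` of them).
#' @param k number of topics (default 5).
#' @param seed RNG seed.
#' @param iterations Gibbs sweeps.
#' @param alpha,beta symmetric Dirichlet hyperparameters on document-topic
#'   and topic-word distributions. Defaults (0.1, 0.1) favour the sparse
#'   mixtures expected of short subgroup corpora.
#' @param top_n words reported per topic.
#' @return object of class `somnia_lda`: `topics` (list of data.frames
#'   `word`/`probability`), `phi` (k x V topic-word matrix, rows sum to 1),
#'   `theta` (D x k document-topic matrix, rows sum to 1), `vocabulary`.
#' @export
lda_topics <- function(texts, k = 5, seed = 1, iterations = 300,
                       alpha = 0.1, beta = 0.1, top_n = 10) {
  stopifnot(is.character(texts), k >= 1, iterations >= 1,
            alpha > 0, beta > 0)
  texts <- texts[nzchar(trimws(texts))]
  if (length(texts) < k) {
    stop("need at least k = ", k, " non-empty documents", call. = FALSE)
  }
  toks <- strsplit(tolower(squeeze_ws(texts)), " ", fixed = TRUE)
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  if (length(vocab) < k) {
    stop("vocabulary (", length(vocab), " words) smaller than k = ", k,
         call. = FALSE)
  }
  doc <- rep.int(seq_along(toks), lengths(toks)) - 1L
  word <- match(unlist(toks, use.names = FALSE), vocab) - 1L
  set.seed(seed)
  fit <- lda_gibbs_cpp(doc, word, length(toks), length(vocab),
                       as.integer(k), alpha, beta, as.integer(iterations))
  phi <- (fit$nkw + beta) / (rowSums(fit$nkw) + length(vocab) * beta)
  theta <- (fit$ndk + alpha) / (rowSums(fit$ndk) + k * alpha)
  colnames(phi) <- vocab
  topics <- lapply(seq_len(k), function(t) {
    ord <- order(-phi[t, ])[seq_len(min(top_n, ncol(phi)))]
    data.frame(word = vocab[ord], probability = unname(phi[t, ord]),
               stringsAsFactors = FALSE)
  })
  structure(list(topics = topics, phi = phi, theta = theta,
                 vocabulary = vocab, k = k, alpha = alpha, beta = beta),
            class = "somnia_lda")
}

#' @export
print.somnia_lda <- function(x, ...) {
  cat("<somnia_lda> ", x$k, " topics over ", length(x$vocabulary),
      " words\n", sep = "")
  for (t in seq_along(x$topics)) {
    cat("  topic ", t, ": ",
        paste(head(x$topics[[t]]$word, 5), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
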