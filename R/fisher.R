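# Fisher-criterion feature selection and collinearity pruning.
#
# For a two-class problem the Fisher criterion of a single feature is
#   J = (mu1 - mu2)^2 / (s1^2 + s2^2),
# the squared between-class mean separation over the summed within-class
# variances. Features with J above a threshold (1.0 by convention) are
# admitted. J is invariant to affine rescaling of the feature and to
# swapping the class labels, and selection is monotone in the threshold.

split_classes <- function(labels) {
  lab <- as.character(labels)
  lv <- unique(lab)
  if (length(lv) != 2) {
    stop("Fisher criterion requires exactly two classes (got ",
         length(lv), ")", call. = FALSE)
  }
  list(a = lab == lv[1], b = lab == lv[2])
}

#' Fisher criterion of a single feature
#'
#' @param x numeric feature column.
#' @param labels two-class label vector, each class with >= 2 observations.
#' @return scalar `J >= 0`.
#' @export
#' @examples
#' fisher_score(c(0, 0, 1, 1), c("a", "a", "b", "b"))
fisher_score <- function(x, labels) {
  stopifnot(is.numeric(x), length(x) == length(labels))
  cls <- split_classes(labels)
  if (sum(cls$a) < 2 || sum(cls$b) < 2) {
    stop("each class needs at least 2 observations", call. = FALSE)
  }
  v <- var(x[cls$a]) + var(x[cls$b])
  if (v == 0) {
    stop("zero within-class variance: Fisher criterion undefined",
         call. = FALSE)
  }
  (mean(x[cls$a]) - mean(x[cls$b]))^2 / v
}

#' Select features by the Fisher criterion
#'
#' Scores every feature column and admits those with `J > threshold`. An
#' empty result is a warning, not an error (a data set can genuinely carry
#' no feature that strong).
#'
#' @param x numeric matrix or data.frame of features (non-feature columns
#'   `user_id`/`label` are ignored if present).
#' @param labels two-class label vector.
#' @param threshold admission cutoff (default 1.0).
#' @return list of class `somnia_fisher`: `selected` (character),
#'   `table` (data.frame feature/j/selected).
#' @export
select_features <- function(x, labels = NULL, threshold = 1.0) {
  if (is.data.frame(x)) {
    if (is.null(labels) && "label" %in% names(x)) labels <- x$label
    x <- x[, setdiff(names(x), c("user_id", "label")), drop = FALSE]
    x <- as.matrix(x)
  }
  stopifnot(is.matrix(x), !is.null(colnames(x)), !is.null(labels))
  j <- apply(x, 2, fisher_score, labels = labels)
  sel <- j > threshold
  if (!any(sel)) {
    warning("no feature exceeds the Fisher threshold ", threshold)
  }
  out <- list(selected = colnames(x)[sel],
              table = data.frame(feature = colnames(x), j = unname(j),
                                 selected = unname(sel),
                                 stringsAsFactors = FALSE),
              threshold = threshold)
  class(out) <- "somnia_fisher"
  out
}

#' @export
print.somnia_fisher <- function(x, ...) {
  cat("<fisher selection> ", length(x$selected), "/", nrow(x$table),
      " features with J > ", x$threshold, "\n", sep = "")
  tab <- x$table[order(-x$table$j), ]
  print(head(tab, 10), row.names = FALSE)
  invisible(x)
}

#' Greedy collinearity pruning
#'
#' Removes one member of every feature pair whose absolute Pearson
#' correlation reaches `r_threshold`, keeping the member with the higher
#' Fisher criterion. Implemented as a deterministic greedy pass in
#' descending-J order: a feature is retained only if it is not too
#' correlated with any already-retained feature. Constant features are
#' dropped first with a warning.
#'
#' @inheritParams select_features
#' @param r_threshold absolute-correlation cutoff (default 0.7).
#' @return list of class `somnia_collinearity`: `retained`, `dropped`
#'   (data.frame feature/reason/partner), `correlations` (matrix).
#' @export
collinearity_prune <- function(x, labels = NULL, r_threshold = 0.7) {
  if (is.data.frame(x)) {
    if (is.null(labels) && "label" %in% names(x)) labels <- x$label
    x <- as.matrix(x[, setdiff(names(x), c("user_id", "label")),
                     drop = FALSE])
  }
  stopifnot(is.matrix(x), ncol(x) >= 2, !is.null(colnames(x)),
            !is.null(labels))
  feats <- colnames(x)
  const <- apply(x, 2, function(v) var(v) == 0)
  dropped <- data.frame(feature = character(), reason = character(),
                        partner = character(), stringsAsFactors = FALSE)
  if (any(const)) {
    warning("constant feature(s) dropped: ",
            paste(feats[const], collapse = ", "))
    dropped <- rbind(dropped,
                     data.frame(feature = feats[const], reason = "constant",
                                partner = NA_character_,
                                stringsAsFactors = FALSE))
    x <- x[, !const, drop = FALSE]
    feats <- colnames(x)
  }
  j <- apply(x, 2, fisher_score, labels = labels)
  cm <- cor(x)
  # descending J; ties broken by original column order (stable)
  ord <- order(-j)
  retained <- character()
  for (f in feats[ord]) {
    partners <- retained[abs(cm[f, retained]) >= r_threshold]
    if (length(partners) == 0) {
      retained <- c(retained, f)
    } else {
      dropped <- rbind(dropped,
                       data.frame(feature = f, reason = "collinear",
                                  partner = partners[1],
                                  stringsAsFactors = FALSE))
    }
  }
  retained <- feats[feats %in% retained]  # restore column order
  out <- list(retained = retained, dropped = dropped, correlations = cm,
              r_threshold = r_threshold, j = j)
  class(out) <- "somnia_collinearity"
  out
}

#' @export
print.somnia_collinearity <- function(x, ...) {
  cat("<collinearity pruning> retained ", length(x$retained),
      ", dropped ", nrow(x$dropped), " at |r| >= ", x$r_threshold, "\n",
      sep = "")
  if (nrow(x$dropped)) print(x$dropped, row.names = FALSE)
  invisible(x)
}

#' Class-wise linear classification-function coefficients
#'
#' The classical discriminant-report companion to the Fisher criterion: for
#' each class k, coefficients `Sigma_pooled^-1 mu_k` and constant
#' `-mu_k' Sigma^-1 mu_k / 2 + log pi_k`, the per-class linear scoring
#' functions of normal-theory discriminant analysis. Emitted for report
#' parity; the selection rule itself operates on the one-dimensional
#' criterion J.
#'
#' @inheritParams select_features
#' @return matrix with one column per class; rows are features plus
#'   `(constant)`.
#' @export
classification_coefficients <- function(x, labels) {
  if (is.data.frame(x)) {
    if (missing(labels) && "label" %in% names(x)) labels <- x$label
    x <- as.matrix(x[, setdiff(names(x), c("user_id", "label")),
                     drop = FALSE])
  }
  lab <- as.character(labels)
  lv <- sort(unique(lab))
  stopifnot(length(lv) == 2, nrow(x) == length(lab))
  n <- nrow(x)
  mu <- lapply(lv, function(l) colMeans(x[lab == l, , drop = FALSE]))
  pooled <- Reduce(`+`, lapply(lv, function(l) {
    xs <- x[lab == l, , drop = FALSE]
    (nrow(xs) - 1) * stats::cov(xs)
  })) / (n - 2)
  inv <- solve(pooled)
  out <- vapply(seq_along(lv), function(k) {
    b <- inv %*% mu[[k]]
    c(b, -0.5 * drop(t(mu[[k]]) %*% b) + log(mean(lab == lv[k])))
  }, numeric(ncol(x) + 1))
  dimnames(out) <- list(c(colnames(x), "(constant)"), lv)
  out
}
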