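# Fixed-length sentence embeddings behind a pluggable backend contract.
#
# A backend is any object exposing a constant `dimension` and a
# deterministic `embed(texts)` returning one row per text. The default
# backend hashes token unigrams and bigrams into a signed 768-dimensional
# space and L2-normalises each document vector: fully offline and
# deterministic, it preserves the *shape* of the transformer-based pipeline
# (768-long per-document vectors, mean-pooled per user) so every downstream
# stage runs unchanged when a pretrained sentence encoder is attached behind
# the same contract.

hash_prime <- 2147483647  # 2^31 - 1; all modular products stay exact doubles

hash_weights <- function(mult, add, len = 256L) {
  (seq_len(len) * mult + add) %% hash_prime
}

# Polynomial string hash: sum of codepoint * weight (mod p). Exact in double
# arithmetic (max product ~2.3e15 < 2^53).
poly_hash <- function(strings, w) {
  lw <- length(w)
  vapply(strings, function(s) {
    cp <- utf8ToInt(s)
    sum((cp * w[(seq_along(cp) - 1L) %% lw + 1L]) %% hash_prime) %% hash_prime
  }, 0, USE.NAMES = FALSE)
}

#' Feature-hashing embedding backend
#'
#' Deterministic signed feature hashing of token n-grams into a fixed
#' `dimension`, L2-normalised per document. Same text always gives the same
#' vector; distinct texts collide with probability ~`1/dimension` per shared
#' coordinate only.
#'
#' @param dimension embedding length (default 768, matching transformer
#'   sentence encoders).
#' @param ngram maximum n-gram order (1 = unigrams only; default 2).
#' @return object of class `somnia_backend` with fields `name`, `dimension`
#'   and function `embed(texts)`.
#' @export
#' @examples
#' b <- hashing_backend()
#' v <- embed_tweet("wide awake at 3am", b)
#' length(v)  # 768
hashing_backend <- function(dimension = 768, ngram = 2) {
  dimension <- as.integer(dimension)
  stopifnot(dimension >= 1, ngram >= 1)
  w_idx <- hash_weights(2654435761, 1013904223)
  w_sign <- hash_weights(2246822519, 3266489917)

  embed <- function(texts) {
    stopifnot(is.character(texts), length(texts) > 0)
    if (any(is.na(texts) | !nzchar(trimws(texts)))) {
      stop("cannot embed empty text", call. = FALSE)
    }
    toks <- strsplit(tolower(squeeze_ws(texts)), " ", fixed = TRUE)
    grams <- lapply(toks, function(tk) {
      g <- tk
      if (ngram >= 2 && length(tk) >= 2) {
        for (k in 2:min(ngram, length(tk))) {
          idx <- seq_len(length(tk) - k + 1L)
          gk <- tk[idx]
          for (j in 1:(k - 1L)) gk <- paste(gk, tk[idx + j], sep = "_")
          g <- c(g, gk)
        }
      }
      g
    })
    all_grams <- unlist(grams, use.names = FALSE)
    ug <- unique(all_grams)
    dim_of <- poly_hash(ug, w_idx) %% dimension + 1L
    sign_of <- ifelse(poly_hash(ug, w_sign) %% 2 == 0, 1, -1)
    gi <- match(all_grams, ug)
    row <- rep.int(seq_along(grams), lengths(grams))
    m <- Matrix::sparseMatrix(i = row, j = dim_of[gi], x = sign_of[gi],
                              dims = c(length(texts), dimension))
    m <- as.matrix(m)
    nrm <- sqrt(rowSums(m^2))
    nrm[nrm == 0] <- 1  # all-gram cancellation: leave the zero vector
    m / nrm
  }

  structure(list(name = "hashing", dimension = dimension, ngram = ngram,
                 embed = embed),
            class = "somnia_backend")
}

#' @export
print.somnia_backend <- function(x, ...) {
  cat("<somnia_backend '", x$name, "'> dimension ", x$dimension, "\n",
      sep = "")
  invisible(x)
}

#' Embed a single document
#'
#' @param text non-empty character scalar.
#' @param backend a backend, e.g. [hashing_backend()].
#' @return numeric vector of length `backend$dimension`.
#' @export
embed_tweet <- function(text, backend = hashing_backend()) {
  stopifnot(inherits(backend, "somnia_backend"), length(text) == 1)
  drop(backend$embed(text))
}

#' Pool per-document vectors into a user embedding
#'
#' Unweighted arithmetic mean of the document vectors: permutation-invariant
#' and coordinate-wise bounded by the inputs.
#'
#' @param vectors matrix with one row per document.
#' @return numeric vector (the column means).
#' @export
user_embedding <- function(vectors) {
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  if (nrow(vectors) == 0) {
    stop("cannot pool an empty set of document vectors", call. = FALSE)
  }
  if (any(!is.finite(vectors))) stop("non-finite embedding", call. = FALSE)
  colMeans(vectors)
}

#' Per-user embedding matrix for a corpus
#'
#' Embeds every cleaned document and mean-pools per user. Every user in
#' `users` must have at least one document.
#'
#' @param pdocs cleaned document data.frame (column `text`).
#' @param users user table defining row order.
#' @param backend embedding backend.
#' @return numeric matrix, one row per user (rownames = user_id).
#' @export
embed_users <- function(pdocs, users, backend = hashing_backend()) {
  stopifnot(is.data.frame(pdocs), "text" %in% names(pdocs))
  missing <- setdiff(users$user_id, pdocs$user_id)
  if (length(missing)) {
    stop("no documents for user(s): ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  }
  m <- backend$embed(pdocs$text)
  f <- factor(pdocs$user_id, levels = users$user_id)
  sums <- rowsum(m, f)
  counts <- as.vector(table(f))
  out <- sums / counts
  rownames(out) <- users$user_id
  out
}
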