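# Two-hidden-layer dense network for the 768-d embedding pathway.
#
# The embedding classifier is a small feed-forward net on one fixed-length
# vector per user: first hidden layer with leaky rectifier activation,
# second hidden layer with tanh activation followed by (inverted) dropout,
# then a 2-unit softmax head trained with binary cross-entropy under the
# adaptive-moment (Adam) optimiser. On a single vector per example a
# convolution is width-one, so the architecture is implemented as dense
# layers with exactly the stated activation sequence.

#' Network configuration for the embedding classifier
#'
#' @param hidden integer 2-vector of hidden layer sizes.
#' @param dropout dropout rate on the second hidden activation, in \[0, 1).
#' @param leaky negative-slope coefficient of the leaky rectifier.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed RNG seed: initialisation, shuffling and dropout masks are
#'   deterministic given the seed.
#' @return object of class `somnia_net_config`.
#' @export
net_config <- function(hidden = c(64, 32), dropout = 0.2, leaky = 0.01,
                       epochs = 120, batch_size = 32, learning_rate = 1e-3,
                       seed = 1) {
  stopifnot(length(hidden) == 2, all(hidden >= 1),
            dropout >= 0, dropout < 1, epochs >= 1, batch_size >= 1,
            learning_rate > 0)
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 leaky = leaky, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "somnia_net_config")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fit the dense embedding network
#'
#' @param x numeric matrix (n x d), finite.
#' @param y binary labels (0/1 or logical), 1 = positive class.
#' @param config a [net_config()].
#' @return object of class `somnia_net`: weights, config and per-epoch mean
#'   training loss (`loss_history`).
#' @export
net_fit <- function(x, y, config = net_config()) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (any(!is.finite(x))) stop("non-finite network input", call. = FALSE)
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), length(y) == nrow(x))
  set.seed(config$seed)
  d <- ncol(x)
  h1 <- config$hidden[1]
  h2 <- config$hidden[2]
  init <- function(nin, nout) {
    matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  }
  W <- list(init(d, h1), init(h1, h2), init(h2, 2L))
  b <- list(numeric(h1), numeric(h2), numeric(2))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(bb) bb * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  keep <- 1 - config$dropout
  Y <- cbind(1 - y, y)
  n <- nrow(x)
  t_step <- 0
  loss_hist <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      xb <- x[bi, , drop = FALSE]
      yb <- Y[bi, , drop = FALSE]
      m <- nrow(xb)
      z1 <- sweep(xb %*% W[[1]], 2, b[[1]], `+`)
      a1 <- ifelse(z1 > 0, z1, config$leaky * z1)
      z2 <- sweep(a1 %*% W[[2]], 2, b[[2]], `+`)
      a2 <- tanh(z2)
      mask <- if (keep < 1) {
        matrix(runif(m * h2) < keep, m, h2) / keep
      } else 1
      a2d <- a2 * mask
      z3 <- sweep(a2d %*% W[[3]], 2, b[[3]], `+`)
      p <- softmax_rows(z3)
      ep_loss <- ep_loss - sum(yb * log(pmax(p, 1e-12))) / m

      dz3 <- (p - yb) / m
      dW3 <- t(a2d) %*% dz3
      db3 <- colSums(dz3)
      da2 <- (dz3 %*% t(W[[3]])) * mask
      dz2 <- da2 * (1 - a2^2)
      dW2 <- t(a1) %*% dz2
      db2 <- colSums(dz2)
      da1 <- dz2 %*% t(W[[2]])
      dz1 <- da1 * ifelse(z1 > 0, 1, config$leaky)
      dW1 <- t(xb) %*% dz1
      db1 <- colSums(dz1)

      gW <- list(dW1, dW2, dW3)
      gb <- list(db1, db2, db3)
      t_step <- t_step + 1
      for (l in 1:3) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb[[l]]^2
        mhW <- mW[[l]] / (1 - b1^t_step)
        vhW <- vW[[l]] / (1 - b2^t_step)
        mhb <- mb[[l]] / (1 - b1^t_step)
        vhb <- vb[[l]] / (1 - b2^t_step)
        W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
    }
    loss_hist[ep] <- ep_loss / length(batches)
  }
  structure(list(W = W, b = b, config = config, loss_history = loss_hist),
            class = "somnia_net")
}

#' Predict positive-class probabilities from a fitted network
#'
#' Dropout is inverted at training time, so prediction is a plain forward
#' pass.
#'
#' @param object a `somnia_net`.
#' @param x numeric matrix.
#' @param ... unused.
#' @return numeric vector of probabilities of the positive class.
#' @export
predict.somnia_net <- function(object, x, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  z1 <- sweep(x %*% object$W[[1]], 2, object$b[[1]], `+`)
  a1 <- ifelse(z1 > 0, z1, object$config$leaky * z1)
  a2 <- tanh(sweep(a1 %*% object$W[[2]], 2, object$b[[2]], `+`))
  p <- softmax_rows(sweep(a2 %*% object$W[[3]], 2, object$b[[3]], `+`))
  p[, 2]
}
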