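softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

mlp_forward <- function(W, X) {
  A1 <- tanh(sweep(X %*% W$W1, 2, W$b1, "+"))
  P <- softmax_rows(sweep(A1 %*% W$W2, 2, W$b2, "+"))
  list(A1 = A1, P = P)
}

# Mean cross-entropy gradient for the cases in X / one-hot Y.
mlp_grad <- function(W, X, Y) {
  fw <- mlp_forward(W, X)
  m <- nrow(X)
  dZ2 <- (fw$P - Y) / m
  dA1 <- dZ2 %*% t(W$W2)
  dZ1 <- dA1 * (1 - fw$A1^2)
  list(W1 = t(X) %*% dZ1, b1 = colSums(dZ1),
       W2 = t(fw$A1) %*% dZ2, b2 = colSums(dZ2))
}

#' Fit a single-hidden-layer tanh/softmax network
#'
#' Feedforward classifier matching the study's architecture: one hidden layer
#' with hyperbolic-tangent activation and a softmax output over the two risk
#' classes, trained on the full data set (no hold-out) by gradient descent on
#' the mean cross-entropy. The training mode controls update granularity:
#' `"batch"` uses the full gradient once per epoch, `"online"` updates after
#' every case (order reshuffled each epoch), `"minibatch"` after every
#' `batch_size` cases. Inputs are standardized internally. Deterministic given
#' `seed`.
#'
#' @param X numeric predictor matrix.
#' @param y binary response (0/1, logical, or 2-level factor; second level = 1).
#' @param hidden_units hidden-layer width; default half the input count,
#'   rounded up.
#' @param mode training mode.
#' @param seed seed for weight initialization and epoch shuffling.
#' @param epochs training epochs.
#' @param learn_rate step size; defaults per mode (batch 0.5, online 0.1,
#'   minibatch 0.2) chosen for stable descent on standardized inputs.
#' @param batch_size cases per mini-batch.
#' @param init_sd standard deviation of the normal weight initialization; 0
#'   gives symmetric (0.5, 0.5) initial outputs.
#' @return object of class `"mlp_model"`: weights, scaling, `mode`, `loss`
#'   (per-epoch mean cross-entropy), `fitted` (P(class 1)).
#' @export
mlp_fit <- function(X, y, hidden_units = NULL,
                    mode = c("batch", "online", "minibatch"),
                    seed = 1, epochs = 1000, learn_rate = NULL,
                    batch_size = 8, init_sd = 0.1) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop_bad("y must be binary")
  n <- nrow(X); p <- ncol(X)
  if (is.null(hidden_units)) hidden_units <- ceiling(p / 2)
  if (hidden_units < 1) stop_bad("need at least one hidden unit")
  if (is.null(learn_rate))
    learn_rate <- switch(mode, batch = 0.5, online = 0.1, minibatch = 0.2)

  sc <- apply(X, 2, sd); sc[sc == 0] <- 1
  ctr <- colMeans(X)
  Xs <- sweep(sweep(X, 2, ctr), 2, sc, "/")
  Y <- cbind(1 - y, y)

  set.seed(seed)
  W <- list(W1 = matrix(stats::rnorm(p * hidden_units, 0, init_sd), p),
            b1 = numeric(hidden_units),
            W2 = matrix(stats::rnorm(hidden_units * 2, 0, init_sd), hidden_units),
            b2 = numeric(2))
  loss <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx_groups <- switch(mode,
      batch = list(seq_len(n)),
      online = as.list(sample.int(n)),
      minibatch = split(sample.int(n), ceiling(seq_len(n) / batch_size)))
    for (idx in idx_groups) {
      g <- mlp_grad(W, Xs[idx, , drop = FALSE], Y[idx, , drop = FALSE])
      W$W1 <- W$W1 - learn_rate * g$W1; W$b1 <- W$b1 - learn_rate * g$b1
      W$W2 <- W$W2 - learn_rate * g$W2; W$b2 <- W$b2 - learn_rate * g$b2
    }
    P <- mlp_forward(W, Xs)$P
    loss[ep] <- -mean(log(pmax(P[cbind(seq_len(n), y + 1L)], 1e-300)))
    if (!is.finite(loss[ep]))
      stop_bad("training diverged (non-finite loss at epoch %d); reduce learn_rate", ep)
  }
  structure(list(weights = W, center = ctr, scale = sc, mode = mode,
                 hidden_units = hidden_units, loss = loss,
                 fitted = mlp_forward(W, Xs)$P[, 2], y = y),
            class = "mlp_model")
}

#' Predicted class-1 probabilities from a fitted network
#'
#' @param model an `"mlp_model"`.
#' @param X predictor matrix in the training column layout; omit for fitted
#'   values.
#' @return numeric vector of P(class 1).
#' @export
mlp_predict <- function(model, X = NULL) {
  stopifnot(inherits(model, "mlp_model"))
  if (is.null(X)) return(model$fitted)
  Xs <- sweep(sweep(as.matrix(X), 2, model$center), 2, model$scale, "/")
  mlp_forward(model$weights, Xs)$P[, 2]
}
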