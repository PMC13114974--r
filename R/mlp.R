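#' Multilayer-perceptron configuration
#'
#' One hidden layer with ReLU activation, inverted dropout, Huber loss, and
#' Adam or Nadam minibatch optimisation. The published architectures are
#' exposed as presets: [pb_mlp_config()] (4000 units, dropout 0, Adam,
#' batch 50, 5000 epochs, learning rate 1e-4) for the two-output
#' propionate/butyrate network and [total_mlp_config()] (1000 units,
#' dropout 0.1, Nadam, batch 30) for the single-output total-SCFA network.
#' [reduced_mlp_config()] is a desk-scale profile for tests and simulation
#' studies.
#'
#' @param hidden_units neurons in the hidden layer.
#' @param dropout hidden-layer dropout fraction in `[0, 1)`.
#' @param optimizer `"adam"` or `"nadam"`.
#' @param learning_rate Adam/Nadam step size.
#' @param huber_delta Huber loss transition point (mM residual scale).
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param lr_schedule `"constant"` or `"cosine"` (cosine decay of the
#'   learning rate to 1/100 of its initial value over the epochs).
#' @param seed integer seed for initialisation, shuffling and dropout.
#' @return An object of class `mlp_config`.
#' @export
mlp_config <- function(hidden_units = 4000, dropout = 0,
                       optimizer = c("adam", "nadam"),
                       learning_rate = 1e-4, huber_delta = 1,
                       batch_size = 50, epochs = 5000,
                       lr_schedule = c("constant", "cosine"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(hidden_units >= 1, dropout >= 0, dropout < 1,
            learning_rate > 0, huber_delta > 0, batch_size >= 1, epochs >= 1)
  structure(list(hidden_units = as.integer(hidden_units), dropout = dropout,
                 optimizer = optimizer, learning_rate = learning_rate,
                 huber_delta = huber_delta, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_schedule = lr_schedule,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' @rdname mlp_config
#' @param ... overrides passed to [mlp_config()].
#' @export
pb_mlp_config <- function(...) {
  do.call(mlp_config, utils::modifyList(
    list(hidden_units = 4000, dropout = 0, optimizer = "adam",
         learning_rate = 1e-4, batch_size = 50, epochs = 5000), list(...)))
}

#' @rdname mlp_config
#' @export
total_mlp_config <- function(...) {
  do.call(mlp_config, utils::modifyList(
    list(hidden_units = 1000, dropout = 0.1, optimizer = "nadam",
         learning_rate = 1e-4, batch_size = 30, epochs = 5000), list(...)))
}

#' @rdname mlp_config
#' @export
reduced_mlp_config <- function(...) {
  do.call(mlp_config, utils::modifyList(
    list(hidden_units = 200, dropout = 0.1, optimizer = "adam",
         learning_rate = 5e-3, batch_size = 16, epochs = 500,
         lr_schedule = "cosine"), list(...)))
}

.huber_grad <- function(r, delta) ifelse(abs(r) <= delta, r, delta * sign(r))
.huber_loss <- function(r, delta) {
  a <- abs(r)
  mean(ifelse(a <= delta, 0.5 * r^2, delta * (a - 0.5 * delta)))
}

#' Train a single-hidden-layer MLP regressor
#'
#' Plain matrix-algebra implementation: He-initialised weights, ReLU hidden
#' layer with inverted dropout, linear output, Huber loss, and Adam/Nadam
#' minibatch updates. Fully deterministic for a fixed `cfg$seed`.
#'
#' @param x numeric matrix of (scaled) inputs, one row per case.
#' @param y numeric matrix (or vector) of targets in mM.
#' @param cfg an [mlp_config()].
#' @return An object of class `scfa_mlp` with the fitted weights, the
#'   config, and the per-epoch training-loss `history`.
#' @export
train_mlp <- function(x, y, cfg = reduced_mlp_config()) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.matrix(y); storage.mode(y) <- "double"
  stopifnot(nrow(x) == nrow(y))
  n <- nrow(x); d <- ncol(x); o <- ncol(y); h <- cfg$hidden_units
  set.seed(cfg$seed)
  W1 <- matrix(stats::rnorm(d * h, 0, sqrt(2 / d)), d, h)
  b1 <- numeric(h)
  W2 <- matrix(stats::rnorm(h * o, 0, sqrt(2 / h)), h, o)
  b2 <- numeric(o)
  opt <- list(mW1 = W1 * 0, vW1 = W1 * 0, mb1 = b1 * 0, vb1 = b1 * 0,
              mW2 = W2 * 0, vW2 = W2 * 0, mb2 = b2 * 0, vb2 = b2 * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- cfg$learning_rate; nadam <- cfg$optimizer == "nadam"
  t_step <- 0
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    if (identical(cfg$lr_schedule, "cosine")) {
      frac <- (epoch - 1) / max(1, cfg$epochs - 1)
      lr <- cfg$learning_rate * (0.01 + 0.99 * 0.5 * (1 + cos(pi * frac)))
    }
    ord <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx, , drop = FALSE]
      nb <- length(idx)
      z1 <- sweep(xb %*% W1, 2, b1, "+")
      a1 <- pmax(z1, 0)
      if (cfg$dropout > 0) {
        mask <- matrix(stats::runif(nb * h) >= cfg$dropout, nb, h) /
          (1 - cfg$dropout)
        a1 <- a1 * mask
      }
      pred <- sweep(a1 %*% W2, 2, b2, "+")
      r <- pred - yb
      ep_loss <- ep_loss + .huber_loss(r, cfg$huber_delta) * nb
      g_out <- .huber_grad(r, cfg$huber_delta) / (nb * o)
      gW2 <- crossprod(a1, g_out)
      gb2 <- colSums(g_out)
      g_h <- g_out %*% t(W2)
      if (cfg$dropout > 0) g_h <- g_h * mask
      g_h <- g_h * (z1 > 0)
      gW1 <- crossprod(xb, g_h)
      gb1 <- colSums(g_h)
      t_step <- t_step + 1
      bc1 <- 1 - beta1^t_step; bc2 <- 1 - beta2^t_step
      step <- function(param, g, m_name, v_name) {
        opt[[m_name]] <<- beta1 * opt[[m_name]] + (1 - beta1) * g
        opt[[v_name]] <<- beta2 * opt[[v_name]] + (1 - beta2) * g^2
        mhat <- opt[[m_name]] / bc1
        if (nadam) mhat <- beta1 * mhat + (1 - beta1) * g / bc1
        vhat <- opt[[v_name]] / bc2
        param - lr * mhat / (sqrt(vhat) + eps)
      }
      W1 <- step(W1, gW1, "mW1", "vW1"); b1 <- step(b1, gb1, "mb1", "vb1")
      W2 <- step(W2, gW2, "mW2", "vW2"); b2 <- step(b2, gb2, "mb2", "vb2")
    }
    history[epoch] <- ep_loss / n
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, cfg = cfg,
                 history = history, n_inputs = d, n_outputs = o,
                 input_names = colnames(x), output_names = colnames(y)),
            class = "scfa_mlp")
}

#' Predict from a fitted MLP
#'
#' @param object a fitted `scfa_mlp`.
#' @param newdata numeric matrix of (scaled) inputs.
#' @param ... unused.
#' @return Numeric matrix of predictions, one row per input row.
#' @export
predict.scfa_mlp <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$n_inputs) stop("input dimension mismatch")
  a1 <- pmax(sweep(x %*% object$W1, 2, object$b1, "+"), 0)
  out <- sweep(a1 %*% object$W2, 2, object$b2, "+")
  colnames(out) <- object$output_names
  out
}

#' @export
print.scfa_mlp <- function(x, ...) {
  cat(sprintf("<scfa_mlp> %d -> %d(relu) -> %d, %s, final loss %.4g\n",
              x$n_inputs, x$cfg$hidden_units, x$n_outputs, x$cfg$optimizer,
              x$history[length(x$history)]))
  invisible(x)
}
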