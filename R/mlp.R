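# Internal multilayer-perceptron regressor.
#
# Fully connected tanh hidden layers with a linear output, trained by
# minibatch Adam on mean-squared error with an L2 weight penalty
# (weights only, not biases) and validation-based early stopping.
# Everything operates on already-standardized inputs/targets; scaling
# lives in the learned_map wrapper.

mlp_init <- function(layer_sizes) {
  nl <- length(layer_sizes) - 1L
  W <- vector("list", nl); b <- vector("list", nl)
  for (l in seq_len(nl)) {
    fan_in <- layer_sizes[l]; fan_out <- layer_sizes[l + 1L]
    sd0 <- sqrt(2 / (fan_in + fan_out))  # Glorot
    W[[l]] <- matrix(rnorm(fan_in * fan_out, sd = sd0), fan_in, fan_out)
    b[[l]] <- rep(0, fan_out)
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X) {
  nl <- length(par$W)
  A <- vector("list", nl + 1L)
  A[[1L]] <- X
  for (l in seq_len(nl)) {
    Z <- A[[l]] %*% par$W[[l]]
    Z <- sweep(Z, 2L, par$b[[l]], "+")
    A[[l + 1L]] <- if (l < nl) tanh(Z) else Z
  }
  A
}

mlp_predict_raw <- function(par, X) {
  nl <- length(par$W)
  A <- X
  for (l in seq_len(nl)) {
    Z <- A %*% par$W[[l]]
    Z <- sweep(Z, 2L, par$b[[l]], "+")
    A <- if (l < nl) tanh(Z) else Z
  }
  A
}

mlp_grad <- function(par, A, Tgt, l2) {
  nl <- length(par$W)
  n <- nrow(Tgt)
  gW <- vector("list", nl); gb <- vector("list", nl)
  delta <- 2 * (A[[nl + 1L]] - Tgt) / (n * ncol(Tgt))
  for (l in rev(seq_len(nl))) {
    gW[[l]] <- crossprod(A[[l]], delta) + 2 * l2 * par$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L) delta <- (delta %*% t(par$W[[l]])) * (1 - A[[l]]^2)
  }
  list(W = gW, b = gb)
}

mlp_mse <- function(par, X, Tgt) {
  P <- mlp_predict_raw(par, X)
  mean((P - Tgt)^2)
}

# Train; returns parameters of the best-validation epoch plus a history.
mlp_train <- function(X, Tgt, X_val, T_val, hidden = c(128L, 64L),
                      max_epochs = 1000L, l2 = 1e-4, learning_rate = 1e-3,
                      batch_size = 256L, patience = 50L, seed = NULL) {
  with_local_seed(seed, {
    layer_sizes <- c(ncol(X), hidden, ncol(Tgt))
    par <- mlp_init(layer_sizes)
    nl <- length(par$W)
    m <- lapply(par$W, function(w) w * 0); v <- m
    mb <- lapply(par$b, function(b) b * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    n <- nrow(X)
    batch_size <- min(batch_size, n)
    best_val <- Inf; best_par <- par; best_epoch <- 0L
    wait <- 0L; t_step <- 0L
    lr <- learning_rate; decay_wait <- max(10L, patience %/% 2L)
    val_hist <- numeric(0)
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        A <- mlp_forward(par, X[idx, , drop = FALSE])
        g <- mlp_grad(par, A, Tgt[idx, , drop = FALSE], l2)
        t_step <- t_step + 1L
        corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
        for (l in seq_len(nl)) {
          m[[l]] <- beta1 * m[[l]] + (1 - beta1) * g$W[[l]]
          v[[l]] <- beta2 * v[[l]] + (1 - beta2) * g$W[[l]]^2
          par$W[[l]] <- par$W[[l]] - lr * (m[[l]] / corr1) /
            (sqrt(v[[l]] / corr2) + eps)
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * g$b[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * g$b[[l]]^2
          par$b[[l]] <- par$b[[l]] - lr * (mb[[l]] / corr1) /
            (sqrt(vb[[l]] / corr2) + eps)
        }
      }
      val <- mlp_mse(par, X_val, T_val)
      val_hist <- c(val_hist, val)
      if (val < best_val - 1e-12) {
        best_val <- val; best_par <- par; best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
        if (wait %% decay_wait == 0L && lr > 1e-5) {
          # plateau: halve the step size and restart from the best weights
          lr <- lr / 2
          par <- best_par
          m <- lapply(par$W, function(w) w * 0); v <- m
          mb <- lapply(par$b, function(b) b * 0); vb <- mb
          t_step <- 0L
        }
      }
    }
    list(par = best_par, epochs_run = epoch, best_epoch = best_epoch,
         val_mse = best_val, val_history = val_hist)
  })
}
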