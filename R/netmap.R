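#' Training configuration for the learned maps
#'
#' Holds every knob of the neural-network surrogate trainer. The data split
#' follows the method's 70% training / 15% testing / 15% validation
#' convention with a maximum of 1000 epochs; the Bayesian-regularization
#' trainer of the original Matlab tooling is surrogated by an L2 weight
#' penalty combined with validation-based early stopping (same shrinkage
#' intent, portable everywhere).
#'
#' @param split Named fractions `c(train=, test=, val=)`; must be positive
#'   and sum to 1.
#' @param max_epochs Maximum training epochs (default 1000).
#' @param l2 L2 weight-decay strength (default 1e-4).
#' @param hidden Hidden-layer sizes (default `c(128, 64)`, tanh units).
#' @param learning_rate Adam step size (default 3e-3; halved on validation
#'   plateaus).
#' @param batch_size Minibatch size (default 256; clipped to n).
#' @param patience Early-stopping patience in epochs (default 100).
#' @param seed Integer seed controlling the split, weight initialization and
#'   minibatch order.
#' @return A `train_config` list.
#' @export
train_config <- function(split = c(train = 0.70, test = 0.15, val = 0.15),
                         max_epochs = 1000L, l2 = 1e-4,
                         hidden = c(128L, 64L), learning_rate = 3e-3,
                         batch_size = 256L, patience = 100L, seed = 1L) {
  if (length(split) != 3L || any(split <= 0) || abs(sum(split) - 1) > 1e-8)
    stop("`split` must be three positive fractions summing to 1", call. = FALSE)
  if (is.null(names(split))) names(split) <- c("train", "test", "val")
  if (max_epochs < 1L) stop("`max_epochs` must be >= 1", call. = FALSE)
  structure(list(split = split, max_epochs = as.integer(max_epochs), l2 = l2,
                 hidden = as.integer(hidden), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), seed = seed),
            class = "train_config")
}

#' Split samples into train / test / validation index sets
#'
#' Disjoint, exhaustive random split with sizes within one sample of the
#' target fractions (largest-remainder rounding), reproducible by the
#' config's seed.
#'
#' @param n Number of samples (`n >= 10`).
#' @param config A [train_config()].
#' @return List of integer index vectors `train`, `test`, `val`.
#' @export
split_data <- function(n, config = train_config()) {
  n <- as.integer(n)
  if (n < 10L) stop("need at least 10 samples to populate all three sets", call. = FALSE)
  fr <- config$split
  sizes <- floor(fr * n)
  rem <- fr * n - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    sizes[bump] <- sizes[bump] + 1L
  }
  if (any(sizes < 1L)) stop("`n` too small for the requested fractions", call. = FALSE)
  perm <- with_local_seed(config$seed, sample.int(n))
  ends <- cumsum(sizes)
  list(train = sort(perm[seq_len(ends[1L])]),
       test  = sort(perm[(ends[1L] + 1L):ends[2L]]),
       val   = sort(perm[(ends[2L] + 1L):ends[3L]]))
}

# shared scaling helpers ----------------------------------------------------

fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}
apply_scaler <- function(x, s) sweep(sweep(x, 2L, s$center, "-"), 2L, s$scale, "/")
invert_scaler <- function(x, s) sweep(sweep(x, 2L, s$scale, "*"), 2L, s$center, "+")

per_dim_r2 <- function(truth, pred) {
  vapply(seq_len(ncol(truth)), function(j) {
    if (sd(truth[, j]) == 0 || sd(pred[, j]) == 0) return(NA_real_)
    cor(truth[, j], pred[, j])^2
  }, numeric(1))
}

# core trainer shared by forward / inverse / cross maps
train_map <- function(x_in, y_out, direction, config, feature_axis = NULL,
                      embedding_method = NULL) {
  x_in <- as.matrix(x_in); y_out <- as.matrix(y_out)
  if (nrow(x_in) != nrow(y_out)) stop("row counts of inputs and targets differ", call. = FALSE)
  if (anyNA(x_in) || any(!is.finite(x_in)) || anyNA(y_out) || any(!is.finite(y_out)))
    stop("non-finite values in training data", call. = FALSE)
  idx <- split_data(nrow(x_in), config)
  sx <- fit_scaler(x_in[idx$train, , drop = FALSE])
  sy <- fit_scaler(y_out[idx$train, , drop = FALSE])
  Xs <- apply_scaler(x_in, sx)
  Ys <- apply_scaler(y_out, sy)
  fit <- mlp_train(Xs[idx$train, , drop = FALSE], Ys[idx$train, , drop = FALSE],
                   Xs[idx$val, , drop = FALSE], Ys[idx$val, , drop = FALSE],
                   hidden = config$hidden, max_epochs = config$max_epochs,
                   l2 = config$l2, learning_rate = config$learning_rate,
                   batch_size = config$batch_size, patience = config$patience,
                   seed = config$seed)
  # constant-predictor baseline on the validation split
  base_val <- mean(sweep(Ys[idx$val, , drop = FALSE], 2L,
                         colMeans(Ys[idx$train, , drop = FALSE]), "-")^2)
  if (fit$val_mse >= base_val)
    warning("training failed to beat the constant-predictor baseline on validation data",
            call. = FALSE)
  pred_all <- invert_scaler(mlp_predict_raw(fit$par, Xs), sy)
  diagnostics <- list(
    r2_train = per_dim_r2(y_out[idx$train, , drop = FALSE], pred_all[idx$train, , drop = FALSE]),
    r2_val   = per_dim_r2(y_out[idx$val, , drop = FALSE], pred_all[idx$val, , drop = FALSE]),
    r2_test  = per_dim_r2(y_out[idx$test, , drop = FALSE], pred_all[idx$test, , drop = FALSE]),
    epochs_run = fit$epochs_run, best_epoch = fit$best_epoch,
    val_mse = fit$val_mse, baseline_val_mse = base_val)
  if (direction == "inverse") {
    sr2 <- spectral_r2(y_out[idx$test, , drop = FALSE], pred_all[idx$test, , drop = FALSE])
    diagnostics$spectral_r2_test <- mean(sr2, na.rm = TRUE)
    diagnostics$spectral_r2_test_median <- stats::median(sr2, na.rm = TRUE)
  }
  structure(list(direction = direction,
                 input_dim = ncol(x_in), output_dim = ncol(y_out),
                 weights = fit$par,
                 x_scaler = sx, y_scaler = sy,
                 split = idx, config = config,
                 feature_axis = feature_axis,
                 embedding_method = embedding_method,
                 diagnostics = diagnostics),
            class = "learned_map")
}

#' Train the forward map: features to embedding coordinates
#'
#' Fits a multilayer perceptron that reproduces the reference embedding from
#' the high-dimensional feature vectors of the subset, so the remaining (and
#' any future) samples can be placed in the same reduced space without
#' re-running t-SNE/UMAP. Targets are the unit-cube normalized coordinates;
#' if `e` is not yet normalized it is normalized internally.
#'
#' @param x [feature_matrix()] (or matrix) of the embedded subset.
#' @param e The subset's [embedding()].
#' @param config A [train_config()].
#' @return A `learned_map` with `direction = "forward"`; held-out
#'   per-dimension r-squared lives in `$diagnostics$r2_test` (see [tidy()]
#'   and [glance()] methods).
#' @export
fit_forward <- function(x, e, config = train_config()) {
  stopifnot(inherits(e, "embedding"))
  if (!e$normalized) e <- normalize_embedding(e)
  xm <- as_plain_matrix(as.matrix(x))
  if (nrow(xm) != nrow(e$coords)) stop("row counts of `x` and `e` differ", call. = FALSE)
  train_map(xm, e$coords, "forward", config,
            feature_axis = if (inherits(x, "feature_matrix")) feature_axis(x),
            embedding_method = e$method)
}

#' Train the inverse map: embedding coordinates to features
#'
#' The reverse direction of [fit_forward()]: predicts a full feature vector
#' (a pseudo-spectrum) from any point of the reduced space, enabling
#' spectral-contribution queries at arbitrary coordinates. Held-out fidelity
#' is summarized as the mean squared Pearson correlation between true and
#' reconstructed feature vectors (`$diagnostics$spectral_r2_test`) alongside
#' per-feature r-squared.
#'
#' @inheritParams fit_forward
#' @return A `learned_map` with `direction = "inverse"`.
#' @export
fit_inverse <- function(e, x, config = train_config()) {
  stopifnot(inherits(e, "embedding"))
  if (!e$normalized) e <- normalize_embedding(e)
  xm <- as_plain_matrix(as.matrix(x))
  if (nrow(xm) != nrow(e$coords)) stop("row counts of `e` and `x` differ", call. = FALSE)
  train_map(e$coords, xm, "inverse", config,
            feature_axis = if (inherits(x, "feature_matrix")) feature_axis(x),
            embedding_method = e$method)
}

#' Apply a learned map to new data
#'
#' Deterministic batched evaluation of a trained map. Rows are processed in
#' chunks so arbitrarily large inputs can be streamed; results are
#' independent of `chunk_size`.
#'
#' @param object A `learned_map`.
#' @param newdata Matrix whose column count equals `object$input_dim`.
#' @param chunk_size Rows per evaluation chunk (default 10000). Results are
#'   independent of the chunk size up to last-ulp floating-point rounding
#'   (the BLAS selects different kernels for different matrix shapes).
#' @param ... Unused.
#' @return Matrix with `object$output_dim` columns. For forward/cross maps
#'   these are unit-cube embedding coordinates; for inverse maps, feature
#'   intensities.
#' @export
predict.learned_map <- function(object, newdata, chunk_size = 10000L, ...) {
  x <- as_plain_matrix(as.matrix(newdata))
  if (ncol(x) != object$input_dim)
    stop(sprintf("input has %d columns, map expects %d", ncol(x), object$input_dim),
         call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite values in input", call. = FALSE)
  n <- nrow(x)
  out <- matrix(NA_real_, n, object$output_dim)
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    xs <- apply_scaler(x[idx, , drop = FALSE], object$x_scaler)
    out[idx, ] <- invert_scaler(mlp_predict_raw(object$weights, xs), object$y_scaler)
  }
  rownames(out) <- rownames(newdata)
  out
}

#' @export
print.learned_map <- function(x, ...) {
  cat(sprintf("<learned_map> %s: %d -> %d (hidden %s; %d epochs, best %d)\n",
              x$direction, x$input_dim, x$output_dim,
              paste(x$config$hidden, collapse = "x"),
              x$diagnostics$epochs_run, x$diagnostics$best_epoch))
  r2 <- x$diagnostics$r2_test
  cat("  held-out r2:", paste(sprintf("%.4f", r2[seq_len(min(5, length(r2)))]), collapse = " "),
      if (length(r2) > 5) "..." else "", "\n")
  if (!is.null(x$diagnostics$spectral_r2_test))
    cat(sprintf("  held-out spectral r2 (mean): %.4f\n", x$diagnostics$spectral_r2_test))
  invisible(x)
}

#' @rdname predict.learned_map
#' @method tidy learned_map
#' @export
tidy.learned_map <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(dimension = seq_along(d$r2_test),
                 r2_train = d$r2_train, r2_val = d$r2_val, r2_test = d$r2_test)
}

#' @rdname predict.learned_map
#' @method glance learned_map
#' @export
glance.learned_map <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(direction = x$direction,
                 input_dim = x$input_dim, output_dim = x$output_dim,
                 min_r2_test = min(d$r2_test, na.rm = TRUE),
                 spectral_r2_test = d$spectral_r2_test %||% NA_real_,
                 epochs_run = d$epochs_run, best_epoch = d$best_epoch,
                 val_mse = d$val_mse)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a learned map to a single JSON file
#'
#' Weights, scalers, configuration and diagnostics are written to one
#' documented JSON container so a map can be applied in a separate process.
#'
#' @param map A `learned_map`.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly; [read_learned_map()] returns the `learned_map`.
#' @export
write_learned_map <- function(map, path) {
  stopifnot(inherits(map, "learned_map"))
  payload <- list(
    container = "netembed.learned_map", version = 1L,
    direction = map$direction, input_dim = map$input_dim,
    output_dim = map$output_dim,
    hidden = map$config$hidden,
    weights = lapply(map$weights$W, unclass),
    biases = map$weights$b,
    x_scaler = map$x_scaler, y_scaler = map$y_scaler,
    config = map$config[setdiff(names(map$config), "split")],
    split_fractions = map$config$split,
    feature_axis = map$feature_axis,
    embedding_method = map$embedding_method,
    diagnostics = map$diagnostics)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_learned_map
#' @export
read_learned_map <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$container, "netembed.learned_map"))
    stop("not a netembed learned_map file: ", path, call. = FALSE)
  cfg <- p$config
  cfg$split <- unlist(p$split_fractions)
  config <- train_config(split = cfg$split, max_epochs = cfg$max_epochs,
                         l2 = cfg$l2, hidden = cfg$hidden,
                         learning_rate = cfg$learning_rate,
                         batch_size = cfg$batch_size, patience = cfg$patience,
                         seed = cfg$seed)
  W <- lapply(p$weights, function(w) {
    w <- as.matrix(w); storage.mode(w) <- "double"; w
  })
  b <- p$biases
  if (is.matrix(b)) b <- lapply(seq_len(nrow(b)), function(i) as.numeric(b[i, ]))
  b <- lapply(b, as.numeric)
  diagnostics <- p$diagnostics
  structure(list(direction = p$direction,
                 input_dim = as.integer(p$input_dim),
                 output_dim = as.integer(p$output_dim),
                 weights = list(W = W, b = b),
                 x_scaler = lapply(p$x_scaler, as.numeric),
                 y_scaler = lapply(p$y_scaler, as.numeric),
                 split = NULL, config = config,
                 feature_axis = p$feature_axis,
                 embedding_method = p$embedding_method,
                 diagnostics = diagnostics),
            class = "learned_map")
}
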