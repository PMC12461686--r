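#' Correlation distance between sample vectors
#'
#' `1 - Pearson correlation` between every pair of rows, the metric used for
#' both t-SNE and UMAP reference embeddings. Samples with zero variance
#' across features have no defined correlation and raise an error rather
#' than silently producing NaN.
#'
#' @param x Numeric matrix (samples x features).
#' @return A `dist` object of length `n(n-1)/2`.
#' @export
correlation_dist <- function(x) {
  x <- as_plain_matrix(as.matrix(x))
  if (anyNA(x) || any(!is.finite(x))) stop("input contains non-finite values", call. = FALSE)
  xc <- x - rowMeans(x)
  ss <- sqrt(rowSums(xc^2))
  if (any(ss == 0)) stop("zero-variance sample vector: correlation distance undefined", call. = FALSE)
  d <- 1 - tcrossprod(xc / ss)
  d[d < 0] <- 0  # guard tiny negative rounding
  stats::as.dist(d)
}

#' Reference nonlinear embedding of a data subset
#'
#' Embeds the (subsampled) data with exact t-SNE or UMAP under the
#' correlation distance metric. Defaults follow the method's standard
#' parameterization: t-SNE with perplexity 30, early exaggeration 4 and the
#' exact (non-approximated) algorithm; UMAP with 30 nearest neighbours and
#' minimum distance 0.3; three output dimensions for RGB rendering (two
#' supported).
#'
#' Both backends receive the same precomputed correlation-distance matrix,
#' which is what makes them interchangeable downstream: everything after
#' this step consumes only an [embedding()].
#'
#' @param x [feature_matrix()] or plain matrix (the subset to embed).
#' @param method `"tsne"` or `"umap"`.
#' @param dims Output dimensionality, 2 or 3 (default 3).
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @param perplexity,exaggeration t-SNE parameters (defaults 30 and 4).
#' @param n_neighbors,min_dist UMAP parameters (defaults 30 and 0.3).
#' @param max_iter t-SNE gradient-descent iterations (default 1000).
#' @param seed Integer seed; fixed seed + fixed backend version gives
#'   reproducible coordinates.
#' @return An [embedding()] whose row order matches the input sample order.
#' @export
embed_reference <- function(x, method = c("tsne", "umap"), dims = 3L,
                            metric = c("correlation", "euclidean"),
                            perplexity = 30, exaggeration = 4,
                            n_neighbors = 30L, min_dist = 0.3,
                            max_iter = 1000L, seed = NULL) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  xm <- as_plain_matrix(as.matrix(x))
  if (anyNA(xm) || any(!is.finite(xm))) stop("input contains non-finite values", call. = FALSE)
  dims <- as.integer(dims)
  if (!dims %in% c(2L, 3L)) stop("`dims` must be 2 or 3", call. = FALSE)
  n <- nrow(xm)
  d <- if (metric == "correlation") correlation_dist(xm) else stats::dist(xm)

  if (method == "tsne") {
    if (perplexity <= 0) stop("perplexity must be positive", call. = FALSE)
    if (n - 1L < 3 * perplexity)
      stop(sprintf("perplexity %g too large for %d samples (need n-1 >= 3*perplexity)",
                   perplexity, n), call. = FALSE)
    fit <- with_local_seed(seed,
      Rtsne::Rtsne(as.matrix(d), dims = dims, perplexity = perplexity, theta = 0,
                   exaggeration_factor = exaggeration, max_iter = max_iter,
                   is_distance = TRUE, pca = FALSE, verbose = FALSE,
                   num_threads = 1L))
    co <- fit$Y
    params <- list(metric = metric, perplexity = perplexity,
                   exaggeration = exaggeration, max_iter = max_iter,
                   algorithm = "exact", seed = seed)
  } else {
    n_neighbors <- as.integer(n_neighbors)
    if (n_neighbors < 2L) stop("n_neighbors must be >= 2", call. = FALSE)
    if (min_dist <= 0 || min_dist >= 1) stop("min_dist must lie in (0, 1)", call. = FALSE)
    if (n <= n_neighbors)
      stop(sprintf("n_neighbors %d too large for %d samples", n_neighbors, n), call. = FALSE)
    co <- with_local_seed(seed,
      uwot::umap(d, n_components = dims, n_neighbors = n_neighbors,
                 min_dist = min_dist, n_threads = 1L, n_sgd_threads = 0L,
                 verbose = FALSE))
    params <- list(metric = metric, n_neighbors = n_neighbors,
                   min_dist = min_dist, seed = seed)
  }
  ids <- if (inherits(x, "feature_matrix")) sample_ids(x) else rownames(xm)
  embedding(co, method = method, params = params, sample_ids = ids)
}
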