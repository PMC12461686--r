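#' Subset selection for the reference embedding
#'
#' Large datasets cannot be embedded directly; a subset is selected, embedded,
#' and used to train the neural-network surrogates. `every_nth()` is the
#' deterministic scheme (every n-th sample starting from the first, so the
#' selection size is `ceiling(n_total / n)`); `random_subset()` draws `k`
#' unique indices reproducibly for a fixed seed.
#'
#' Indices are 1-based.
#'
#' @param n_total Number of samples in the full dataset.
#' @param n Step of the deterministic scheme (`n >= 1`).
#' @param k Size of the random subset (`1 <= k <= n_total`).
#' @param seed Integer seed for the random scheme.
#' @return A `subsample_result`: list with `indices` (strictly increasing),
#'   `n_total`, `scheme` and `parameters`.
#' @export
every_nth <- function(n_total, n) {
  n_total <- as.integer(n_total); n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (is.na(n_total) || n_total < 1L) stop("`n_total` must be >= 1", call. = FALSE)
  idx <- seq.int(1L, n_total, by = n)
  structure(list(indices = idx, n_total = n_total, scheme = "every_nth",
                 parameters = list(n = n)),
            class = "subsample_result")
}

#' @rdname every_nth
#' @export
random_subset <- function(n_total, k, seed = NULL) {
  n_total <- as.integer(n_total); k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n_total)
    stop("`k` must satisfy 1 <= k <= n_total", call. = FALSE)
  idx <- with_local_seed(seed, sort(sample.int(n_total, k)))
  structure(list(indices = idx, n_total = n_total, scheme = "random",
                 parameters = list(k = k, seed = seed)),
            class = "subsample_result")
}

#' @export
print.subsample_result <- function(x, ...) {
  cat(sprintf("<subsample_result> %d of %d samples (%s)\n",
              length(x$indices), x$n_total, x$scheme))
  invisible(x)
}
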