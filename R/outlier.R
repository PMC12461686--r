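#' Novelty scores for new data projected into a learned embedding
#'
#' Flags new samples that are dissimilar to everything the reference
#' embedding was trained on — a quality-control metric and a way to surface
#' data of interest. The primary score is the Euclidean distance from each
#' projected new sample to its k-th nearest training point in embedding
#' space; if an inverse map is supplied, a secondary score is the
#' correlation distance between each new spectrum and its round-trip
#' reconstruction `inv(fwd(x))`.
#'
#' @param fwd Forward `learned_map`.
#' @param x_new Matrix of new samples (features as in training).
#' @param e_train [embedding()] of the training subset (normalized;
#'   normalized internally otherwise).
#' @param k Neighbour order of the distance score (default 10; must not
#'   exceed the training size).
#' @param inv Optional inverse `learned_map` enabling the round-trip score.
#' @return Tibble with `sample`, `knn_dist` and (when `inv` is given)
#'   `roundtrip`.
#' @export
novelty_score <- function(fwd, x_new, e_train, k = 10L, inv = NULL) {
  stopifnot(inherits(fwd, "learned_map"), inherits(e_train, "embedding"))
  if (!e_train$normalized) e_train <- normalize_embedding(e_train)
  k <- as.integer(k)
  ref <- e_train$coords
  if (k < 1L || k > nrow(ref)) stop("`k` must lie in [1, training size]", call. = FALSE)
  x_new <- as_plain_matrix(as.matrix(x_new))
  proj <- predict(fwd, x_new)
  knn_dist <- kth_nn_dist(proj, ref, k)
  out <- tibble::tibble(
    sample = rownames(x_new) %||% as.character(seq_len(nrow(x_new))),
    knn_dist = knn_dist)
  if (!is.null(inv)) {
    recon <- predict(inv, proj)
    out$roundtrip <- vapply(seq_len(nrow(x_new)), function(i) {
      if (sd(x_new[i, ]) == 0 || sd(recon[i, ]) == 0) return(NA_real_)
      1 - cor(x_new[i, ], recon[i, ])
    }, numeric(1))
  }
  out
}

# distance from each row of `q` to its k-th nearest row of `ref`
# (chunked brute force; leave_self_out drops the single nearest match,
#  used when q is ref itself)
kth_nn_dist <- function(q, ref, k, leave_self_out = FALSE) {
  ref2 <- rowSums(ref^2)
  kk <- k + leave_self_out
  out <- numeric(nrow(q))
  step <- max(1L, floor(2e7 / nrow(ref)))
  for (start in seq(1L, nrow(q), by = step)) {
    idx <- start:min(start + step - 1L, nrow(q))
    qi <- q[idx, , drop = FALSE]
    d2 <- outer(rowSums(qi^2), ref2, "+") - 2 * tcrossprod(qi, ref)
    d2[d2 < 0] <- 0
    out[idx] <- apply(d2, 1L, function(v) sqrt(sort(v, partial = kk)[kk]))
  }
  out
}

#' Calibrate a novelty threshold from training self-scores
#'
#' The empirical quantile of the training samples' own leave-self-out k-NN
#' distances: new samples scoring above it are flagged as novel.
#'
#' @param scores Numeric vector of at least 20 training self-scores (e.g.
#'   from [training_self_scores()]).
#' @param quantile Probability in (0, 1), default 0.99.
#' @return The threshold (a single number).
#' @export
calibrate_threshold <- function(scores, quantile = 0.99) {
  if (quantile <= 0 || quantile >= 1) stop("`quantile` must lie in (0, 1)", call. = FALSE)
  scores <- as.numeric(scores)
  if (length(scores) < 20L) stop("need at least 20 scores to calibrate", call. = FALSE)
  unname(stats::quantile(scores, probs = quantile, type = 7))
}

#' @rdname calibrate_threshold
#' @param e_train Training [embedding()].
#' @param k Neighbour order (as in [novelty_score()]).
#' @return [training_self_scores()] returns each training sample's
#'   leave-self-out k-NN distance within the training embedding.
#' @export
training_self_scores <- function(e_train, k = 10L) {
  stopifnot(inherits(e_train, "embedding"))
  if (!e_train$normalized) e_train <- normalize_embedding(e_train)
  ref <- e_train$coords
  if (k < 1L || k > nrow(ref) - 1L) stop("`k` must lie in [1, n-1]", call. = FALSE)
  kth_nn_dist(ref, ref, k, leave_self_out = TRUE)
}

#' Assemble a novelty report
#'
#' @param scores Numeric scores (one per sample).
#' @param threshold Threshold from [calibrate_threshold()].
#' @param score_type Identifier of the score definition (`"knn"` or
#'   `"roundtrip"`).
#' @param sample Optional sample identifiers.
#' @return Tibble with `sample`, `score`, `flag` (`score > threshold`) and
#'   the threshold/score definition as attributes.
#' @export
novelty_report <- function(scores, threshold, score_type = "knn", sample = NULL) {
  scores <- as.numeric(scores)
  out <- tibble::tibble(
    sample = sample %||% as.character(seq_along(scores)),
    score = scores,
    flag = scores > threshold)
  attr(out, "threshold") <- threshold
  attr(out, "score_type") <- score_type
  out
}
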