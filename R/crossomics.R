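#' Pair two omics modalities by sample identifier
#'
#' Builds the matched-sample container for cross-omics training. Pairing is
#' always by explicit sample id, never by row order: silent row
#' misalignment is the dominant failure mode in matched-omics work.
#'
#' @param x_a [feature_matrix()] of modality A (e.g. metabolomics).
#' @param x_b [feature_matrix()] of modality B (e.g. transcriptomics).
#' @param pairing Optional two-column data frame `(id_a, id_b)`; by default
#'   samples present in both matrices are paired by shared id. The pairing
#'   must be one-to-one.
#' @return A `matched_pair` holding both matrices and the pairing table.
#' @export
matched_pair <- function(x_a, x_b, pairing = NULL) {
  stopifnot(inherits(x_a, "feature_matrix"), inherits(x_b, "feature_matrix"))
  if (is.null(pairing)) {
    shared <- intersect(sample_ids(x_a), sample_ids(x_b))
    pairing <- data.frame(id_a = shared, id_b = shared, stringsAsFactors = FALSE)
  }
  pairing <- as.data.frame(pairing)
  names(pairing)[1:2] <- c("id_a", "id_b")
  if (nrow(pairing) < 1L) stop("pairing is empty", call. = FALSE)
  if (anyDuplicated(pairing$id_a) || anyDuplicated(pairing$id_b))
    stop("pairing must be one-to-one", call. = FALSE)
  if (!all(pairing$id_a %in% sample_ids(x_a)) || !all(pairing$id_b %in% sample_ids(x_b)))
    stop("pairing references unknown sample ids", call. = FALSE)
  structure(list(x_a = x_a, x_b = x_b, pairing = tibble::as_tibble(pairing)),
            class = "matched_pair")
}

#' @export
print.matched_pair <- function(x, ...) {
  cat(sprintf("<matched_pair> %d paired samples; A: %d features, B: %d features\n",
              nrow(x$pairing), ncol(x$x_a), ncol(x$x_b)))
  invisible(x)
}

#' Train a cross-omics map: modality A features to modality B's embedding
#'
#' Learns to place modality-A samples (e.g. metabolomics spectra) into the
#' reduced space of modality B (e.g. a transcriptomics t-SNE or UMAP), using
#' the paired samples as supervision. When B's embedding separates a
#' phenotype that A's own embedding mixes, the projection transfers that
#' separation to A.
#'
#' @param pair A [matched_pair()].
#' @param e_b [embedding()] of `pair$x_b` (rows in `x_b` sample order; either
#'   backend).
#' @param config A [train_config()].
#' @return A `learned_map` with `direction = "cross"`.
#' @export
fit_cross <- function(pair, e_b, config = train_config()) {
  stopifnot(inherits(pair, "matched_pair"), inherits(e_b, "embedding"))
  if (nrow(e_b$coords) != nrow(pair$x_b))
    stop("`e_b` rows must correspond to `x_b` samples", call. = FALSE)
  if (nrow(pair$pairing) < 10L) stop("need at least 10 matched pairs", call. = FALSE)
  if (!e_b$normalized) e_b <- normalize_embedding(e_b)
  ia <- match(pair$pairing$id_a, sample_ids(pair$x_a))
  ib <- match(pair$pairing$id_b, sample_ids(pair$x_b))
  m <- train_map(as_plain_matrix(pair$x_a)[ia, , drop = FALSE],
                 e_b$coords[ib, , drop = FALSE],
                 "cross", config,
                 feature_axis = feature_axis(pair$x_a),
                 embedding_method = e_b$method)
  m
}

#' @rdname fit_cross
#' @param map A cross-direction `learned_map`.
#' @param x_a_new New modality-A samples (matrix or [feature_matrix()]).
#' @param chunk_size Rows per evaluation chunk.
#' @return [project_cross()] returns coordinates in modality B's embedding
#'   space.
#' @export
project_cross <- function(map, x_a_new, chunk_size = 10000L) {
  stopifnot(inherits(map, "learned_map"))
  if (map$direction != "cross")
    stop("`map` must be a cross-omics map", call. = FALSE)
  predict(map, x_a_new, chunk_size = chunk_size)
}
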