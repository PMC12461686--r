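#' Embedding container
#'
#' Holds `n x d` reduced coordinates together with provenance: the method
#' that produced them, its parameters, and whether the coordinates have been
#' min-max normalized to the unit cube.
#'
#' @param coords Numeric matrix `n x d`, `d` in `{2, 3}`.
#' @param method One of `"tsne"`, `"umap"`, `"network"`.
#' @param params List of the parameters used (recorded, not interpreted).
#' @param normalized Logical; `TRUE` when every coordinate lies in `[0, 1]`.
#' @param sample_ids Optional identifiers carried along from the source data.
#' @return An `embedding` object.
#' @export
embedding <- function(coords, method = c("tsne", "umap", "network"),
                      params = list(), normalized = FALSE, sample_ids = NULL) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (!ncol(coords) %in% c(2L, 3L)) stop("embedding dimension must be 2 or 3", call. = FALSE)
  if (anyNA(coords) || any(!is.finite(coords)))
    stop("coordinates must be finite", call. = FALSE)
  if (isTRUE(normalized) && (min(coords) < 0 || max(coords) > 1))
    stop("normalized embedding must lie in [0, 1]", call. = FALSE)
  if (!is.null(sample_ids)) rownames(coords) <- as.character(sample_ids)
  structure(list(coords = coords, method = method, params = params,
                 normalized = isTRUE(normalized)),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d x %d (%s%s)\n", nrow(x$coords), ncol(x$coords),
              x$method, if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
dim.embedding <- function(x) dim(x$coords)

#' @export
as.matrix.embedding <- function(x, ...) x$coords

#' @method as_tibble embedding
#' @export
as_tibble.embedding <- function(x, ...) {
  out <- tibble::as_tibble(x$coords, .name_repair = ~ paste0("dim", seq_along(.x)))
  if (!is.null(rownames(x$coords))) out <- tibble::add_column(out, sample_id = rownames(x$coords), .before = 1L)
  out
}

#' Min-max normalize an embedding to the unit cube
#'
#' Rescales every dimension to `[0, 1]` so that corner queries such as
#' red `[1, 0, 0]`, green `[0, 1, 0]` and blue `[0, 0, 1]` are well defined
#' and coordinates can double as RGB channels. A dimension with zero range
#' maps to the constant 0 and is flagged as degenerate. The per-dimension
#' minima and ranges are stored so the transform is invertible for
#' non-degenerate dimensions; the operation is idempotent.
#'
#' @param e An [embedding()].
#' @return A normalized [embedding()] with attributes `center` (minima),
#'   `range` and `degenerate` recorded in `$params$normalization`.
#' @export
normalize_embedding <- function(e) {
  stopifnot(inherits(e, "embedding"))
  co <- e$coords
  lo <- apply(co, 2L, min)
  hi <- apply(co, 2L, max)
  rg <- hi - lo
  degen <- rg == 0
  out <- sweep(co, 2L, lo, "-")
  out[, !degen] <- sweep(out[, !degen, drop = FALSE], 2L, rg[!degen], "/")
  out[, degen] <- 0
  params <- e$params
  params$normalization <- list(min = lo, range = rg, degenerate = degen)
  embedding(out, method = e$method, params = params, normalized = TRUE,
            sample_ids = rownames(co))
}

coords_of <- function(e) if (inherits(e, "embedding")) e$coords else as.matrix(e)

#' Per-dimension squared correlation between two embeddings
#'
#' Measures how faithfully a predicted embedding reproduces a reference one:
#' the squared Pearson correlation between true and predicted coordinates,
#' computed per dimension, plus the minimum over dimensions as a conservative
#' single-number summary. Invariant under affine rescaling of either argument
#' in any dimension.
#'
#' @param e_true,e_pred Coordinate matrices (or [embedding()] objects) of
#'   equal shape with at least 3 rows.
#' @return List with `per_dim` (named numeric vector) and `min`.
#' @export
embedding_r2 <- function(e_true, e_pred) {
  a <- coords_of(e_true); b <- coords_of(e_pred)
  if (!all(dim(a) == dim(b))) stop("embeddings must have equal shape", call. = FALSE)
  if (nrow(a) < 3L) stop("need at least 3 samples", call. = FALSE)
  sa <- apply(a, 2L, sd); sb <- apply(b, 2L, sd)
  if (any(sa == 0) || any(sb == 0))
    stop("degenerate input: zero-variance embedding dimension", call. = FALSE)
  r2 <- vapply(seq_len(ncol(a)), function(j) cor(a[, j], b[, j])^2, numeric(1))
  names(r2) <- paste0("dim", seq_along(r2))
  list(per_dim = r2, min = min(r2))
}

#' Per-sample squared spectral correlation
#'
#' For inverse (coordinates-to-features) maps: the squared Pearson
#' correlation between each true feature vector and its reconstruction,
#' computed across features for every sample.
#'
#' @param x_true,x_pred Matrices of equal shape (samples x features).
#' @return Numeric vector of per-sample r-squared values.
#' @export
spectral_r2 <- function(x_true, x_pred) {
  a <- as.matrix(x_true); b <- as.matrix(x_pred)
  if (!all(dim(a) == dim(b))) stop("matrices must have equal shape", call. = FALSE)
  if (ncol(a) < 2L) return(rep(NA_real_, nrow(a)))  # correlation needs >= 2 features
  vapply(seq_len(nrow(a)), function(i) {
    u <- a[i, ]; v <- b[i, ]
    su <- sd(u); sv <- sd(v)
    if (is.na(su) || is.na(sv) || su == 0 || sv == 0) return(NA_real_)
    cor(u, v)^2
  }, numeric(1))
}

#' Rand index between two partitions
#'
#' The plain (unadjusted) Rand index: the fraction of the `n(n-1)/2` sample
#' pairs on which two partitions agree, a pair agreeing when both partitions
#' co-cluster it or both separate it. Symmetric and invariant to label
#' renaming.
#'
#' @param labels_a,labels_b Vectors of categorical labels, equal length,
#'   `n >= 2`.
#' @return A number in `[0, 1]`.
#' @export
rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length", call. = FALSE)
  n <- length(labels_a)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  tab <- table(labels_a, labels_b)
  ch2 <- function(m) sum(m * (m - 1) / 2)
  same_both <- ch2(tab)
  same_a <- ch2(rowSums(tab))
  same_b <- ch2(colSums(tab))
  total <- n * (n - 1) / 2
  disagree <- same_a + same_b - 2 * same_both
  1 - disagree / total
}
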