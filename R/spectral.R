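#' Pseudo-spectrum from an inverse query
#'
#' Evaluates a trained inverse map at a point of the (unit-cube) embedding
#' space and returns the predicted per-feature contributions. Querying the
#' red/green/blue corners `[1,0,0]`, `[0,1,0]`, `[0,0,1]` yields the relative
#' spectral contributions along the three colour channels of an RGB
#' segmentation; contributions may be negative, indicating features that
#' argue against that corner. Points far outside the unit cube (outside
#' `[-0.5, 1.5]` in any dimension) trigger an extrapolation warning.
#'
#' @param inv A `learned_map` with `direction = "inverse"`.
#' @param point Numeric vector of length `inv$input_dim`.
#' @return A `pseudo_spectrum`: list with `feature_axis`, `contributions`
#'   and `query_point`; `as_tibble()` gives a two-column table.
#' @export
reverse_query <- function(inv, point) {
  stopifnot(inherits(inv, "learned_map"))
  if (inv$direction != "inverse")
    stop("`inv` must be an inverse map (embedding -> features)", call. = FALSE)
  point <- as.numeric(point)
  if (length(point) != inv$input_dim)
    stop(sprintf("query point must have length %d", inv$input_dim), call. = FALSE)
  if (any(point < -0.5 | point > 1.5))
    warning("query point lies far outside the unit cube; extrapolating", call. = FALSE)
  contrib <- drop(predict(inv, matrix(point, nrow = 1L)))
  structure(list(feature_axis = inv$feature_axis %||% seq_along(contrib),
                 contributions = as.numeric(contrib),
                 query_point = point),
            class = "pseudo_spectrum")
}

#' @export
print.pseudo_spectrum <- function(x, ...) {
  cat(sprintf("<pseudo_spectrum> %d features at [%s]\n",
              length(x$contributions),
              paste(sprintf("%.3f", x$query_point), collapse = ", ")))
  invisible(x)
}

#' @method as_tibble pseudo_spectrum
#' @export
as_tibble.pseudo_spectrum <- function(x, ...) {
  tibble::tibble(mz = x$feature_axis, contribution = x$contributions)
}

#' Pseudo-spectrum of a region centroid
#'
#' Computes the arithmetic mean of the selected samples' embedding
#' coordinates and runs [reverse_query()] there: the spectrum that would be
#' derived from that region of the reduced space.
#'
#' @param inv Inverse `learned_map`.
#' @param e [embedding()] (normalized; normalized internally otherwise).
#' @param mask Logical or integer vector selecting at least one sample.
#' @return A `pseudo_spectrum`.
#' @export
centroid_spectrum <- function(inv, e, mask) {
  stopifnot(inherits(e, "embedding"))
  if (!e$normalized) e <- normalize_embedding(e)
  co <- e$coords[mask, , drop = FALSE]
  if (nrow(co) < 1L) stop("mask selects no samples", call. = FALSE)
  reverse_query(inv, colMeans(co))
}

#' Rank the spectral drivers of a pseudo-spectrum
#'
#' Orders features by the magnitude of their contribution, optionally after
#' restricting to one sign, and returns the top `k`. Ties in magnitude are
#' broken by ascending m/z.
#'
#' @param ps A `pseudo_spectrum` (or anything with `feature_axis` and
#'   `contributions`).
#' @param k Number of drivers to return (clipped to the number of features,
#'   with a warning, when larger).
#' @param sign `"both"` (default), `"positive"` or `"negative"`.
#' @return Tibble with columns `rank`, `feature`, `mz`, `contribution`,
#'   sorted by descending `abs(contribution)`.
#' @export
rank_drivers <- function(ps, k = 10L, sign = c("both", "positive", "negative")) {
  sign <- match.arg(sign)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  mz <- ps$feature_axis; contrib <- ps$contributions
  keep <- switch(sign,
                 both = rep(TRUE, length(contrib)),
                 positive = contrib > 0,
                 negative = contrib < 0)
  idx <- which(keep)
  ord <- idx[order(-abs(contrib[idx]), mz[idx])]
  if (k > length(ord)) {
    warning(sprintf("k = %d exceeds %d available features; clipping", k, length(ord)),
            call. = FALSE)
    k <- length(ord)
  }
  sel <- ord[seq_len(k)]
  tibble::tibble(rank = seq_len(k), feature = sel, mz = mz[sel],
                 contribution = contrib[sel])
}

#' Read an annotation table
#'
#' Delimited text with columns `name`, `mass` (Da, positive) and optionally
#' `adduct`. The package never bundles a metabolite database; users supply
#' their own export (e.g. from HMDB).
#'
#' @param path Delimited text file.
#' @param sep Field separator.
#' @return Tibble with columns `name`, `mass`, `adduct`.
#' @export
read_annotation_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  if (!all(c("name", "mass") %in% names(dt)))
    stop("annotation table needs `name` and `mass` columns", call. = FALSE)
  if (!"adduct" %in% names(dt)) dt$adduct <- NA_character_
  annotation_table(dt$name, dt$mass, dt$adduct)
}

#' @rdname read_annotation_table
#' @param name,mass,adduct Vectors building a table in code.
#' @export
annotation_table <- function(name, mass, adduct = NA_character_) {
  mass <- as.numeric(mass)
  if (any(!nzchar(name))) stop("annotation names must be non-empty", call. = FALSE)
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("masses must be positive", call. = FALSE)
  tibble::tibble(name = as.character(name), mass = mass,
                 adduct = rep_len(as.character(adduct), length(mass)))
}

#' Match a query mass against an annotation table within a ppm tolerance
#'
#' Returns every entry whose mass lies within `tol_ppm` parts per million of
#' the query, `|mass - mz_query| / mz_query * 1e6 <= tol_ppm`, sorted by
#' absolute ppm error. The match set is monotone in the tolerance.
#'
#' @param mz_query Query m/z in Da.
#' @param table An [annotation_table()].
#' @param tol_ppm Tolerance in ppm (default 5).
#' @return Tibble of matches with a signed `ppm_error` column.
#' @export
ppm_match <- function(mz_query, table, tol_ppm = 5) {
  if (tol_ppm <= 0) stop("`tol_ppm` must be positive", call. = FALSE)
  ppm <- (table$mass - mz_query) / mz_query * 1e6
  hit <- abs(ppm) <= tol_ppm
  out <- table[hit, , drop = FALSE]
  out$ppm_error <- ppm[hit]
  out[order(abs(out$ppm_error)), , drop = FALSE]
}
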