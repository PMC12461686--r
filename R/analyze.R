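#' Render a normalized embedding as an RGB image
#'
#' Paints each pixel with its embedding coordinates used directly as colour
#' channels: in 3-D, dimensions 1/2/3 are red/green/blue, so the unit-cube
#' corners `[1,0,0]`, `[0,1,0]`, `[0,0,1]` are pure red, green and blue. A
#' 2-D embedding uses the four-corner colour-square convention: blue at
#' `(0,0)`, red at `(1,0)`, green at `(0,1)` and yellow at `(1,1)`, blended
#' bilinearly. Raster cells without samples are black. Because colours are a
#' fixed function of coordinates, two sections rendered with the same
#' trained map share colour semantics.
#'
#' @param e Normalized [embedding()] (normalized internally otherwise —
#'   note that re-normalizing per section would break shared colour
#'   semantics, so pass coordinates from a shared map already in `[0,1]`).
#' @param geometry [pixel_geometry()] with one position per sample.
#' @return Numeric array `ny x nx x 3` with values in `[0, 1]`.
#' @export
rgb_render <- function(e, geometry) {
  stopifnot(inherits(geometry, "pixel_geometry"))
  co <- if (inherits(e, "embedding")) {
    if (!e$normalized) e <- normalize_embedding(e)
    e$coords
  } else as.matrix(e)
  if (nrow(co) != nrow(geometry))
    stop("geometry must cover exactly the embedded samples", call. = FALSE)
  co[co < 0] <- 0; co[co > 1] <- 1
  if (ncol(co) == 2L) co <- colour_square(co)
  shape <- image_shape(geometry)
  img <- array(0, dim = c(shape[2L], shape[1L], 3L))
  for (ch in 1:3) {
    plane <- matrix(0, shape[2L], shape[1L])
    plane[cbind(geometry$y, geometry$x)] <- co[, ch]
    img[, , ch] <- plane
  }
  img
}

# 2-D colour-square: bilinear blend of blue(0,0), red(1,0), green(0,1),
# yellow(1,1)
colour_square <- function(uv) {
  u <- uv[, 1L]; v <- uv[, 2L]
  corners <- rbind(c(0, 0, 1),   # (0,0) blue
                   c(1, 0, 0),   # (1,0) red
                   c(0, 1, 0),   # (0,1) green
                   c(1, 1, 0))   # (1,1) yellow
  w00 <- (1 - u) * (1 - v); w10 <- u * (1 - v)
  w01 <- (1 - u) * v;       w11 <- u * v
  cbind(w00, w10, w01, w11) %*% corners
}

#' Mask samples inside a box of embedding space
#'
#' Bounding boxes are the segmentation primitive of the reduced space:
#' `box_mask()` returns the samples whose coordinates all fall inside the
#' closed per-dimension intervals.
#'
#' @param e [embedding()] or coordinate matrix.
#' @param lo,hi Numeric vectors of per-dimension bounds (`lo <= hi`).
#' @param label Optional region label, attached as an attribute.
#' @return Logical vector, one entry per sample.
#' @export
box_mask <- function(e, lo, hi, label = NULL) {
  co <- coords_of(e)
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (length(lo) != ncol(co) || length(hi) != ncol(co))
    stop("box dimensionality must match the embedding", call. = FALSE)
  if (any(lo > hi)) stop("`lo` must be <= `hi` in every dimension", call. = FALSE)
  mask <- rep(TRUE, nrow(co))
  for (j in seq_len(ncol(co)))
    mask <- mask & co[, j] >= lo[j] & co[, j] <= hi[j]
  if (!is.null(label)) attr(mask, "label") <- label
  mask
}

#' Leave-one-out linear discriminant classification on reduced coordinates
#'
#' Classifies samples from their embedding coordinates with linear
#' discriminant analysis, evaluated by leave-one-out cross-validation.
#' Priors are proportional to class frequency. The pooled within-class
#' covariance is regularized by adding `eps * I` with
#' `eps = 1e-6 * trace / d`, so degenerate directions cannot make the
#' discriminant singular. Deterministic given its input.
#'
#' @param coords Numeric matrix `n x d` (or [embedding()]).
#' @param labels Class labels; at least 2 classes with at least 2 members
#'   each.
#' @return List with `accuracy`, `confusion` (true x predicted table) and
#'   `predicted`.
#' @export
lda_loo <- function(coords, labels) {
  x <- coords_of(coords)
  labels <- factor(labels)
  if (nrow(x) != length(labels)) stop("labels must match rows", call. = FALSE)
  if (nlevels(labels) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(table(labels) < 2L)) stop("every class needs at least 2 members", call. = FALSE)
  n <- nrow(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    pred[i] <- lda_predict(x[-i, , drop = FALSE], labels[-i],
                           x[i, , drop = FALSE])
  }
  pred <- factor(pred, levels = levels(labels))
  list(accuracy = mean(pred == labels),
       confusion = table(true = labels, predicted = pred),
       predicted = pred)
}

# closed-form LDA with ridge-regularized pooled covariance
lda_predict <- function(xtr, ytr, xte) {
  ytr <- droplevels(factor(ytr))
  cls <- levels(ytr)
  d <- ncol(xtr)
  mu <- t(vapply(cls, function(k) colMeans(xtr[ytr == k, , drop = FALSE]),
                 numeric(d)))
  centered <- xtr - mu[as.integer(ytr), , drop = FALSE]
  Sw <- crossprod(centered) / (nrow(xtr) - length(cls))
  eps <- 1e-6 * sum(diag(Sw)) / d
  Sw <- Sw + diag(eps + 1e-12, d)
  Sinv <- solve(Sw)
  prior <- as.numeric(table(ytr)) / length(ytr)
  scores <- vapply(seq_along(cls), function(k) {
    m <- mu[k, ]
    drop(xte %*% Sinv %*% m) - 0.5 * drop(m %*% Sinv %*% m) + log(prior[k])
  }, numeric(nrow(xte)))
  scores <- matrix(scores, nrow = nrow(xte))
  # exact argmax (max.col's relative tie tolerance randomizes when a
  # degenerate direction inflates all scores by a large common offset)
  cls[apply(scores, 1L, which.max)]
}
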