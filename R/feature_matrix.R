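#' Construct a feature matrix
#'
#' The central data container: an `n` samples by `p` features matrix of
#' nonnegative intensities with an ordered feature axis (m/z values in Da,
#' or genomic bin start coordinates) and unique sample identifiers.
#'
#' @param values Numeric matrix, `n` rows (samples) by `p` columns (features).
#'   All entries must be finite and nonnegative.
#' @param feature_axis Numeric vector of length `p`. For mass spectra this is
#'   the m/z axis and must be strictly increasing.
#' @param sample_ids Character vector of length `n` of unique identifiers.
#'   Defaults to existing rownames or `"s1" ... "sn"`.
#' @param group_labels Optional vector of length `n` of categorical labels
#'   (tissue region, class, chromosome, ...).
#' @param axis_type Either `"mz"` (strictly increasing axis enforced) or
#'   `"bin"` (labeled genomic bins, monotonicity not required).
#'
#' @return An object of class `feature_matrix`: the values matrix with the
#'   axis, ids and labels attached as attributes.
#' @export
feature_matrix <- function(values, feature_axis, sample_ids = NULL,
                           group_labels = NULL, axis_type = c("mz", "bin")) {
  axis_type <- match.arg(axis_type)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  n <- nrow(values); p <- ncol(values)
  if (n < 1L || p < 1L) stop("need at least one sample and one feature", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` contains non-finite entries", call. = FALSE)
  if (any(values < 0)) stop("intensities must be nonnegative", call. = FALSE)
  feature_axis <- as.numeric(feature_axis)
  if (length(feature_axis) != p)
    stop("`feature_axis` length must equal the number of columns", call. = FALSE)
  if (axis_type == "mz" && p > 1L && any(diff(feature_axis) <= 0))
    stop("m/z feature axis must be strictly increasing", call. = FALSE)
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(rownames(values))) rownames(values)
                  else paste0("s", seq_len(n))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop("`sample_ids` length must equal the number of rows", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("`sample_ids` must be unique", call. = FALSE)
  if (!is.null(group_labels) && length(group_labels) != n)
    stop("`group_labels` length must equal the number of rows", call. = FALSE)
  rownames(values) <- sample_ids
  structure(values,
            feature_axis = feature_axis,
            group_labels = group_labels,
            axis_type = axis_type,
            class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  ax <- feature_axis(x)
  cat(sprintf("<feature_matrix> %d samples x %d features (%s axis %.4g..%.4g)\n",
              nrow(x), ncol(x), attr(x, "axis_type"), min(ax), max(ax)))
  if (!is.null(attr(x, "group_labels")))
    cat("  groups:", paste(utils::head(unique(attr(x, "group_labels")), 8L), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.feature_matrix` <- function(x, i, j, ..., drop = FALSE) {
  vals <- as_plain_matrix(x)[i, j, drop = FALSE]
  ax <- feature_axis(x); gl <- group_labels(x)
  if (!missing(j)) ax <- ax[j]
  if (!missing(i) && !is.null(gl)) gl <- gl[i]
  feature_matrix(vals, ax, sample_ids = rownames(vals), group_labels = gl,
                 axis_type = attr(x, "axis_type"))
}

#' @rdname feature_matrix
#' @param x A `feature_matrix`.
#' @export
feature_axis <- function(x) attr(x, "feature_axis")

#' @rdname feature_matrix
#' @export
sample_ids <- function(x) rownames(x)

#' @rdname feature_matrix
#' @export
group_labels <- function(x) attr(x, "group_labels")

# strip attributes down to a plain numeric matrix
as_plain_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "feature_axis") <- NULL
  attr(y, "group_labels") <- NULL
  attr(y, "axis_type") <- NULL
  y
}

#' Pixel geometry for image rendering
#'
#' Maps each sample (pixel) of an imaging dataset to an integer raster
#' position so embeddings and ion intensities can be painted back as images.
#'
#' @param x,y Integer raster coordinates, 1-based, one per sample.
#' @param image_shape Integer `c(nx, ny)`; defaults to `c(max(x), max(y))`.
#'
#' @return A `pixel_geometry` object (a tibble of positions with the raster
#'   shape attached).
#' @export
pixel_geometry <- function(x, y, image_shape = NULL) {
  x <- as.integer(x); y <- as.integer(y)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (is.null(image_shape)) image_shape <- c(max(x), max(y))
  image_shape <- as.integer(image_shape)
  if (any(x < 1L) || any(y < 1L) || any(x > image_shape[1]) || any(y > image_shape[2]))
    stop("positions must lie within `image_shape`", call. = FALSE)
  if (anyDuplicated(cbind(x, y))) stop("pixel positions must be unique", call. = FALSE)
  structure(tibble::tibble(x = x, y = y),
            image_shape = image_shape,
            class = c("pixel_geometry", "tbl_df", "tbl", "data.frame"))
}

#' @rdname pixel_geometry
#' @param geometry A `pixel_geometry`.
#' @export
image_shape <- function(geometry) attr(geometry, "image_shape")

#' Read / write delimited feature matrices
#'
#' Plain-text interchange format: one header row carrying the feature axis
#' and one id column carrying sample identifiers. With
#' `orientation = "samples_in_rows"` (default) rows are samples; with
#' `"samples_in_columns"` the file is transposed on read.
#'
#' @param path File path.
#' @param orientation Which dimension holds samples in the file.
#' @param sep Field separator (default `,`).
#' @param axis_type Passed to [feature_matrix()].
#' @return [read_feature_matrix()] returns a [feature_matrix()];
#'   [write_feature_matrix()] returns `path` invisibly.
#' @export
read_feature_matrix <- function(path,
                                orientation = c("samples_in_rows", "samples_in_columns"),
                                sep = ",", axis_type = "mz") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty file: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1L))
  if (ncol(dt) < 2L) stop("malformed matrix file: need id column plus data", call. = FALSE)
  ids <- dt[[1L]]
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric cells in ", path, call. = FALSE)
  axis <- suppressWarnings(as.numeric(colnames(dt)[-1L]))
  if (anyNA(axis)) stop("header does not contain a numeric feature axis", call. = FALSE)
  if (orientation == "samples_in_columns") {
    vals <- t(vals)
    tmp <- ids; ids <- colnames(dt)[-1L]
    axis <- suppressWarnings(as.numeric(tmp))
    if (anyNA(axis)) stop("id column does not contain a numeric feature axis", call. = FALSE)
  }
  feature_matrix(vals, axis, sample_ids = ids, axis_type = axis_type)
}

#' @rdname read_feature_matrix
#' @param x A `feature_matrix` to write.
#' @export
write_feature_matrix <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "feature_matrix"))
  dt <- data.table::data.table(id = sample_ids(x))
  vals <- as_plain_matrix(x)
  colnames(vals) <- format(feature_axis(x), digits = 17, trim = TRUE, scientific = FALSE)
  dt <- cbind(dt, data.table::as.data.table(vals))
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}
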