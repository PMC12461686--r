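#' Read a Hi-C contact list
#'
#' Parses the 3-column whitespace/tab-delimited text used for un-normalized
#' contact counts (the `.RAWobserved` convention): `pos1 pos2 count` per
#' row, positions being 0-based bin start coordinates in bp. Counts are
#' retained exactly as given.
#'
#' @param path File path.
#' @param chromosome Optional label attached to all records.
#' @return A `sparse_contacts` tibble with columns `pos1`, `pos2`, `count`
#'   (and `chromosome` when supplied). Empty files yield 0 records.
#' @export
read_contacts <- function(path, chromosome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L) {
    out <- tibble::tibble(pos1 = numeric(0), pos2 = numeric(0), count = numeric(0))
  } else {
    dt <- tryCatch(
      data.table::fread(path, header = FALSE, data.table = FALSE,
                        colClasses = "numeric"),
      error = function(e) stop("malformed contact list ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    if (ncol(dt) != 3L)
      stop("contact list must have exactly 3 columns, got ", ncol(dt), call. = FALSE)
    bad <- which(!stats::complete.cases(dt) | dt[[1L]] < 0 | dt[[2L]] < 0 | dt[[3L]] <= 0)
    if (length(bad))
      stop("malformed contact record at line ", bad[1L], " of ", path, call. = FALSE)
    out <- tibble::tibble(pos1 = dt[[1L]], pos2 = dt[[2L]], count = dt[[3L]])
  }
  if (!is.null(chromosome)) out$chromosome <- chromosome
  class(out) <- c("sparse_contacts", class(out))
  out
}

#' @rdname read_contacts
#' @param pos1,pos2,count Vectors building a contact list in code.
#' @export
sparse_contacts <- function(pos1, pos2, count, chromosome = NULL) {
  if (any(pos1 < 0) || any(pos2 < 0)) stop("positions must be >= 0", call. = FALSE)
  if (any(count <= 0)) stop("counts must be positive", call. = FALSE)
  out <- tibble::tibble(pos1 = as.numeric(pos1), pos2 = as.numeric(pos2),
                        count = as.numeric(count))
  if (!is.null(chromosome)) out$chromosome <- chromosome
  class(out) <- c("sparse_contacts", class(out))
  out
}

#' Bin a sparse contact list into a dense asymmetric-resolution matrix
#'
#' Rows are fine (`row_bin` bp) loci — the samples to embed — and columns
#' are coarse (`col_bin` bp) bins — the features. Each contact
#' `(p1, p2, c)` adds `c` at `(floor(p1/row_bin), floor(p2/col_bin))`; with
#' `mirror = TRUE` (the convention for intrachromosomal upper-triangle
#' lists) it also adds `c` at `(floor(p2/row_bin), floor(p1/col_bin))` when
#' `p1 != p2`, so total count mass is conserved (doubled for mirrored
#' off-diagonal records). For interchromosomal lists use `mirror = FALSE`.
#'
#' @param contacts A [sparse_contacts()] table.
#' @param row_bin,col_bin Bin widths in bp; `col_bin` must be an integer
#'   multiple of `row_bin`.
#' @param mirror Symmetrize as described (default `TRUE`).
#' @return A [feature_matrix()] whose sample ids are row-locus start
#'   coordinates and whose feature axis holds column-bin start coordinates;
#'   an empty contact list yields a 0 x 0 plain matrix.
#' @export
bin_contacts <- function(contacts, row_bin, col_bin, mirror = TRUE) {
  if (row_bin <= 0 || col_bin <= 0) stop("bin widths must be positive", call. = FALSE)
  if (col_bin %% row_bin != 0)
    stop("`col_bin` must be an integer multiple of `row_bin`", call. = FALSE)
  if (nrow(contacts) == 0L) return(matrix(numeric(0), 0L, 0L))
  p1 <- contacts$pos1; p2 <- contacts$pos2; ct <- contacts$count
  ri <- floor(p1 / row_bin); ci <- floor(p2 / col_bin)
  if (mirror) {
    off <- p1 != p2
    ri <- c(ri, floor(p2[off] / row_bin))
    ci <- c(ci, floor(p1[off] / col_bin))
    ct <- c(ct, ct[off])
  }
  nr <- max(ri) + 1L; nc <- max(ci) + 1L
  m <- matrix(0, nr, nc)
  agg <- rowsum(ct, group = ri * nc + ci)
  key <- as.numeric(rownames(agg))
  m[cbind(key %/% nc + 1L, key %% nc + 1L)] <- agg[, 1L]
  feature_matrix(m, feature_axis = (seq_len(nc) - 1L) * col_bin,
                 sample_ids = as.character((seq_len(nr) - 1L) * row_bin),
                 axis_type = "bin")
}

#' Remove fully zero rows and columns
#'
#' Drops samples and features whose entries are all zero (empty genomic
#' loci after binning) and reports the surviving indices for traceability.
#'
#' @param x A [feature_matrix()] or plain matrix.
#' @return List with `matrix` (the pruned matrix, `NULL` when everything was
#'   zero), `rows_kept`, `cols_kept` and `empty` (logical flag). Idempotent.
#' @export
drop_zero <- function(x) {
  m <- as.matrix(x)
  rows_kept <- which(rowSums(m != 0) > 0L)
  cols_kept <- which(colSums(m != 0) > 0L)
  if (length(rows_kept) == 0L || length(cols_kept) == 0L)
    return(list(matrix = NULL, rows_kept = integer(0), cols_kept = integer(0),
                empty = TRUE))
  out <- m[rows_kept, cols_kept, drop = FALSE]
  if (inherits(x, "feature_matrix"))
    out <- feature_matrix(out, feature_axis = feature_axis(x)[cols_kept],
                          sample_ids = sample_ids(x)[rows_kept],
                          axis_type = attr(x, "axis_type"))
  list(matrix = out, rows_kept = rows_kept, cols_kept = cols_kept, empty = FALSE)
}
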