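# imzML input/output.
#
# Minimal reader/writer for the open MSI interchange format: an XML index
# (.imzML) plus a binary array file (.ibd, 16-byte UUID header followed by
# the m/z and intensity arrays referenced by external offset/length).
# Supports both layouts of the standard: "continuous" (one shared m/z axis)
# and "processed" (per-pixel m/z axes). Only the subset of the format this
# workflow touches is implemented.

ibd_path_for <- function(path) {
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  for (ext in c(".ibd", ".IBD")) {
    cand <- paste0(base, ext)
    if (file.exists(cand)) return(cand)
  }
  paste0(base, ".ibd")
}

#' Read an imzML mass spectrometry imaging dataset
#'
#' Parses the XML index, reads the external binary arrays, and assembles a
#' per-pixel intensity matrix. With `bin_edges` supplied, every spectrum is
#' accumulated onto the common bins (intensities summed within each
#' half-open bin `[edge_i, edge_{i+1})`), which also unifies processed-mode
#' data with per-pixel m/z axes; without bin edges the file must be
#' continuous-mode and the shared axis is used as-is. Pixels absent from the
#' raster simply have no row.
#'
#' @param path Path to the `.imzML` file (the `.ibd` must sit next to it).
#' @param bin_edges Optional strictly increasing numeric vector of bin
#'   edges (Da); the resulting feature axis is the bin midpoints.
#' @return List with `matrix` (a [feature_matrix()]) and `geometry`
#'   (a [pixel_geometry()]).
#' @export
read_imzml <- function(path, bin_edges = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ibd <- ibd_path_for(path)
  if (!file.exists(ibd)) stop("missing .ibd binary file for ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  mode <- if (length(xml2::xml_find_all(doc, "//*[@accession='IMS:1000030']")) > 0)
    "continuous" else "processed"
  spectra <- xml2::xml_find_all(doc, "//*[local-name()='spectrum']")
  if (length(spectra) == 0L) stop("no spectra in ", path, call. = FALSE)

  get_cv <- function(node, accession) {
    v <- xml2::xml_attr(
      xml2::xml_find_first(node, sprintf(".//*[@accession='%s']", accession)),
      "value")
    v
  }
  con <- file(ibd, "rb")
  on.exit(close(con))

  read_array <- function(node, which_acc) {
    arr <- xml2::xml_find_first(
      node, sprintf(".//*[local-name()='binaryDataArray'][.//*[@accession='%s']]",
                    which_acc))
    if (is.na(xml2::xml_name(arr))) stop("missing binary data array", call. = FALSE)
    offset <- as.numeric(get_cv(arr, "IMS:1000102"))
    len <- as.integer(get_cv(arr, "IMS:1000103"))
    size <- if (length(xml2::xml_find_all(arr, ".//*[@accession='MS:1000521']")) > 0) 4L else 8L
    seek(con, where = offset, origin = "start")
    readBin(con, "double", n = len, size = size)
  }

  n <- length(spectra)
  xs <- integer(n); ys <- integer(n)
  mzl <- vector("list", n); intl <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    px <- get_cv(sp, "IMS:1000050"); py <- get_cv(sp, "IMS:1000051")
    if (is.na(px) || is.na(py)) stop("pixel coordinates absent in spectrum ", i, call. = FALSE)
    xs[i] <- as.integer(px); ys[i] <- as.integer(py)
    mzl[[i]] <- read_array(sp, "MS:1000514")
    intl[[i]] <- read_array(sp, "MS:1000515")
  }

  if (is.null(bin_edges)) {
    if (mode != "continuous")
      stop("processed-mode imzML requires `bin_edges`", call. = FALSE)
    axis <- mzl[[1L]]
    vals <- do.call(rbind, intl)
  } else {
    bin_edges <- as.numeric(bin_edges)
    if (any(diff(bin_edges) <= 0)) stop("`bin_edges` must be strictly increasing", call. = FALSE)
    nb <- length(bin_edges) - 1L
    axis <- (bin_edges[-1L] + bin_edges[-length(bin_edges)]) / 2
    vals <- matrix(0, n, nb)
    for (i in seq_len(n)) {
      b <- findInterval(mzl[[i]], bin_edges)
      keep <- b >= 1L & b <= nb
      if (any(keep)) {
        sums <- tapply(intl[[i]][keep], b[keep], sum)
        vals[i, as.integer(names(sums))] <- as.numeric(sums)
      }
    }
  }
  ids <- sprintf("x%03d_y%03d", xs, ys)
  list(matrix = feature_matrix(vals, axis, sample_ids = ids),
       geometry = pixel_geometry(xs, ys))
}

#' @rdname read_imzml
#' @param x A [feature_matrix()] to write.
#' @param geometry Matching [pixel_geometry()].
#' @param mode `"continuous"` (shared m/z axis, default) or `"processed"`
#'   (per-pixel axes; identical content, different layout).
#' @return [write_imzml()] writes `path` and the sibling `.ibd`, returning
#'   `path` invisibly.
#' @export
write_imzml <- function(x, geometry, path, mode = c("continuous", "processed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "feature_matrix"), inherits(geometry, "pixel_geometry"))
  if (nrow(x) != nrow(geometry)) stop("geometry must cover all samples", call. = FALSE)
  ibd <- paste0(sub("\\.imzML$", "", path, ignore.case = TRUE), ".ibd")
  axis <- feature_axis(x)
  p <- length(axis)
  vals <- as_plain_matrix(x)

  con <- file(ibd, "wb")
  writeBin(as.raw(rep(0L, 16L)), con)  # uuid placeholder
  offset <- 16
  mz_off <- integer(nrow(x)); int_off <- integer(nrow(x))
  if (mode == "continuous") {
    writeBin(as.numeric(axis), con, size = 8L)
    shared_mz <- offset; offset <- offset + 8 * p
    for (i in seq_len(nrow(x))) {
      mz_off[i] <- shared_mz
      int_off[i] <- offset
      writeBin(as.numeric(vals[i, ]), con, size = 8L)
      offset <- offset + 8 * p
    }
  } else {
    for (i in seq_len(nrow(x))) {
      mz_off[i] <- offset
      writeBin(as.numeric(axis), con, size = 8L)
      offset <- offset + 8 * p
      int_off[i] <- offset
      writeBin(as.numeric(vals[i, ]), con, size = 8L)
      offset <- offset + 8 * p
    }
  }
  close(con)

  arr_xml <- function(acc, name, off) paste0(
    '      <binaryDataArray encodedLength="0">\n',
    sprintf('        <cvParam cvRef="MS" accession="%s" name="%s"/>\n', acc, name),
    '        <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    sprintf('        <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n', p),
    sprintf('        <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n', off),
    '        <binary/>\n      </binaryDataArray>\n')

  sp_xml <- vapply(seq_len(nrow(x)), function(i) paste0(
    sprintf('  <spectrum id="spectrum=%d" index="%d" defaultArrayLength="0">\n', i, i - 1L),
    '    <scanList count="1"><scan>\n',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n', geometry$x[i]),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n', geometry$y[i]),
    '    </scan></scanList>\n',
    '    <binaryDataArrayList count="2">\n',
    arr_xml("MS:1000514", "m/z array", mz_off[i]),
    arr_xml("MS:1000515", "intensity array", int_off[i]),
    '    </binaryDataArrayList>\n  </spectrum>\n'), character(1))

  mode_acc <- if (mode == "continuous") "IMS:1000030" else "IMS:1000031"
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '<fileDescription><fileContent>\n',
    sprintf('  <cvParam cvRef="IMS" accession="%s" name="%s"/>\n', mode_acc, mode),
    '</fileContent></fileDescription>\n',
    sprintf('<run id="run1"><spectrumList count="%d">\n', nrow(x)),
    paste(sp_xml, collapse = ""),
    '</spectrumList></run>\n</mzML>\n')
  writeLines(xml, path)
  invisible(path)
}

#' Interpolated rebinning of a spectrum
#'
#' Linear interpolation of a centroided or profile spectrum onto a uniform
#' m/z grid of spacing `bin_width` spanning `[min(mz), max(mz)]` — the
#' standard preprocessing step before averaging spectra acquired on
#' slightly different axes. The conventional bin width is 0.002 Da.
#'
#' @param mz Strictly increasing m/z values (at least 2).
#' @param intensity Intensities, same length.
#' @param bin_width Grid spacing in Da (default 0.002).
#' @return List with the new `mz` grid and interpolated `intensity`.
#' @export
rebin_spectrum <- function(mz, intensity, bin_width = 0.002) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) < 2L) stop("need at least 2 points", call. = FALSE)
  if (length(mz) != length(intensity)) stop("lengths differ", call. = FALSE)
  if (any(diff(mz) <= 0)) stop("`mz` must be strictly increasing", call. = FALSE)
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  nb <- floor((max(mz) - min(mz)) / bin_width + 1e-9)
  grid <- min(mz) + bin_width * (0:nb)
  list(mz = grid, intensity = approx(mz, intensity, xout = grid)$y)
}

#' Ion image for a peak window
#'
#' Integrates intensities across a peak — the per-pixel sum of all feature
#' columns with `mz_lo <= m/z <= mz_hi` — and paints the result at each
#' pixel's raster position. Raster cells without samples are 0. A window
#' containing no features yields an all-zero image with a warning.
#'
#' @param x [feature_matrix()].
#' @param geometry [pixel_geometry()] (one position per sample).
#' @param window Numeric `c(mz_lo, mz_hi)`.
#' @return Numeric matrix `ny x nx`.
#' @export
ion_image <- function(x, geometry, window) {
  stopifnot(inherits(x, "feature_matrix"), inherits(geometry, "pixel_geometry"))
  if (nrow(x) != nrow(geometry)) stop("geometry must cover all samples", call. = FALSE)
  window <- as.numeric(window)
  ax <- feature_axis(x)
  cols <- which(ax >= window[1L] & ax <= window[2L])
  shape <- image_shape(geometry)
  img <- matrix(0, shape[2L], shape[1L])
  if (length(cols) == 0L) {
    warning("no features inside the m/z window; returning an all-zero image", call. = FALSE)
    return(img)
  }
  totals <- rowSums(as_plain_matrix(x)[, cols, drop = FALSE])
  img[cbind(geometry$y, geometry$x)] <- totals
  img
}
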