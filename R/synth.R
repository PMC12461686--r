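#' Synthetic MSI-like dataset
#'
#' Generates a clustered, nonnegative "spectral" dataset laid out on an
#' image grid: contiguous tissue-like regions (a Voronoi partition of the
#' raster), a shared log-normal baseline spectrum with large dynamic range,
#' per-region log-normal fold effects, and per-region planted marker
#' features that are intense in their own region and near-absent elsewhere.
#' Pixel noise is multiplicative log-normal plus an additive Gaussian floor,
#' clipped at zero — a standard caricature of MS intensity noise.
#'
#' The region truth (layout, mean spectra, markers) is a deterministic
#' function of `seed`; [synth_replicate()] redraws only the pixel noise, so
#' it emulates a serial section of the same tissue.
#'
#' @param n_pixels Number of pixels (default 50000).
#' @param n_features Number of m/z features (default 500).
#' @param n_regions Number of regions/classes (default 6).
#' @param markers_per_region Unique marker features per region (default 2).
#' @param noise_sdlog Multiplicative log-normal noise sd (default 0.25).
#' @param region_sdlog Spread of per-region fold effects on the log scale
#'   (default 0.6).
#' @param baseline_sdlog Dynamic range of the baseline spectrum (default 1.2).
#' @param floor_frac Additive Gaussian floor sd as a fraction of the median
#'   baseline intensity (default 0.01).
#' @param seed Integer seed; generators are pure functions of their
#'   arguments.
#' @return An `msi_synth` list: `matrix` ([feature_matrix()] with region
#'   `group_labels`), `geometry` ([pixel_geometry()]), `labels` (region
#'   factor) and `truth` (region mean spectra, marker table, layout).
#' @export
synth_msi <- function(n_pixels = 50000L, n_features = 500L, n_regions = 6L,
                      markers_per_region = 2L, noise_sdlog = 0.25,
                      region_sdlog = 0.6, baseline_sdlog = 1.2,
                      floor_frac = 0.01, seed = 1L) {
  n_pixels <- as.integer(n_pixels); n_features <- as.integer(n_features)
  n_regions <- as.integer(n_regions)
  if (n_regions > n_pixels) stop("more regions than pixels", call. = FALSE)
  truth <- with_local_seed(seed, {
    axis <- sort(runif(n_features, 100, 1000))
    baseline <- stats::rlnorm(n_features, meanlog = log(50), sdlog = baseline_sdlog)
    region_means <- vapply(seq_len(n_regions), function(r)
      baseline * exp(rnorm(n_features, 0, region_sdlog)), numeric(n_features))
    marker_idx <- sample.int(n_features, n_regions * markers_per_region)
    marker_high <- stats::quantile(baseline, 0.95) * 5
    markers <- tibble::tibble(
      region = rep(seq_len(n_regions), each = markers_per_region),
      feature = marker_idx)
    for (i in seq_len(nrow(markers))) {
      f <- markers$feature[i]; r <- markers$region[i]
      region_means[f, ] <- marker_high * 0.02
      region_means[f, r] <- marker_high
    }
    markers$mz <- axis[markers$feature]
    nx <- ceiling(sqrt(n_pixels)); ny <- ceiling(n_pixels / nx)
    px <- ((seq_len(n_pixels) - 1L) %% nx) + 1L
    py <- ((seq_len(n_pixels) - 1L) %/% nx) + 1L
    centers <- sample.int(n_pixels, n_regions)
    d2 <- outer(px, px[centers], "-")^2 + outer(py, py[centers], "-")^2
    assignment <- max.col(-d2, ties.method = "first")
    list(axis = axis, baseline = baseline, region_means = region_means,
         markers = markers, px = px, py = py, image_shape = c(nx, ny),
         assignment = assignment,
         params = list(n_pixels = n_pixels, n_features = n_features,
                       n_regions = n_regions, noise_sdlog = noise_sdlog,
                       floor_frac = floor_frac, seed = seed))
  })
  synth_section(truth, noise_seed = seed)
}

# draw one "section": region means + pixel noise
synth_section <- function(truth, noise_seed) {
  p <- truth$params
  vals <- with_local_seed(noise_seed + 10000L, {
    m <- t(truth$region_means[, truth$assignment, drop = FALSE])
    if (p$noise_sdlog > 0)
      m <- m * exp(matrix(rnorm(length(m), 0, p$noise_sdlog), nrow(m)))
    floor_sd <- p$floor_frac * stats::median(truth$baseline)
    if (floor_sd > 0)
      m <- m + matrix(rnorm(length(m), 0, floor_sd), nrow(m))
    m[m < 0] <- 0
    m
  })
  labels <- factor(paste0("region", truth$assignment))
  fm <- feature_matrix(vals, truth$axis,
                       sample_ids = sprintf("px%06d", seq_len(nrow(vals))),
                       group_labels = labels)
  structure(list(matrix = fm,
                 geometry = pixel_geometry(truth$px, truth$py, truth$image_shape),
                 labels = labels, truth = truth),
            class = "msi_synth")
}

#' @rdname synth_msi
#' @param x An `msi_synth` object.
#' @return [synth_replicate()] returns a new `msi_synth` drawn from the same
#'   region truth (a serial section) with fresh noise.
#' @export
synth_replicate <- function(x, seed) {
  stopifnot(inherits(x, "msi_synth"))
  synth_section(x$truth, noise_seed = seed)
}

#' @export
print.msi_synth <- function(x, ...) {
  cat(sprintf("<msi_synth> %d pixels x %d features, %d regions (grid %dx%d)\n",
              nrow(x$matrix), ncol(x$matrix), x$truth$params$n_regions,
              x$truth$image_shape[1], x$truth$image_shape[2]))
  invisible(x)
}

#' Synthetic matched two-modality dataset
#'
#' Emulates matched-sample multiomics where one modality separates the
#' phenotype cleanly and the other does not: a shared latent class variable
#' plus nested "cell line" nuisance structure. Modality B (e.g.
#' transcriptomics) carries a strong class signal and a mild line effect;
#' modality A (e.g. metabolomics) is dominated by the line effect with only
#' an attenuated class signal, so A's own unsupervised embedding organizes
#' by line, not class. Intensities are log-normal (all positive); pairing
#' is one-to-one by sample id.
#'
#' @param n Matched samples (default 200).
#' @param p_a,p_b Feature counts of modalities A and B (defaults 300, 2000).
#' @param classes Number of phenotype classes (default 2).
#' @param n_lines Number of nuisance "cell lines", a multiple of `classes`
#'   (default 10), each line belonging to one class.
#' @param a_class_sep,b_class_sep Class effect sizes on the log scale for A
#'   and B; `b_class_sep` must exceed `a_class_sep` (defaults 0.3 and 2).
#' @param line_sep Line effect size (default 2 in A, `line_sep/4` in B).
#' @param noise_sd Residual log-scale noise sd (default 0.5).
#' @param seed Integer seed.
#' @return List with `pair` (a [matched_pair()]), `class` (factor of length
#'   `n`) and `line`.
#' @export
synth_matched <- function(n = 200L, p_a = 300L, p_b = 2000L, classes = 2L,
                          n_lines = 10L, a_class_sep = 0.3, b_class_sep = 2,
                          line_sep = 2, noise_sd = 0.5, seed = 1L) {
  if (a_class_sep >= b_class_sep)
    stop("modality B must separate classes more cleanly than A (b_class_sep > a_class_sep)",
         call. = FALSE)
  if (n_lines %% classes != 0) stop("`n_lines` must be a multiple of `classes`", call. = FALSE)
  with_local_seed(seed, {
    line <- sample(rep_len(seq_len(n_lines), n))
    class_of_line <- rep_len(seq_len(classes), n_lines)
    cls <- class_of_line[line]
    sig <- function(p, frac = 0.1) {
      v <- numeric(p)
      on <- sample.int(p, max(1L, round(frac * p)))
      v[on] <- sample(c(-1, 1), length(on), replace = TRUE)
      v
    }
    class_dir_a <- vapply(seq_len(classes), function(k) sig(p_a), numeric(p_a))
    class_dir_b <- vapply(seq_len(classes), function(k) sig(p_b), numeric(p_b))
    line_dir_a <- vapply(seq_len(n_lines), function(k) sig(p_a), numeric(p_a))
    line_dir_b <- vapply(seq_len(n_lines), function(k) sig(p_b), numeric(p_b))
    za <- t(class_dir_a[, cls, drop = FALSE]) * a_class_sep +
      t(line_dir_a[, line, drop = FALSE]) * line_sep +
      matrix(rnorm(n * p_a, 0, noise_sd), n)
    zb <- t(class_dir_b[, cls, drop = FALSE]) * b_class_sep +
      t(line_dir_b[, line, drop = FALSE]) * (line_sep / 4) +
      matrix(rnorm(n * p_b, 0, noise_sd), n)
    ids <- sprintf("sample%04d", seq_len(n))
    x_a <- feature_matrix(exp(za), sort(runif(p_a, 50, 1200)),
                          sample_ids = ids, group_labels = factor(cls))
    x_b <- feature_matrix(exp(zb), seq_len(p_b), sample_ids = ids,
                          group_labels = factor(cls), axis_type = "bin")
    list(pair = matched_pair(x_a, x_b),
         class = factor(paste0("class", cls)),
         line = factor(paste0("line", line)))
  })
}

#' Synthetic outlier-detection set
#'
#' Builds a clustered training matrix, an in-distribution replicate drawn
#' from the same clusters, and a novel cluster whose mean is displaced from
#' every training cluster mean by `offset` within-cluster standard
#' deviations per feature (in log space). At `offset = 0` the "novel"
#' samples are statistically indistinguishable from the training data.
#'
#' @param n_train,n_new Training and per-set new sample counts.
#' @param n_features,n_clusters Shape of the training mixture.
#' @param offset Displacement of the novel cluster mean in units of the
#'   within-cluster sd (default 5).
#' @param noise_sdlog Within-cluster log-scale sd (default 0.25).
#' @param seed Integer seed.
#' @return List with `train` ([feature_matrix()] with cluster labels),
#'   `replicate`, `novel` and `truth` (logical flags for
#'   `rbind(replicate, novel)`).
#' @export
synth_outliers <- function(n_train = 600L, n_new = 100L, n_features = 200L,
                           n_clusters = 4L, offset = 5, noise_sdlog = 0.25,
                           seed = 1L) {
  if (offset < 0) stop("`offset` must be >= 0", call. = FALSE)
  with_local_seed(seed, {
    axis <- sort(runif(n_features, 100, 1000))
    baseline <- stats::rlnorm(n_features, log(50), 1)
    centers <- vapply(seq_len(n_clusters), function(k)
      log(baseline) + rnorm(n_features, 0, 0.6), numeric(n_features))
    cl_train <- rep_len(seq_len(n_clusters), n_train)
    xtr <- t(exp(centers[, cl_train] + matrix(rnorm(n_features * n_train, 0, noise_sdlog), n_features)))
    cl_rep <- rep_len(seq_len(n_clusters), n_new)
    xrep <- t(exp(centers[, cl_rep] + matrix(rnorm(n_features * n_new, 0, noise_sdlog), n_features)))
    novel_center <- centers[, 1L] + rnorm(n_features, 0, offset * noise_sdlog)
    xnov <- t(exp(novel_center + matrix(rnorm(n_features * n_new, 0, noise_sdlog), n_features)))
    mk <- function(v, prefix, labels = NULL)
      feature_matrix(v, axis, sample_ids = sprintf("%s%05d", prefix, seq_len(nrow(v))),
                     group_labels = labels)
    list(train = mk(xtr, "tr", factor(cl_train)),
         replicate = mk(xrep, "rep", factor(cl_rep)),
         novel = mk(xnov, "nov"),
         truth = c(rep(FALSE, n_new), rep(TRUE, n_new)))
  })
}

#' Toy Hi-C contact-list generator
#'
#' Writes a small random intrachromosomal contact list in the 3-column
#' text convention for I/O tests and examples; not a physically realistic
#' contact model.
#'
#' @param n_records Number of contacts.
#' @param genome_bp Chromosome length in bp.
#' @param bin_bp Position granularity (positions are multiples of this).
#' @param seed Integer seed.
#' @return A [sparse_contacts()] table (upper triangle: `pos1 <= pos2`).
#' @export
synth_contacts <- function(n_records = 100L, genome_bp = 1e6, bin_bp = 1000L,
                           seed = 1L) {
  with_local_seed(seed, {
    nbin <- floor(genome_bp / bin_bp)
    p1 <- (sample.int(nbin, n_records, replace = TRUE) - 1L) * bin_bp
    p2 <- (sample.int(nbin, n_records, replace = TRUE) - 1L) * bin_bp
    lo <- pmin(p1, p2); hi <- pmax(p1, p2)
    ct <- stats::rpois(n_records, 3) + 1L
    sparse_contacts(lo, hi, ct)
  })
}

#' @rdname synth_contacts
#' @param contacts A [sparse_contacts()] table.
#' @param path Output path.
#' @export
write_contacts <- function(contacts, path) {
  data.table::fwrite(contacts[, c("pos1", "pos2", "count")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}
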