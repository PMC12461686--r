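#' Run the full surrogate-embedding pipeline
#'
#' Ties the stages together: subsample the data, compute the reference
#' embedding of the subset, train the forward and inverse networks, apply
#' the forward network to all samples, and write every artifact plus a
#' machine-readable provenance record to a directory. Rerunning with the
#' same configuration and seeds reproduces identical artifacts.
#'
#' @param x A [feature_matrix()], or a path to a delimited matrix readable
#'   by [read_feature_matrix()].
#' @param out_dir Output directory (created if absent).
#' @param geometry Optional [pixel_geometry()]; when present an RGB
#'   rendering of the full-data coordinates is written as PNG.
#' @param subsample_n Step of the every-n-th subsampling (default 10).
#' @param method,dims,metric,seed Passed to [embed_reference()].
#' @param config [train_config()] for both network directions.
#' @param ... Further arguments to [embed_reference()].
#' @return Invisibly, a list with the embedding, both maps, the full-data
#'   coordinates and the artifact paths.
#' @export
run_pipeline <- function(x, out_dir, geometry = NULL, subsample_n = 10L,
                         method = "tsne", dims = 3L, metric = "correlation",
                         seed = 1L, config = train_config(seed = seed), ...) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("input path not found: ", x, call. = FALSE)
    x <- read_feature_matrix(x)
  }
  stopifnot(inherits(x, "feature_matrix"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)

  sub <- every_nth(nrow(x), subsample_n)
  write.csv(data.frame(index = sub$indices), pth("subset_indices.csv"), row.names = FALSE)

  xs <- x[sub$indices, , drop = FALSE]
  xs <- feature_matrix(xs, feature_axis(x), sample_ids = sample_ids(x)[sub$indices])
  e <- normalize_embedding(embed_reference(xs, method = method, dims = dims,
                                           metric = metric, seed = seed, ...))
  write.csv(as.data.frame(e$coords), pth("subset_embedding.csv"), row.names = FALSE)

  fwd <- fit_forward(xs, e, config)
  inv <- fit_inverse(e, xs, config)
  write_learned_map(fwd, pth("forward_map.json"))
  write_learned_map(inv, pth("inverse_map.json"))

  coords <- predict(fwd, x)
  write.csv(as.data.frame(coords), pth("coordinates.csv"), row.names = FALSE)

  paths <- c(indices = pth("subset_indices.csv"),
             embedding = pth("subset_embedding.csv"),
             forward = pth("forward_map.json"),
             inverse = pth("inverse_map.json"),
             coordinates = pth("coordinates.csv"))
  if (!is.null(geometry) && dims == 3L) {
    img <- rgb_render(pmin(pmax(coords, 0), 1), geometry)
    png::writePNG(img, pth("rgb.png"))
    paths["rgb"] <- pth("rgb.png")
  }

  provenance <- list(
    n_samples = nrow(x), n_features = ncol(x),
    subsample = list(scheme = "every_nth", n = subsample_n,
                     n_selected = length(sub$indices)),
    embedding = list(method = method, dims = dims, metric = metric,
                     params = e$params, seed = seed),
    train_config = unclass(config),
    diagnostics = list(forward = fwd$diagnostics, inverse = inv$diagnostics))
  jsonlite::write_json(provenance, pth("provenance.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  paths["provenance"] <- pth("provenance.json")

  invisible(list(subset = sub, embedding = e, forward = fwd, inverse = inv,
                 coordinates = coords, paths = paths))
}
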