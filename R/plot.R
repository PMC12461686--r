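#' @method autoplot embedding
#' @export
autoplot.embedding <- function(object, colour = NULL, ...) {
  df <- as.data.frame(object$coords[, 1:2, drop = FALSE])
  names(df) <- c("dim1", "dim2")
  if (ncol(object$coords) == 3L && is.null(colour)) {
    e <- if (object$normalized) object else normalize_embedding(object)
    df$col <- grDevices::rgb(e$coords[, 1], e$coords[, 2], e$coords[, 3])
    ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2)) +
      ggplot2::geom_point(colour = df$col, size = 0.5) +
      ggplot2::labs(x = "dimension 1", y = "dimension 2") +
      ggplot2::theme_minimal()
  } else {
    df$colour <- colour %||% "sample"
    ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2, colour = .data$colour)) +
      ggplot2::geom_point(size = 0.5) +
      ggplot2::labs(x = "dimension 1", y = "dimension 2", colour = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Plot an ion image or RGB rendering
#'
#' @param img Matrix from [ion_image()] or `ny x nx x 3` array from
#'   [rgb_render()].
#' @return A ggplot object.
#' @export
plot_image <- function(img) {
  if (length(dim(img)) == 3L) {
    ny <- dim(img)[1L]; nx <- dim(img)[2L]
    df <- expand.grid(y = seq_len(ny), x = seq_len(nx))
    df$fill <- grDevices::rgb(img[, , 1][cbind(df$y, df$x)],
                              img[, , 2][cbind(df$y, df$x)],
                              img[, , 3][cbind(df$y, df$x)])
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
      ggplot2::geom_raster(fill = df$fill) +
      ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
      ggplot2::theme_void()
  } else {
    df <- expand.grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
    df$intensity <- img[cbind(df$y, df$x)]
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
      ggplot2::scale_fill_viridis_c() + ggplot2::theme_void()
  }
}
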