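# ggplot2 views of slices, training histories and method comparisons.

#' Plot one slice of a volume with optional mask overlays
#'
#' @param volume An [mr_volume()] or 3-d array.
#' @param slice Slice index.
#' @param masks Optional named list of binary 3-d arrays to outline.
#' @return A ggplot object.
#' @export
plot_slice <- function(volume, slice = 1L, masks = NULL) {
  vox <- if (inherits(volume, "mr_volume")) volume$voxels else volume
  sl <- vox[, , slice]
  df <- tidyr::expand_grid(y = seq_len(nrow(sl)), x = seq_len(ncol(sl)))
  df$intensity <- as.vector(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(masks)) {
    overlay <- dplyr::bind_rows(lapply(names(masks), function(nm) {
      m <- masks[[nm]][, , slice]
      idx <- which(m != 0, arr.ind = TRUE)
      if (!nrow(idx)) return(NULL)
      tibble::tibble(y = idx[, 1], x = idx[, 2], mask = nm)
    }))
    if (nrow(overlay)) {
      p <- p + ggplot2::geom_tile(
        data = overlay,
        ggplot2::aes(.data$x, .data$y, colour = .data$mask),
        fill = NA, linewidth = 0.2, inherit.aes = FALSE)
    }
  }
  p
}

#' @rdname autoplot.train_history
#' @export
autoplot.train_history <- function(object, ...) {
  ggplot2::ggplot(tidy.train_history(object),
                  ggplot2::aes(.data$epoch, .data$value,
                               colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot training curves or comparison tables
#'
#' `autoplot()` methods for the package's result objects: loss/validation
#' curves for a `train_history`, and per-metric mean +/- sd bars for a
#' `method_comparison`.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.method_comparison <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(.data$method, .data$mean, fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "method", y = "% (mean ± sd across patients)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
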