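#' Plot a topography
#'
#' Interpolated scalp map over the idealized cap layout, faceted by any
#' metadata columns present (task, band, condition). Interpolation is an
#' inverse-distance weighting on a regular grid clipped to the unit disc;
#' electrode positions are overplotted as points.
#'
#' @param object a `topography` tibble.
#' @param grid_n interpolation grid resolution per axis (default 60).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.topography <- function(object, grid_n = 60, ...) {
  meta_cols <- intersect(c("task", "band", "condition", "bin"), names(object))
  meta_cols <- meta_cols[vapply(meta_cols, function(c) {
    length(unique(object[[c]])) > 1
  }, logical(1))]
  groups <- if (length(meta_cols)) split(object, object[meta_cols], drop = TRUE)
            else list(object)
  gx <- seq(-1.05, 1.05, length.out = grid_n)
  grid <- expand.grid(x = gx, y = gx)
  grid <- grid[grid$x^2 + grid$y^2 <= 1.1, ]
  interp <- dplyr::bind_rows(lapply(groups, function(g) {
    w <- outer(seq_len(nrow(grid)), seq_len(nrow(g)), function(i, j) {
      1 / ((grid$x[i] - g$x[j])^2 + (grid$y[i] - g$y[j])^2 + 1e-3)
    })
    out <- grid
    out$value <- as.numeric(w %*% g$value / rowSums(w))
    for (c in meta_cols) out[[c]] <- g[[c]][1]
    out
  }))
  p <- ggplot2::ggplot(interp, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(data = object, size = 0.4, colour = "black") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "value")
  if (length(meta_cols)) {
    p <- p + ggplot2::facet_wrap(meta_cols)
  }
  p
}

#' Plot classifier weight images
#'
#' Component x (band, bin) heat map per one-vs-all learner: which
#' component, band and trial phase the classifier weighted.
#'
#' @param object a `weight_image` from [reproject_weights()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.weight_image <- function(object, ...) {
  df <- dplyr::mutate(object,
                      band = factor(.data$band, levels = eeg_bands()$name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = factor(.data$component),
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$learner),
                        cols = ggplot2::vars(.data$band)) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = "time bin", y = "component", fill = "weight") +
    ggplot2::theme_minimal()
}

#' Plot EMG fingerprints
#'
#' Average rate of change of each muscle's activity envelope over
#' normalized trial time, per task.
#'
#' @param object an `emg_fingerprint` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.emg_fingerprint <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$rate_of_change,
                                       colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(ggplot2::vars(.data$task)) +
    ggplot2::labs(x = "normalized time bin", y = "rate of change (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot per-condition accuracies of an experiment report
#'
#' @param object an `experiment_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.experiment_report <- function(object, ...) {
  df <- object$accuracies
  df$condition <- factor(df$condition,
                         levels = c("brain", "artifact", "all", "emg"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data$mean_accuracy)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0.2, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(ggplot2::vars(.data$approach)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "classification accuracy", x = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
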