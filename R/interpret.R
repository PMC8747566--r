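#' Topography container
#'
#' One scalar per channel plus the 2-D layout, with metadata describing what
#' the values are (task, band, bin, condition). Tabular throughout: a tibble
#' with class `topography` so it pipes into dplyr and [ggplot2::autoplot()].
#'
#' @param values numeric vector, one per channel.
#' @param layout cap layout tibble from [cap_layout()].
#' @param ... metadata columns recycled across channels (e.g. `task`,
#'   `band`, `condition`).
#' @return tibble with columns `channel`, `x`, `y`, `value`, and metadata.
#' @export
topography <- function(values, layout, ...) {
  stopifnot(length(values) == nrow(layout))
  out <- tibble::tibble(channel = layout$channel, x = layout$x, y = layout$y,
                        value = as.numeric(values), ...)
  class(out) <- c("topography", class(out))
  out
}

#' Reproject classifier weights to the component time-frequency space
#'
#' Inverts the per-band PCA of the feature pipeline: each binary learner's
#' weight vector (length bands x per-band components, e.g. 70) is multiplied
#' band-by-band with the stored PCA rotation, recovering a weight per
#' original (component, band, bin) column -- 500 values for a 10-component
#' condition. Weights learned on standardized features are unscaled first.
#'
#' @param model a `trained_linear_model` from [ecoc_train_test()] fitted
#'   with `per_band_k` set.
#' @param projection optional `pca_projection`; defaults to the one stored
#'   in the model.
#' @return object of class `weight_image`: tibble with columns `learner`
#'   (the positive task of the one-vs-all learner), `component`, `band`,
#'   `bin`, `weight`.
#' @export
reproject_weights <- function(model, projection = NULL) {
  stopifnot(inherits(model, "trained_linear_model"))
  projection <- projection %||% model$projection
  if (is.null(projection)) stop("model carries no PCA projection record")
  stopifnot(inherits(projection, "pca_projection"))
  meta <- model$column_meta
  src <- projection$source_meta
  rows <- list()
  for (cls in model$classes) {
    w <- model$weights[cls, ] / model$standardize$scale
    for (b in names(projection$bands) ) {
      pb <- projection$bands[[b]]
      cols_b <- meta$column[meta$band == b]
      if (!all(cols_b %in% names(w))) stop("feature metadata mismatch")
      w_src <- drop(pb$rotation %*% w[cols_b])   # back to original columns
      m <- src[match(pb$columns, src$column), ]
      rows[[length(rows) + 1]] <- tibble::tibble(
        learner = cls, component = m$component, band = m$band, bin = m$bin,
        weight = w_src)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("weight_image", class(out))
  out
}

#' Sensor-space topography of a weight-image slice
#'
#' Takes the component weights of one (learner, band, bin) slice and
#' multiplies them by the ICA mixing matrix, giving one value per channel:
#' the scalp projection of what the classifier weighted.
#'
#' @param image a `weight_image` from [reproject_weights()].
#' @param band band name.
#' @param bin time-bin index.
#' @param mixing channels x components mixing matrix restricted to the
#'   components in the image (e.g. `dec$mixing[, indices]`).
#' @param layout cap layout tibble.
#' @param learner which one-vs-all learner (default: all, one topography
#'   each).
#' @return a `topography` tibble (stacked over learners).
#' @export
weights_to_topography <- function(image, band, bin, mixing, layout,
                                  learner = NULL) {
  stopifnot(inherits(image, "weight_image"))
  slice <- image[image$band == band & image$bin == bin, ]
  if (nrow(slice) == 0) stop("no such band/bin slice in the weight image")
  learners <- learner %||% unique(slice$learner)
  comps <- sort(unique(slice$component))
  if (length(comps) != ncol(mixing)) {
    stop("mixing column count does not match the image's component count")
  }
  dplyr::bind_rows(lapply(learners, function(l) {
    s <- slice[slice$learner == l, ]
    w <- s$weight[match(comps, s$component)]
    topography(drop(mixing %*% w), layout, task = l, band = band, bin = bin)
  }))
}

#' Forward-model ("ideal") task pattern from a filter topography
#'
#' Multiplies a sensor-space filter by the channel covariance of one task's
#' epochs (averaged over trials), converting the backward decoding filter
#' into a forward activation pattern -- for a linear decoder on Gaussian
#' data this recovers the generative pattern up to scale.
#'
#' @param top a `topography` holding the filter values (one learner).
#' @param task_epochs list of channel-space [trial_epoch()]s of one task.
#' @param layout cap layout tibble.
#' @return a `topography` of the task pattern.
#' @export
task_pattern <- function(top, task_epochs, layout) {
  stopifnot(inherits(top, "topography"), length(task_epochs) >= 1)
  covs <- lapply(task_epochs, function(e) {
    Xc <- e$data - rowMeans(e$data)
    tcrossprod(Xc) / (ncol(Xc) - 1)
  })
  C <- Reduce(`+`, covs) / length(covs)
  if (nrow(C) != nrow(top)) stop("dimension mismatch between epochs and topography")
  if (sum(abs(C)) == 0) stop("degenerate (all-zero) task covariance")
  vals <- drop(C %*% top$value)
  meta <- top[1, setdiff(names(top), c("channel", "x", "y", "value")), drop = FALSE]
  out <- topography(vals, layout)
  for (nm in names(meta)) out[[nm]] <- meta[[nm]]
  out
}

#' Per-task bandpower topographies
#'
#' Averages the per-channel bandpower features over all trials of each task,
#' giving one topography per task for a given band and condition.
#'
#' @param table a bandpower `feature_table` (from
#'   [bandpower_feature_table()]).
#' @param layout cap layout tibble.
#' @param condition optional condition tag carried into the metadata.
#' @return a `topography` tibble stacked over tasks.
#' @export
bandpower_topography <- function(table, layout, condition = NULL) {
  stopifnot(inherits(table, "feature_table"))
  meta <- attr(table, "column_meta")
  band <- unique(meta$band)
  means <- table |>
    dplyr::group_by(.data$task) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(meta$column), mean),
                     .groups = "drop")
  dplyr::bind_rows(lapply(seq_len(nrow(means)), function(i) {
    vals <- as.numeric(means[i, meta$column])
    topography(vals, layout, task = means$task[i], band = band,
               condition = condition %||% NA_character_)
  }))
}
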