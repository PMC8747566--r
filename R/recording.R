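#' Multichannel recording container
#'
#' A lightweight matrix-backed container for continuous multichannel biosignal
#' data: a channels x samples matrix (microvolts), a sampling rate in Hz, an
#' ordered vector of channel names, and an event table.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param rate sampling rate in Hz (> 0).
#' @param channel_names character vector, one name per row of `data`.
#' @param events tibble with columns `code` (character) and `sample`
#'   (0-based integer sample index); further columns (e.g. `trial`, `task`,
#'   `phase`) are carried along untouched.
#'
#' @return An object of class `mc_recording`.
#' @export
mc_recording <- function(data, rate, channel_names = NULL, events = NULL) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), length(rate) == 1L, rate > 0)
  if (is.null(channel_names)) {
    channel_names <- sprintf("E%02d", seq_len(nrow(data)))
  }
  stopifnot(length(channel_names) == nrow(data))
  if (is.null(events)) {
    events <- tibble::tibble(code = character(), sample = integer())
  }
  events <- tibble::as_tibble(events)
  stopifnot(all(c("code", "sample") %in% names(events)))
  if (nrow(events) > 0 &&
      (min(events$sample) < 0 || max(events$sample) >= ncol(data))) {
    stop("event sample indices must lie in [0, n_samples)")
  }
  structure(
    list(data = data, rate = rate, channel_names = channel_names,
         events = events),
    class = "mc_recording"
  )
}

#' @export
print.mc_recording <- function(x, ...) {
  cat(sprintf("<mc_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
              nrow(x$events)))
  invisible(x)
}

#' @export
dim.mc_recording <- function(x) dim(x$data)

#' Trial epoch container
#'
#' One task/phase segment of a recording: channels x samples, with the task
#' label and phase attached. Epoch durations vary from trial to trial because
#' the execution phase ends when the movement does.
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param rate sampling rate in Hz.
#' @param task task label (character scalar).
#' @param phase `"preparation"` or `"execution"`.
#' @param trial integer trial index within the session.
#' @param channel_names optional channel names.
#'
#' @return An object of class `trial_epoch`.
#' @export
trial_epoch <- function(data, rate, task, phase = "execution", trial = NA_integer_,
                        channel_names = NULL) {
  data <- as.matrix(data)
  stopifnot(ncol(data) > 0, rate > 0)
  if (is.null(channel_names)) channel_names <- rownames(data)
  structure(
    list(data = data, rate = rate, task = as.character(task),
         phase = phase, trial = as.integer(trial),
         channel_names = channel_names),
    class = "trial_epoch"
  )
}

#' @export
print.trial_epoch <- function(x, ...) {
  cat(sprintf("<trial_epoch> trial %s task '%s' (%s): %d ch x %d samples @ %g Hz\n",
              x$trial, x$task, x$phase, nrow(x$data), ncol(x$data), x$rate))
  invisible(x)
}

#' Idealized 2-D electrode cap layout
#'
#' Places `n` electrodes on the unit disc with a sunflower (Fibonacci-spiral)
#' arrangement, rotated so the first electrodes sit frontally. The layout is a
#' smooth idealization of an extended 10-5 montage: the positive y direction
#' is the nasion (front), radius 1 is the cap edge. It is used for synthetic
#' source topographies, the rule-based component labeler, and topographic
#' plots; it does not claim to reproduce any particular physical montage.
#'
#' @param n number of electrodes.
#' @return tibble with columns `channel`, `x`, `y`, `radius` (distance from
#'   vertex) and `frontal` / `edge` flags used by the labeler.
#' @export
cap_layout <- function(n = 64) {
  stopifnot(n >= 1)
  i <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  r <- sqrt((i - 0.5) / n)
  theta <- i * golden + pi / 2   # rotate so index 1 is frontal-ish
  tibble::tibble(
    channel = sprintf("E%02d", i),
    x = r * cos(theta),
    y = r * sin(theta),
    radius = r,
    frontal = r * sin(theta) > 0.55,
    edge = r > 0.85
  )
}

# Gaussian bump over the layout, used for synthetic topographies.
topo_bump <- function(layout, center, width) {
  d2 <- (layout$x - center[1])^2 + (layout$y - center[2])^2
  exp(-d2 / (2 * width^2))
}
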