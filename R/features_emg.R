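#' RMS envelope of an EMG epoch
#'
#' High-pass filters each channel (zero-phase Butterworth, default 10 Hz
#' cutoff), computes a centered sliding-window RMS envelope (default 250 ms,
#' edge-padded so the output has the same length as the input) and smooths it
#' with a Gaussian kernel (default 100 ms window, sigma = window / 4
#' truncated at +/- 2 sigma). The envelope is non-negative by construction.
#'
#' @param epoch a [trial_epoch()] of EMG data.
#' @param hp_cutoff high-pass cutoff in Hz (default 10).
#' @param rms_window RMS window length in seconds (default 0.25).
#' @param smooth_window Gaussian smoothing window in seconds (default 0.1).
#' @return numeric matrix, channels x samples, the smoothed envelope.
#' @export
emg_envelope <- function(epoch, hp_cutoff = 10, rms_window = 0.25,
                         smooth_window = 0.1) {
  stopifnot(inherits(epoch, "trial_epoch"))
  n <- ncol(epoch$data)
  win <- round(rms_window * epoch$rate)
  if (n <= win) stop("epoch shorter than the RMS window")
  bf <- signal::butter(2, hp_cutoff / (epoch$rate / 2), type = "high")
  box <- rep(1 / win, win)
  sd_samp <- smooth_window * epoch$rate / 4
  t(apply(epoch$data, 1, function(ch) {
    f <- as.numeric(signal::filtfilt(bf, ch))^2
    ms <- conv_same(f, box)
    gauss_smooth(sqrt(pmax(ms, 0)), sd_samp)
  }))
}

#' Duration-normalize and bin an envelope
#'
#' Resamples an envelope to `n_points` time points via linear interpolation
#' (so trials of different durations become comparable), then averages over
#' consecutive blocks of `n_points / n_bins` points, yielding `n_bins`
#' values.
#'
#' @param envelope numeric vector (one channel's envelope).
#' @param n_points number of normalized time points (default 1000).
#' @param n_bins number of output bins (default 10).
#' @return numeric vector of length `n_bins`.
#' @export
normalize_and_bin <- function(envelope, n_points = 1000, n_bins = 10) {
  stopifnot(length(envelope) >= n_bins, n_points %% n_bins == 0)
  u <- seq(0, 1, length.out = length(envelope))
  res <- stats::approx(u, envelope, xout = seq(0, 1, length.out = n_points))$y
  colMeans(matrix(res, nrow = n_points / n_bins))
}

#' EMG feature row for one trial
#'
#' Envelope, duration normalization and binning for each of the 7 muscle
#' channels, concatenated to a 70-element feature vector (channel-major:
#' channel 1 bins 1..10, channel 2 bins 1..10, ...).
#'
#' @param epoch a 7-channel EMG [trial_epoch()].
#' @param n_bins bins per channel (default 10).
#' @param ... passed to [emg_envelope()].
#' @return named numeric vector of length `7 * n_bins`; names are
#'   `<channel>.b<bin>`.
#' @export
emg_feature_vector <- function(epoch, n_bins = 10, ...) {
  stopifnot(inherits(epoch, "trial_epoch"))
  if (nrow(epoch$data) != 7) stop("expected 7 EMG channels")
  env <- emg_envelope(epoch, ...)
  chn <- epoch$channel_names %||% sprintf("emg%d", 1:7)
  out <- unlist(lapply(seq_len(7), function(ch) {
    v <- normalize_and_bin(env[ch, ], n_bins = n_bins)
    names(v) <- sprintf("%s.b%02d", chn[ch], seq_len(n_bins))
    v
  }))
  out
}

#' EMG feature table across trials
#'
#' @param epochs list of 7-channel EMG [trial_epoch()]s.
#' @param n_bins bins per channel (default 10).
#' @param ... passed to [emg_envelope()].
#' @return a `feature_table` tibble: one row per trial with `trial`, `task`
#'   and 70 feature columns; column metadata (channel, bin) in
#'   `attr(, "column_meta")`, approach `"emg"`.
#' @export
emg_feature_table <- function(epochs, n_bins = 10, ...) {
  rows <- lapply(epochs, function(e) {
    v <- emg_feature_vector(e, n_bins = n_bins, ...)
    tibble::tibble(trial = e$trial, task = e$task, !!!as.list(v))
  })
  tbl <- dplyr::bind_rows(rows)
  meta <- tibble::tibble(
    column = names(tbl)[-(1:2)],
    channel = sub("\\.b\\d+$", "", names(tbl)[-(1:2)]),
    bin = as.integer(sub("^.*\\.b", "", names(tbl)[-(1:2)]))
  )
  new_feature_table(tbl, meta, approach = "emg")
}

#' Task-average EMG rate-of-change fingerprint
#'
#' For each channel: first difference of the duration-normalized, binned
#' envelope, averaged across all trials of a task (and, when epochs from
#' several sessions are pooled, across sessions). This is the task's "EMG
#' fingerprint": which muscles accelerate or release at which phase of the
#' movement, in arbitrary units.
#'
#' @param epochs list of EMG [trial_epoch()]s, all with the same task (or
#'   mixed; fingerprints are computed per task).
#' @param n_bins number of normalized time bins (default 10; the curve has
#'   `n_bins - 1` points).
#' @param ... passed to [emg_envelope()].
#' @return tibble with columns `task`, `channel`, `bin`, `rate_of_change`;
#'   class `emg_fingerprint`.
#' @export
emg_fingerprint <- function(epochs, n_bins = 10, ...) {
  stopifnot(length(epochs) >= 1)
  rows <- lapply(epochs, function(e) {
    env <- emg_envelope(e, ...)
    chn <- e$channel_names %||% sprintf("emg%d", seq_len(nrow(env)))
    dplyr::bind_rows(lapply(seq_len(nrow(env)), function(ch) {
      b <- normalize_and_bin(env[ch, ], n_bins = n_bins)
      tibble::tibble(task = e$task, channel = chn[ch],
                     bin = seq_len(n_bins - 1), rate_of_change = diff(b))
    }))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$task, .data$channel, .data$bin) |>
    dplyr::summarise(rate_of_change = mean(.data$rate_of_change),
                     .groups = "drop")
  class(out) <- c("emg_fingerprint", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
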