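#' Resample a recording to a lower rate
#'
#' Anti-alias low-pass filtering (zero-phase Butterworth at 0.45 of the
#' target rate) followed by decimation when the ratio of rates is an integer,
#' or linear interpolation onto the new sample grid otherwise. Event sample
#' indices are rescaled and floored to the nearest output sample.
#'
#' @param rec a [mc_recording()].
#' @param target_rate target sampling rate in Hz; must not exceed `rec$rate`.
#' @return a resampled [mc_recording()].
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "mc_recording"))
  if (target_rate > rec$rate) stop("upsampling is not supported")
  if (target_rate == rec$rate) return(rec)
  bf <- signal::butter(4, 0.45 * target_rate / (rec$rate / 2), type = "low")
  filtered <- t(apply(rec$data, 1, function(ch) signal::filtfilt(bf, ch)))
  ratio <- rec$rate / target_rate
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1, ncol(filtered), by = round(ratio))
    out <- filtered[, idx, drop = FALSE]
  } else {
    old_t <- (seq_len(ncol(filtered)) - 1) / rec$rate
    new_t <- seq(0, old_t[length(old_t)], by = 1 / target_rate)
    out <- t(apply(filtered, 1, function(ch) {
      stats::approx(old_t, ch, xout = new_t)$y
    }))
  }
  events <- rec$events
  if (nrow(events) > 0) {
    events$sample <- pmin(as.integer(floor(events$sample * target_rate / rec$rate)),
                          ncol(out) - 1L)
  }
  mc_recording(out, target_rate, rec$channel_names, events)
}

apply_filter_all <- function(rec, flt) {
  out <- rec
  out$data <- t(apply(rec$data, 1, function(ch) {
    as.numeric(signal::filtfilt(flt, ch))
  }))
  out
}

#' High-pass filter a recording
#'
#' Zero-phase Butterworth high-pass (second-order section applied
#' forward-backward, i.e. fourth-order magnitude response), removing drift
#' and DC offsets while leaving the passband (>= 2x cutoff) within 1 dB.
#'
#' @param rec a [mc_recording()].
#' @param cutoff cutoff frequency in Hz (default 0.5).
#' @return filtered [mc_recording()].
#' @export
highpass_filter <- function(rec, cutoff = 0.5) {
  stopifnot(inherits(rec, "mc_recording"))
  if (cutoff <= 0 || cutoff >= rec$rate / 2) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  }
  apply_filter_all(rec, signal::butter(2, cutoff / (rec$rate / 2), type = "high"))
}

#' Notch filter line noise
#'
#' Zero-phase second-order IIR notch (constrained biquad, quality factor 30
#' by default) centered on the mains frequency; bands 5 Hz away are
#' attenuated by less than 1 dB.
#'
#' @param rec a [mc_recording()].
#' @param freq notch center frequency in Hz (default 50).
#' @param q quality factor (center frequency / -3 dB bandwidth).
#' @return filtered [mc_recording()].
#' @export
notch_filter <- function(rec, freq = 50, q = 30) {
  stopifnot(inherits(rec, "mc_recording"))
  if (freq <= 0 || freq >= rec$rate / 2) {
    stop("notch frequency must lie strictly between 0 and the Nyquist frequency")
  }
  w0 <- 2 * pi * freq / rec$rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  apply_filter_all(rec, signal::Arma(b = b / a[1], a = a / a[1]))
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the per-sample channel mean of the output is exactly zero. Note this
#' reduces the rank of the data by one.
#'
#' @param rec a [mc_recording()].
#' @return re-referenced [mc_recording()].
#' @export
rereference_car <- function(rec) {
  stopifnot(inherits(rec, "mc_recording"))
  if (nrow(rec$data) < 2) stop("common average reference needs >= 2 channels")
  out <- rec
  out$data <- sweep(rec$data, 2, colMeans(rec$data))
  out
}

#' Epoch a recording by its event markers
#'
#' Builds one preparation and one execution [trial_epoch()] per trial from
#' the phase markers: the preparation epoch spans fixation onset to task
#' onset, the execution epoch spans task onset to completion. Trials with a
#' malformed marker sequence (e.g. an onset without a completion) are skipped
#' with a warning, mirroring the false-trigger checks of the original
#' protocol.
#'
#' @param rec a [mc_recording()] whose `events` carry `trial`, `task` and
#'   `phase` columns (as produced by [simulate_session()]), or an explicit
#'   `event_table` in the same shape.
#' @param event_table optional tibble overriding `rec$events`.
#' @param phases which phases to emit (default preparation + execution).
#' @return list of [trial_epoch()]s, ordered by trial.
#' @export
epoch_by_events <- function(rec, event_table = NULL,
                            phases = c("preparation", "execution")) {
  stopifnot(inherits(rec, "mc_recording"))
  ev <- if (is.null(event_table)) rec$events else tibble::as_tibble(event_table)
  if (nrow(ev) == 0) stop("empty event table")
  if (!all(c("trial", "task", "phase", "sample") %in% names(ev))) {
    stop("event table needs trial, task, phase, sample columns")
  }
  epochs <- list()
  for (tr in sort(unique(ev$trial))) {
    e <- ev[ev$trial == tr, ]
    task <- e$task[1]
    fix <- e$sample[e$phase == "fixation"]
    onset <- e$sample[e$phase == "execution"]
    completion <- e$sample[e$phase == "completion"]
    rest <- e$sample[e$phase == "rest"]
    if ("preparation" %in% phases) {
      if (length(fix) == 1 && length(onset) == 1 && onset > fix) {
        epochs[[length(epochs) + 1]] <- trial_epoch(
          rec$data[, (fix + 1):onset, drop = FALSE], rec$rate, task,
          phase = "preparation", trial = tr, channel_names = rec$channel_names)
      } else {
        warning(sprintf("trial %d: malformed preparation markers, skipped", tr))
      }
    }
    if ("execution" %in% phases) {
      stop_sample <- if (length(completion) == 1) completion
        else NA_integer_
      if (length(onset) == 1 && !is.na(stop_sample) && stop_sample > onset) {
        epochs[[length(epochs) + 1]] <- trial_epoch(
          rec$data[, (onset + 1):stop_sample, drop = FALSE], rec$rate, task,
          phase = "execution", trial = tr, channel_names = rec$channel_names)
      } else {
        warning(sprintf("trial %d: missing completion marker, skipped", tr))
      }
    }
  }
  if (length(epochs) == 0) stop("no well-formed trials found")
  epochs
}

#' Subtract the per-channel mean from an epoch
#'
#' @param epoch a [trial_epoch()].
#' @return the baselined [trial_epoch()]: every channel has zero mean.
#' @export
baseline_subtract <- function(epoch) {
  stopifnot(inherits(epoch, "trial_epoch"), ncol(epoch$data) > 0)
  epoch$data <- epoch$data - rowMeans(epoch$data)
  epoch
}

#' Standard continuous-conditioning pipeline
#'
#' Applies, in order: downsample to `analysis_rate`, high-pass at `hp_cutoff`,
#' notch at `notch_freq`, common average reference (EEG only), epoching by
#' event markers, and per-channel mean baselining of every epoch.
#'
#' @param rec a [mc_recording()].
#' @param analysis_rate target rate in Hz (default 500).
#' @param hp_cutoff high-pass cutoff in Hz (default 0.5).
#' @param notch_freq mains frequency in Hz (default 50).
#' @param car apply the common average reference (default `TRUE`; set to
#'   `FALSE` for EMG).
#' @param phases phases to epoch (default execution only, the segments the
#'   decoding pipeline consumes).
#' @return list with `recording` (the conditioned continuous signal) and
#'   `epochs` (list of baselined [trial_epoch()]s).
#' @export
preprocess_pipeline <- function(rec, analysis_rate = 500, hp_cutoff = 0.5,
                                notch_freq = 50, car = TRUE,
                                phases = "execution") {
  out <- resample_recording(rec, analysis_rate)
  out <- highpass_filter(out, hp_cutoff)
  out <- notch_filter(out, notch_freq)
  if (car) out <- rereference_car(out)
  epochs <- epoch_by_events(out, phases = phases)
  epochs <- lapply(epochs, baseline_subtract)
  list(recording = out, epochs = epochs)
}
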