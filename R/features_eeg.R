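#' Canonical EEG frequency bands
#'
#' theta 3-7 Hz, alpha 7-13 Hz, low beta 13-16 Hz, beta 16-26 Hz, gamma
#' 26-40 Hz; the bandpower route adds `all` = 3-40 Hz.
#'
#' @param include_all include the broadband 3-40 Hz band (default `FALSE`).
#' @return tibble with columns `name`, `lo`, `hi`.
#' @export
eeg_bands <- function(include_all = FALSE) {
  b <- tibble::tribble(
    ~name,      ~lo, ~hi,
    "theta",      3,   7,
    "alpha",      7,  13,
    "low_beta",  13,  16,
    "beta",      16,  26,
    "gamma",     26,  40
  )
  if (include_all) b <- dplyr::bind_rows(b, tibble::tibble(name = "all", lo = 3, hi = 40))
  b
}

# minimal feature-table constructor: tibble + column metadata + approach
new_feature_table <- function(tbl, column_meta, approach) {
  stopifnot(all(column_meta$column %in% names(tbl)))
  structure(tbl, column_meta = column_meta, approach = approach,
            class = c("feature_table", class(tbl)))
}

#' @export
print.feature_table <- function(x, ...) {
  meta <- attr(x, "column_meta")
  cat(sprintf("<feature_table> approach '%s': %d trials x %d features\n",
              attr(x, "approach"), nrow(x), nrow(meta)))
  NextMethod()
}

feature_matrix <- function(table) {
  meta <- attr(table, "column_meta")
  as.matrix(table[, meta$column, drop = FALSE])
}

#' Binned time-frequency matrix of one epoch channel/component
#'
#' Short-time FFT (Hann windows, default 500 ms with 75% overlap) of one
#' signal; frame powers are averaged within each frequency band, then frames
#' are averaged into `n_bins` equal time bins spanning the epoch (empty bins,
#' possible on very short epochs, are interpolated from their neighbors), so
#' trials of different durations produce comparable maps.
#'
#' @param x numeric vector, one channel or component of an epoch.
#' @param rate sampling rate in Hz.
#' @param bands band tibble from [eeg_bands()].
#' @param n_bins number of time bins (default 10).
#' @param window STFT window length in seconds (default 0.5).
#' @return numeric matrix, bands x bins (row names = band names).
#' @export
trial_tfa <- function(x, rate, bands = eeg_bands(), n_bins = 10, window = 0.5) {
  n <- length(x)
  if (n < rate / min(bands$lo)) {
    stop("epoch too short for the lowest analysis band")
  }
  wlen <- min(round(window * rate), n)
  hop <- max(1L, floor(wlen / 4))
  starts <- seq(1L, n - wlen + 1L, by = hop)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1))
  freqs <- (seq_len(wlen) - 1) * rate / wlen
  band_rows <- lapply(seq_len(nrow(bands)), function(b) {
    which(freqs >= bands$lo[b] & freqs < bands$hi[b])
  })
  P <- vapply(starts, function(s) {
    seg <- x[s:(s + wlen - 1)] * hann
    px <- Mod(stats::fft(seg))^2 / wlen
    vapply(band_rows, function(rws) {
      if (length(rws) == 0) 0 else mean(px[rws])
    }, numeric(1))
  }, numeric(nrow(bands)))
  P <- matrix(P, nrow = nrow(bands))
  centers <- (starts - 1 + wlen / 2) / n          # frame centers in [0,1]
  bin_of <- pmin(floor(centers * n_bins) + 1L, n_bins)
  bin_centers <- (seq_len(n_bins) - 0.5) / n_bins
  out <- t(vapply(seq_len(nrow(bands)), function(b) {
    v <- vapply(seq_len(n_bins), function(k) {
      if (any(bin_of == k)) mean(P[b, bin_of == k]) else NA_real_
    }, numeric(1))
    if (anyNA(v)) {
      if (sum(!is.na(v)) == 1) v[] <- v[!is.na(v)]
      else v <- stats::approx(bin_centers[!is.na(v)], v[!is.na(v)],
                              xout = bin_centers, rule = 2)$y
    }
    v
  }, numeric(n_bins)))
  rownames(out) <- bands$name
  out
}

#' Time-frequency feature table for a condition
#'
#' Per trial, [trial_tfa()] of every retained component's activation,
#' concatenated component-major into one row: component x band x bin. Ten
#' retained components with 5 bands and 10 bins give 500 columns; a
#' 64-component all-condition gives 3200.
#'
#' @param cond a `condition_signal` from [reconstruct_condition()].
#' @param bands band tibble from [eeg_bands()].
#' @param n_bins time bins per band (default 10).
#' @param average_trials if `TRUE`, average the TF maps across the trials of
#'   each task before flattening (one row per task; for visualization only
#'   -- trial-wise classification needs the default `FALSE`).
#' @return a `feature_table` tibble (`trial`, `task`, features); column
#'   metadata columns: `component`, `band`, `bin`.
#' @export
tfa_feature_table <- function(cond, bands = eeg_bands(), n_bins = 10,
                              average_trials = FALSE) {
  stopifnot(inherits(cond, "condition_signal"))
  comps <- cond$selected_components
  rows <- lapply(seq_along(cond$component_epochs), function(i) {
    a <- cond$component_epochs[[i]]
    v <- unlist(lapply(seq_len(nrow(a)), function(j) {
      m <- trial_tfa(a[j, ], cond$rate, bands, n_bins)
      as.numeric(t(m))   # band-major within component: band1 bins, band2 bins...
    }))
    names(v) <- paste0(
      rep(sprintf("c%02d", comps), each = nrow(bands) * n_bins), ".",
      rep(rep(bands$name, each = n_bins), length(comps)), ".b",
      sprintf("%02d", rep(seq_len(n_bins), nrow(bands) * length(comps))))
    tibble::tibble(trial = cond$epoch_meta$trial[i],
                   task = cond$epoch_meta$task[i], !!!as.list(v))
  })
  tbl <- dplyr::bind_rows(rows)
  if (average_trials) {
    tbl <- tbl |>
      dplyr::group_by(.data$task) |>
      dplyr::summarise(dplyr::across(-"trial", mean), .groups = "drop") |>
      dplyr::mutate(trial = NA_integer_, .before = 1)
  }
  cols <- setdiff(names(tbl), c("trial", "task"))
  meta <- tibble::tibble(
    column = cols,
    component = as.integer(sub("^c(\\d+)\\..*$", "\\1", cols)),
    band = sub("^c\\d+\\.(.*)\\.b\\d+$", "\\1", cols),
    bin = as.integer(sub("^.*\\.b", "", cols))
  )
  new_feature_table(tbl, meta, approach = "tfa")
}

#' Per-band PCA reduction of a time-frequency feature table
#'
#' Fits PCA separately on each frequency band's columns and keeps
#' `per_band_k` components per band (fewer if the rank is lower, with a
#' message), concatenating to `n_bands * per_band_k` features (70 for the
#' canonical 5 bands x 14). The returned projection record stores, per band,
#' the centering vector and rotation matrix so classifier weights can later
#' be reprojected exactly back to the component x band x bin space.
#'
#' @param table a TFA `feature_table`.
#' @param per_band_k principal components kept per band (default 14).
#' @param fit_rows optional row indices to fit the PCA on (e.g. the training
#'   rows of a split); all rows are transformed.
#' @return list with `table` (reduced `feature_table`) and `projection`
#'   (class `pca_projection`).
#' @export
pca_reduce <- function(table, per_band_k = 14, fit_rows = NULL) {
  stopifnot(inherits(table, "feature_table"), nrow(table) >= 2)
  meta <- attr(table, "column_meta")
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(table))
  bands <- unique(meta$band)
  pieces <- list(); proj <- list()
  for (b in bands) {
    cols <- meta$column[meta$band == b]
    X <- as.matrix(table[, cols, drop = FALSE])
    k <- min(per_band_k, length(fit_rows) - 1, length(cols))
    if (k < per_band_k) {
      message(sprintf("pca_reduce: band %s rank-limited to %d components", b, k))
    }
    p <- stats::prcomp(X[fit_rows, , drop = FALSE], center = TRUE, scale. = FALSE)
    k <- min(k, ncol(p$rotation))
    rot <- p$rotation[, seq_len(k), drop = FALSE]
    scores <- sweep(X, 2, p$center) %*% rot
    colnames(scores) <- sprintf("%s.PC%02d", b, seq_len(k))
    pieces[[b]] <- scores
    proj[[b]] <- list(center = p$center, rotation = rot, columns = cols,
                      sdev = p$sdev[seq_len(k)])
  }
  scores <- do.call(cbind, pieces)
  tbl <- dplyr::bind_cols(table[, c("trial", "task")],
                          tibble::as_tibble(scores))
  meta_out <- tibble::tibble(
    column = colnames(scores),
    band = rep(bands, vapply(pieces, ncol, integer(1))),
    component = NA_integer_,
    bin = NA_integer_
  )
  out <- new_feature_table(tbl, meta_out, approach = "tfa_pca")
  projection <- structure(list(bands = proj, source_meta = meta),
                          class = "pca_projection")
  list(table = out, projection = projection)
}

#' Log bandpower of one band-passed epoch channel
#'
#' `10 * log10(mean(x^2))` in dB: the mean squared amplitude of the signal
#' over the trial, log-scaled. The input is band-pass filtered to `band`
#' first unless `filter = FALSE` (zero-phase Butterworth). An all-zero
#' signal returns the configured floor instead of -Inf.
#'
#' @param x numeric vector, one channel of one trial epoch.
#' @param rate sampling rate in Hz (needed when filtering).
#' @param band one-row band tibble (or list with `lo`, `hi`); ignored when
#'   `filter = FALSE`.
#' @param filter band-pass filter before measuring (default `TRUE`).
#' @param floor_db value returned for an all-zero signal (default -200).
#' @return bandpower in dB.
#' @export
bandpower <- function(x, rate = NULL, band = NULL, filter = TRUE,
                      floor_db = -200) {
  stopifnot(length(x) > 0)
  if (filter) {
    stopifnot(!is.null(rate), !is.null(band))
    bf <- signal::butter(2, c(band$lo, band$hi) / (rate / 2), type = "pass")
    x <- as.numeric(signal::filtfilt(bf, x))
  }
  ms <- mean(x^2)
  if (ms <= 0) {
    message("bandpower: zero-power signal, returning floor")
    return(floor_db)
  }
  10 * log10(ms)
}

#' Bandpower feature table for a condition
#'
#' One feature per channel: the log bandpower of the band-passed
#' channel-space reconstruction, per trial. 64 channels give 64 features.
#'
#' @param cond a `condition_signal` (channel-space epochs).
#' @param band one-row band tibble, e.g. a row of `eeg_bands(include_all =
#'   TRUE)`.
#' @return a `feature_table` tibble (`trial`, `task`, one column per
#'   channel); column metadata: `channel`, `band`.
#' @export
bandpower_feature_table <- function(cond, band) {
  stopifnot(inherits(cond, "condition_signal"))
  band <- as.list(band)
  rows <- lapply(seq_along(cond$epochs), function(i) {
    e <- cond$epochs[[i]]
    bf <- signal::butter(2, c(band$lo, band$hi) / (e$rate / 2), type = "pass")
    v <- apply(e$data, 1, function(ch) {
      bandpower(as.numeric(signal::filtfilt(bf, ch)), filter = FALSE)
    })
    names(v) <- e$channel_names %||% sprintf("E%02d", seq_along(v))
    tibble::tibble(trial = e$trial, task = e$task, !!!as.list(v))
  })
  tbl <- dplyr::bind_rows(rows)
  cols <- setdiff(names(tbl), c("trial", "task"))
  meta <- tibble::tibble(column = cols, channel = cols,
                         band = band$name %||% sprintf("%g-%g", band$lo, band$hi))
  new_feature_table(tbl, meta, approach = "bandpower")
}
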