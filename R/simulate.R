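#' Source specification for the synthetic session generator
#'
#' Describes one latent signal source: what kind it is, how it projects to
#' the scalp, its spectral carrier, and how strongly each task modulates it.
#'
#' @param kind one of `"brain"`, `"eye_blink"`, `"eye_movement"`, `"muscle"`,
#'   `"line_noise"`, `"sensor_noise"`.
#' @param topography per-channel gain vector (unitless), one entry per channel.
#' @param carrier list describing the spectrum: for brain sources
#'   `list(band = c(lo, hi), pink = TRUE)`; for muscle
#'   `list(highpass = 20)`; for line noise `list(freq = 50)`.
#' @param class_gain per-task multiplicative modulation (unitless, >= 0), one
#'   entry per task; trial amplitude scales with `1 + delta * class_gain[task]`.
#' @param event_rate events per second for transient sources (blinks,
#'   saccades), or `"tonic"` for continuously active sources.
#' @param amplitude overall source amplitude (microvolt scale at the scalp
#'   for a unit-gain channel).
#'
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(kind, topography, carrier, class_gain = NULL,
                        event_rate = "tonic", amplitude = 1) {
  kind <- match.arg(kind, c("brain", "eye_blink", "eye_movement", "muscle",
                            "line_noise", "sensor_noise"))
  if (!identical(event_rate, "tonic")) {
    stopifnot(is.numeric(event_rate), event_rate >= 0)
  }
  stopifnot(all(is.finite(topography)), is.null(class_gain) || all(class_gain >= 0))
  structure(
    list(kind = kind, topography = as.numeric(topography), carrier = carrier,
         class_gain = class_gain, event_rate = event_rate,
         amplitude = amplitude),
    class = "source_spec"
  )
}

#' Synthetic session configuration
#'
#' Holds the protocol and effect-size parameters of one simulated recording
#' session: a 64-channel EEG cap and 7 bipolar EMG channels sampled at 1 kHz,
#' five movement tasks presented in randomized order, and per-trial phases of
#' 2 s fixation, 4 s preparation, a variable-length execution (uniform over
#' `execution_range`) and 2 s rest.
#'
#' The two scalars `brain_effect` and `artifact_effect` control how strongly
#' the task label modulates the execution-phase amplitude of brain sources
#' and of artifact sources respectively: a source's trial amplitude is
#' multiplied by `1 + delta * class_gain[task]`. Setting `artifact_effect`
#' above `brain_effect` reproduces the regime where movement artifacts carry
#' more class information than the underlying brain activity.
#'
#' @param n_channels number of EEG channels (default 64).
#' @param n_tasks number of movement tasks (default 5).
#' @param trials_per_task trials per task (default 10).
#' @param acquisition_rate sampling rate in Hz (default 1000).
#' @param fixation,preparation,rest phase durations in seconds.
#' @param execution_range range (seconds) from which execution durations are
#'   drawn uniformly.
#' @param brain_effect class-dependence of brain sources (delta >= 0).
#' @param artifact_effect class-dependence of artifact sources (delta >= 0).
#' @param snr_db sensor-noise level: ratio of mixed-signal RMS to additive
#'   white sensor noise, in dB. `Inf` disables sensor noise.
#' @param n_brain_sources number of brain sources.
#' @param seed integer seed; identical configurations produce bit-identical
#'   sessions.
#'
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_channels = 64, n_tasks = 5, trials_per_task = 10,
                           acquisition_rate = 1000,
                           fixation = 2, preparation = 4,
                           execution_range = c(2, 6), rest = 2,
                           brain_effect = 0.3, artifact_effect = 0.8,
                           snr_db = 20, n_brain_sources = 8, seed = 1L) {
  counts <- c(n_channels = n_channels, n_tasks = n_tasks,
              trials_per_task = trials_per_task, n_brain_sources = n_brain_sources)
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("all counts must be positive integers")
  }
  if (any(c(fixation, preparation, rest, execution_range) <= 0)) {
    stop("phase durations must be positive")
  }
  if (acquisition_rate <= 0) stop("acquisition_rate must be positive")
  if (brain_effect < 0 || artifact_effect < 0) {
    stop("effect sizes must be non-negative")
  }
  task_names <- c("painting", "faucet", "glass", "head_slow", "head_fast", "lamp")
  tasks <- if (n_tasks <= 6) task_names[seq_len(n_tasks)] else
    c(task_names, sprintf("task%d", 7:n_tasks))
  structure(
    list(n_channels = n_channels, n_tasks = n_tasks, tasks = tasks,
         trials_per_task = trials_per_task,
         acquisition_rate = acquisition_rate,
         fixation = fixation, preparation = preparation,
         execution_range = sort(execution_range), rest = rest,
         brain_effect = brain_effect, artifact_effect = artifact_effect,
         snr_db = snr_db, n_brain_sources = n_brain_sources,
         seed = as.integer(seed)),
    class = "session_config"
  )
}

#' Default artifact source bank
#'
#' The canonical artifact taxonomy instantiated over an idealized cap layout:
#' an eye-blink source (frontal topography, slow transient pulses), a
#' horizontal eye-movement source (frontal left-right dipole, step-like
#' saccades), left and right neck/temporal muscle sources (narrow cap-edge
#' topographies, broadband high-frequency carrier), and a 50 Hz line-noise
#' source (spatially broad).
#'
#' @param layout cap layout tibble from [cap_layout()].
#' @param n_tasks number of tasks (class-gain vectors are drawn later, per
#'   session; here they are `NULL` placeholders).
#' @return list of [source_spec()] objects.
#' @export
default_artifact_bank <- function(layout = cap_layout(64), n_tasks = 5) {
  # artifact scalp amplitudes deliberately dwarf the brain sources (unit
  # scale): ocular and muscular potentials at the scalp are far larger than
  # in-band brain activity
  blink <- source_spec(
    "eye_blink",
    topography = topo_bump(layout, c(0, 1.1), 0.45),
    carrier = list(pulse_ms = 160), event_rate = 0.5, amplitude = 30
  )
  eye_mov <- source_spec(
    "eye_movement",
    topography = topo_bump(layout, c(-0.45, 1.0), 0.4) -
      topo_bump(layout, c(0.45, 1.0), 0.4),
    carrier = list(step = TRUE), event_rate = 1.0, amplitude = 12
  )
  muscle_l <- source_spec(
    "muscle",
    topography = topo_bump(layout, c(-1.05, -0.35), 0.3),
    carrier = list(highpass = 20), amplitude = 6
  )
  muscle_r <- source_spec(
    "muscle",
    topography = topo_bump(layout, c(1.05, -0.35), 0.3),
    carrier = list(highpass = 20), amplitude = 6
  )
  line <- source_spec(
    "line_noise",
    topography = 0.7 + 0.3 * topo_bump(layout, c(0, -1.0), 0.8),
    carrier = list(freq = 50), amplitude = 1.5
  )
  list(blink = blink, eye_movement = eye_mov,
       muscle_left = muscle_l, muscle_right = muscle_r, line_noise = line)
}

# Brain source bank: smooth dipolar Gaussian-bump topographies at roughly
# sensorimotor/parietal locations, each carrying a band-limited oscillation
# over a 1/f background. Bands rotate through the canonical EEG bands so that
# every analysis band contains at least one brain source.
default_brain_bank <- function(layout, n_sources = 8) {
  bands <- list(c(8, 12), c(16, 24), c(4, 7), c(27, 35))
  centers <- list(c(-0.45, 0.15), c(0.45, 0.15), c(-0.35, -0.35), c(0.35, -0.35),
                  c(0, 0.45), c(0, -0.15), c(-0.6, -0.1), c(0.6, -0.1),
                  c(-0.2, 0.3), c(0.2, 0.3), c(0, -0.5), c(-0.15, -0.15))
  lapply(seq_len(n_sources), function(i) {
    ctr <- centers[[(i - 1) %% length(centers) + 1]]
    # dipolar: positive bump minus a weaker displaced lobe
    topo <- topo_bump(layout, ctr, 0.35) -
      0.6 * topo_bump(layout, ctr + c(0.18, -0.18), 0.35)
    source_spec("brain", topography = topo,
                carrier = list(band = bands[[(i - 1) %% length(bands) + 1]],
                               pink = TRUE),
                amplitude = 1.2)
  })
}

# --- carrier synthesis helpers (all vectorized over the whole session) -----

# Gaussian noise with an ideal band-limited spectrum, synthesized by FFT
# masking with a raised-cosine edge (cheap and exactly band-limited).
spectral_noise <- function(n, rate, lo, hi, roll = 1) {
  m <- 2^ceiling(log2(n + 1))
  f <- c(seq(0, m / 2), seq(-m / 2 + 1, -1)) * rate / m
  af <- abs(f)
  mask <- rep(0, m)
  mask[af >= lo & af <= hi] <- 1
  ramp_lo <- af >= lo - roll & af < lo
  mask[ramp_lo] <- 0.5 + 0.5 * cos(pi * (lo - af[ramp_lo]) / roll)
  ramp_hi <- af > hi & af <= hi + roll
  mask[ramp_hi] <- 0.5 + 0.5 * cos(pi * (af[ramp_hi] - hi) / roll)
  x <- Re(stats::fft(stats::fft(stats::rnorm(m)) * mask, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

band_noise <- function(n, rate, lo, hi) {
  spectral_noise(n, rate, lo, min(hi, 0.45 * rate))
}

highpass_noise <- function(n, rate, cutoff) {
  spectral_noise(n, rate, cutoff, rate / 2)
}

pink_noise <- function(n) {
  x <- as.numeric(stats::filter(stats::rnorm(n), 0.98, method = "recursive"))
  x / stats::sd(x)
}

gauss_kernel <- function(sd_samples) {
  half <- max(1L, ceiling(2 * sd_samples))
  k <- exp(-((-half:half)^2) / (2 * sd_samples^2))
  k / sum(k)
}

# short-kernel convolution with edge replication; stats::filter is O(n * k)
conv_same <- function(x, k) {
  half <- (length(k) - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], length(k) - 1L - half))
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(half + 1L):(half + length(x))])
}

gauss_smooth <- function(x, sd_samples) {
  conv_same(x, gauss_kernel(sd_samples))
}

# impulse train smeared by a (symmetric) pulse kernel
pulse_train <- function(impulses, kernel) {
  conv_same(impulses, kernel)
}

# per-sample gain vector: 1 outside execution, (1 + delta*g)*trial_noise inside
execution_gain <- function(n, event_table, rate, delta, g, trial_noise) {
  gain <- rep(1, n)
  ex <- event_table[event_table$phase == "execution", ]
  for (i in seq_len(nrow(ex))) {
    idx <- (ex$start[i] + 1):ex$end[i]
    gain[idx] <- (1 + delta * g[ex$task_index[i]]) * trial_noise[i]
  }
  gain
}

draw_class_gain <- function(tasks, kind) {
  g <- stats::runif(length(tasks))
  if (kind %in% c("eye_blink", "eye_movement", "muscle")) {
    # head movements drive ocular and neck-muscle sources harder
    g[grepl("^head", tasks)] <- g[grepl("^head", tasks)] + 0.6
  }
  if (diff(range(g)) < 1e-12) return(rep(0, length(g)))
  (g - min(g)) / (max(g) - min(g))
}

# activation time course for one source over the full session
synth_source <- function(spec, n, rate, event_table, delta, g, trial_noise) {
  base <- switch(
    spec$kind,
    brain = {
      osc <- band_noise(n, rate, spec$carrier$band[1], spec$carrier$band[2])
      # bursty amplitude modulation: oscillations wax and wane, which also
      # makes the source super-Gaussian enough for ICA to resolve
      am <- 0.2 + 1.6 * gauss_smooth(abs(stats::rnorm(n)), 0.25 * rate)^2
      gain <- execution_gain(n, event_table, rate, delta, g, trial_noise)
      osc * am * gain + 0.4 * pink_noise(n)
    },
    eye_blink = {
      rate_ts <- rep(spec$event_rate * 0.4, n)
      ex <- event_table[event_table$phase == "execution", ]
      for (i in seq_len(nrow(ex))) {
        idx <- (ex$start[i] + 1):ex$end[i]
        rate_ts[idx] <- spec$event_rate * (1 + delta * g[ex$task_index[i]])
      }
      imp <- as.numeric(stats::runif(n) < rate_ts / rate)
      gain <- execution_gain(n, event_table, rate, delta, g, trial_noise)
      imp <- imp * gain   # blink amplitude also task-modulated
      sd_s <- spec$carrier$pulse_ms / 1000 * rate / 4
      pulse_train(imp, gauss_kernel(sd_s) / max(gauss_kernel(sd_s)))
    },
    eye_movement = {
      gain <- execution_gain(n, event_table, rate, delta, g, trial_noise)
      imp <- (stats::runif(n) < spec$event_rate / rate) * stats::rnorm(n) * gain
      pos <- as.numeric(stats::filter(imp, 0.9995, method = "recursive"))
      # ~50 ms transition: ocular potentials are predominantly sub-5 Hz
      gauss_smooth(pos, 0.05 * rate)
    },
    muscle = {
      carrier <- highpass_noise(n, rate, spec$carrier$highpass)
      # tonic floor plus phasic bursts (squared smoothed noise -> sparse)
      env <- 0.15 + 0.9 * gauss_smooth(abs(stats::rnorm(n)), 0.3 * rate)^2
      gain <- execution_gain(n, event_table, rate, delta, g, trial_noise)
      carrier * env * gain
    },
    line_noise = {
      drift <- 1 + 0.1 * gauss_smooth(stats::rnorm(n), rate)
      sin(2 * pi * spec$carrier$freq * (seq_len(n) - 1) / rate +
            stats::runif(1, 0, 2 * pi)) * drift
    },
    stop("unsupported source kind: ", spec$kind)
  )
  spec$amplitude * base
}

build_event_table <- function(config) {
  n_trials <- config$n_tasks * config$trials_per_task
  task_seq <- sample(rep(seq_len(config$n_tasks), config$trials_per_task))
  rate <- config$acquisition_rate
  rows <- vector("list", n_trials)
  cursor <- 0L
  for (tr in seq_len(n_trials)) {
    exec_dur <- stats::runif(1, config$execution_range[1], config$execution_range[2])
    durs <- c(fixation = config$fixation, preparation = config$preparation,
              execution = exec_dur, rest = config$rest)
    lens <- round(durs * rate)
    starts <- cursor + c(0L, cumsum(lens[-length(lens)]))
    rows[[tr]] <- tibble::tibble(
      trial = tr, task_index = task_seq[tr],
      task = config$tasks[task_seq[tr]],
      phase = names(durs), start = as.integer(starts),
      end = as.integer(starts + lens)
    )
    cursor <- cursor + sum(lens)
  }
  dplyr::bind_rows(rows)
}

#' Simulate one ground-truth-annotated EEG + EMG session
#'
#' Generates a full session following the task protocol (randomized task
#' order, fixation / preparation / variable-length execution / rest phases),
#' mixes brain and artifact sources linearly onto the scalp through smooth
#' synthetic topographies, adds 50 Hz line noise and white sensor noise, and
#' simulates 7-channel EMG with task-specific activation-envelope templates.
#' Identical configurations (including the seed) give bit-identical output.
#'
#' @param config a [session_config()].
#' @param artifact_bank optional list of [source_spec()] artifact sources;
#'   defaults to [default_artifact_bank()] on the session's cap layout.
#' @param keep_sources if `TRUE` (default) the ground truth retains the
#'   source activation matrix, enabling exact mixing-linearity oracles.
#'
#' @return list with elements `eeg` and `emg` ([mc_recording()]s) and
#'   `truth`, a list holding `mixing_columns` (channels x sources),
#'   `source_labels`, `class_gains` (sources x tasks), `event_table`
#'   (trial, task, phase, start, end; 0-based half-open sample ranges),
#'   `emg_templates`, `layout`, and (optionally) `sources`.
#' @export
simulate_session <- function(config, artifact_bank = NULL, keep_sources = TRUE) {
  stopifnot(inherits(config, "session_config"))
  withr::with_seed(config$seed, {
    layout <- cap_layout(config$n_channels)
    if (is.null(artifact_bank)) artifact_bank <- default_artifact_bank(layout)
    brain_bank <- default_brain_bank(layout, config$n_brain_sources)
    sources <- c(brain_bank, unname(artifact_bank))
    kinds <- vapply(sources, function(s) s$kind, character(1))

    event_table <- build_event_table(config)
    n <- max(event_table$end)
    rate <- config$acquisition_rate
    n_trials <- max(event_table$trial)

    class_gains <- t(vapply(sources, function(s) {
      if (s$kind == "line_noise") rep(0, config$n_tasks)
      else draw_class_gain(config$tasks, s$kind)
    }, numeric(config$n_tasks)))

    S <- matrix(0, nrow = length(sources), ncol = n)
    for (j in seq_along(sources)) {
      delta <- switch(kinds[j], brain = config$brain_effect,
                      line_noise = 0, config$artifact_effect)
      trial_noise <- stats::rlnorm(n_trials, 0, 0.15)
      S[j, ] <- synth_source(sources[[j]], n, rate, event_table, delta,
                             class_gains[j, ], trial_noise)
    }

    A <- vapply(sources, function(s) s$topography, numeric(config$n_channels))
    X <- A %*% S
    if (is.finite(config$snr_db)) {
      sig_rms <- sqrt(mean(X^2))
      X <- X + matrix(stats::rnorm(length(X),
                                   sd = sig_rms * 10^(-config$snr_db / 20)),
                      nrow = nrow(X))
    }

    events <- event_table |>
      dplyr::transmute(
        code = paste(.data$phase, .data$task, sep = ":"),
        sample = .data$start, trial = .data$trial, task = .data$task,
        phase = .data$phase)
    # completion markers for execution phases
    completions <- event_table |>
      dplyr::filter(.data$phase == "execution") |>
      dplyr::transmute(code = paste("completion", .data$task, sep = ":"),
                       sample = .data$end, trial = .data$trial,
                       task = .data$task, phase = "completion")
    events <- dplyr::arrange(dplyr::bind_rows(events, completions),
                             .data$sample, .data$trial)

    eeg <- mc_recording(X, rate, layout$channel, events)

    truth <- list(
      mixing_columns = A, source_labels = kinds, class_gains = class_gains,
      brain_effect = config$brain_effect, artifact_effect = config$artifact_effect,
      event_table = event_table[, c("trial", "task", "phase", "start", "end")],
      layout = layout, tasks = config$tasks
    )
    if (keep_sources) truth$sources <- S

    emg_sim <- simulate_emg(config, truth, events = events)
    truth$emg_templates <- emg_sim$templates

    list(eeg = eeg, emg = emg_sim$recording, truth = truth)
  })
}

# piecewise ramp/plateau template on [0,1], values >= 0, 100 support points
emg_template <- function(task_index, channel_index, n_tasks) {
  n_seg <- 4
  u <- seq(0, 1, length.out = 101)
  # deterministic per (task, channel): knot heights from a fixed lattice so
  # templates are distinct across tasks without drawing from the session RNG
  h <- ((task_index * 7 + channel_index * 3 + seq_len(n_seg + 1) * 11) %% 13) / 13
  h <- 0.15 + 0.85 * h
  stats::approx(seq(0, 1, length.out = n_seg + 1), h, xout = u)$y
}

#' Simulate the 7-channel EMG stream for a session
#'
#' Each of the 7 bipolar muscle channels carries rectifiable broadband noise
#' whose amplitude envelope, during the execution phase of a trial, follows a
#' task-and-muscle-specific piecewise ramp/plateau template (the planted
#' "EMG fingerprint"); outside execution only a weak baseline is active.
#'
#' @param config a [session_config()].
#' @param truth ground-truth list containing `event_table` (from
#'   [simulate_session()]).
#' @param events optional event tibble to attach to the recording.
#' @return list with `recording` (a 7-channel [mc_recording()]) and
#'   `templates` (list indexed by task of 7 x 101 template matrices).
#' @export
simulate_emg <- function(config, truth, events = NULL) {
  stopifnot(inherits(config, "session_config"))
  et <- truth$event_table
  if (is.null(et) || nrow(et) == 0) stop("ground-truth event table required")
  n <- max(et$end)
  rate <- config$acquisition_rate
  n_ch <- 7L
  muscles <- c("brachioradialis", "extensor_digitorum", "flexor_digitorum",
               "biceps", "deltoid", "sternocleidomastoid_L",
               "sternocleidomastoid_R")

  templates <- lapply(seq_len(config$n_tasks), function(k) {
    t(vapply(seq_len(n_ch), function(ch) emg_template(k, ch, config$n_tasks),
             numeric(101)))
  })
  names(templates) <- config$tasks

  withr::with_seed(config$seed + 104729L, {
    env <- matrix(0.05, nrow = n_ch, ncol = n)   # baseline tone
    ex <- et[et$phase == "execution", ]
    task_idx <- match(ex$task, config$tasks)
    for (i in seq_len(nrow(ex))) {
      idx <- (ex$start[i] + 1):ex$end[i]
      u <- seq(0, 1, length.out = length(idx))
      tpl <- templates[[task_idx[i]]]
      for (ch in seq_len(n_ch)) {
        env[ch, idx] <- stats::approx(seq(0, 1, length.out = 101), tpl[ch, ],
                                      xout = u)$y
      }
    }
    carrier <- matrix(0, nrow = n_ch, ncol = n)
    for (ch in seq_len(n_ch)) carrier[ch, ] <- highpass_noise(n, rate, 20)
    data <- env * carrier
    if (is.finite(config$snr_db)) {
      data <- data + matrix(
        stats::rnorm(length(data), sd = 0.02 * stats::sd(data)), nrow = n_ch)
    }
    rec <- mc_recording(data, rate, muscles, events)
    list(recording = rec, templates = templates)
  })
}
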