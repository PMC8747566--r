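# Shared fixtures, computed lazily and cached for the whole test run.
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A small but full-featured session: 24 channels at 125 Hz, 6 trials/task,
# the default artifact/brain effect contrast.
small_session <- function() {
  cached("small_session", {
    simulate_session(session_config(
      n_channels = 24, trials_per_task = 6, acquisition_rate = 125,
      execution_range = c(2, 4), seed = 11))
  })
}

small_prep <- function() {
  cached("small_prep", preprocess_pipeline(small_session()$eeg,
                                           analysis_rate = 125))
}

small_ica <- function() {
  cached("small_ica", suppressMessages(
    fit_ica(small_prep()$epochs, n_components = 16, seed = 5)))
}

small_labels <- function() {
  cached("small_labels",
         label_components(small_ica(), small_session()$truth$layout))
}

small_conditions <- function() {
  cached("small_conditions", {
    dec <- small_ica(); labs <- small_labels()
    suppressWarnings(list(
      brain = reconstruct_condition(
        dec, select_top_components(labs, dec, "brain", 10), "brain"),
      artifact = reconstruct_condition(
        dec, select_top_components(labs, dec, "artifact", 10), "artifact"),
      all = reconstruct_condition(dec, integer(), "all")))
  })
}

# Ground-truth pseudo-decomposition: planted topographies and activations
# wrapped in the decomposition contract, for labeler tests.
truth_decomposition <- function(sim) {
  tr <- sim$truth
  et <- tr$event_table
  ex <- et[et$phase == "execution", ]
  acts <- lapply(seq_len(nrow(ex)), function(i) {
    tr$sources[, (ex$start[i] + 1):ex$end[i], drop = FALSE]
  })
  structure(
    list(unmixing = t(tr$mixing_columns), mixing = tr$mixing_columns,
         activations = acts,
         variance_share = rep(1 / nrow(tr$mixing_columns),
                              ncol(tr$mixing_columns)),
         rate = sim$eeg$rate, channel_names = sim$eeg$channel_names,
         epoch_meta = tibble::tibble(trial = ex$trial, task = ex$task)),
    class = "decomposition")
}

# Well-separated 5-class Gaussian clouds as a feature table.
cloud_table <- function(n_per_class = 20, n_features = 12, sep = 8,
                        seed = 1) {
  withr::with_seed(seed, {
    tasks <- c("painting", "faucet", "glass", "head_slow", "head_fast")
    centers <- matrix(rnorm(5 * n_features), 5, n_features) * sep
    rows <- lapply(1:5, function(k) {
      X <- matrix(rnorm(n_per_class * n_features), n_per_class) +
        matrix(centers[k, ], n_per_class, n_features, byrow = TRUE)
      colnames(X) <- sprintf("f%02d", seq_len(n_features))
      dplyr::bind_cols(tibble::tibble(trial = seq_len(n_per_class),
                                      task = tasks[k]),
                       tibble::as_tibble(X))
    })
    tbl <- dplyr::bind_rows(rows)
    meta <- tibble::tibble(column = sprintf("f%02d", seq_len(n_features)),
                           band = "all")
    eegdecode:::new_feature_table(tbl, meta, approach = "synthetic")
  })
}

# Two-class epochs differing in variance along a planted spatial direction.
planted_csp_epochs <- function(n_ch = 16, n_per_class = 20, len = 500,
                               boost = 6, seed = 10) {
  withr::with_seed(seed, {
    v <- rnorm(n_ch); v <- v / sqrt(sum(v^2))
    eps <- list()
    for (k in 1:2) {
      for (i in seq_len(n_per_class)) {
        X <- matrix(rnorm(n_ch * len), n_ch)
        if (k == 2) X <- X + boost * tcrossprod(v, rnorm(len))
        eps[[length(eps) + 1]] <- trial_epoch(
          X, 250, c("glass", "faucet")[k], trial = length(eps) + 1L)
      }
    }
    list(epochs = eps, v = v)
  })
}

# Forward-model recovery: x = a*s + noise, linear (least-squares) decoder w
# of the source fitted on the samples; covariance times w must point back
# at a. Returns |cor| between the reprojected pattern and a.
haufe_recovery_cor <- function(seed = 12, n_ch = 16, n_trials = 50,
                               len = 400, noise = 0.5) {
  sim <- withr::with_seed(seed, {
    a <- rnorm(n_ch); a <- a / sqrt(sum(a^2))
    s <- rnorm(n_trials * len)
    X <- tcrossprod(a, s) + matrix(rnorm(n_ch * n_trials * len, sd = noise),
                                   n_ch)
    list(a = a, s = s, X = X)
  })
  eps <- lapply(seq_len(n_trials), function(i) {
    cols <- ((i - 1) * len + 1):(i * len)
    trial_epoch(sim$X[, cols], 250, "glass", trial = i)
  })
  Xc <- sim$X - rowMeans(sim$X)
  C <- tcrossprod(Xc) / (ncol(Xc) - 1)
  w <- drop(solve(C, Xc %*% sim$s / (ncol(Xc) - 1)))   # backward filter
  layout <- cap_layout(n_ch)
  pat <- task_pattern(topography(w, layout, task = "glass"), eps, layout)
  abs(stats::cor(pat$value, sim$a))
}

permuted_labels <- function(table, seed = 2) {
  withr::with_seed(seed, {
    table$task <- sample(table$task)
    table
  })
}
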