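#' Independent component analysis of concatenated execution epochs
#'
#' Fits a symmetric fixed-point ICA (logcosh contrast, the FastICA family)
#' on the concatenation of all execution epochs of a session. The data are
#' centered and whitened by eigendecomposition of the channel covariance;
#' rank deficiency (common average referenced data has rank channels - 1) is
#' handled by retaining only eigenvalues above a relative tolerance, with a
#' message. Components are ordered by the fraction of sensor-space variance
#' they explain, descending (ties broken by component index).
#'
#' @param epochs list of [trial_epoch()]s (channel space).
#' @param n_components number of components to estimate; default = available
#'   rank.
#' @param seed integer seed for the random orthonormal initialization.
#' @param tol convergence tolerance on the unmixing update (default 1e-6).
#' @param max_iter maximum fixed-point iterations (default 200). With more
#'   components than clearly non-Gaussian sources the criterion may never be
#'   met (the residual subspace rotates freely); the decomposition after
#'   `max_iter` iterations is then used, with a message.
#' @param max_samples cap on the number of (evenly thinned) samples used to
#'   estimate the unmixing matrix; activations are always computed on the
#'   full data. Default 50000.
#' @return object of class `decomposition`: `unmixing` (components x
#'   channels), `mixing` (channels x components, the pseudoinverse),
#'   `activations` (list per epoch of components x samples),
#'   `variance_share`, `rate`, `channel_names`, `epoch_meta` (tibble of
#'   trial/task per epoch).
#' @export
fit_ica <- function(epochs, n_components = NULL, seed = 1L,
                    tol = 1e-6, max_iter = 200L, max_samples = 30000L) {
  stopifnot(length(epochs) > 0, inherits(epochs[[1]], "trial_epoch"))
  X <- do.call(cbind, lapply(epochs, function(e) e$data))
  n_ch <- nrow(X); n_s <- ncol(X)
  if (n_s < 20 * n_ch) {
    message(sprintf("fit_ica: only %d samples for %d channels (< 20x rule of thumb)",
                    n_s, n_ch))
  }
  ctr <- rowMeans(X)
  Xc <- X - ctr
  C <- tcrossprod(Xc) / (n_s - 1)
  eg <- eigen(C, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values) * 1e-9)
  if (rank < n_ch) {
    message(sprintf("fit_ica: rank-deficient input (rank %d of %d), fitting on reduced subspace",
                    rank, n_ch))
  }
  k <- if (is.null(n_components)) rank else min(n_components, rank)
  E <- eg$vectors[, seq_len(k), drop = FALSE]
  d <- eg$values[seq_len(k)]
  K <- diag(1 / sqrt(d), k) %*% t(E)        # whitening, k x channels
  fit_cols <- if (n_s > max_samples) {
    round(seq(1, n_s, length.out = max_samples))
  } else seq_len(n_s)
  Z <- K %*% Xc[, fit_cols, drop = FALSE]
  n_fit <- length(fit_cols)

  W <- withr::with_seed(seed, {
    W0 <- matrix(stats::rnorm(k * k), k, k)
    sym_decorrelate(W0)
  })
  for (it in seq_len(max_iter)) {
    U <- W %*% Z
    G <- tanh(U)
    gprime <- rowMeans(1 - G^2)
    W_new <- sym_decorrelate(tcrossprod(G, Z) / n_fit - diag(gprime, k) %*% W)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) break
  }
  if (it == max_iter && delta >= tol) {
    message(sprintf("fit_ica: stopping after %d iterations (delta %.2e); residual subspace still rotating",
                    max_iter, delta))
  }

  unmixing <- W %*% K                             # k x channels
  mixing <- E %*% diag(sqrt(d), k) %*% t(W)       # channels x k

  # variance share of component j in sensor space
  act_all <- unmixing %*% Xc
  total_var <- sum(Xc^2)
  vs <- vapply(seq_len(k), function(j) {
    sum(mixing[, j]^2) * sum(act_all[j, ]^2) / total_var
  }, numeric(1))
  ord <- order(-vs, seq_len(k))
  unmixing <- unmixing[ord, , drop = FALSE]
  mixing <- mixing[, ord, drop = FALSE]
  vs <- vs[ord]

  activations <- lapply(epochs, function(e) unmixing %*% (e$data - ctr))
  structure(
    list(unmixing = unmixing, mixing = mixing, center = ctr,
         activations = activations, variance_share = vs,
         rate = epochs[[1]]$rate,
         channel_names = epochs[[1]]$channel_names,
         epoch_meta = tibble::tibble(
           trial = vapply(epochs, function(e) e$trial, integer(1)),
           task = vapply(epochs, function(e) e$task, character(1)))),
    class = "decomposition"
  )
}

sym_decorrelate <- function(W) {
  s <- eigen(tcrossprod(W), symmetric = TRUE)
  s$vectors %*% diag(1 / sqrt(pmax(s$values, 1e-300)),
                     length(s$values)) %*% t(s$vectors) %*% W
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %d components over %d channels, %d epochs\n",
              nrow(x$unmixing), ncol(x$unmixing), length(x$activations)))
  invisible(x)
}

ic_classes <- c("brain", "muscle", "eye", "heart", "line_noise",
                "channel_noise", "other")

# spectral and topographic summary features of one component
component_features <- function(topo, act, rate, layout) {
  at <- abs(topo) / sum(abs(topo))
  frontal <- sum(at[layout$frontal])
  edge <- sum(at[layout$edge])
  dominance <- max(topo^2) / sum(topo^2)
  # smoothness: correlation between each channel and mean of its 5 nearest
  d <- as.matrix(stats::dist(cbind(layout$x, layout$y)))
  diag(d) <- Inf
  nb_mean <- vapply(seq_along(topo), function(i) {
    mean(topo[order(d[i, ])[1:5]])
  }, numeric(1))
  smooth <- suppressWarnings(stats::cor(topo, nb_mean))
  if (!is.finite(smooth)) smooth <- 0

  # spectral summary from a centered power-of-two window (fast, stable FFT)
  if (length(act) > 32768) {
    off <- (length(act) - 32768) %/% 2
    act <- act[(off + 1):(off + 32768)]
  }
  n <- length(act)
  spec <- Mod(stats::fft(act - mean(act)))[seq_len(floor(n / 2))]^2
  freqs <- (seq_len(floor(n / 2)) - 1) * rate / n
  total <- sum(spec) + 1e-300
  lowfreq <- sum(spec[freqs < 4]) / total
  # above the highest analysis band: oscillatory brain sources have next to
  # no power here, broadband muscle activity does
  highfreq <- sum(spec[freqs > 40 & freqs < 0.48 * rate]) / total
  midband <- sum(spec[freqs >= 4 & freqs <= 30]) / total
  in50 <- sum(spec[abs(freqs - 50) <= 1.5])
  nb50 <- sum(spec[(abs(freqs - 45) <= 1.5) | (abs(freqs - 55) <= 1.5)]) + 1e-300
  line_ratio <- in50 / nb50
  list(frontal = frontal, edge = edge, dominance = dominance, smooth = smooth,
       lowfreq = lowfreq, highfreq = highfreq, midband = midband,
       line_ratio = line_ratio)
}

#' Rule-based component labeling
#'
#' A transparent heuristic standing behind the same contract as automated
#' component classifiers: for every independent component it returns a
#' probability vector over \{brain, muscle, eye, heart, line_noise,
#' channel_noise, other\} summing to one, plus the winning class. Rules:
#' frontal topography concentration plus low-frequency dominance scores eye;
#' high-frequency (> 20 Hz) spectral fraction plus cap-edge concentration
#' scores muscle; a 50 Hz spectral peak scores line noise; single-channel
#' dominance scores channel noise; a smooth topography with mid-band (5-20
#' Hz) power scores brain. Scores are non-negative and normalized to
#' probabilities, so the output is deterministic in the decomposition.
#'
#' Any function with signature `(decomposition, layout) -> tibble` matching
#' this output can be used in its place throughout the pipeline, including
#' probability tables produced by external classifiers (see
#' [read_label_table()]).
#'
#' @param dec a `decomposition` from [fit_ica()].
#' @param layout cap layout tibble from [cap_layout()] (rows aligned with
#'   channels).
#' @return tibble with one row per component: `component`, one probability
#'   column per class, and `winning_class`.
#' @export
label_components <- function(dec, layout) {
  stopifnot(inherits(dec, "decomposition"))
  act <- do.call(cbind, dec$activations)
  k <- nrow(dec$unmixing)
  rows <- lapply(seq_len(k), function(j) {
    f <- component_features(dec$mixing[, j], act[j, ], dec$rate, layout)
    sm <- max(f$smooth, 0)   # rough (noise-like) topographies score nothing
    s <- c(
      brain = sm * f$midband * (1 - f$highfreq) * (1 - f$lowfreq) * 6,
      muscle = sm * f$edge * f$highfreq * 10,
      eye = sm * f$frontal * f$lowfreq * 6,
      heart = 0,
      line_noise = min(max(f$line_ratio - 3, 0), 10),
      channel_noise = max(f$dominance - 0.55, 0) * 6,
      other = 0.1
    )
    p <- s / sum(s)
    tibble::tibble(component = j, !!!as.list(p),
                   winning_class = ic_classes[which.max(p[ic_classes])])
  })
  dplyr::bind_rows(rows)
}

#' Select the top-k components of a kind, by variance
#'
#' Returns up to `k` component indices whose winning class matches `kind`
#' ("artifact" pools muscle and eye; heart, line-noise, channel-noise and
#' other components are excluded), ordered by explained variance descending.
#' If fewer than `k` match, all matches are returned with a warning.
#'
#' @param labels label tibble from [label_components()].
#' @param dec the `decomposition`.
#' @param kind `"brain"` or `"artifact"`.
#' @param k number of components to select (default 10).
#' @return integer vector of component indices.
#' @export
select_top_components <- function(labels, dec, kind = c("brain", "artifact"),
                                  k = 10) {
  kind <- match.arg(kind)
  wanted <- if (kind == "brain") "brain" else c("muscle", "eye")
  idx <- labels$component[labels$winning_class %in% wanted]
  if (length(idx) == 0) {
    warning(sprintf("no components labeled %s", kind))
    return(integer())
  }
  # components are already stored in variance order; preserve it
  idx <- sort(idx)
  if (length(idx) < k) {
    warning(sprintf("only %d %s components available (requested %d)",
                    length(idx), kind, k))
    return(idx)
  }
  idx[seq_len(k)]
}

#' Reconstruct a condition signal from selected components
#'
#' Projects the chosen components back to channel space
#' (`mixing[, idx] %*% activations[idx, ]`), keeping the component-space
#' activations alongside for feature extraction that operates per component.
#' Selecting every component reproduces the input epochs up to numerical
#' tolerance when the decomposition retains the full data rank (otherwise it
#' reproduces their projection onto the retained subspace); an empty
#' selection gives a zero signal.
#'
#' @param dec a `decomposition`.
#' @param indices integer component indices (may be empty).
#' @param condition `"brain"`, `"artifact"` or `"all"`.
#' @return object of class `condition_signal`: `condition`,
#'   `selected_components`, `epochs` (channel-space [trial_epoch()]s),
#'   `component_epochs` (list of components x samples matrices),
#'   `epoch_meta`, `mixing` (channels x selected components), `rate`.
#' @export
reconstruct_condition <- function(dec, indices,
                                  condition = c("brain", "artifact", "all")) {
  condition <- match.arg(condition)
  stopifnot(inherits(dec, "decomposition"))
  k <- nrow(dec$unmixing)
  if (condition == "all") indices <- seq_len(k)
  if (length(indices) > 0 && (min(indices) < 1 || max(indices) > k)) {
    stop("component index out of range")
  }
  if (condition != "all" && length(indices) > 10) {
    stop("brain/artifact conditions select at most 10 components")
  }
  epochs <- vector("list", length(dec$activations))
  comp_epochs <- vector("list", length(dec$activations))
  for (i in seq_along(dec$activations)) {
    a <- dec$activations[[i]][indices, , drop = FALSE]
    comp_epochs[[i]] <- a
    recon <- if (length(indices) == 0) {
      matrix(0, nrow = ncol(dec$unmixing), ncol = ncol(a))
    } else {
      dec$mixing[, indices, drop = FALSE] %*% a
    }
    epochs[[i]] <- trial_epoch(recon, dec$rate,
                               task = dec$epoch_meta$task[i],
                               phase = "execution",
                               trial = dec$epoch_meta$trial[i],
                               channel_names = dec$channel_names)
  }
  structure(
    list(condition = condition, selected_components = indices,
         epochs = epochs, component_epochs = comp_epochs,
         epoch_meta = dec$epoch_meta,
         mixing = dec$mixing[, indices, drop = FALSE], rate = dec$rate),
    class = "condition_signal"
  )
}

#' @export
print.condition_signal <- function(x, ...) {
  cat(sprintf("<condition_signal> '%s': %d components, %d epochs\n",
              x$condition, length(x$selected_components), length(x$epochs)))
  invisible(x)
}
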