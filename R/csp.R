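#' Ledoit-Wolf shrinkage covariance estimator
#'
#' Blends the sample covariance with a scaled identity target,
#' `(1 - rho) * S + rho * mu * I`, with the shrinkage intensity `rho`
#' estimated from the data (Ledoit & Wolf 2004). The result is symmetric
#' positive definite even when samples are scarcer than channels.
#'
#' @param X samples x channels numeric matrix.
#' @return list with `cov` (the shrunk covariance), `shrinkage` (`rho` in
#'   \[0, 1\]) and `mu` (the target scale).
#' @export
ledoit_wolf_cov <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 2)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2)
  if (d2 < 1e-300) {
    return(list(cov = diag(mu, p), shrinkage = 1, mu = mu))
  }
  b2 <- 0
  for (i in seq_len(n)) {
    xi <- Xc[i, ]
    b2 <- b2 + sum((tcrossprod(xi) - S)^2)
  }
  b2 <- min(b2 / n^2, d2)
  rho <- b2 / d2
  list(cov = (1 - rho) * S + rho * diag(mu, p), shrinkage = rho, mu = mu)
}

#' Per-class shrinkage covariance matrices
#'
#' Concatenates each class's epochs along time and applies the Ledoit-Wolf
#' estimator over channels.
#'
#' @param epochs list of [trial_epoch()]s (channel space); classes taken
#'   from their `task` labels.
#' @return named list (one entry per class) of lists with `cov`,
#'   `shrinkage`, `n_epochs`.
#' @export
class_covariances <- function(epochs) {
  tasks <- vapply(epochs, function(e) e$task, character(1))
  out <- lapply(split(seq_along(epochs), tasks), function(idx) {
    if (length(idx) < 2) stop("every class needs at least 2 epochs")
    X <- t(do.call(cbind, lapply(epochs[idx], function(e) e$data)))
    lw <- ledoit_wolf_cov(X)
    lw$n_epochs <- length(idx)
    lw
  })
  out
}

inv_sqrt_sym <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) <= 0) stop("singular pooled covariance")
  e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
}

#' Multiclass common spatial patterns
#'
#' CSP extremizes the ratio of class-conditional variances through a
#' generalized eigendecomposition of class covariances. The two-class
#' algorithm is extended to many classes one-vs-rest: for each class, the
#' whitened (class vs pooled-rest) eigenproblem is solved, candidate filters
#' are scored by how far their class-variance ratio deviates from the
#' uninformative 0.5, and the `n_components` filters with the largest
#' deviation are pooled across classes (near-collinear duplicates dropped).
#' Patterns for visualization are the pooled covariance times the filters.
#'
#' @param epochs list of channel-space [trial_epoch()]s with task labels.
#' @param n_components number of spatial filters to keep (default 4).
#' @return object of class `csp_result`: `filters` (channels x
#'   `n_components`), `patterns` (channels x `n_components`), `eigenvalues`
#'   (class-variance ratios, ordered by `|ratio - 0.5|` descending),
#'   `classes` (the one-vs-rest class of each filter),
#'   `transformed_features` (tibble: trials x log-variance features),
#'   `channel_names`.
#' @export
fit_csp_multiclass <- function(epochs, n_components = 4) {
  covs <- class_covariances(epochs)
  classes <- names(covs)
  if (length(classes) < 2) stop("need at least 2 classes")
  cand <- list()
  for (cl in classes) {
    Cc <- covs[[cl]]$cov
    rest <- Reduce(`+`, lapply(covs[setdiff(classes, cl)], `[[`, "cov")) /
      (length(classes) - 1)
    P <- inv_sqrt_sym(Cc + rest)
    e <- eigen(P %*% Cc %*% t(P), symmetric = TRUE)
    W <- t(P) %*% e$vectors            # channels x k filters
    for (j in seq_len(ncol(W))) {
      cand[[length(cand) + 1]] <- list(filter = W[, j], ratio = e$values[j],
                                       class = cl)
    }
  }
  dev <- vapply(cand, function(c) abs(c$ratio - 0.5), numeric(1))
  ord <- order(-dev)
  keep <- list()
  for (i in ord) {
    f <- cand[[i]]$filter / sqrt(sum(cand[[i]]$filter^2))
    dup <- any(vapply(keep, function(k) {
      abs(sum(f * k$filter / sqrt(sum(k$filter^2)))) > 0.99
    }, logical(1)))
    if (!dup) keep[[length(keep) + 1]] <- cand[[i]]
    if (length(keep) == n_components) break
  }
  filters <- vapply(keep, `[[`, numeric(length(keep[[1]]$filter)), "filter")
  pooled <- Reduce(`+`, lapply(covs, `[[`, "cov")) / length(covs)
  patterns <- pooled %*% filters
  feats <- t(vapply(epochs, function(e) {
    log(pmax(apply(t(filters) %*% e$data, 1, stats::var), 1e-300))
  }, numeric(ncol(filters))))
  colnames(feats) <- sprintf("csp%d", seq_len(ncol(filters)))
  structure(
    list(filters = filters, patterns = patterns,
         eigenvalues = vapply(keep, `[[`, numeric(1), "ratio"),
         classes = vapply(keep, `[[`, character(1), "class"),
         transformed_features = dplyr::bind_cols(
           tibble::tibble(
             trial = vapply(epochs, function(e) e$trial, integer(1)),
             task = vapply(epochs, function(e) e$task, character(1))),
           tibble::as_tibble(feats)),
         channel_names = epochs[[1]]$channel_names),
    class = "csp_result"
  )
}

#' @export
print.csp_result <- function(x, ...) {
  cat(sprintf("<csp_result> %d spatial filters; variance ratios: %s\n",
              ncol(x$filters), paste(sprintf("%.2f", x$eigenvalues), collapse = ", ")))
  invisible(x)
}

#' Screen CSP patterns for residual artifacts
#'
#' Applies the rule-based component labeler to each CSP pattern (topography
#' plus the filter's projected time course), flagging patterns whose winning
#' class is ocular or muscular. On supposedly clean brain-only data a flag
#' indicates that class-separability-maximizing filters have recovered
#' leaked artifact activity.
#'
#' @param result a `csp_result`.
#' @param epochs the channel-space epochs the CSP was fitted on.
#' @param layout cap layout tibble aligned with the channels.
#' @param labeler labeling function with the [label_components()] contract.
#' @return tibble: `pattern`, `winning_class`, `artifact` (logical flag),
#'   plus the class probabilities.
#' @export
csp_artifact_screen <- function(result, epochs, layout,
                                labeler = label_components) {
  stopifnot(inherits(result, "csp_result"))
  if (ncol(result$filters) == 0) {
    return(tibble::tibble(pattern = integer(), winning_class = character(),
                          artifact = logical()))
  }
  acts <- lapply(epochs, function(e) t(result$filters) %*% e$data)
  pseudo <- structure(
    list(unmixing = t(result$filters), mixing = result$patterns,
         activations = acts,
         variance_share = rep(NA_real_, ncol(result$filters)),
         rate = epochs[[1]]$rate, channel_names = result$channel_names,
         epoch_meta = tibble::tibble(
           trial = vapply(epochs, function(e) e$trial, integer(1)),
           task = vapply(epochs, function(e) e$task, character(1)))),
    class = "decomposition")
  labs <- labeler(pseudo, layout)
  labs |>
    dplyr::rename(pattern = "component") |>
    dplyr::mutate(artifact = .data$winning_class %in% c("eye", "muscle"))
}
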