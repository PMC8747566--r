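new_outcome <- function(approach, condition, band, accuracies, n_classes) {
  structure(
    list(approach = approach, condition = condition, band = band,
         accuracies = accuracies, mean_accuracy = mean(accuracies),
         n_classes = n_classes),
    class = "classification_outcome"
  )
}

#' @export
print.classification_outcome <- function(x, ...) {
  cat(sprintf("<classification_outcome> %s / %s%s: mean accuracy %.3f over %d repetitions (chance %.2f)\n",
              x$approach, x$condition,
              if (is.null(x$band)) "" else paste0(" / ", x$band),
              x$mean_accuracy, length(x$accuracies), 1 / x$n_classes))
  invisible(x)
}

stratified_split <- function(y, split) {
  train <- integer()
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_tr <- max(1L, min(length(idx) - 1L, round(split * length(idx))))
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

# one-vs-all linear SVM bank; returns weights (classes x features),
# intercepts, and a predict closure
fit_ova_svm <- function(X, y, cost = 1) {
  classes <- levels(y)
  W <- matrix(0, nrow = length(classes), ncol = ncol(X),
              dimnames = list(classes, colnames(X)))
  b <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    yy <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    m <- e1071::svm(X, yy, kernel = "linear", cost = cost, scale = FALSE)
    w <- drop(crossprod(m$coefs, m$SV))
    b0 <- -m$rho
    # orient decision so the positive class has the larger decision value
    dec <- X %*% w + b0
    if (mean(dec[yy == "pos"]) < mean(dec[yy == "neg"])) {
      w <- -w; b0 <- -b0
    }
    W[cl, ] <- w
    b[cl] <- b0
  }
  list(weights = W, intercepts = b,
       predict = function(Xnew) {
         d <- Xnew %*% t(W) + matrix(b, nrow(Xnew), length(b), byrow = TRUE)
         factor(classes[max.col(d, ties.method = "first")], levels = classes)
       })
}

#' One-vs-all ECOC classification with repeated train/test splits
#'
#' Reduces the multiclass problem to one binary linear margin classifier
#' (support vector machine, fixed unit cost, no hyperparameter optimization)
#' per class under one-vs-all coding; prediction is the learner with the
#' maximal decision value. Accuracy is estimated over `n_boot` fresh
#' stratified train/test splits (default 100 splits at 80-20). Features are
#' standardized using training-split statistics. When the input is a PCA-
#' reduced table produced by [pca_reduce()], pass the unreduced table
#' instead and set `per_band_k`: the PCA is then refitted inside each
#' training split (no leakage); `per_band_k = NULL` classifies the table as
#' given.
#'
#' @param table a `feature_table`.
#' @param split training fraction (default 0.8).
#' @param n_boot number of random splits (default 100).
#' @param seed integer seed; fixed seed gives an identical accuracy list.
#' @param per_band_k if non-`NULL`, per-band PCA to this many components is
#'   fitted on each training split before classification.
#' @param cost SVM cost parameter (default 1, untuned).
#' @return list with `outcome` (a `classification_outcome`) and `model`
#'   (a `trained_linear_model` fitted on all rows -- with, if applicable,
#'   the full-data PCA projection -- for weight interpretation).
#' @export
ecoc_train_test <- function(table, split = 0.8, n_boot = 100, seed = 1L,
                            per_band_k = NULL, cost = 1, condition = NULL) {
  stopifnot(inherits(table, "feature_table"))
  y <- factor(table$task)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 trials")

  get_matrix <- function(tbl) feature_matrix(tbl)

  accs <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      tr <- stratified_split(y, split)
      te <- setdiff(seq_along(y), tr)
      if (!is.null(per_band_k)) {
        red <- pca_reduce(table, per_band_k = per_band_k, fit_rows = tr)
        X <- get_matrix(red$table)
      } else {
        X <- get_matrix(table)
      }
      mu <- colMeans(X[tr, , drop = FALSE])
      sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv < 1e-12] <- 1
      Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
      fit <- fit_ova_svm(Xs[tr, , drop = FALSE], y[tr], cost = cost)
      mean(fit$predict(Xs[te, , drop = FALSE]) == y[te])
    }, numeric(1))
  })

  # interpretation model on all rows
  if (!is.null(per_band_k)) {
    red <- pca_reduce(table, per_band_k = per_band_k)
    X <- get_matrix(red$table); projection <- red$projection
    red_meta <- attr(red$table, "column_meta")
  } else {
    X <- get_matrix(table); projection <- NULL
    red_meta <- attr(table, "column_meta")
  }
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  fit <- fit_ova_svm(Xs, y, cost = cost)
  model <- structure(
    list(weights = fit$weights, intercepts = fit$intercepts,
         classes = levels(y), coding = "one_vs_all",
         standardize = list(center = mu, scale = sdv),
         projection = projection, column_meta = red_meta),
    class = "trained_linear_model")

  approach <- if (identical(attr(table, "approach"), "emg")) "emg_ecoc" else "tfa_ecoc"
  list(outcome = new_outcome(approach,
                             condition %||% attr(table, "approach"),
                             NULL, accs, nlevels(y)),
       model = model)
}

#' @export
print.trained_linear_model <- function(x, ...) {
  cat(sprintf("<trained_linear_model> %s coding, %d binary learners x %d features\n",
              x$coding, nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

#' Multiclass LDA with repeated k-fold cross-validation
#'
#' Linear discriminant analysis (SVD-based solver, no explicit covariance
#' inversion) evaluated by `repeats` x `folds` stratified cross-validation
#' (default 10 x 10 = 100 accuracy values).
#'
#' @param table a `feature_table`.
#' @param folds number of CV folds (default 10).
#' @param repeats number of CV repetitions (default 10).
#' @param seed integer seed.
#' @return a `classification_outcome` with `folds * repeats` accuracies.
#' @export
lda_cv <- function(table, folds = 10, repeats = 10, seed = 1L,
                   condition = NULL) {
  stopifnot(inherits(table, "feature_table"))
  y <- factor(table$task)
  if (any(table(y) < folds)) {
    stop("a class has fewer trials than folds; apply the low-trial exclusion rule first")
  }
  X <- feature_matrix(table)
  accs <- withr::with_seed(seed, {
    unlist(lapply(seq_len(repeats), function(r) {
      fold_of <- integer(length(y))
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        fold_of[idx] <- rep_len(seq_len(folds), length(idx))
      }
      vapply(seq_len(folds), function(f) {
        tr <- which(fold_of != f); te <- which(fold_of == f)
        Xtr <- X[tr, , drop = FALSE]
        # LDA cannot use directions without any within-group variance
        keep <- apply(Xtr, 2, function(col) {
          any(tapply(col, y[tr], stats::sd) > 1e-10)
        })
        if (!any(keep)) {
          # degenerate features: fall back to the majority training class
          pred <- factor(rep(names(which.max(table(y[tr]))), length(te)),
                         levels = levels(y))
          return(mean(pred == y[te]))
        }
        fit <- suppressWarnings(MASS::lda(Xtr[, keep, drop = FALSE],
                                          grouping = y[tr]))
        pred <- stats::predict(fit, X[te, keep, drop = FALSE])$class
        mean(pred == y[te])
      }, numeric(1))
    }))
  })
  new_outcome("bandpower_lda", condition %||% attr(table, "approach"),
              NULL, accs, nlevels(y))
}

#' Exclude participants with too few trials
#'
#' @param counts tibble with a `participant` column and one or more numeric
#'   trial-count columns (one per condition), or a named numeric vector of
#'   per-participant counts.
#' @param min_trials minimum trials required in every condition (default 10).
#' @return the filtered counts (same shape as the input); excluded
#'   participants are reported via message.
#' @export
exclude_low_trial_participants <- function(counts, min_trials = 10) {
  if (is.numeric(counts) && !is.null(names(counts))) {
    keep <- counts >= min_trials
    if (any(!keep)) message("excluded: ", paste(names(counts)[!keep], collapse = ", "))
    return(counts[keep])
  }
  counts <- tibble::as_tibble(counts)
  stopifnot("participant" %in% names(counts))
  num_cols <- names(counts)[vapply(counts, is.numeric, logical(1))]
  ok <- apply(counts[num_cols] >= min_trials, 1, all)
  if (all(!ok)) stop("all participants excluded")
  if (any(!ok)) {
    message("excluded: ", paste(counts$participant[!ok], collapse = ", "))
  }
  counts[ok, ]
}

signif_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "n.s.")
}

#' Pairwise condition comparison of per-participant accuracies
#'
#' For every pair of conditions: the mean paired difference across
#' participants, a two-sided paired test (Wilcoxon signed-rank by default,
#' paired t-test via `test = "t"`), optional Holm correction, and
#' significance stars at the 0.05 / 0.01 / 0.001 levels.
#'
#' @param accuracies tibble with columns `participant`, `condition`,
#'   `accuracy` (one row per participant x condition).
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @param adjust p-value adjustment method (default `"none"`; e.g.
#'   `"holm"`).
#' @return tibble with one row per condition pair: `condition_a`,
#'   `condition_b`, `mean_a`, `mean_b`, `mean_diff` (b - a), `p_value`,
#'   `stars`.
#' @export
compare_conditions <- function(accuracies, test = c("wilcoxon", "t"),
                               adjust = "none") {
  test <- match.arg(test)
  accuracies <- tibble::as_tibble(accuracies)
  stopifnot(all(c("participant", "condition", "accuracy") %in% names(accuracies)))
  wide <- tidyr::pivot_wider(accuracies, id_cols = "participant",
                             names_from = "condition",
                             values_from = "accuracy")
  conds <- setdiff(names(wide), "participant")
  if (anyNA(wide[conds])) stop("unpaired inputs: every participant needs every condition")
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  out <- dplyr::bind_rows(lapply(pairs, function(pr) {
    a <- wide[[pr[1]]]; b <- wide[[pr[2]]]
    p <- if (all(b == a)) 1 else if (test == "wilcoxon") {
      suppressWarnings(stats::wilcox.test(b, a, paired = TRUE))$p.value
    } else {
      stats::t.test(b, a, paired = TRUE)$p.value
    }
    tibble::tibble(condition_a = pr[1], condition_b = pr[2],
                   mean_a = mean(a), mean_b = mean(b),
                   mean_diff = mean(b - a), p_value = p)
  }))
  out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  out$stars <- signif_stars(out$p_value)
  out
}

#' Per-frequency-band classification
#'
#' Runs the chosen harness once per canonical band: the time-frequency route
#' restricts the TFA table to one band's columns and PCA-reduces them to 14
#' features inside each training split before the one-vs-all classifier; the
#' bandpower route computes the per-channel bandpower table for the band
#' (one feature per channel) and runs repeated-CV LDA.
#'
#' @param cond a `condition_signal`.
#' @param approach `"tfa"` or `"bandpower"`.
#' @param bands band tibble (default [eeg_bands()]).
#' @param seed integer seed.
#' @param per_band_k PCA components per band for the TFA route (default 14).
#' @param ... passed to [ecoc_train_test()] / [lda_cv()].
#' @return tibble with one row per band: `band`, `mean_accuracy`, and an
#'   `outcome` list-column of `classification_outcome`s.
#' @export
per_band_analysis <- function(cond, approach = c("tfa", "bandpower"),
                              bands = eeg_bands(), seed = 1L,
                              per_band_k = 14, ...) {
  approach <- match.arg(approach)
  if (approach == "tfa") full <- tfa_feature_table(cond, bands = bands)
  rows <- lapply(seq_len(nrow(bands)), function(b) {
    bnd <- bands[b, ]
    if (approach == "tfa") {
      meta <- attr(full, "column_meta")
      cols <- meta$column[meta$band == bnd$name]
      sub <- new_feature_table(full[, c("trial", "task", cols)],
                               meta[meta$band == bnd$name, ], "tfa")
      res <- ecoc_train_test(sub, seed = seed, per_band_k = per_band_k, ...)
      out <- res$outcome
    } else {
      tbl <- bandpower_feature_table(cond, bnd)
      out <- lda_cv(tbl, seed = seed, ...)
    }
    out$band <- bnd$name
    tibble::tibble(band = bnd$name, mean_accuracy = out$mean_accuracy,
                   outcome = list(out))
  })
  dplyr::bind_rows(rows)
}
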