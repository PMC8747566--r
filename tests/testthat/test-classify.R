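test_that("the one-vs-all harness separates well-separated clouds", {
  tbl <- cloud_table(n_per_class = 15, sep = 8)
  res <- ecoc_train_test(tbl, n_boot = 20, seed = 1)
  expect_length(res$outcome$accuracies, 20)
  expect_gt(res$outcome$mean_accuracy, 0.95)
  expect_equal(res$outcome$mean_accuracy, mean(res$outcome$accuracies))
  expect_true(all(res$outcome$accuracies >= 0 & res$outcome$accuracies <= 1))
})

test_that("the one-vs-all harness is at chance under permuted labels", {
  tbl <- permuted_labels(cloud_table(n_per_class = 20, sep = 8), seed = 7)
  res <- ecoc_train_test(tbl, n_boot = 50, seed = 2)
  expect_gt(res$outcome$mean_accuracy, 0.1)
  expect_lt(res$outcome$mean_accuracy, 0.3)
})

test_that("repeated splits are reproducible under a fixed seed", {
  tbl <- cloud_table(n_per_class = 8, sep = 2)
  a <- ecoc_train_test(tbl, n_boot = 10, seed = 5)$outcome$accuracies
  b <- ecoc_train_test(tbl, n_boot = 10, seed = 5)$outcome$accuracies
  expect_identical(a, b)
})

test_that("LDA cross-validation returns folds x repeats accuracies", {
  tbl <- cloud_table(n_per_class = 15, sep = 8)
  out <- lda_cv(tbl, folds = 10, repeats = 10, seed = 1)
  expect_length(out$accuracies, 100)
  expect_gt(out$mean_accuracy, 0.95)

  perm <- permuted_labels(cloud_table(n_per_class = 15, sep = 8), seed = 3)
  out_p <- lda_cv(perm, folds = 10, repeats = 5, seed = 1)
  expect_lt(abs(out_p$mean_accuracy - 0.2), 0.1)

  small <- cloud_table(n_per_class = 5)
  expect_error(lda_cv(small, folds = 10), "exclusion")
})

test_that("low-trial participants are excluded", {
  counts <- c(A = 12, B = 9, C = 30)
  expect_message(kept <- exclude_low_trial_participants(counts, 10), "B")
  expect_named(kept, c("A", "C"))
  expect_silent(exclude_low_trial_participants(c(A = 12, C = 30), 10))
  expect_named(exclude_low_trial_participants(counts, 0), c("A", "B", "C"))

  df <- tibble::tibble(participant = c("A", "B"), brain = c(12, 9),
                       artifact = c(15, 20))
  expect_message(kept_df <- exclude_low_trial_participants(df, 10))
  expect_equal(kept_df$participant, "A")
  expect_error(exclude_low_trial_participants(df, 100), "all participants")
})

test_that("paired condition comparisons report differences and stars", {
  acc <- tibble::tibble(
    participant = rep(sprintf("P%02d", 1:15), 2),
    condition = rep(c("brain", "artifact"), each = 15),
    accuracy = c(seq(0.4, 0.6, length.out = 15),
                 seq(0.4, 0.6, length.out = 15) + 0.2))
  cmp <- compare_conditions(acc)
  expect_equal(nrow(cmp), 1)
  expect_equal(abs(cmp$mean_diff), 0.2, tolerance = 1e-12)
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$stars, "***")

  same <- acc
  same$accuracy <- rep(seq(0.4, 0.6, length.out = 15), 2)
  cmp0 <- compare_conditions(same)
  expect_equal(cmp0$mean_diff, 0)
  expect_equal(cmp0$stars, "n.s.")

  unpaired <- acc[-1, ]
  expect_error(compare_conditions(unpaired), "unpaired")
})

test_that("star thresholds follow the 0.05 / 0.01 / 0.001 convention", {
  expect_equal(eegdecode:::signif_stars(c(0.03, 0.004, 0.0004, 0.2)),
               c("*", "**", "***", "n.s."))
})

test_that("per-band analysis produces one outcome per band with 14 TFA features", {
  cond <- small_conditions()$artifact
  res <- suppressMessages(
    per_band_analysis(cond, "tfa", seed = 1, n_boot = 8))
  expect_equal(res$band, eeg_bands()$name)
  expect_length(res$outcome, 5)
  for (o in res$outcome) expect_length(o$accuracies, 8)
})

test_that("a planted theta-band artifact makes theta the most informative band", {
  # artifact source concentrated in the theta band, frontal topography,
  # task-modulated amplitude, white sensor noise: only the theta band
  # carries class information above the noise floor
  layout <- cap_layout(12)
  topo <- eegdecode:::topo_bump(layout, c(0, 1.0), 0.5)
  tasks <- c("painting", "faucet", "glass", "head_slow", "head_fast")
  g <- c(0, 0.25, 0.5, 0.75, 1)
  eps <- withr::with_seed(24, {
    lapply(seq_len(50), function(i) {
      k <- (i - 1) %% 5 + 1
      len <- sample(250:500, 1)
      s <- eegdecode:::band_noise(len, 125, 4, 6) * (1 + 0.8 * g[k])
      X <- tcrossprod(topo, s) + matrix(rnorm(12 * len, sd = 0.3), 12)
      trial_epoch(X, 125, tasks[k], trial = i)
    })
  })
  cond <- structure(
    list(condition = "artifact", selected_components = 1:12, epochs = eps,
         component_epochs = lapply(eps, function(e) e$data),
         epoch_meta = tibble::tibble(
           trial = seq_along(eps),
           task = vapply(eps, function(e) e$task, character(1))),
         rate = 125),
    class = "condition_signal")
  res <- per_band_analysis(cond, "bandpower", seed = 1,
                           folds = 5, repeats = 2)
  expect_equal(res$band[which.max(res$mean_accuracy)], "theta")
})

test_that("identical features across bands give equal band accuracies", {
  tbl <- cloud_table(n_per_class = 10, n_features = 10, sep = 3)
  # duplicate the same features under two band labels
  meta <- attr(tbl, "column_meta")
  accs <- vapply(c("alpha", "beta"), function(b) {
    m2 <- meta; m2$band <- b
    t2 <- eegdecode:::new_feature_table(tbl, m2, "tfa")
    lda_cv(t2, folds = 5, repeats = 2, seed = 4)$mean_accuracy
  }, numeric(1))
  expect_equal(accs[["alpha"]], accs[["beta"]])
})
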