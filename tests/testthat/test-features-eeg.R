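# brute-force oracle for the log bandpower definition
bp_oracle <- function(x) {
  s <- 0
  for (v in x) s <- s + v * v
  10 * log10(s / length(x))
}

test_that("bandpower matches the brute-force oracle and closed forms", {
  expect_equal(bandpower(c(1, 2, 2, 1), filter = FALSE),
               10 * log10(10 / 4), tolerance = 1e-12)
  withr::with_seed(1, {
    for (i in 1:20) {
      x <- rnorm(sample(50:500, 1), sd = 10^runif(1, -2, 2))
      expect_equal(bandpower(x, filter = FALSE), bp_oracle(x),
                   tolerance = 1e-12)
    }
  })
  # unit sinusoid over whole cycles: mean square 1/2
  t <- seq(0, 2 - 1 / 500, by = 1 / 500)
  s <- sin(2 * pi * 10 * t)
  expect_equal(bandpower(s, filter = FALSE), 10 * log10(0.5),
               tolerance = 1e-6)
  # 10x amplitude = +20 dB exactly
  x <- rnorm(300)
  expect_equal(bandpower(10 * x, filter = FALSE),
               bandpower(x, filter = FALSE) + 20, tolerance = 1e-10)
  expect_message(fl <- bandpower(rep(0, 100), filter = FALSE), "floor")
  expect_equal(fl, -200)
})

test_that("band-pass filtering isolates the band before the power measure", {
  t <- seq(0, 4 - 1 / 500, by = 1 / 500)
  x <- sin(2 * pi * 10 * t) + sin(2 * pi * 35 * t)
  alpha <- eeg_bands()[2, ]
  bp_alpha <- bandpower(x, rate = 500, band = alpha)
  expect_equal(bp_alpha, 10 * log10(0.5), tolerance = 0.1)
})

test_that("the TF map concentrates a sinusoid's power in its band", {
  t <- seq(0, 4 - 1 / 250, by = 1 / 250)
  m <- trial_tfa(sin(2 * pi * 10 * t), 250)
  band_means <- rowMeans(m)
  expect_equal(names(which.max(band_means)), "alpha")
  expect_true(all(band_means["alpha"] > 5 * band_means[names(band_means) != "alpha"]))
  expect_true(all(trial_tfa(rep(0, 1000), 250) == 0))
  expect_error(trial_tfa(rnorm(40), 250), "too short")
})

test_that("stationary noise gives flat time bins up to sampling error", {
  # one 4-s epoch has only a few spectral degrees of freedom per narrow
  # band, so per-epoch bins scatter with CV well below 1 but not tightly;
  # averaging maps over independent epochs must drive the CV below 0.3
  withr::with_seed(3, {
    maps <- replicate(10, trial_tfa(rnorm(4 * 250), 250), simplify = FALSE)
  })
  cv1 <- apply(maps[[1]], 1, function(r) stats::sd(r) / mean(r))
  expect_true(all(cv1 < 1))
  avg <- Reduce(`+`, maps) / length(maps)
  cv <- apply(avg, 1, function(r) stats::sd(r) / mean(r))
  expect_true(all(cv < 0.3))
})

test_that("TFA feature counts follow components x bands x bins", {
  cond <- small_conditions()$brain
  n_comp <- length(cond$selected_components)
  tbl <- tfa_feature_table(cond)
  expect_equal(nrow(attr(tbl, "column_meta")), n_comp * 5 * 10)
  expect_equal(nrow(tbl), length(cond$epochs))

  # degenerate configuration: 1 component, 1 band, 10 bins
  one <- cond
  one$selected_components <- cond$selected_components[1]
  one$component_epochs <- lapply(cond$component_epochs, function(a)
    a[1, , drop = FALSE])
  tbl1 <- tfa_feature_table(one, bands = eeg_bands()[2, ])
  expect_equal(nrow(attr(tbl1, "column_meta")), 10)
})

test_that("trial averaging collapses the table to one row per task", {
  cond <- small_conditions()$brain
  tbl <- tfa_feature_table(cond, average_trials = TRUE)
  expect_equal(nrow(tbl), length(unique(cond$epoch_meta$task)))
})

test_that("per-band PCA keeps 14 components per band and stores the inverse", {
  cond <- small_conditions()$brain
  tbl <- tfa_feature_table(cond)
  red <- pca_reduce(tbl, per_band_k = 14)
  expect_equal(nrow(attr(red$table, "column_meta")), 70)
  expect_s3_class(red$projection, "pca_projection")
  # per-band variance bookkeeping: kept variance <= total variance
  meta <- attr(tbl, "column_meta")
  for (b in unique(meta$band)) {
    X <- as.matrix(tbl[, meta$column[meta$band == b]])
    kept <- sum(red$projection$bands[[b]]$sdev^2)
    expect_lte(kept, sum(apply(X, 2, stats::var)) * (1 + 1e-8))
  }
})

test_that("PCA reduction is lossless when the data rank is within budget", {
  withr::with_seed(5, {
    n <- 40
    basis <- qr.Q(qr(matrix(rnorm(100 * 5), 100, 5)))
    X <- matrix(rnorm(n * 5), n, 5) %*% t(basis)   # rank 5 in 100 dims
  })
  colnames(X) <- sprintf("c01.alpha.b%03d", 1:100)
  tbl <- dplyr::bind_cols(tibble::tibble(trial = 1:n, task = "glass"),
                          tibble::as_tibble(X))
  meta <- tibble::tibble(column = colnames(X), component = 1L,
                         band = "alpha", bin = 1:100)
  ft <- eegdecode:::new_feature_table(tbl, meta, "tfa")
  red <- suppressMessages(pca_reduce(ft, per_band_k = 5))
  S <- as.matrix(red$table[, attr(red$table, "column_meta")$column])
  pb <- red$projection$bands$alpha
  recon <- S %*% t(pb$rotation)
  recon <- sweep(recon, 2, pb$center, "+")
  expect_lt(max(abs(recon - X)), 1e-8)
})

test_that("bandpower tables have one column per channel and obey scaling", {
  cond <- small_conditions()$all
  band <- eeg_bands(include_all = TRUE)[6, ]
  tbl <- bandpower_feature_table(cond, band)
  expect_equal(nrow(attr(tbl, "column_meta")), nrow(cond$epochs[[1]]$data))
  doubled <- cond
  doubled$epochs <- lapply(cond$epochs, function(e) { e$data <- 2 * e$data; e })
  tbl2 <- bandpower_feature_table(doubled, band)
  cols <- attr(tbl, "column_meta")$column
  expect_equal(as.matrix(tbl2[, cols]) - as.matrix(tbl[, cols]),
               matrix(20 * log10(2), nrow(tbl), length(cols)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("broadband power dominates any single band on narrowband signals", {
  t <- seq(0, 4 - 1 / 250, by = 1 / 250)
  x <- sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 20 * t)
  bands <- eeg_bands(include_all = TRUE)
  vals <- vapply(seq_len(nrow(bands)), function(i) {
    bandpower(x, rate = 250, band = bands[i, ])
  }, numeric(1))
  expect_gte(vals[6] + 1e-6, max(vals[1:5]))
})
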