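test_that("weight reprojection inverts the per-band PCA exactly", {
  cond <- small_conditions()$brain
  tbl <- tfa_feature_table(cond)
  res <- ecoc_train_test(tbl, n_boot = 5, seed = 1, per_band_k = 6)
  img <- reproject_weights(res$model)
  n_comp <- length(cond$selected_components)
  expect_equal(nrow(img), length(res$model$classes) * n_comp * 5 * 10)
  expect_setequal(unique(img$band), eeg_bands()$name)

  # single nonzero PCA coefficient reconstructs that principal axis
  model <- res$model
  model$weights[] <- 0
  model$weights[1, 1] <- 1          # first learner, first kept column
  model$standardize$scale[] <- 1
  img1 <- reproject_weights(model)
  b1 <- attr(res$model$column_meta, "names")   # not used; band from meta
  first_col <- model$column_meta$column[1]
  band1 <- model$column_meta$band[model$column_meta$column == first_col]
  pb <- model$projection$bands[[band1]]
  axis <- pb$rotation[, 1]
  got <- img1$weight[img1$learner == model$classes[1] & img1$band == band1]
  expect_equal(unname(got), unname(axis), tolerance = 1e-10)
  other <- img1$weight[img1$band != band1 & img1$learner == model$classes[1]]
  expect_true(all(other == 0))
})

test_that("identity projection returns the raw weights reshaped", {
  # build a tiny model whose per-band PCA rotation is the identity
  cols <- sprintf("c01.alpha.b%02d", 1:4)
  proj <- structure(list(
    bands = list(alpha = list(center = rep(0, 4),
                              rotation = diag(4), columns = cols,
                              sdev = rep(1, 4))),
    source_meta = tibble::tibble(column = cols, component = 1L,
                                 band = "alpha", bin = 1:4)),
    class = "pca_projection")
  red_cols <- sprintf("alpha.PC%02d", 1:4)
  w <- matrix(c(1, -2, 3, 0.5), 1, dimnames = list("glass", red_cols))
  model <- structure(list(
    weights = w, intercepts = c(glass = 0), classes = "glass",
    coding = "one_vs_all",
    standardize = list(center = rep(0, 4),
                       scale = stats::setNames(rep(1, 4), red_cols)),
    projection = proj,
    column_meta = tibble::tibble(column = red_cols, band = "alpha")),
    class = "trained_linear_model")
  img <- reproject_weights(model)
  expect_equal(img$weight, c(1, -2, 3, 0.5))
  expect_equal(img$bin, 1:4)
})

test_that("weight topographies are linear in the component weights", {
  layout <- cap_layout(12)
  mixing <- matrix(rnorm(12 * 2), 12, 2)
  img <- tibble::tibble(learner = "glass",
                        component = rep(1:2, each = 1),
                        band = "alpha", bin = 1L, weight = c(1, -1))
  class(img) <- c("weight_image", class(img))
  top <- weights_to_topography(img, "alpha", 1, mixing, layout)
  expect_equal(top$value, drop(mixing %*% c(1, -1)))

  img$weight <- c(1, 0)
  top1 <- weights_to_topography(img, "alpha", 1, mixing, layout)
  expect_equal(top1$value, mixing[, 1])

  img$weight <- c(0, 0)
  expect_true(all(weights_to_topography(img, "alpha", 1, mixing,
                                        layout)$value == 0))
  expect_error(weights_to_topography(img, "alpha", 1, mixing[, 1, drop = FALSE],
                                     layout), "component count")
})

test_that("task patterns scale with the covariance and recover iid filters", {
  layout <- cap_layout(6)
  withr::with_seed(6, {
    eps <- lapply(1:10, function(i) {
      trial_epoch(matrix(rnorm(6 * 5000), 6), 250, "glass", trial = i)
    })
  })
  filt <- topography(c(1, -1, 2, 0, 0.5, -0.25), layout, task = "glass")
  pat <- task_pattern(filt, eps, layout)
  # iid unit-variance channels: covariance ~ identity, pattern ~ filter
  expect_gt(stats::cor(pat$value, filt$value), 0.99)

  scaled <- lapply(eps, function(e) { e$data <- 2 * e$data; e })
  pat2 <- task_pattern(filt, scaled, layout)
  expect_equal(pat2$value, 4 * pat$value, tolerance = 1e-10)

  zero <- lapply(eps[1:2], function(e) { e$data[] <- 0; e })
  expect_error(task_pattern(filt, zero, layout), "degenerate")
})

test_that("covariance times decoder weights recovers the planted forward pattern", {
  # generative model: x = a * s + noise; a linear decoder's weights are a
  # backward filter, but C %*% w points back at a
  for (seed in c(12, 13)) {
    expect_gt(haufe_recovery_cor(seed = seed), 0.95)
  }
})

test_that("bandpower topographies localize the dominant artifact frontally", {
  sim <- small_session()
  conds <- small_conditions()
  layout <- sim$truth$layout
  theta <- eeg_bands()[1, ]
  top_art <- bandpower_topography(
    bandpower_feature_table(conds$artifact, theta), layout,
    condition = "artifact")
  one_task <- top_art[top_art$task == top_art$task[1], ]
  expect_equal(nrow(one_task), 24)
  expect_true(layout$frontal[which.max(one_task$value)])

  # all-condition topography mimics the artifact condition more than brain
  # (compared on the linear power scale, where the dominant source shows)
  top_all <- bandpower_topography(
    bandpower_feature_table(conds$all, theta), layout, condition = "all")
  top_brain <- bandpower_topography(
    bandpower_feature_table(conds$brain, theta), layout, condition = "brain")
  tsk <- top_art$task[1]
  lin <- function(top) 10^(top$value[top$task == tsk] / 10)
  r_art <- stats::cor(lin(top_all), lin(top_art))
  r_brain <- stats::cor(lin(top_all), lin(top_brain))
  expect_gt(r_art, r_brain)

  # averaging identical trials equals the single-trial map
  cond1 <- conds$all
  cond1$epochs <- rep(conds$all$epochs[1], 3)
  t1 <- bandpower_topography(bandpower_feature_table(cond1, theta), layout)
  single <- bandpower_feature_table(
    structure(modifyList(conds$all, list(epochs = conds$all$epochs[1])),
              class = "condition_signal"), theta)
  expect_equal(t1$value,
               as.numeric(single[1, attr(single, "column_meta")$column]))
})
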