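planted_mixture <- function(n = 20000, n_ch = 64, seed = 42) {
  withr::with_seed(seed, {
    S <- rbind(sign(rnorm(n)) * rexp(n),
               sign(rnorm(n)) * rexp(n),
               sign(rnorm(n)) * rexp(n))
    A <- matrix(rnorm(n_ch * 3), n_ch, 3)
    list(A = A, S = S,
         epoch = trial_epoch(A %*% S, 500, "t", trial = 1L))
  })
}

test_that("ICA recovers planted super-Gaussian mixing columns", {
  m <- planted_mixture()
  dec <- suppressMessages(fit_ica(list(m$epoch), seed = 1))
  expect_equal(nrow(dec$unmixing), 3)  # rank-limited
  cr <- abs(stats::cor(dec$mixing, m$A))
  # best-match assignment: every planted column matched by some component
  expect_true(all(apply(cr, 2, max) > 0.95))
})

test_that("ICA is deterministic under a fixed seed and orders by variance", {
  m <- planted_mixture(n = 8000, n_ch = 16)
  d1 <- suppressMessages(fit_ica(list(m$epoch), seed = 3))
  d2 <- suppressMessages(fit_ica(list(m$epoch), seed = 3))
  expect_identical(d1$unmixing, d2$unmixing)
  expect_true(all(diff(d1$variance_share) <= 1e-12))
  expect_true(all(d1$variance_share >= 0))
  expect_lte(sum(d1$variance_share), 1 + 1e-6)
})

test_that("on white noise no component dominates the variance", {
  withr::with_seed(8, {
    ep <- trial_epoch(matrix(rnorm(16 * 30000), 16), 500, "t", trial = 1L)
  })
  dec <- suppressMessages(fit_ica(list(ep), seed = 2, max_iter = 50))
  expect_lt(max(dec$variance_share), 3 * (3 / 16))
})

test_that("the labeler identifies planted blink, muscle and line components", {
  cfg <- session_config(n_channels = 24, trials_per_task = 4, n_tasks = 5,
                        acquisition_rate = 125, snr_db = Inf, seed = 21)
  sim <- simulate_session(cfg)
  dec <- truth_decomposition(sim)
  labs <- label_components(dec, sim$truth$layout)
  kinds <- sim$truth$source_labels
  expect_equal(labs$winning_class[which(kinds == "eye_blink")], "eye")
  expect_true(all(labs$winning_class[which(kinds == "muscle")] == "muscle"))
  expect_equal(labs$winning_class[which(kinds == "line_noise")], "line_noise")
  expect_true(all(labs$winning_class[which(kinds == "brain")] == "brain"))
  probs <- as.matrix(labs[, eegdecode:::ic_classes])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(labs)), tolerance = 1e-6)
  expect_true(all(probs >= 0 & probs <= 1))
})

fake_labels <- function(classes) {
  k <- length(classes)
  tibble::tibble(component = seq_len(k),
                 winning_class = classes)
}

test_that("top-component selection ranks by variance and pools muscle+eye", {
  classes <- c(rep("brain", 12), "muscle", "eye", "heart", "line_noise",
               "channel_noise", "other")
  labs <- fake_labels(classes)
  dec <- structure(list(variance_share = seq(0.2, 0.01,
                                             length.out = length(classes))),
                   class = "decomposition")
  expect_equal(select_top_components(labs, dec, "brain", 10), 1:10)
  expect_warning(art <- select_top_components(labs, dec, "artifact", 10),
                 "only 2")
  expect_equal(art, c(13L, 14L))   # heart/line/channel/other excluded
  expect_warning(none <- select_top_components(fake_labels("other"),
                                               dec, "brain"),
                 "no components")
  expect_equal(none, integer())
})

test_that("condition reconstruction is complete, additive and index-safe", {
  # full-rank decomposition: 8 super-Gaussian sources in 8 channels
  withr::with_seed(14, {
    S <- matrix(sign(rnorm(8 * 10000)) * rexp(8 * 10000), 8)
    A <- matrix(rnorm(64), 8, 8)
    eps <- list(trial_epoch(A %*% S[, 1:6000], 250, "glass", trial = 1L),
                trial_epoch(A %*% S[, 6001:10000], 250, "faucet", trial = 2L))
  })
  eps <- lapply(eps, baseline_subtract)
  dec <- suppressMessages(fit_ica(eps, seed = 4))
  k <- nrow(dec$unmixing)
  expect_equal(k, 8)
  orig <- eps[[1]]$data
  scale <- max(abs(orig))
  all_cond <- reconstruct_condition(dec, integer(), "all")
  expect_lt(max(abs(all_cond$epochs[[1]]$data - orig)) / scale, 1e-8)

  idx_a <- 1:3; idx_b <- 4:6; idx_c <- 7:8
  ra <- reconstruct_condition(dec, idx_a, "brain")
  rb <- reconstruct_condition(dec, idx_b, "artifact")
  rc <- dec$mixing[, idx_c] %*% dec$activations[[1]][idx_c, ]
  total <- ra$epochs[[1]]$data + rb$epochs[[1]]$data + rc
  expect_lt(max(abs(total - orig)) / scale, 1e-8)

  empty <- reconstruct_condition(dec, integer(), "brain")
  expect_true(all(empty$epochs[[1]]$data == 0))
  expect_error(reconstruct_condition(dec, k + 1, "brain"), "out of range")
})

test_that("an injected label table can drive the condition split", {
  dec <- small_ica()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  k <- nrow(dec$unmixing)
  probs <- matrix(0.01, k, 7,
                  dimnames = list(NULL, eegdecode:::ic_classes))
  probs[1:3, "eye"] <- 2   # unnormalized on purpose
  probs[4:k, "brain"] <- 2
  utils::write.table(cbind(component = 1:k, as.data.frame(probs)), tmp,
                     sep = "\t", row.names = FALSE)
  labs <- read_label_table(tmp)
  expect_equal(labs$winning_class[1:3], rep("eye", 3))
  expect_equal(rowSums(as.matrix(labs[, eegdecode:::ic_classes])),
               rep(1, k), ignore_attr = TRUE)
  expect_warning(sel <- select_top_components(labs, dec, "artifact", 10),
                 "only 3")
  expect_equal(sel, 1:3)
})
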