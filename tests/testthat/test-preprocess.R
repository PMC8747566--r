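sine_recording <- function(freqs, amps = rep(1, length(freqs)), rate = 1000,
                           dur = 10, n_ch = 1) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  x <- Reduce(`+`, Map(function(f, a) a * sin(2 * pi * f * t), freqs, amps))
  mc_recording(matrix(rep(x, each = n_ch), nrow = n_ch), rate)
}

amp_of <- function(rec, ch = 1, trim = 0.2) {
  n <- ncol(rec$data)
  i <- seq(floor(n * trim), ceiling(n * (1 - trim)))
  max(abs(rec$data[ch, i]))
}

test_that("resampling halves the sample count and preserves passband amplitude", {
  rec <- sine_recording(10, rate = 1000, dur = 10)
  out <- resample_recording(rec, 500)
  expect_equal(out$rate, 500)
  expect_equal(ncol(out$data), 5000)
  expect_equal(amp_of(out), 1, tolerance = 0.01)
  expect_identical(resample_recording(rec, 1000), rec)
  expect_error(resample_recording(rec, 2000), "upsampling")
})

test_that("resampling rescales event indices", {
  rec <- sine_recording(5, rate = 1000, dur = 4)
  rec$events <- tibble::tibble(code = "m", sample = c(0L, 1001L, 3999L))
  out <- resample_recording(rec, 500)
  expect_equal(out$events$sample, c(0L, 500L, 1999L))
})

test_that("high-pass removes DC and slow drift but passes 10 Hz", {
  const <- mc_recording(matrix(5, 1, 30000), 500)
  out <- highpass_filter(const, 0.5)
  expect_lt(max(abs(out$data[1, 5000:25000])), 1e-6)

  s10 <- sine_recording(10, rate = 500, dur = 60)
  expect_equal(amp_of(highpass_filter(s10, 0.5)), 1, tolerance = 0.01)

  slow <- sine_recording(0.05, rate = 500, dur = 120)
  atten <- 20 * log10(amp_of(highpass_filter(slow, 0.5)))
  expect_lt(atten, -20)
  expect_error(highpass_filter(s10, 300), "Nyquist")
})

test_that("notch removes 50 Hz and leaves neighbors and 10 Hz intact", {
  s50 <- sine_recording(50, rate = 500, dur = 30)
  expect_lt(amp_of(notch_filter(s50, 50)), 0.1)
  s10 <- sine_recording(10, rate = 500, dur = 30)
  expect_equal(amp_of(notch_filter(s10, 50)), 1, tolerance = 0.01)
  s45 <- sine_recording(45, rate = 500, dur = 30)
  expect_gt(amp_of(notch_filter(s45, 50)), 10^(-1 / 20))  # within 1 dB

  mix <- sine_recording(c(10, 50), rate = 500, dur = 30)
  out <- notch_filter(mix, 50)
  n <- ncol(out$data)
  sp <- Mod(stats::fft(out$data[1, ]))[1:(n / 2)] * 2 / n
  fr <- (seq_len(n / 2) - 1) * 500 / n
  expect_equal(max(sp[abs(fr - 10) < 1]), 1, tolerance = 0.02)
  expect_lt(max(sp[abs(fr - 50) < 1]), 0.05)
})

test_that("common average reference zeroes the instantaneous channel mean", {
  set.seed(1)
  rec <- mc_recording(matrix(rnorm(5 * 1000), 5), 500)
  out <- rereference_car(rec)
  expect_lt(max(abs(colSums(out$data))), 1e-9)
  expect_equal(rereference_car(out)$data, out$data)   # idempotent
  two <- mc_recording(rbind(a = c(1, 2, 3), b = c(3, 2, 1)), 100)
  expect_equal(rereference_car(two)$data,
               rbind(c(-1, 0, 1), c(1, 0, -1)), ignore_attr = TRUE)
  expect_error(rereference_car(mc_recording(matrix(1, 1, 10), 100)),
               ">= 2 channels")
})

test_that("epoching recovers every execution epoch with the right label", {
  sim <- small_session()
  prep <- preprocess_pipeline(sim$eeg, analysis_rate = 125)
  et <- sim$truth$event_table
  ex <- et[et$phase == "execution", ]
  expect_length(prep$epochs, nrow(ex))
  got <- vapply(prep$epochs, function(e) e$task, character(1))
  expect_equal(got, ex$task[order(ex$trial)])
  lens <- vapply(prep$epochs, function(e) ncol(e$data), integer(1))
  expect_equal(lens, as.integer(ex$end - ex$start))
})

test_that("execution epoch length is completion minus onset", {
  rec <- mc_recording(matrix(rnorm(3000), 1), 500,
                      events = tibble::tibble(
                        code = c("fixation:glass", "execution:glass",
                                 "completion:glass"),
                        sample = c(200L, 1000L, 2500L),
                        trial = 1L, task = "glass",
                        phase = c("fixation", "execution", "completion")))
  eps <- epoch_by_events(rec)
  exec <- eps[[which(vapply(eps, function(e) e$phase, "") == "execution")]]
  expect_equal(ncol(exec$data), 1500)
})

test_that("a trial missing its completion marker is skipped with a warning", {
  rec <- mc_recording(matrix(rnorm(4000), 1), 500,
                      events = tibble::tibble(
                        code = c("fixation:glass", "execution:glass",
                                 "fixation:faucet", "execution:faucet",
                                 "completion:faucet"),
                        sample = c(0L, 500L, 1500L, 2000L, 3000L),
                        trial = c(1L, 1L, 2L, 2L, 2L),
                        task = c("glass", "glass", rep("faucet", 3)),
                        phase = c("fixation", "execution",
                                  "fixation", "execution", "completion")))
  expect_warning(eps <- epoch_by_events(rec, phases = "execution"),
                 "missing completion")
  expect_length(eps, 1)
  expect_equal(eps[[1]]$task, "faucet")
  expect_error(epoch_by_events(mc_recording(matrix(0, 1, 10), 100)),
               "empty event table")
})

test_that("baselining removes the per-channel mean", {
  ep <- trial_epoch(rbind(c(1, 2, 3), c(10, 20, 30)), 100, "glass")
  out <- baseline_subtract(ep)
  expect_equal(out$data[1, ], c(-1, 0, 1))
  expect_equal(max(abs(rowMeans(out$data))), 0, tolerance = 1e-12)
  expect_equal(baseline_subtract(out)$data, out$data)
})
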