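sinusoid_rec <- function(freq, fs = 250, dur = 8, amp = 1) {
  t <- seq(1 / fs, dur, by = 1 / fs)
  continuous_recording(matrix(amp * sin(2 * pi * freq * t), 1), fs)
}

# steady-state samples, away from filter edge transients
core <- 500:1500

test_that("band-pass is zero-phase with the expected passband/stopband gains", {
  rec <- sinusoid_rec(10)
  out <- bandpass_filter(rec)
  gain <- stats::sd(out$signals[1, core]) / stats::sd(rec$signals[1, core])
  expect_gt(gain, 0.95)
  expect_lt(gain, 1.05)
  # zero lag: cross-correlation peak at lag 0
  cc <- stats::ccf(out$signals[1, core], rec$signals[1, core],
                   lag.max = 10, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)

  low <- bandpass_filter(sinusoid_rec(1))
  expect_lt(max(abs(low$signals[1, core])), 0.3)

  zero <- bandpass_filter(continuous_recording(matrix(0, 2, 2000), 250))
  expect_true(all(zero$signals == 0))

  expect_error(bandpass_filter(sinusoid_rec(10, fs = 60)), "Nyquist")
})

test_that("notch suppresses 50 Hz by >= 20 dB and passes 10 Hz", {
  r50 <- sinusoid_rec(50)
  out <- notch_filter(r50)
  resid <- stats::sd(out$signals[1, core]) / stats::sd(r50$signals[1, core])
  expect_lt(resid, 0.1)   # >= 20 dB attenuation
  r10 <- sinusoid_rec(10)
  out10 <- notch_filter(r10)
  g10 <- stats::sd(out10$signals[1, core]) / stats::sd(r10$signals[1, core])
  expect_gt(g10, 0.95)
  expect_lt(g10, 1.05)
  zero <- notch_filter(continuous_recording(matrix(0, 1, 2000), 250))
  expect_true(all(zero$signals == 0))
})

test_that("filtering is linear", {
  set.seed(31)
  x <- matrix(rnorm(2000), 1)
  y <- matrix(rnorm(2000), 1)
  a <- 2.5; b <- -1.2
  f <- function(m) bandpass_filter(continuous_recording(m, 250))$signals
  expect_equal(f(a * x + b * y), a * f(x) + b * f(y), tolerance = 1e-9)
})

test_that("resampling preserves length ratio, rate, and spectral content", {
  set.seed(32)
  rec <- continuous_recording(matrix(rnorm(1600), 1), 160,
                              events = data.frame(sample = 800, label = "a"))
  out <- resample_recording(rec, 250)
  expect_identical(ncol(out$signals), 2500L)
  expect_equal(out$rate, 250)
  expect_equal(out$events$sample, 1250)

  same <- resample_recording(rec, 160)
  expect_identical(same$signals, rec$signals)

  t <- seq(1 / 160, 10, by = 1 / 160)
  tone <- continuous_recording(matrix(sin(2 * pi * 8 * t), 1), 160)
  res <- resample_recording(tone, 250)
  n <- ncol(res$signals)
  spec <- abs(stats::fft(res$signals[1, ]))[2:(n %/% 2)]
  peak_hz <- which.max(spec) * 250 / n
  expect_equal(peak_hz, 8, tolerance = 250 / n + 1e-9)
})

test_that("epoching slices cue-locked windows with baseline correction", {
  fs <- 250
  set.seed(33)
  sig <- matrix(rnorm(3 * 20 * fs) + 5, 3, 20 * fs)  # constant offset 5
  events <- data.frame(sample = c(2000, 3000), label = c("a", "b"))
  rec <- continuous_recording(sig, fs, events = events)

  ts1 <- epoch_trials(rec, window_s = c(0, 4), baseline = "whole")
  expect_identical(dim(ts1$trials)[3], 1000L)
  expect_identical(n_trials(ts1), 2L)
  expect_equal(mean(ts1$trials[1, 1, ]), 0, tolerance = 1e-12)

  ts2 <- epoch_trials(rec, window_s = c(-0.5, 4.5))
  expect_identical(dim(ts2$trials)[3], 1250L)
  # pre-cue baseline: the first 125 samples of each channel average zero
  expect_equal(mean(ts2$trials[1, 2, 1:125]), 0, tolerance = 1e-12)

  bad <- data.frame(sample = c(1, 2000), label = c("a", "b"))
  rec2 <- continuous_recording(sig, fs, events = bad)
  expect_warning(ts3 <- epoch_trials(rec2, window_s = c(-0.5, 4.5)),
                 "skipped")
  expect_identical(n_trials(ts3), 1L)
  expect_identical(ts3$n_skipped, 1L)
})

test_that("amplitude rejection uses a strict threshold boundary", {
  arr <- array(0, dim = c(3, 2, 50))
  arr[1, 1, 10] <- 99.9
  arr[2, 2, 20] <- -100.1
  arr[3, 1, 30] <- 100            # exactly at threshold: kept
  ts <- trial_set(arr, c("a", "b", "a"), rep("S01", 3), 250,
                  classes = c("a", "b"))
  out <- reject_amplitude(ts, 100)
  expect_identical(out$rejected, 2L)
  expect_identical(n_trials(out$trials), 2L)

  # planted outliers are exactly the rejected set
  set.seed(34)
  arr2 <- array(rnorm(10 * 2 * 50), dim = c(10, 2, 50))
  hot <- c(2L, 5L, 9L)
  for (i in hot) arr2[i, 1, 25] <- 150
  ts2 <- trial_set(arr2, rep("a", 10), rep("S01", 10), 250, classes = "a")
  out2 <- reject_amplitude(ts2, 100)
  expect_identical(out2$rejected, hot)
})

test_that("joint-probability rejection flags planted outliers, spares iid data", {
  set.seed(35)
  arr <- array(rnorm(50 * 4 * 100), dim = c(50, 4, 100))
  arr[17, , ] <- 10 * arr[17, , ]          # 10x amplitude outlier
  ts <- trial_set(arr, rep("a", 50), rep("S01", 50), 250, classes = "a")
  out <- reject_joint_probability(ts, 3)
  expect_true(17L %in% out$rejected)

  # iid normal trials: expected rejection fraction small
  fracs <- vapply(1:5, function(s) {
    set.seed(100 + s)
    a <- array(rnorm(60 * 4 * 100), dim = c(60, 4, 100))
    t2 <- trial_set(a, rep("a", 60), rep("S01", 60), 250, classes = "a")
    length(reject_joint_probability(t2, 3)$rejected) / 60
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)

  expect_identical(reject_joint_probability(ts, Inf)$rejected, integer(0))
  small <- subset_trials(ts, 1:4)
  expect_error(reject_joint_probability(small, 3), "at least 5")
})

test_that("z-scoring normalizes per channel and is idempotent", {
  ts <- random_trial_set(n = 6, C = 3, T = 200, seed = 36)
  z1 <- zscore_trials(ts)
  for (i in 1:6) {
    expect_equal(rowMeans(z1$trials[i, , ]), rep(0, 3), tolerance = 1e-9)
    expect_equal(apply(z1$trials[i, , ], 1, function(x) sqrt(mean(x^2))),
                 rep(1, 3), tolerance = 1e-9)
  }
  z2 <- zscore_trials(z1)
  expect_equal(z2$trials, z1$trials, tolerance = 1e-12)

  flat <- ts
  flat$trials[2, 1, ] <- 7
  expect_error(zscore_trials(flat), "zero-variance channel 1 in trial 2")
})

test_that("channel selection respects order and reports unknown names", {
  set.seed(37)
  rec <- continuous_recording(matrix(rnorm(4 * 100), 4), 250,
                              channel_names = c("C3", "Cz", "C4", "Fz"))
  sel <- select_channels(rec, c("C4", "C3"))
  expect_identical(sel$channel_names, c("C4", "C3"))
  expect_equal(sel$signals[1, ], rec$signals[3, ])
  ident <- select_channels(rec, rec$channel_names)
  expect_identical(ident$signals, rec$signals)
  expect_error(select_channels(rec, c("C3", "Pz")), "Pz")

  ts <- fixture_dataset()
  sub <- select_channels(ts, c("C3", "C4"))
  expect_identical(dim(sub$trials)[2], 2L)
})

test_that("preprocessing never mutates its input and logs provenance", {
  rec <- sinusoid_rec(10)
  before <- rec$signals
  out <- bandpass_filter(rec)
  expect_identical(rec$signals, before)
  expect_match(out$provenance[1], "bandpass")
  out2 <- notch_filter(out)
  expect_length(out2$provenance, 2)
})
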