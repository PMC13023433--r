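test_that("dataset generation is balanced, labeled, and bit-reproducible", {
  cfg <- sim_config(n_subjects = 2, trials_per_class = 5, master_seed = 55)
  ds1 <- generate_dataset(cfg)
  expect_identical(n_trials(ds1), 2L * 5L * 4L)
  expect_true(all(table(ds1$labels) == 10))
  expect_true(all(table(ds1$subject_ids) == 20))
  expect_identical(dim(ds1$trials)[2:3], c(22L, 1000L))
  expect_equal(ds1$rate, 250)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$trials, ds2$trials)
  expect_identical(ds1$labels, ds2$labels)
})

test_that("subject models are deterministic, distinct, and contralateral", {
  cfg <- sim_config(master_seed = 9)
  m1 <- generate_subject_model(cfg, 1)
  m1b <- generate_subject_model(cfg, 1)
  expect_identical(m1$topographies, m1b$topographies)
  expect_identical(m1$gain, m1b$gain)

  # topographies differ across subjects by more than jitter tolerance
  topo_dist <- vapply(2:10, function(i) {
    mi <- generate_subject_model(cfg, i)
    max(abs(mi$topographies$left_central - m1$topographies$left_central))
  }, numeric(1))
  expect_gt(mean(topo_dist > 1e-3), 0.8)

  # fixed class -> source assignment: imagery attenuates the contralateral
  # (or midline/fronto-central) source
  expect_gt(m1$erd["left_hand", "right_central"], 0)
  expect_gt(m1$erd["right_hand", "left_central"], 0)
  expect_gt(m1$erd["feet", "midline_central"], 0)
  expect_gt(m1$erd["tongue", "fronto_central"], 0)
  expect_equal(sum(m1$erd > 0), 4)

  m0 <- generate_subject_model(sim_config(erd_depth = 0, master_seed = 9), 1)
  expect_true(all(m0$erd == 0))
})

test_that("post-cue mu power drops at the targeted channels, and only then", {
  cfg <- sim_config(erd_depth = 0.4, master_seed = 13)
  model <- generate_subject_model(cfg, 1)
  mont <- mi_montage()
  ratio_for <- function(model, n = 25) {
    trials <- lapply(seq_len(n), function(r)
      simulate_trial(model, "left_hand", derive_seed(13, "erd", r)))
    arr <- array(0, c(n, 22, 1000))
    for (r in seq_len(n)) arr[r, , ] <- trials[[r]]
    ts <- trial_set(arr, rep("left_hand", n), rep("S01", n), 250,
                    window = c(-0.5, 3.5),
                    channel_names = mont$channels)
    erd_ratio(ts, mont$groups$right_central, band = model$mu_band)
  }
  r_erd <- ratio_for(model)
  expect_lt(r_erd, 0.95)
  model0 <- generate_subject_model(sim_config(erd_depth = 0,
                                              master_seed = 13), 1)
  r_flat <- ratio_for(model0)
  expect_equal(r_flat, 1, tolerance = 0.15)
  expect_lt(r_erd, r_flat)

  # identical seed -> identical trial; different seed -> different noise
  a <- simulate_trial(model, "feet", 77)
  b <- simulate_trial(model, "feet", 77)
  c <- simulate_trial(model, "feet", 78)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_error(simulate_trial(model, "rest", 1), "unknown class")
})

test_that("background noise follows the configured 1/f spectrum", {
  set.seed(61)
  n <- 5000
  slopes <- vapply(1:5, function(i) {
    x <- midecode:::pink_noise(n, 1.0)
    P <- abs(stats::fft(x))[2:(n %/% 2 + 1)]^2
    f <- seq_len(n %/% 2) * 250 / n
    sel <- f >= 1 & f <= 40
    unname(stats::coef(stats::lm(log(P[sel]) ~ log(f[sel])))[2])
  }, numeric(1))
  expect_equal(mean(slopes), -1, tolerance = 0.2)
})

test_that("class separability grows with ERD depth for a linear baseline", {
  skip_if_not_installed("MASS")
  acc_at <- function(erd) {
    cfg <- sim_config(n_subjects = 1, trials_per_class = 20,
                      erd_depth = erd, master_seed = 73)
    ds <- generate_dataset(cfg)
    X <- bandpower_features(ds, window_idx = 126:1000)
    y <- ds$labels
    set.seed(1)
    tr <- unlist(lapply(levels(y), function(cl) sample(which(y == cl), 10)))
    te <- setdiff(seq_along(y), tr)
    fit <- suppressWarnings(MASS::lda(X[tr, ], grouping = y[tr]))
    mean(stats::predict(fit, X[te, ])$class == y[te])
  }
  a0 <- acc_at(0)
  a4 <- acc_at(0.4)
  a6 <- acc_at(0.6)
  expect_lt(a0, 0.45)          # near chance without ERD
  expect_gt(a4, 0.40)          # clearly above 25% chance
  expect_gte(a6, a4 - 0.05)    # non-decreasing within tolerance
})

test_that("meta-task construction counts, separates, and validates support", {
  cfg <- sim_config(n_subjects = 2, trials_per_class = 15, master_seed = 81)
  ds <- generate_dataset(cfg)
  tasks <- make_meta_tasks(ds, k_shot = 10, seed = 3)
  expect_length(tasks, 2)
  for (tk in tasks) {
    expect_identical(n_trials(tk$support), 40L)
    expect_identical(n_trials(tk$query), 20L)
    expect_true(all(table(tk$support$labels) == 10))
    # support and query are disjoint: joint fingerprints never collide
    fp <- function(ts) apply(ts$trials[, 1, 1:10, drop = FALSE], 1, paste,
                             collapse = ",")
    expect_length(intersect(fp(tk$support), fp(tk$query)), 0)
  }
  expect_error(make_meta_tasks(ds, k_shot = 15), "need > 15")
  ok <- make_meta_tasks(ds, k_shot = 14)
  expect_identical(n_trials(ok[[1]]$query), 4L)
})

test_that("trial-set serialization round-trips", {
  ds <- subset_trials(fixture_dataset(), 1:6)
  path <- file.path(tempdir(), "ts_roundtrip")
  write_trial_set(ds, path)
  back <- read_trial_set(path)
  expect_equal(back$trials, ds$trials)
  expect_identical(as.character(back$labels), as.character(ds$labels))
  expect_identical(levels(back$labels), levels(ds$labels))
  expect_identical(back$subject_ids, ds$subject_ids)
  expect_equal(back$rate, ds$rate)
})
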