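# Shared fixtures, generated in code and memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

memoise_fixture <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# A configuration small enough for finite-difference checks.
tiny_model_config <- function(...) {
  args <- list(...)
  defaults <- list(n_channels = 3L, n_samples = 48L,
                   conv_out_channels = c(2L, 3L, 3L, 4L), conv_kernel = 3L,
                   conv_dropout = 0, lstm_hidden = 3L, lstm_dropout = 0,
                   patch_size = 2L, stride = 1L, embed_dim = 4L,
                   tf_layers = 1L, n_heads = 2L, ff_dim = 6L,
                   tf_dropout = 0, n_classes = 3L)
  do.call(model_config, utils::modifyList(defaults, args))
}

# Small two-subject dataset (8 trials per class) for pipeline tests.
fixture_dataset <- function() {
  memoise_fixture("ds_2x8", function() {
    generate_dataset(sim_config(n_subjects = 2L, trials_per_class = 8L,
                                erd_depth = 0.5, master_seed = 101L))
  })
}

# Random trial_set with gaussian samples (no structure).
random_trial_set <- function(n = 10, C = 4, T = 100, seed = 1,
                             classes = c("a", "b")) {
  set.seed(seed)
  arr <- array(rnorm(n * C * T), dim = c(n, C, T))
  trial_set(arr, rep(classes, length.out = n),
            rep("S01", n), rate = 250, classes = classes)
}

expect_same_params <- function(a, b, tol = 0) {
  expect_equal(flatten_params(a), flatten_params(b), tolerance = tol)
}
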