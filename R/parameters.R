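#' Component-wise trainable-parameter accounting
#'
#' Closed-form counts of every trainable scalar in the network, grouped by
#' stage. Conventions: each conv block has a kernel (in x out x k), a bias per
#' output channel, and batch-norm scale + shift; each LSTM gate block carries
#' TWO bias vectors (input-side and hidden-side) per direction per layer; the
#' tokenizer is an affine projection plus one layer normalization (sinusoidal
#' positional encodings are non-learned and contribute nothing); each
#' Transformer layer has query/key/value/output projections with biases, a
#' two-layer feed-forward, and two layer norms, with one extra final norm; the
#' head is two affine maps d -> d -> n_classes.
#'
#' Under the default configuration the five components count
#' 137,696 / 659,456 / 786,816 / 265,216 / 17,028 (total 1,866,212).
#'
#' @param config A [model_config()].
#' @return An object of class \code{parameter_breakdown}: a list with fields
#'   \code{spatial_spectral}, \code{temporal_encoder}, \code{patch_embedding},
#'   \code{transformer_encoder}, \code{classification_head}, \code{total}.
#' @export
count_parameters <- function(config = model_config()) {
  k <- config$conv_kernel
  widths <- c(config$n_channels, config$conv_out_channels)
  spatial <- 0
  for (b in seq_along(config$conv_out_channels)) {
    cin <- widths[b]; cout <- widths[b + 1L]
    spatial <- spatial + (cin * cout * k + cout) + 2 * cout
  }

  dh <- config$lstm_hidden
  temporal <- 0
  for (l in seq_len(config$lstm_layers)) {
    din <- if (l == 1L) utils::tail(config$conv_out_channels, 1L) else 2L * dh
    per_dir <- 4 * dh * din + 4 * dh * dh + 2 * (4 * dh)
    temporal <- temporal + 2 * per_dir
  }

  d <- config$embed_dim
  patch <- config$patch_size * 2 * dh * d + d + 2 * d

  ff <- config$ff_dim
  per_layer <- 4 * (d * d + d) + (d * ff + ff) + (ff * d + d) + 2 * (2 * d)
  transformer <- config$tf_layers * per_layer + 2 * d

  head <- (d * d + d) + (d * config$n_classes + config$n_classes)

  out <- list(
    spatial_spectral = spatial,
    temporal_encoder = temporal,
    patch_embedding = patch,
    transformer_encoder = transformer,
    classification_head = head,
    total = spatial + temporal + patch + transformer + head
  )
  class(out) <- "parameter_breakdown"
  out
}

#' @export
print.parameter_breakdown <- function(x, ...) {
  comp <- c("Patch Embedding" = x$patch_embedding,
            "Temporal Encoder (BiLSTM)" = x$temporal_encoder,
            "Transformer Encoder" = x$transformer_encoder,
            "Spatial-Spectral Encoder" = x$spatial_spectral,
            "Classification Head" = x$classification_head)
  cat("Component-wise parameter breakdown\n")
  for (nm in names(comp)) {
    cat(sprintf("  %-28s %12s  %5.1f%%\n", nm,
                format(comp[[nm]], big.mark = ","),
                100 * comp[[nm]] / x$total))
  }
  cat(sprintf("  %-28s %12s  100.0%%\n", "Total",
              format(x$total, big.mark = ",")))
  invisible(x)
}

#' Multiply-accumulate (MAC) accounting per component
#'
#' Deterministic per-trial MAC totals counting multiplies only: convolution
#' kernels, recurrent gate products, the tokenizer projection, attention
#' projections plus score/apply products, feed-forward maps, and the head.
#' Normalizations, activations, and softmax are not counted. Used as the
#' hardware-independent latency surrogate for architecture search.
#'
#' @param config A [model_config()].
#' @return A list of per-component MAC counts and \code{total}.
#' @export
estimate_macs <- function(config = model_config()) {
  k <- config$conv_kernel
  widths <- c(config$n_channels, config$conv_out_channels)
  len <- config$n_samples
  conv <- 0
  for (b in seq_along(config$conv_out_channels)) {
    conv <- conv + widths[b] * widths[b + 1L] * k * len
    len <- len %/% config$pool_size
  }
  tprime <- len

  dh <- config$lstm_hidden
  lstm <- 0
  for (l in seq_len(config$lstm_layers)) {
    din <- if (l == 1L) utils::tail(config$conv_out_channels, 1L) else 2L * dh
    lstm <- lstm + 2 * tprime * 4 * dh * (din + dh)
  }

  d <- config$embed_dim
  N <- n_patches(tprime, config)
  tokenizer <- N * config$patch_size * 2 * dh * d

  ff <- config$ff_dim
  per_layer <- 4 * N * d * d + 2 * N * N * d + N * (d * ff + ff * d)
  transformer <- config$tf_layers * per_layer

  head <- d * d + d * config$n_classes

  list(conv = conv, lstm = lstm, tokenizer = tokenizer,
       transformer = transformer, head = head,
       total = conv + lstm + tokenizer + transformer + head)
}

# Glorot-uniform matrix.
glorot <- function(nrow, ncol, fan_in = ncol, fan_out = nrow) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialize model parameters
#'
#' Draws a fresh trainable-parameter set for a configuration. Weight matrices
#' use Glorot-uniform initialization; LSTM weights use the conventional
#' uniform(-1/sqrt(dh), 1/sqrt(dh)) with forget-gate biases at 1; norms start
#' at scale 1, shift 0. Deterministic in \code{seed}. Batch normalization uses
#' batch statistics at every forward pass, so no running-moment buffers exist.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return A nested list of arrays (class \code{model_parameters}) whose
#'   top-level components mirror [count_parameters()].
#' @export
init_model_parameters <- function(config = model_config(), seed = 1L) {
  with_seed(seed, {
    k <- config$conv_kernel
    widths <- c(config$n_channels, config$conv_out_channels)
    conv <- lapply(seq_along(config$conv_out_channels), function(b) {
      cin <- widths[b]; cout <- widths[b + 1L]
      W <- array(stats::runif(cout * cin * k, -1, 1) *
                   sqrt(6 / (cin * k + cout * k)), dim = c(cout, cin, k))
      list(W = W, b = numeric(cout),
           gamma = rep(1, cout), beta = numeric(cout))
    })

    dh <- config$lstm_hidden
    lim <- 1 / sqrt(dh)
    lstm <- lapply(seq_len(config$lstm_layers), function(l) {
      din <- if (l == 1L) utils::tail(config$conv_out_channels, 1L) else 2L * dh
      lapply(1:2, function(dir) {
        bi <- numeric(4 * dh); bh <- numeric(4 * dh)
        bi[(dh + 1L):(2L * dh)] <- 1  # forget-gate bias
        list(
          Wi = matrix(stats::runif(4 * dh * din, -lim, lim), 4 * dh, din),
          Wh = matrix(stats::runif(4 * dh * dh, -lim, lim), 4 * dh, dh),
          bi = bi, bh = bh
        )
      })
    })

    d <- config$embed_dim
    pin <- config$patch_size * 2L * dh
    tok <- list(We = glorot(pin, d, fan_in = pin, fan_out = d),
                be = numeric(d), ln_g = rep(1, d), ln_b = numeric(d))

    ff <- config$ff_dim
    tf <- lapply(seq_len(config$tf_layers), function(l) {
      list(Wq = glorot(d, d), bq = numeric(d),
           Wk = glorot(d, d), bk = numeric(d),
           Wv = glorot(d, d), bv = numeric(d),
           Wo = glorot(d, d), bo = numeric(d),
           W1 = glorot(ff, d, fan_in = d, fan_out = ff), b1 = numeric(ff),
           W2 = glorot(d, ff, fan_in = ff, fan_out = d), b2 = numeric(d),
           ln1_g = rep(1, d), ln1_b = numeric(d),
           ln2_g = rep(1, d), ln2_b = numeric(d))
    })
    ln_f <- list(g = rep(1, d), b = numeric(d))

    head <- list(W1 = glorot(d, d), b1 = numeric(d),
                 W2 = glorot(config$n_classes, d, fan_in = d,
                             fan_out = config$n_classes),
                 b2 = numeric(config$n_classes))

    params <- list(conv = conv, lstm = lstm, tok = tok, tf = tf,
                   ln_f = ln_f, head = head)
    class(params) <- c("model_parameters", "list")
    # non-trainable running moments for the conv-block normalizations ride
    # along as an attribute (excluded from flatten_params/optimizer)
    attr(params, "bn_state") <- bn_state_init(config)
    params
  })
}
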