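#' Architectural configuration of the three-stage decoder
#'
#' Collects every architectural hyperparameter of the hierarchical network:
#' a four-block 1-D convolutional spatial-spectral encoder, a two-layer
#' bidirectional LSTM temporal encoder, an overlapping-patch tokenizer, and a
#' lightweight Transformer encoder with a two-layer classification head.
#' Defaults correspond to the reference architecture for 22-channel,
#' 4-s motor-imagery trials sampled at 250 Hz.
#'
#' Temporal resolution is reduced only by the max-pooling stage of each
#' convolutional block (stride-1, length-preserving convolutions), so the
#' encoder output length is \code{T} floor-divided by \code{pool_size} once per
#' block; see [derive_temporal_length()].
#'
#' @param n_channels Number of EEG channels C (default 22).
#' @param n_samples Trial length T in samples (default 1000 = 4 s at 250 Hz).
#' @param conv_out_channels Output widths of the four conv blocks.
#' @param conv_kernel Convolution kernel length (default 5, i.e. 20 ms).
#' @param pool_size Max-pool width per block (default 2).
#' @param conv_dropout Dropout after each conv block (default 0.25).
#' @param lstm_hidden Hidden units per LSTM direction, dh (default 128).
#' @param lstm_layers Number of stacked BiLSTM layers (default 2).
#' @param lstm_dropout Dropout between LSTM layers (default 0.3).
#' @param patch_size Patch length p in encoder time steps (default 24).
#' @param stride Patch stride s (default 12; s <= p gives overlap).
#' @param embed_dim Token embedding dimension d (default 128).
#' @param tf_layers Number of Transformer encoder layers L (default 2).
#' @param n_heads Attention heads h (default 4); must divide \code{embed_dim}.
#' @param ff_dim Feed-forward width (default 2 * embed_dim).
#' @param tf_dropout Dropout inside attention/feed-forward (default 0.1).
#' @param n_classes Number of output classes (default 4).
#' @param head_activation Nonlinearity between the two head layers
#'   (\code{"gelu"} or \code{"identity"}; parameter counts are unaffected).
#' @return An object of class \code{model_config}.
#' @export
model_config <- function(n_channels = 22L,
                         n_samples = 1000L,
                         conv_out_channels = c(32L, 64L, 128L, 128L),
                         conv_kernel = 5L,
                         pool_size = 2L,
                         conv_dropout = 0.25,
                         lstm_hidden = 128L,
                         lstm_layers = 2L,
                         lstm_dropout = 0.3,
                         patch_size = 24L,
                         stride = 12L,
                         embed_dim = 128L,
                         tf_layers = 2L,
                         n_heads = 4L,
                         ff_dim = 2L * embed_dim,
                         tf_dropout = 0.1,
                         n_classes = 4L,
                         head_activation = "gelu") {
  cfg <- list(
    n_channels = as.integer(n_channels),
    n_samples = as.integer(n_samples),
    conv_out_channels = as.integer(conv_out_channels),
    conv_kernel = as.integer(conv_kernel),
    pool_size = as.integer(pool_size),
    conv_dropout = conv_dropout,
    lstm_hidden = as.integer(lstm_hidden),
    lstm_layers = as.integer(lstm_layers),
    lstm_dropout = lstm_dropout,
    patch_size = as.integer(patch_size),
    stride = as.integer(stride),
    embed_dim = as.integer(embed_dim),
    tf_layers = as.integer(tf_layers),
    n_heads = as.integer(n_heads),
    ff_dim = as.integer(ff_dim),
    tf_dropout = tf_dropout,
    n_classes = as.integer(n_classes),
    head_activation = match.arg(head_activation, c("gelu", "identity"))
  )
  class(cfg) <- "model_config"
  validate_model_config(cfg)
  cfg
}

validate_model_config <- function(cfg) {
  counts <- c(cfg$n_channels, cfg$n_samples, cfg$conv_out_channels,
              cfg$conv_kernel, cfg$pool_size, cfg$lstm_hidden,
              cfg$lstm_layers, cfg$patch_size, cfg$stride, cfg$embed_dim,
              cfg$tf_layers, cfg$n_heads, cfg$ff_dim, cfg$n_classes)
  if (any(counts < 1L)) stop("all count-valued fields must be >= 1")
  drops <- c(cfg$conv_dropout, cfg$lstm_dropout, cfg$tf_dropout)
  if (any(drops < 0 | drops >= 1)) stop("dropout fractions must lie in [0, 1)")
  if (cfg$embed_dim %% cfg$n_heads != 0L)
    stop("embed_dim must be divisible by n_heads")
  if (cfg$stride > cfg$patch_size)
    stop("stride must satisfy 1 <= stride <= patch_size")
  if (length(cfg$conv_out_channels) != 4L)
    stop("conv_out_channels must list four block widths")
  tprime <- derive_temporal_length(cfg$n_samples, cfg)
  if (cfg$patch_size > tprime)
    stop(sprintf("patch_size (%d) exceeds derived temporal length T' = %d",
                 cfg$patch_size, tprime))
  invisible(cfg)
}

#' Temporal length after the convolutional encoder
#'
#' The four convolutional blocks preserve length (stride-1, half-kernel
#' padding); each block's max-pool floor-divides the length by
#' \code{pool_size}. For the defaults (T = 1000, pool 2) this gives
#' floor(floor(floor(floor(1000/2)/2)/2)/2) = 62.
#'
#' @param T Input length in samples.
#' @param config A [model_config()].
#' @return Integer length T' of the encoder output.
#' @export
derive_temporal_length <- function(T, config = model_config()) {
  if (T < config$conv_kernel)
    stop("input length is shorter than the convolution kernel")
  len <- as.integer(T)
  for (b in seq_along(config$conv_out_channels)) {
    len <- len %/% config$pool_size
  }
  if (len < 1L)
    stop(sprintf("temporal length collapses to %d after pooling; %s", len,
                 "the configuration is invalid for this input length"))
  len
}

#' Number of overlapping patches
#'
#' N = floor((T' - p) / s) + 1 sliding windows of length p and stride s
#' over a sequence of length T'.
#'
#' @param tprime Encoder output length T'.
#' @param config A [model_config()] supplying \code{patch_size}, \code{stride}.
#' @return Integer patch count N.
#' @export
n_patches <- function(tprime, config = model_config()) {
  if (config$patch_size > tprime)
    stop(sprintf("patch_size (%d) exceeds sequence length (%d)",
                 config$patch_size, tprime))
  as.integer((tprime - config$patch_size) %/% config$stride + 1L)
}

#' Compact architecture for CPU-scale experiments
#'
#' The reference architecture scaled down (8/12/16/16 conv widths, 16 hidden
#' units per LSTM direction, 32-dimensional embeddings, one Transformer
#' layer with two heads) — about 49k parameters instead of 1.87M, with
#' dropout halved to match the reduced capacity. Retains every structural
#' element of the full model; intended for desk-scale protocol runs,
#' meta-learning fixtures, and examples on a single CPU.
#'
#' @param ... Overrides passed to [model_config()].
#' @return A [model_config()].
#' @export
compact_model_config <- function(...) {
  args <- list(...)
  defaults <- list(conv_out_channels = c(8L, 12L, 16L, 16L),
                   lstm_hidden = 16L, embed_dim = 32L, tf_layers = 1L,
                   n_heads = 2L, ff_dim = 64L,
                   conv_dropout = 0.125, lstm_dropout = 0.15,
                   tf_dropout = 0.05)
  do.call(model_config, utils::modifyList(defaults, args))
}

#' Training regimen for CPU-scale experiments
#'
#' The reference regimen rescaled for the compact architecture and small
#' synthetic cohorts: learning rate 3e-3 with a 3-epoch warm-up, batch
#' size 4, a fixed 30-epoch budget (early stopping disabled — at a few
#' dozen training trials the validation loss is too noisy to stop on),
#' best-validation checkpointing as usual, and training-time augmentation
#' (additive Gaussian noise, SD 0.2 of the standardized signal, plus
#' circular time shifts up to 50 samples = 0.2 s), the standard small-cohort
#' remedies in EEG decoding.
#'
#' @param ... Overrides passed to [train_config()].
#' @return A [train_config()].
#' @export
compact_train_config <- function(...) {
  args <- list(...)
  defaults <- list(lr = 3e-3, warmup_epochs = 3L, batch_size = 4L,
                   max_epochs = 30L, early_stop_patience = 30L,
                   augment_noise_sd = 0.2, augment_shift_max = 50L)
  merged <- utils::modifyList(defaults, args)
  # keep "no early stopping" semantics when the epoch budget is overridden
  if (!("early_stop_patience" %in% names(args)))
    merged$early_stop_patience <- merged$max_epochs
  do.call(train_config, merged)
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat(sprintf("  input: %d channels x %d samples\n", x$n_channels, x$n_samples))
  cat(sprintf("  conv blocks: %s (kernel %d, pool %d, dropout %.2f)\n",
              paste(x$conv_out_channels, collapse = "-"),
              x$conv_kernel, x$pool_size, x$conv_dropout))
  cat(sprintf("  BiLSTM: %d layers x %d hidden/direction (dropout %.2f)\n",
              x$lstm_layers, x$lstm_hidden, x$lstm_dropout))
  cat(sprintf("  patches: p = %d, s = %d -> N = %d tokens of dim %d\n",
              x$patch_size, x$stride,
              n_patches(derive_temporal_length(x$n_samples, x), x),
              x$embed_dim))
  cat(sprintf("  Transformer: %d layers, %d heads, ff %d (dropout %.2f)\n",
              x$tf_layers, x$n_heads, x$ff_dim, x$tf_dropout))
  cat(sprintf("  head: %d -> %d -> %d classes (%s)\n",
              x$embed_dim, x$embed_dim, x$n_classes, x$head_activation))
  invisible(x)
}
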