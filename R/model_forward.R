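# Full-network forward pass and exact reverse-mode gradients, plus the public
# stage-by-stage operations for inspection and testing.

# X: array (C, T, B). Returns logits and (optionally) all stage caches.
network_forward <- function(params, X, config, training = FALSE,
                            return_cache = FALSE) {
  enc <- conv_encoder_forward(X, params$conv, config, training,
                              bn_state = attr(params, "bn_state"))
  rnn <- bilstm_forward(enc$out, params$lstm, config, training)
  tk <- tokenizer_forward(rnn$out, params$tok, config)
  tf <- transformer_forward(tk$out, params$tf, params$ln_f, config, training)
  hd <- head_forward(tf$out, params$head, config)
  out <- list(logits = hd$out, pooled = tf$out, attention = tf$attention,
              bn_state = enc$bn_state)
  if (return_cache) {
    out$cache <- list(enc = enc$caches, rnn = rnn$caches, tok = tk$cache,
                      tf = tf$caches, head = hd$cache)
  }
  out
}

# Cross-entropy loss (mean over the batch) and full parameter gradient.
# y: integer class indices in 1..n_classes. Returns loss, gradient (same
# nested structure as params), probabilities, and accuracy on the batch.
network_loss_grad <- function(params, X, y, config, training = TRUE,
                              compute_grad = TRUE) {
  B <- dim(X)[3]
  fw <- network_forward(params, X, config, training, return_cache = compute_grad)
  P <- softmax_cols(fw$logits)
  eps <- 1e-12
  picked <- P[cbind(y, seq_len(B))]
  loss <- -mean(log(picked + eps))
  acc <- mean(max.col(t(fw$logits)) == y)
  if (!compute_grad)
    return(list(loss = loss, acc = acc, probs = P, bn_state = fw$bn_state))

  dLogits <- P
  dLogits[cbind(y, seq_len(B))] <- dLogits[cbind(y, seq_len(B))] - 1
  dLogits <- dLogits / B

  hb <- head_backward(dLogits, fw$cache$head, config)
  tb <- transformer_backward(hb$dE, fw$cache$tf, config)
  kb <- tokenizer_backward(tb$dZ, fw$cache$tok, config)
  rb <- bilstm_backward(kb$dH, fw$cache$rnn, config)
  cb <- conv_encoder_backward(rb$dX, fw$cache$enc)

  grad <- list(conv = cb$grads, lstm = rb$grads, tok = kb$grads,
               tf = tb$grads, ln_f = tb$ln_f, head = hb$grads)
  list(loss = loss, grad = grad, acc = acc, probs = P,
       bn_state = fw$bn_state)
}

# ---- public stage operations ------------------------------------------------

#' Spatial-spectral convolutional encoding of one trial
#'
#' Applies the four conv + batch-norm + ReLU + max-pool blocks to a single
#' trial, producing the feature map consumed by the temporal encoder.
#'
#' @param X Numeric matrix, channels x samples.
#' @param params Model parameters from [init_model_parameters()].
#' @param config The matching [model_config()].
#' @return A D x T' feature matrix (class \code{feature_map}) with the
#'   configuration attached as an attribute.
#' @export
encode_spatial_spectral <- function(X, params, config = model_config()) {
  if (!is.matrix(X) || nrow(X) != config$n_channels ||
      ncol(X) != config$n_samples)
    stop(sprintf("trial must be a %d x %d matrix, got %d x %d",
                 config$n_channels, config$n_samples, nrow(X), ncol(X)))
  enc <- conv_encoder_forward(array(X, dim = c(dim(X), 1L)), params$conv,
                              config, training = FALSE,
                              bn_state = attr(params, "bn_state"))
  out <- matrix(enc$out, nrow = dim(enc$out)[1])
  structure(out, class = c("feature_map", "matrix"), config = config)
}

#' Bidirectional temporal encoding of a feature map
#'
#' Runs the stacked BiLSTM over the encoder feature map. Each output row at
#' time t is the concatenation [forward state; backward state].
#'
#' @param F A D x T' feature matrix (e.g. from [encode_spatial_spectral()]).
#' @param params Model parameters.
#' @param config The matching [model_config()].
#' @return A T' x 2*lstm_hidden matrix (class \code{temporal_sequence}).
#' @export
encode_temporal <- function(F, params, config = model_config()) {
  Fa <- array(as.matrix(F), dim = c(nrow(F), ncol(F), 1L))
  rnn <- bilstm_forward(Fa, params$lstm, config, training = FALSE)
  out <- t(matrix(rnn$out, nrow = dim(rnn$out)[1]))
  structure(out, class = c("temporal_sequence", "matrix"), config = config)
}

#' Overlapping-patch tokenization
#'
#' Segments the temporal sequence into N = floor((T' - p)/s) + 1 overlapping
#' patches, flattens each patch time-major, projects it affinely to the
#' embedding dimension, layer-normalizes, and adds deterministic sinusoidal
#' positional encodings.
#'
#' @param H A T' x 2*lstm_hidden matrix (e.g. from [encode_temporal()]).
#' @param config The matching [model_config()].
#' @param params Model parameters.
#' @return An object of class \code{token_sequence}: list with \code{tokens}
#'   (N x d, positional encodings added) and \code{positional} (N x d).
#' @export
tokenize_patches <- function(H, config = model_config(), params) {
  Ha <- array(t(as.matrix(H)), dim = c(ncol(H), nrow(H), 1L))
  tk <- tokenizer_forward(Ha, params$tok, config)
  structure(list(tokens = t(matrix(tk$out, nrow = config$embed_dim)),
                 positional = t(tk$positional)),
            class = "token_sequence", config = config)
}

#' Transformer encoding and pooled embedding
#'
#' Passes a token sequence through the L encoder layers (multi-head
#' self-attention with scale 1/sqrt(d_k), GELU feed-forward, residual
#' connections, post-layer normalization), applies the final normalization,
#' and mean-pools across tokens.
#'
#' @param Z A \code{token_sequence} or an N x d token matrix (positional
#'   encodings already added).
#' @param params Model parameters.
#' @param config The matching [model_config()].
#' @return Numeric vector of length d (the pooled embedding) with the
#'   per-layer attention weight matrices attached as attribute
#'   \code{"attention"} (one list per layer, one N x N matrix per head).
#' @export
apply_transformer <- function(Z, params, config = model_config()) {
  Zm <- if (inherits(Z, "token_sequence")) Z$tokens else as.matrix(Z)
  Za <- array(t(Zm), dim = c(ncol(Zm), nrow(Zm), 1L))
  tf <- transformer_forward(Za, params$tf, params$ln_f, config,
                            training = FALSE)
  structure(as.vector(tf$out),
            attention = lapply(tf$attention, function(layer) layer[[1]]))
}

#' Full forward pass: trial to class posterior
#'
#' Composes the four stages and the two-layer classification head, then
#' applies softmax. Bit-identical to chaining [encode_spatial_spectral()],
#' [encode_temporal()], [tokenize_patches()], [apply_transformer()] and the
#' head by hand.
#'
#' @param X Numeric matrix, channels x samples.
#' @param params Model parameters.
#' @param config The matching [model_config()].
#' @return An object of class \code{class_posterior}: numeric probability
#'   vector of length \code{n_classes} (sums to 1), with logits attached as
#'   attribute \code{"logits"}.
#' @export
forward_pass <- function(X, params, config = model_config()) {
  F <- encode_spatial_spectral(X, params, config)
  H <- encode_temporal(F, params, config)
  Z <- tokenize_patches(H, config, params)
  e <- apply_transformer(Z, params, config)
  hd <- head_forward(matrix(e, ncol = 1), params$head, config)
  logits <- as.vector(hd$out)
  p <- as.vector(softmax_cols(matrix(logits, ncol = 1)))
  structure(p, class = "class_posterior", logits = logits)
}

#' Predict class posteriors for a batch of trials
#'
#' @param trials Array n_trials x channels x samples, or a \code{trial_set}.
#' @param params Model parameters.
#' @param config The matching [model_config()].
#' @return Matrix n_trials x n_classes of posterior probabilities.
#' @export
predict_trials <- function(trials, params, config = model_config()) {
  if (inherits(trials, "trial_set")) trials <- trials$trials
  n <- dim(trials)[1]
  X <- aperm(trials, c(2, 3, 1))
  fw <- network_forward(params, X, config, training = FALSE)
  t(softmax_cols(fw$logits))
}
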