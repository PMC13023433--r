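# Internal neural-network layer primitives.
#
# All layer functions operate on batched arrays and return both the output and
# a cache sufficient for exact reverse-mode differentiation. Conventions:
#   - trial batches are arrays dim (channels/features, time, batch)
#   - token batches are arrays dim (embed_dim, n_tokens, batch)
#   - weight matrices act on column vectors: y = W %*% x + b
# Batch normalization uses the statistics of the current forward pass (over
# time x batch per channel); there are no running-moment buffers.

# ---- 1-D convolution (stride 1, length-preserving padding) ------------------

conv1d_forward <- function(A, W, b) {
  dims <- dim(A); C <- dims[1]; T <- dims[2]; B <- dims[3]
  k <- dim(W)[3]; cout <- dim(W)[1]
  pad_l <- (k - 1L) %/% 2L
  Tp <- T + k - 1L
  Apad <- array(0, dim = c(C, Tp, B))
  Apad[, (pad_l + 1L):(pad_l + T), ] <- A
  M <- matrix(Apad, nrow = C)
  Z <- matrix(b, nrow = cout, ncol = T * B)
  idx <- vector("list", k)
  for (j in seq_len(k)) {
    idx[[j]] <- as.vector(outer(seq_len(T) + (j - 1L), (0:(B - 1L)) * Tp, "+"))
    Z <- Z + matrix(W[, , j], nrow = cout) %*% M[, idx[[j]], drop = FALSE]
  }
  list(out = array(Z, dim = c(cout, T, B)),
       cache = list(M = M, idx = idx, dimA = dims, pad_l = pad_l,
                    Tp = Tp, W = W))
}

conv1d_backward <- function(dZ, cache) {
  W <- cache$W; k <- dim(W)[3]; cout <- dim(W)[1]
  C <- cache$dimA[1]; T <- cache$dimA[2]; B <- cache$dimA[3]
  dZm <- matrix(dZ, nrow = cout)
  dW <- array(0, dim = dim(W))
  dM <- matrix(0, nrow = C, ncol = cache$Tp * B)
  for (j in seq_len(k)) {
    cols <- cache$idx[[j]]
    dW[, , j] <- dZm %*% t(cache$M[, cols, drop = FALSE])
    dM[, cols] <- dM[, cols] + t(matrix(W[, , j], nrow = cout)) %*% dZm
  }
  db <- rowSums(dZm)
  dApad <- array(dM, dim = c(C, cache$Tp, B))
  dA <- dApad[, (cache$pad_l + 1L):(cache$pad_l + T), , drop = FALSE]
  list(dA = dA, dW = dW, db = db)
}

# ---- batch normalization per channel with running statistics ----------------
#
# Training mode normalizes by the current batch statistics (per channel over
# time x batch) and updates the running moments by exponential moving
# average; evaluation mode normalizes by the frozen running moments, so
# inference is independent of batch composition.

bn_state_init <- function(config) {
  lapply(config$conv_out_channels, function(cout) {
    list(mean = numeric(cout), var = rep(1, cout))
  })
}

batchnorm_forward <- function(A, gamma, beta, state, training,
                              eps = 1e-5, momentum = 0.1) {
  dims <- dim(A)
  X <- matrix(A, nrow = dims[1])
  if (training) {
    mu <- rowMeans(X)
    xc <- X - mu
    v <- rowMeans(xc * xc)
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * inv
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
    cache <- list(mode = "batch", xhat = xhat, inv = inv, gamma = gamma,
                  dims = dims)
  } else {
    inv <- 1 / sqrt(state$var + eps)
    xhat <- (X - state$mean) * inv
    cache <- list(mode = "frozen", xhat = xhat, inv = inv, gamma = gamma,
                  dims = dims)
  }
  list(out = array(xhat * gamma + beta, dim = dims), cache = cache,
       state = state)
}

batchnorm_backward <- function(dOut, cache) {
  dims <- cache$dims
  dY <- matrix(dOut, nrow = dims[1])
  xhat <- cache$xhat
  dgamma <- rowSums(dY * xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * cache$gamma
  if (cache$mode == "batch") {
    M <- ncol(dY)
    dX <- cache$inv / M *
      (M * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  } else {
    # frozen moments: the normalization is an affine map per channel
    dX <- dxhat * cache$inv
  }
  list(dA = array(dX, dim = dims), dgamma = dgamma, dbeta = dbeta)
}

# ---- max pooling along time with floor division -----------------------------

maxpool_forward <- function(A, pool) {
  dims <- dim(A); T <- dims[2]
  T2 <- T %/% pool
  stopifnot(T2 >= 1L)
  cols <- seq(1L, by = pool, length.out = T2)
  out <- A[, cols, , drop = FALSE]
  win <- array(1L, dim = dim(out))   # offset within window that won (ties -> first)
  if (pool > 1L) {
    for (j in 2:pool) {
      S <- A[, cols + (j - 1L), , drop = FALSE]
      upd <- S > out
      out[upd] <- S[upd]
      win[upd] <- j
    }
  }
  list(out = out, cache = list(win = win, pool = pool, dims = dims, T2 = T2))
}

maxpool_backward <- function(dOut, cache) {
  dims <- cache$dims; pool <- cache$pool; T2 <- cache$T2
  dA <- array(0, dim = dims)
  cols <- seq(1L, by = pool, length.out = T2)
  for (j in seq_len(pool)) {
    mask <- cache$win == j
    if (any(mask)) {
      contrib <- array(0, dim = dim(dOut))
      contrib[mask] <- dOut[mask]
      dA[, cols + (j - 1L), ] <- dA[, cols + (j - 1L), ] + contrib
    }
  }
  dA
}

# ---- dropout (inverted scaling) ---------------------------------------------

dropout_forward <- function(A, p, training) {
  if (!training || p <= 0) return(list(out = A, cache = NULL))
  mask <- array(stats::rbinom(length(A), 1L, 1 - p) / (1 - p), dim = dim(A))
  list(out = A * mask, cache = mask)
}

dropout_backward <- function(dOut, cache) {
  if (is.null(cache)) dOut else dOut * cache
}

# ---- convolutional encoder (four blocks) ------------------------------------

conv_encoder_forward <- function(X, conv_params, config, training = FALSE,
                                 bn_state = NULL) {
  if (is.null(bn_state)) bn_state <- bn_state_init(config)
  A <- X
  caches <- vector("list", length(conv_params))
  for (b in seq_along(conv_params)) {
    prm <- conv_params[[b]]
    cv <- conv1d_forward(A, prm$W, prm$b)
    bn <- batchnorm_forward(cv$out, prm$gamma, prm$beta, bn_state[[b]],
                            training)
    bn_state[[b]] <- bn$state
    relu_mask <- bn$out > 0
    R <- bn$out * relu_mask
    dp <- dropout_forward(R, config$conv_dropout, training)
    mp <- maxpool_forward(dp$out, config$pool_size)
    caches[[b]] <- list(conv = cv$cache, bn = bn$cache, relu = relu_mask,
                        drop = dp$cache, pool = mp$cache)
    A <- mp$out
  }
  list(out = A, caches = caches, bn_state = bn_state)
}

conv_encoder_backward <- function(dOut, caches) {
  grads <- vector("list", length(caches))
  dA <- dOut
  for (b in rev(seq_along(caches))) {
    cc <- caches[[b]]
    dA <- maxpool_backward(dA, cc$pool)
    dA <- dropout_backward(dA, cc$drop)
    dA <- dA * cc$relu
    bn <- batchnorm_backward(dA, cc$bn)
    cv <- conv1d_backward(bn$dA, cc$conv)
    grads[[b]] <- list(W = cv$dW, b = cv$db, gamma = bn$dgamma, beta = bn$dbeta)
    dA <- cv$dA
  }
  list(dX = dA, grads = grads)
}

# ---- LSTM (single direction) ------------------------------------------------

lstm_dir_forward <- function(X, prm) {
  dims <- dim(X); T <- dims[2]; B <- dims[3]
  dh <- ncol(prm$Wh)
  bias <- prm$bi + prm$bh
  h <- matrix(0, dh, B); cst <- matrix(0, dh, B)
  H <- array(0, dim = c(dh, T, B))
  steps <- vector("list", T)
  ii <- 1:dh; fi <- (dh + 1L):(2L * dh)
  gi <- (2L * dh + 1L):(3L * dh); oi <- (3L * dh + 1L):(4L * dh)
  for (t in seq_len(T)) {
    xt <- matrix(X[, t, ], nrow = dims[1])
    G <- prm$Wi %*% xt + prm$Wh %*% h + bias
    i_g <- sigmoid(G[ii, , drop = FALSE])
    f_g <- sigmoid(G[fi, , drop = FALSE])
    g_g <- tanh(G[gi, , drop = FALSE])
    o_g <- sigmoid(G[oi, , drop = FALSE])
    c_new <- f_g * cst + i_g * g_g
    tc <- tanh(c_new)
    h_new <- o_g * tc
    steps[[t]] <- list(x = xt, h_prev = h, c_prev = cst,
                       i = i_g, f = f_g, g = g_g, o = o_g, tc = tc)
    h <- h_new; cst <- c_new
    H[, t, ] <- h
  }
  list(out = H, cache = list(steps = steps, prm = prm, dims = dims, dh = dh))
}

lstm_dir_backward <- function(dH, cache) {
  prm <- cache$prm; dims <- cache$dims
  T <- dims[2]; B <- dims[3]; dh <- cache$dh
  dWi <- matrix(0, nrow(prm$Wi), ncol(prm$Wi))
  dWh <- matrix(0, 4L * dh, dh)
  dbias <- numeric(4 * dh)
  dX <- array(0, dim = dims)
  dh_next <- matrix(0, dh, B); dc_next <- matrix(0, dh, B)
  for (t in rev(seq_len(T))) {
    st <- cache$steps[[t]]
    dht <- matrix(dH[, t, ], nrow = dh) + dh_next
    do <- dht * st$tc
    dc <- dc_next + dht * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dG <- rbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do * st$o * (1 - st$o))
    dWi <- dWi + dG %*% t(st$x)
    dWh <- dWh + dG %*% t(st$h_prev)
    dbias <- dbias + rowSums(dG)
    dX[, t, ] <- t(prm$Wi) %*% dG
    dh_next <- t(prm$Wh) %*% dG
    dc_next <- dc * st$f
  }
  list(dX = dX, grads = list(Wi = dWi, Wh = dWh, bi = dbias, bh = dbias))
}

# ---- bidirectional stacked LSTM ---------------------------------------------

bilstm_forward <- function(X, lstm_params, config, training = FALSE) {
  A <- X
  caches <- vector("list", length(lstm_params))
  for (l in seq_along(lstm_params)) {
    if (l > 1L && config$lstm_dropout > 0) {
      dp <- dropout_forward(A, config$lstm_dropout, training)
      drop_cache <- dp$cache
      A <- dp$out
    } else drop_cache <- NULL
    fwd <- lstm_dir_forward(A, lstm_params[[l]][[1]])
    T <- dim(A)[2]
    rev_idx <- rev(seq_len(T))
    bwd <- lstm_dir_forward(A[, rev_idx, , drop = FALSE], lstm_params[[l]][[2]])
    Hb <- bwd$out[, rev_idx, , drop = FALSE]
    H <- array(0, dim = c(2L * config$lstm_hidden, T, dim(A)[3]))
    H[seq_len(config$lstm_hidden), , ] <- fwd$out
    H[(config$lstm_hidden + 1L):(2L * config$lstm_hidden), , ] <- Hb
    caches[[l]] <- list(fwd = fwd$cache, bwd = bwd$cache,
                        rev_idx = rev_idx, drop = drop_cache)
    A <- H
  }
  list(out = A, caches = caches)
}

bilstm_backward <- function(dOut, caches, config) {
  dh <- config$lstm_hidden
  grads <- vector("list", length(caches))
  dA <- dOut
  for (l in rev(seq_along(caches))) {
    cc <- caches[[l]]
    dF <- dA[seq_len(dh), , , drop = FALSE]
    dB <- dA[(dh + 1L):(2L * dh), , , drop = FALSE]
    gf <- lstm_dir_backward(dF, cc$fwd)
    gb <- lstm_dir_backward(dB[, cc$rev_idx, , drop = FALSE], cc$bwd)
    dA <- gf$dX + gb$dX[, cc$rev_idx, , drop = FALSE]
    if (!is.null(cc$drop)) dA <- dropout_backward(dA, cc$drop)
    grads[[l]] <- list(gf$grads, gb$grads)
  }
  list(dX = dA, grads = grads)
}

# ---- layer normalization over features per token ----------------------------

layernorm_forward <- function(X, g, b, eps = 1e-5) {
  d <- nrow(X)
  mu <- colMeans(X)
  xc <- sweep(X, 2, mu, "-")
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, "*")
  list(out = xhat * g + b,
       cache = list(xhat = xhat, inv = inv, g = g, d = d))
}

layernorm_backward <- function(dY, cache) {
  d <- cache$d; xhat <- cache$xhat
  dg <- rowSums(dY * xhat)
  db <- rowSums(dY)
  dxhat <- dY * cache$g
  colsum1 <- colSums(dxhat)
  colsum2 <- colSums(dxhat * xhat)
  dX <- sweep(d * dxhat - rep(1, d) %o% colsum1 - sweep(xhat, 2, colsum2, "*"),
              2, cache$inv / d, "*")
  list(dX = dX, dg = dg, db = db)
}

# ---- sinusoidal positional encoding -----------------------------------------

#' Sinusoidal positional encodings
#'
#' Deterministic, non-learned encodings: for token position t (0-based) and
#' embedding index i, even rows carry sin(t / 10000^(i/d)) and odd rows the
#' matching cosine. Contributes no trainable parameters.
#'
#' @param n_tokens Number of tokens N.
#' @param d Embedding dimension.
#' @return A d x N matrix (one column per token position).
#' @export
positional_encoding <- function(n_tokens, d) {
  pos <- 0:(n_tokens - 1L)
  pe <- matrix(0, d, n_tokens)
  for (i in 0:(d - 1L)) {
    angle <- pos / 10000^((i %/% 2L) * 2 / d)
    pe[i + 1L, ] <- if (i %% 2L == 0L) sin(angle) else cos(angle)
  }
  pe
}

# ---- patch tokenizer --------------------------------------------------------

# H: array (2dh, T', B). Patches span patch_size steps with the configured
# stride; each patch is flattened time-major (time index fastest), projected
# affinely to embed_dim, layer-normalized, then positional encodings added.
tokenizer_forward <- function(H, tok, config, add_positional = TRUE) {
  dims <- dim(H); feat <- dims[1]; tprime <- dims[2]; B <- dims[3]
  p <- config$patch_size; s <- config$stride
  N <- n_patches(tprime, config)
  d <- config$embed_dim
  Flat <- matrix(0, p * feat, N * B)
  col <- 0L
  for (b in seq_len(B)) {
    for (i in seq_len(N)) {
      t0 <- (i - 1L) * s + 1L
      col <- col + 1L
      # t(H-slice) has rows = time, so column-major vec is time-major
      Flat[, col] <- as.vector(t(matrix(H[, t0:(t0 + p - 1L), b], nrow = feat)))
    }
  }
  Z <- crossprod(tok$We, Flat) + tok$be
  ln <- layernorm_forward(Z, tok$ln_g, tok$ln_b)
  pe <- positional_encoding(N, d)
  out <- ln$out
  if (add_positional) out <- out + pe[, rep(seq_len(N), times = B)]
  list(out = array(out, dim = c(d, N, B)),
       cache = list(Flat = Flat, ln = ln$cache, dims = dims, N = N, B = B,
                    tok = tok),
       positional = pe)
}

tokenizer_backward <- function(dOut, cache, config) {
  d <- config$embed_dim; N <- cache$N; B <- cache$B
  p <- config$patch_size; s <- config$stride
  feat <- cache$dims[1]
  dZpe <- matrix(dOut, nrow = d)          # positional term has zero gradient
  ln <- layernorm_backward(dZpe, cache$ln)
  dWe <- cache$Flat %*% t(ln$dX)
  dbe <- rowSums(ln$dX)
  dFlat <- cache$tok$We %*% ln$dX
  dH <- array(0, dim = cache$dims)
  col <- 0L
  for (b in seq_len(B)) {
    for (i in seq_len(N)) {
      t0 <- (i - 1L) * s + 1L
      col <- col + 1L
      patch <- t(matrix(dFlat[, col], nrow = p))   # back to (feat, p)
      dH[, t0:(t0 + p - 1L), b] <- dH[, t0:(t0 + p - 1L), b] + patch
    }
  }
  list(dH = dH,
       grads = list(We = dWe, be = dbe, ln_g = ln$dg, ln_b = ln$db))
}

# ---- Transformer encoder ----------------------------------------------------

# Multi-head self-attention on one sample's token matrix X (d x N).
mha_forward_sample <- function(Q, K, V, n_heads) {
  d <- nrow(Q); N <- ncol(Q); dk <- d %/% n_heads
  out <- matrix(0, d, N)
  A_list <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    rows <- ((h - 1L) * dk + 1L):(h * dk)
    S <- crossprod(Q[rows, , drop = FALSE], K[rows, , drop = FALSE]) / sqrt(dk)
    S <- S - apply(S, 1, max)
    E <- exp(S)
    A <- E / rowSums(E)
    out[rows, ] <- V[rows, , drop = FALSE] %*% t(A)
    A_list[[h]] <- A
  }
  list(out = out, A = A_list)
}

mha_backward_sample <- function(dOut, Q, K, V, A_list, n_heads) {
  d <- nrow(Q); dk <- d %/% n_heads
  dQ <- matrix(0, d, ncol(Q)); dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    rows <- ((h - 1L) * dk + 1L):(h * dk)
    A <- A_list[[h]]
    dOh <- dOut[rows, , drop = FALSE]
    dV[rows, ] <- dOh %*% A
    # dA[j, k] = dOh[, j] . V[rows, k]; softmax rows of S
    dA <- crossprod(dOh, V[rows, , drop = FALSE])
    dS <- A * (dA - rowSums(dA * A))
    dQ[rows, ] <- K[rows, , drop = FALSE] %*% t(dS) / sqrt(dk)
    dK[rows, ] <- Q[rows, , drop = FALSE] %*% dS / sqrt(dk)
  }
  list(dQ = dQ, dK = dK, dV = dV)
}

# One Transformer encoder layer (post-norm): X -> LN1(X + MHA(X)) ->
# LN2(. + FF(.)), with GELU feed-forward and dropout after attention output
# and feed-forward output during training.
tf_layer_forward <- function(X, prm, config, training = FALSE) {
  dims <- dim(X); d <- dims[1]; N <- dims[2]; B <- dims[3]
  Xm <- matrix(X, nrow = d)
  Q <- prm$Wq %*% Xm + prm$bq
  K <- prm$Wk %*% Xm + prm$bk
  V <- prm$Wv %*% Xm + prm$bv
  attn <- matrix(0, d, N * B)
  A_caches <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- ((b - 1L) * N + 1L):(b * N)
    mh <- mha_forward_sample(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                             V[, cols, drop = FALSE], config$n_heads)
    attn[, cols] <- mh$out
    A_caches[[b]] <- mh$A
  }
  O <- prm$Wo %*% attn + prm$bo
  dp1 <- dropout_forward(O, config$tf_dropout, training)
  ln1 <- layernorm_forward(Xm + dp1$out, prm$ln1_g, prm$ln1_b)
  X1 <- ln1$out
  F1 <- prm$W1 %*% X1 + prm$b1
  G <- gelu(F1)
  F2 <- prm$W2 %*% G + prm$b2
  dp2 <- dropout_forward(F2, config$tf_dropout, training)
  ln2 <- layernorm_forward(X1 + dp2$out, prm$ln2_g, prm$ln2_b)
  list(out = array(ln2$out, dim = dims),
       cache = list(Xm = Xm, Q = Q, K = K, V = V, attn = attn,
                    A_caches = A_caches, dp1 = dp1$cache, ln1 = ln1$cache,
                    X1 = X1, F1 = F1, G = G, dp2 = dp2$cache,
                    ln2 = ln2$cache, prm = prm, N = N, B = B),
       attention = A_caches)
}

tf_layer_backward <- function(dOut, cache, config) {
  prm <- cache$prm; N <- cache$N; B <- cache$B
  d <- nrow(cache$Xm)
  dY <- matrix(dOut, nrow = d)
  l2 <- layernorm_backward(dY, cache$ln2)
  dRes2 <- l2$dX
  dF2 <- dropout_backward(dRes2, cache$dp2)
  dW2 <- dF2 %*% t(cache$G)
  db2 <- rowSums(dF2)
  dG <- t(prm$W2) %*% dF2
  dF1 <- dG * gelu_grad(cache$F1)
  dW1 <- dF1 %*% t(cache$X1)
  db1 <- rowSums(dF1)
  dX1 <- dRes2 + t(prm$W1) %*% dF1
  l1 <- layernorm_backward(dX1, cache$ln1)
  dRes1 <- l1$dX
  dO <- dropout_backward(dRes1, cache$dp1)
  dWo <- dO %*% t(cache$attn)
  dbo <- rowSums(dO)
  dAttn <- t(prm$Wo) %*% dO
  dQ <- matrix(0, d, N * B); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    cols <- ((b - 1L) * N + 1L):(b * N)
    mh <- mha_backward_sample(dAttn[, cols, drop = FALSE],
                              cache$Q[, cols, drop = FALSE],
                              cache$K[, cols, drop = FALSE],
                              cache$V[, cols, drop = FALSE],
                              cache$A_caches[[b]], config$n_heads)
    dQ[, cols] <- mh$dQ; dK[, cols] <- mh$dK; dV[, cols] <- mh$dV
  }
  Xm <- cache$Xm
  dWq <- dQ %*% t(Xm); dWk <- dK %*% t(Xm); dWv <- dV %*% t(Xm)
  dXm <- dRes1 + t(prm$Wq) %*% dQ + t(prm$Wk) %*% dK + t(prm$Wv) %*% dV
  list(dX = array(dXm, dim = c(d, N, B)),
       grads = list(Wq = dWq, bq = rowSums(dQ),
                    Wk = dWk, bk = rowSums(dK),
                    Wv = dWv, bv = rowSums(dV),
                    Wo = dWo, bo = dbo,
                    W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    ln1_g = l1$dg, ln1_b = l1$db,
                    ln2_g = l2$dg, ln2_b = l2$db))
}

# Full Transformer encoder: L layers, final layer norm, mean pooling.
transformer_forward <- function(Ztok, tf_params, ln_f, config,
                                training = FALSE) {
  A <- Ztok
  caches <- vector("list", length(tf_params))
  for (l in seq_along(tf_params)) {
    lf <- tf_layer_forward(A, tf_params[[l]], config, training)
    caches[[l]] <- lf$cache
    A <- lf$out
  }
  dims <- dim(A); d <- dims[1]; N <- dims[2]; B <- dims[3]
  fn <- layernorm_forward(matrix(A, nrow = d), ln_f$g, ln_f$b)
  Xf <- array(fn$out, dim = dims)
  pooled <- matrix(0, d, B)
  for (b in seq_len(B)) pooled[, b] <- rowMeans(matrix(Xf[, , b], nrow = d))
  list(out = pooled,
       caches = list(layers = caches, final_ln = fn$cache, dims = dims),
       attention = lapply(caches, function(cc) cc$A_caches))
}

transformer_backward <- function(dPooled, caches, config) {
  dims <- caches$dims; d <- dims[1]; N <- dims[2]; B <- dims[3]
  dXf <- array(0, dim = dims)
  for (b in seq_len(B)) dXf[, , b] <- dPooled[, b] / N
  fn <- layernorm_backward(matrix(dXf, nrow = d), caches$final_ln)
  dA <- array(fn$dX, dim = dims)
  grads <- vector("list", length(caches$layers))
  for (l in rev(seq_along(caches$layers))) {
    lb <- tf_layer_backward(dA, caches$layers[[l]], config)
    grads[[l]] <- lb$grads
    dA <- lb$dX
  }
  list(dZ = dA, grads = grads, ln_f = list(g = fn$dg, b = fn$db))
}

# ---- classification head ----------------------------------------------------

head_forward <- function(E, head, config) {
  H1 <- head$W1 %*% E + head$b1
  Act <- if (config$head_activation == "gelu") gelu(H1) else H1
  logits <- head$W2 %*% Act + head$b2
  list(out = logits, cache = list(E = E, H1 = H1, Act = Act, head = head))
}

head_backward <- function(dLogits, cache, config) {
  head <- cache$head
  dW2 <- dLogits %*% t(cache$Act)
  db2 <- rowSums(dLogits)
  dAct <- t(head$W2) %*% dLogits
  dH1 <- if (config$head_activation == "gelu") {
    dAct * gelu_grad(cache$H1)
  } else dAct
  dW1 <- dH1 %*% t(cache$E)
  db1 <- rowSums(dH1)
  dE <- t(head$W1) %*% dH1
  list(dE = dE, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}
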