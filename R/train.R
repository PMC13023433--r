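#' Supervised training configuration
#'
#' The reference regimen: AdamW (decoupled weight decay), initial learning
#' rate 3e-4 with a 10-epoch linear warm-up, halving on validation plateau,
#' batch size 32, at most 100 epochs with early stopping after 10
#' non-improving validation epochs, and gradient-norm clipping at 1.0.
#'
#' @param lr Peak learning rate.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum epochs.
#' @param early_stop_patience Consecutive non-improving validation epochs
#'   before stopping; the plateau decay triggers at half this patience.
#' @param warmup_epochs Linear warm-up duration in epochs.
#' @param plateau_decay Multiplicative decay factor on plateau.
#' @param grad_clip_norm Global gradient-norm clip.
#' @param augment_noise_sd SD of Gaussian noise added to training batches
#'   (in units of the standardized input; 0 disables).
#' @param augment_shift_max Maximum circular time shift (samples) applied to
#'   training trials (0 disables). Both augmentations affect only the
#'   training batches, never validation or evaluation.
#' @param seed Integer seed controlling shuffling, dropout, initialization.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(lr = 3e-4, weight_decay = 1e-2, batch_size = 32L,
                         max_epochs = 100L, early_stop_patience = 10L,
                         warmup_epochs = 10L, plateau_decay = 0.5,
                         grad_clip_norm = 1.0, augment_noise_sd = 0,
                         augment_shift_max = 0L, seed = 1L) {
  stopifnot(lr > 0, weight_decay >= 0, batch_size >= 1, max_epochs >= 1,
            early_stop_patience >= 1, early_stop_patience <= max_epochs,
            warmup_epochs >= 1, plateau_decay > 0, grad_clip_norm > 0,
            augment_noise_sd >= 0, augment_shift_max >= 0)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 warmup_epochs = as.integer(warmup_epochs),
                 plateau_decay = plateau_decay,
                 grad_clip_norm = grad_clip_norm,
                 augment_noise_sd = augment_noise_sd,
                 augment_shift_max = as.integer(augment_shift_max),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Training-time augmentation: additive Gaussian noise and a per-trial
# circular time shift. Draws from the current RNG stream.
augment_batch <- function(X, noise_sd, shift_max) {
  if (shift_max > 0L) {
    T <- dim(X)[2]
    for (b in seq_len(dim(X)[3])) {
      sh <- sample.int(2L * shift_max + 1L, 1L) - shift_max - 1L
      if (sh != 0L) {
        idx <- ((seq_len(T) - 1L + sh) %% T) + 1L
        X[, , b] <- X[, idx, b]
      }
    }
  }
  if (noise_sd > 0) X <- X + stats::rnorm(length(X), 0, noise_sd)
  X
}

#' Learning-rate schedule
#'
#' Linear warm-up from lr/warmup_epochs to lr over the warm-up epochs, then
#' constant, multiplied by \code{plateau_decay} once per plateau trigger (a
#' trigger fires after early_stop_patience/2 consecutive non-improving
#' validation epochs).
#'
#' @param epoch Training epoch (1-based).
#' @param cfg A [train_config()].
#' @param n_plateau Number of plateau triggers so far.
#' @return The learning rate for this epoch.
#' @export
lr_schedule <- function(epoch, cfg = train_config(), n_plateau = 0L) {
  stopifnot(epoch >= 1)
  cfg$lr * min(1, epoch / cfg$warmup_epochs) * cfg$plateau_decay^n_plateau
}

# Early-stopping / plateau bookkeeping: returns the updated state after
# observing one validation loss. `improved` uses strict decrease.
update_early_stop <- function(state, val_loss, cfg) {
  if (is.null(state)) {
    state <- list(best = Inf, n_bad = 0L, n_bad_plateau = 0L,
                  n_plateau = 0L, stop = FALSE, improved = FALSE)
  }
  if (val_loss < state$best) {
    state$best <- val_loss
    state$n_bad <- 0L
    state$n_bad_plateau <- 0L
    state$improved <- TRUE
  } else {
    state$n_bad <- state$n_bad + 1L
    state$n_bad_plateau <- state$n_bad_plateau + 1L
    state$improved <- FALSE
    plateau_patience <- max(1L, cfg$early_stop_patience %/% 2L)
    if (state$n_bad_plateau >= plateau_patience) {
      state$n_plateau <- state$n_plateau + 1L
      state$n_bad_plateau <- 0L
    }
  }
  state$stop <- state$n_bad >= cfg$early_stop_patience
  state
}

# ---- model container --------------------------------------------------------

#' Construct a decoder model
#'
#' Bundles a [model_config()] with freshly initialized parameters.
#'
#' @param config A [model_config()].
#' @param seed Initialization seed.
#' @return An object of class \code{mi_model} (fields \code{config},
#'   \code{params}).
#' @export
mi_model <- function(config = model_config(), seed = 1L) {
  structure(list(config = config,
                 params = init_model_parameters(config, seed)),
            class = "mi_model")
}

#' @export
print.mi_model <- function(x, ...) {
  cat("<mi_model>\n")
  print(x$config)
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x$config)$total, big.mark = ",")))
  invisible(x)
}

# trial_set -> (X array (C,T,B), y integer vector)
as_batch <- function(ts) {
  list(X = aperm(ts$trials, c(2, 3, 1)), y = as.integer(ts$labels))
}

# ---- AdamW ------------------------------------------------------------------

adamw_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adamw_step <- function(theta, grad, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * theta)
  list(theta = theta, state = state)
}

clip_global_norm <- function(grad, max_norm) {
  nrm <- sqrt(sum(grad^2))
  if (nrm > max_norm) grad * (max_norm / nrm) else grad
}

#' Train a model with cross-entropy and the standard regimen
#'
#' AdamW with warm-up/plateau scheduling, gradient-norm clipping, early
#' stopping on validation loss, and restoration of the best-validation
#' checkpoint.
#'
#' @param model An [mi_model()].
#' @param train,val Disjoint [trial_set()]s.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with the trained \code{model} and \code{history} (data frame
#'   with one row per epoch run: train/val loss, accuracy, lr).
#' @export
train_supervised <- function(model, train, val, cfg = train_config(),
                             verbose = FALSE) {
  if (n_trials(train) == 0L || n_trials(val) == 0L)
    stop("train and validation sets must be non-empty")
  config <- model$config
  template <- model$params
  theta <- flatten_params(template)
  opt <- adamw_init(length(theta))
  tr <- as_batch(train)
  vl <- as_batch(val)
  es <- NULL
  best_theta <- theta
  best_state <- attr(template, "bn_state")
  history <- data.frame()
  n <- dim(tr$X)[3]
  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- lr_schedule(epoch, cfg, if (is.null(es)) 0L else es$n_plateau)
    set.seed(derive_seed(cfg$seed, "epoch", epoch))
    order <- sample(n)
    batches <- split(order, ceiling(seq_along(order) / cfg$batch_size))
    tl <- 0; ta <- 0
    params <- unflatten_params(theta, template)
    for (bidx in batches) {
      Xb <- tr$X[, , bidx, drop = FALSE]
      if (cfg$augment_noise_sd > 0 || cfg$augment_shift_max > 0L)
        Xb <- augment_batch(Xb, cfg$augment_noise_sd, cfg$augment_shift_max)
      lg <- network_loss_grad(params, Xb, tr$y[bidx],
                              config, training = TRUE)
      attr(template, "bn_state") <- lg$bn_state
      g <- clip_global_norm(flatten_params(lg$grad), cfg$grad_clip_norm)
      st <- adamw_step(theta, g, opt, lr, cfg$weight_decay)
      theta <- st$theta; opt <- st$state
      params <- unflatten_params(theta, template)
      tl <- tl + lg$loss * length(bidx); ta <- ta + lg$acc * length(bidx)
    }
    ev <- network_loss_grad(params, vl$X, vl$y, config, training = FALSE,
                            compute_grad = FALSE)
    es <- update_early_stop(es, ev$loss, cfg)
    if (es$improved) {
      best_theta <- theta
      best_state <- attr(template, "bn_state")
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = tl / n, train_acc = ta / n,
      val_loss = ev$loss, val_acc = ev$acc, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f  lr %.2e",
                      epoch, tl / n, ev$loss, ev$acc, lr))
    if (es$stop) break
  }
  attr(template, "bn_state") <- best_state
  model$params <- unflatten_params(best_theta, template)
  list(model = model, history = history)
}

# ---- metrics ----------------------------------------------------------------

#' Classification metrics from predictions
#'
#' Accuracy, macro-F1 (unweighted mean of per-class F1; a class with no true
#' members and no predictions contributes 0), and the confusion matrix
#' (rows = truth, columns = prediction).
#'
#' @param truth Factor (or character) of true labels.
#' @param pred Predicted labels over the same class set.
#' @param classes Optional explicit class set.
#' @return An object of class \code{mi_metrics}: list with \code{accuracy},
#'   \code{macro_f1}, \code{confusion}.
#' @export
classification_metrics <- function(truth, pred, classes = NULL) {
  if (is.null(classes)) classes <- levels(factor(truth))
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  conf <- table(truth = truth, pred = pred)
  metrics_from_confusion(unclass(conf))
}

#' Metrics from a confusion matrix
#' @param conf Square count matrix, rows = truth, columns = prediction.
#' @return An \code{mi_metrics} object.
#' @export
metrics_from_confusion <- function(conf) {
  conf <- as.matrix(conf)
  total <- sum(conf)
  acc <- sum(diag(conf)) / total
  f1 <- vapply(seq_len(nrow(conf)), function(k) {
    tp <- conf[k, k]
    fp <- sum(conf[, k]) - tp
    fn <- sum(conf[k, ]) - tp
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  structure(list(accuracy = acc, macro_f1 = mean(f1), confusion = conf),
            class = "mi_metrics")
}

#' @export
print.mi_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f  macro-F1 %.3f\n", x$accuracy, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a model on a test set
#'
#' @param model A trained [mi_model()].
#' @param test A non-empty [trial_set()].
#' @return An \code{mi_metrics} object.
#' @export
evaluate_model <- function(model, test) {
  if (n_trials(test) == 0L) stop("test set is empty")
  P <- predict_trials(test, model$params, model$config)
  pred <- levels(test$labels)[max.col(P)]
  classification_metrics(test$labels, pred, classes = levels(test$labels))
}
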