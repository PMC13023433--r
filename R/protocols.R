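# Evaluation protocols: within-subject, leave-one-subject-out (LOSO), and
# subject-specific fine-tuning, with a leakage audit over every fold.

#' Audit disjointness of protocol splits
#'
#' Certifies that the train/validation/test index sets of a fold are pairwise
#' disjoint. Called internally by every protocol; exported so pipelines can
#' audit custom splits.
#'
#' @param ... Integer index vectors (e.g. train, val, test).
#' @return TRUE invisibly; stops with a message on overlap.
#' @export
audit_disjoint <- function(...) {
  sets <- list(...)
  nm <- names(sets)
  if (is.null(nm)) nm <- paste0("set", seq_along(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i < j && length(intersect(sets[[i]], sets[[j]])) > 0)
        stop(sprintf("leakage: %s and %s share trials", nm[i], nm[j]))
    }
  }
  invisible(TRUE)
}

protocol_result <- function(records, protocol) {
  structure(list(records = records, protocol = protocol,
                 mean_accuracy = mean(records$accuracy),
                 sd_accuracy = stats::sd(records$accuracy),
                 mean_macro_f1 = mean(records$macro_f1)),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result: %s> %d records\n", x$protocol,
              nrow(x$records)))
  cat(sprintf("  accuracy %.3f +/- %.3f   macro-F1 %.3f\n",
              x$mean_accuracy,
              if (is.na(x$sd_accuracy)) 0 else x$sd_accuracy,
              x$mean_macro_f1))
  invisible(x)
}

# Carve a stratified validation subset out of a training trial set.
carve_validation <- function(train_ts, val_fraction, seed) {
  sp <- stratified_split(train_ts, val_fraction, seed)
  list(val = subset_trials(train_ts, sp$first),
       train = subset_trials(train_ts, sp$second))
}

#' Within-subject evaluation protocol
#'
#' Per subject and run: a stratified disjoint 50/50 split (emulating separate
#' recording sessions), a validation subset carved from the training half,
#' supervised training, and evaluation on the held-out half. Aggregates over
#' subjects x runs.
#'
#' @param data A multi-subject [trial_set()].
#' @param cfg A [train_config()].
#' @param model_cfg The [model_config()] to train.
#' @param runs Independent runs (seeds derive from \code{cfg$seed}).
#' @param split_fraction Fraction of each (subject, class) cell used for
#'   training (default 0.5).
#' @param val_fraction Fraction of the training half used for validation.
#' @return A \code{protocol_result}; \code{records} has one row per
#'   subject x run.
#' @export
within_subject_protocol <- function(data, cfg = train_config(),
                                    model_cfg = model_config(),
                                    runs = 5L, split_fraction = 0.5,
                                    val_fraction = 0.25) {
  subjects <- unique(data$subject_ids)
  records <- data.frame()
  for (run in seq_len(runs)) {
    for (s in subjects) {
      sub_idx <- which(data$subject_ids == s)
      sub <- subset_trials(data, sub_idx)
      if (min(table(sub$labels)) < 2L)
        stop(sprintf("subject %s has fewer than 2 trials in some class", s))
      sp <- stratified_split(sub, split_fraction,
                             derive_seed(cfg$seed, "within", run, s))
      audit_disjoint(train = sp$first, test = sp$second)
      train_all <- subset_trials(sub, sp$first)
      cv <- carve_validation(train_all, val_fraction,
                             derive_seed(cfg$seed, "within-val", run, s))
      run_cfg <- cfg
      run_cfg$seed <- derive_seed(cfg$seed, "within-train", run, s)
      model <- mi_model(model_cfg, seed = run_cfg$seed)
      fit <- train_supervised(model, cv$train, cv$val, run_cfg)
      m <- evaluate_model(fit$model, subset_trials(sub, sp$second))
      records <- rbind(records, data.frame(
        protocol = "within_subject", subject = s, run = run,
        accuracy = m$accuracy, macro_f1 = m$macro_f1,
        n_test = sum(m$confusion)))
    }
  }
  protocol_result(records, "within_subject")
}

#' Leave-one-subject-out (LOSO) evaluation protocol
#'
#' One fold per subject: the held-out subject contributes no trials to
#' training or validation; the validation subset is carved from the training
#' subjects only.
#'
#' @inheritParams within_subject_protocol
#' @return A \code{protocol_result}; one record per subject x run.
#' @export
loso_protocol <- function(data, cfg = train_config(),
                          model_cfg = model_config(), runs = 1L,
                          val_fraction = 0.2) {
  subjects <- unique(data$subject_ids)
  if (length(subjects) < 3L) stop("LOSO needs at least 3 subjects")
  records <- data.frame()
  for (run in seq_len(runs)) {
    for (s in subjects) {
      test_idx <- which(data$subject_ids == s)
      train_idx <- which(data$subject_ids != s)
      audit_disjoint(train = train_idx, test = test_idx)
      train_all <- subset_trials(data, train_idx)
      cv <- carve_validation(train_all, val_fraction,
                             derive_seed(cfg$seed, "loso-val", run, s))
      run_cfg <- cfg
      run_cfg$seed <- derive_seed(cfg$seed, "loso-train", run, s)
      model <- mi_model(model_cfg, seed = run_cfg$seed)
      fit <- train_supervised(model, cv$train, cv$val, run_cfg)
      m <- evaluate_model(fit$model, subset_trials(data, test_idx))
      records <- rbind(records, data.frame(
        protocol = "loso", subject = s, run = run,
        accuracy = m$accuracy, macro_f1 = m$macro_f1,
        n_test = length(test_idx)))
    }
  }
  protocol_result(records, "loso")
}

#' Subject-specific fine-tuning protocol
#'
#' Per fold: pretrain on all other subjects (LOSO-style), fine-tune on a
#' small labeled support subset of the held-out subject
#' (\code{shots_per_class} trials per class), and test on that subject's
#' remaining trials. Reports pre- and post-adaptation metrics.
#' \code{shots_per_class = 0} skips adaptation, reducing to LOSO.
#'
#' @inheritParams within_subject_protocol
#' @param shots_per_class Labeled calibration trials per class.
#' @param finetune_epochs Adaptation epochs on the support set.
#' @param finetune_lr Adaptation learning rate (plain gradient descent on the
#'   full support batch).
#' @return A \code{protocol_result} whose records carry \code{accuracy} /
#'   \code{macro_f1} (post-adaptation) and \code{pre_accuracy} /
#'   \code{pre_macro_f1}.
#' @export
finetune_protocol <- function(data, cfg = train_config(),
                              model_cfg = model_config(), runs = 1L,
                              shots_per_class = 10L, finetune_epochs = 20L,
                              finetune_lr = 1e-3, val_fraction = 0.2) {
  subjects <- unique(data$subject_ids)
  if (length(subjects) < 3L) stop("needs at least 3 subjects")
  records <- data.frame()
  for (run in seq_len(runs)) {
    for (s in subjects) {
      held_idx <- which(data$subject_ids == s)
      train_idx <- which(data$subject_ids != s)
      train_all <- subset_trials(data, train_idx)
      # same seed tags as loso_protocol: the pretraining stage IS the LOSO
      # model, so zero-shot fine-tuning reproduces LOSO exactly
      cv <- carve_validation(train_all, val_fraction,
                             derive_seed(cfg$seed, "loso-val", run, s))
      run_cfg <- cfg
      run_cfg$seed <- derive_seed(cfg$seed, "loso-train", run, s)
      model <- mi_model(model_cfg, seed = run_cfg$seed)
      fit <- train_supervised(model, cv$train, cv$val, run_cfg)

      held <- subset_trials(data, held_idx)
      if (shots_per_class > 0L) {
        sup <- integer()
        with_seed(derive_seed(cfg$seed, "ft-support", run, s), {
          for (cl in levels(held$labels)) {
            idx <- which(held$labels == cl)
            if (length(idx) <= shots_per_class)
              stop(sprintf("subject %s lacks trials for %d-shot adaptation",
                           s, shots_per_class))
            sup <- c(sup, sample(idx, shots_per_class))
          }
        })
        qry <- setdiff(seq_len(n_trials(held)), sup)
        audit_disjoint(support = sup, query = qry)
        pre <- evaluate_model(fit$model, subset_trials(held, qry))
        theta <- flatten_params(fit$model$params)
        obj <- network_objective(fit$model$config, fit$model$params)
        sb <- as_batch(subset_trials(held, sup))
        theta <- inner_adapt(theta, obj, sb, alpha = finetune_lr,
                             steps = finetune_epochs,
                             grad_clip_norm = cfg$grad_clip_norm)
        post_model <- fit$model
        post_model$params <- unflatten_params(theta, fit$model$params)
        post <- evaluate_model(post_model, subset_trials(held, qry))
      } else {
        pre <- evaluate_model(fit$model, held)
        post <- pre
      }
      records <- rbind(records, data.frame(
        protocol = "finetune", subject = s, run = run,
        accuracy = post$accuracy, macro_f1 = post$macro_f1,
        pre_accuracy = pre$accuracy, pre_macro_f1 = pre$macro_f1,
        shots = shots_per_class))
    }
  }
  protocol_result(records, "finetune")
}
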