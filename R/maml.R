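# Model-agnostic meta-learning (MAML): learn an initialization whose few
# inner gradient steps on a small support set yield good subject-specific
# parameters. The engine is generic over an "objective" (loss + gradient on a
# flat parameter vector), so the same code runs the full decoder network and
# the closed-form toy problems used to verify the update algebra.

#' Meta-learning configuration
#'
#' Defaults follow the reference regimen: inner learning rate alpha = 0.01,
#' outer learning rate beta = 0.001, five inner gradient steps during
#' meta-training, deployment analyzed at 5/10/20 steps, meta-batches of 4
#' subject-tasks, episodic meta-training after a 20-epoch supervised warm
#' start, and support sizes of 5/10/15/20 trials per class.
#'
#' @param inner_lr Inner-loop step size alpha.
#' @param outer_lr Outer-loop step size beta.
#' @param inner_steps_train Inner steps per task during meta-training.
#' @param inner_steps_deploy Step counts analyzed at deployment.
#' @param meta_batch Tasks per meta-update.
#' @param warm_start_epochs Supervised epochs before the episodic phase.
#' @param meta_epochs Episodic epochs (each covers all meta-training
#'   subjects).
#' @param support_sizes Support trials per class for sensitivity sweeps.
#' @param second_order Differentiate through the inner steps (TRUE) or stop
#'   gradients at the adapted parameters (first-order, faster).
#' @param fd_eps Base step for the finite-difference Hessian-vector products
#'   used by the second-order path.
#' @return An object of class \code{meta_config}.
#' @export
meta_config <- function(inner_lr = 0.01, outer_lr = 0.001,
                        inner_steps_train = 5L,
                        inner_steps_deploy = c(5L, 10L, 20L),
                        meta_batch = 4L, warm_start_epochs = 20L,
                        meta_epochs = 10L,
                        support_sizes = c(5L, 10L, 15L, 20L),
                        second_order = TRUE, fd_eps = 1e-4) {
  stopifnot(inner_lr >= 0, outer_lr >= 0, inner_steps_train >= 0,
            meta_batch >= 1, warm_start_epochs >= 0, meta_epochs >= 0)
  structure(list(inner_lr = inner_lr, outer_lr = outer_lr,
                 inner_steps_train = as.integer(inner_steps_train),
                 inner_steps_deploy = as.integer(inner_steps_deploy),
                 meta_batch = as.integer(meta_batch),
                 warm_start_epochs = as.integer(warm_start_epochs),
                 meta_epochs = as.integer(meta_epochs),
                 support_sizes = as.integer(support_sizes),
                 second_order = isTRUE(second_order), fd_eps = fd_eps),
            class = "meta_config")
}

#' Objective wrapper for the decoder network
#'
#' Exposes the network's cross-entropy loss and exact gradient as functions
#' of a flat parameter vector, for use with [inner_adapt()] and
#' [meta_step()]. Dropout is disabled inside the loss so adaptation is
#' deterministic.
#'
#' @param config A [model_config()].
#' @param template Parameters from [init_model_parameters()] fixing the
#'   flat-vector layout.
#' @return List of functions \code{loss(theta, data)} and
#'   \code{grad(theta, data)}; \code{data} is a list with array \code{X}
#'   (channels x samples x batch) and integer labels \code{y}, as produced
#'   by the internal trial-set converter.
#' @export
network_objective <- function(config, template) {
  check <- function(data) {
    if (is.null(data$X) || length(data$y) == 0L)
      stop("empty batch: the support set must be non-empty")
  }
  list(
    loss = function(theta, data) {
      check(data)
      network_loss_grad(unflatten_params(theta, template), data$X, data$y,
                        config, training = FALSE, compute_grad = FALSE)$loss
    },
    grad = function(theta, data) {
      check(data)
      flatten_params(
        network_loss_grad(unflatten_params(theta, template), data$X, data$y,
                          config, training = FALSE)$grad)
    }
  )
}

#' Quadratic toy objective
#'
#' L(theta) = 0.5 * ||theta - c||^2 with gradient theta - c; \code{data} is
#' the target vector c. Used to verify the meta-update algebra against
#' closed forms.
#'
#' @return An objective list as in [network_objective()].
#' @export
quadratic_objective <- function() {
  list(loss = function(theta, data) 0.5 * sum((theta - data)^2),
       grad = function(theta, data) theta - data)
}

#' Inner-loop adaptation
#'
#' \code{steps} full-batch gradient-descent steps on the support loss,
#' starting from \code{theta} (which is never modified): the task-specific
#' parameters theta' = theta - alpha * grad, iterated.
#'
#' @param theta Flat parameter vector.
#' @param objective An objective (e.g. [network_objective()]).
#' @param data Support data for the objective.
#' @param alpha Inner step size.
#' @param steps Number of gradient steps (0 returns \code{theta} unchanged).
#' @param grad_clip_norm Optional global-norm clip on each inner gradient
#'   (default \code{Inf}: plain gradient descent). Network adaptation passes
#'   the training regimen's clip, which keeps few-shot steps stable.
#' @return The adapted flat parameter vector.
#' @export
inner_adapt <- function(theta, objective, data, alpha, steps,
                        grad_clip_norm = Inf) {
  stopifnot(steps >= 0)
  th <- theta
  for (k in seq_len(steps)) {
    if (alpha == 0) break
    g <- objective$grad(th, data)
    if (is.finite(grad_clip_norm)) g <- clip_global_norm(g, grad_clip_norm)
    th <- th - alpha * g
  }
  th
}

# Hessian-vector product by central finite differences on the gradient.
# Exact for quadratic objectives.
fd_hvp <- function(objective, theta, data, v, fd_eps) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(v * 0)
  eps <- fd_eps * max(1, sqrt(sum(theta^2))) / nv
  (objective$grad(theta + eps * v, data) -
     objective$grad(theta - eps * v, data)) / (2 * eps)
}

#' One meta-update over a batch of tasks
#'
#' For each task, adapts theta on the support set (inner loop), evaluates the
#' query-loss gradient at the adapted parameters, and backpropagates through
#' the inner trajectory: the second-order path multiplies by
#' (I - alpha * Hessian) at every inner step (realized with finite-difference
#' Hessian-vector products); the first-order path stops gradients at the
#' adapted parameters. The outer update is
#' theta <- theta - beta * sum of task meta-gradients.
#'
#' @param theta Flat parameter vector.
#' @param tasks List of tasks, each a list with \code{support} and
#'   \code{query} data for the objective.
#' @param objective An objective list.
#' @param cfg A [meta_config()].
#' @param grad_clip_norm Optional global-norm clip applied to the summed
#'   meta-gradient before the outer step (default \code{Inf}: the exact
#'   update). [meta_train()] passes the training regimen's clip here.
#' @return List with the updated \code{theta}, per-task \code{query_losses}
#'   (at the adapted parameters), and the summed \code{meta_grad} (before
#'   clipping).
#' @export
meta_step <- function(theta, tasks, objective, cfg = meta_config(),
                      grad_clip_norm = Inf) {
  stopifnot(length(tasks) >= 1)
  total <- numeric(length(theta))
  qloss <- numeric(length(tasks))
  for (i in seq_along(tasks)) {
    task <- tasks[[i]]
    path <- vector("list", cfg$inner_steps_train + 1L)
    th <- theta
    path[[1L]] <- th
    for (k in seq_len(cfg$inner_steps_train)) {
      g_in <- objective$grad(th, task$support)
      if (is.finite(grad_clip_norm))
        g_in <- clip_global_norm(g_in, grad_clip_norm)
      th <- th - cfg$inner_lr * g_in
      path[[k + 1L]] <- th
    }
    qloss[i] <- objective$loss(th, task$query)
    g <- objective$grad(th, task$query)
    if (cfg$second_order && cfg$inner_lr > 0) {
      for (k in rev(seq_len(cfg$inner_steps_train))) {
        g <- g - cfg$inner_lr *
          fd_hvp(objective, path[[k]], task$support, g, cfg$fd_eps)
      }
    }
    total <- total + g
  }
  applied <- if (is.finite(grad_clip_norm))
    clip_global_norm(total, grad_clip_norm) else total
  list(theta = theta - cfg$outer_lr * applied, query_losses = qloss,
       meta_grad = total)
}

meta_task_to_data <- function(task) {
  list(support = as_batch(task$support), query = as_batch(task$query))
}

#' Meta-train a decoder initialization
#'
#' Warm start: conventional supervised training on the pooled meta-training
#' trials for \code{warm_start_epochs}. Then the episodic phase: each epoch
#' shuffles the meta-training subjects, forms meta-batches, and applies
#' [meta_step()]; per-episode pre/post-adaptation query accuracy is logged.
#' Meta-training subjects must be disjoint from any held-out subjects.
#'
#' @param model An [mi_model()].
#' @param tasks List of \code{meta_task}s (from [make_meta_tasks()]).
#' @param cfg A [meta_config()].
#' @param train_cfg A [train_config()] for the warm-start phase.
#' @param held_out_subjects Subjects reserved for evaluation; overlap with
#'   task subjects is an error.
#' @return List with the meta-trained \code{model} and an episode \code{log}
#'   data frame.
#' @export
meta_train <- function(model, tasks, cfg = meta_config(),
                       train_cfg = train_config(),
                       held_out_subjects = character()) {
  task_subjects <- vapply(tasks, function(t) t$subject_id, character(1))
  overlap <- intersect(task_subjects, held_out_subjects)
  if (length(overlap))
    stop("meta-training subjects overlap held-out subjects: ",
         paste(overlap, collapse = ", "))

  if (cfg$warm_start_epochs > 0L) {
    pooled <- combine_trials(lapply(tasks, function(t)
      combine_trials(t$support, t$query)))
    cv <- carve_validation(pooled, 0.2,
                           derive_seed(train_cfg$seed, "meta-warm-val"))
    warm_cfg <- train_cfg
    warm_cfg$max_epochs <- cfg$warm_start_epochs
    warm_cfg$early_stop_patience <- cfg$warm_start_epochs
    fit <- train_supervised(model, cv$train, cv$val, warm_cfg)
    model <- fit$model
  }

  theta <- flatten_params(model$params)
  obj <- network_objective(model$config, model$params)
  data_tasks <- lapply(tasks, meta_task_to_data)
  log <- data.frame()
  episode <- 0L
  for (epoch in seq_len(cfg$meta_epochs)) {
    ord <- with_seed(derive_seed(train_cfg$seed, "meta-epoch", epoch),
                     sample(length(tasks)))
    chunks <- split(ord, ceiling(seq_along(ord) / cfg$meta_batch))
    for (ch in chunks) {
      episode <- episode + 1L
      batch <- data_tasks[ch]
      pre_acc <- mean(vapply(batch, function(tk) {
        query_accuracy(theta, obj, model, tk$query)
      }, numeric(1)))
      st <- meta_step(theta, batch, obj, cfg,
                      grad_clip_norm = train_cfg$grad_clip_norm)
      theta <- st$theta
      post_acc <- mean(vapply(batch, function(tk) {
        th <- inner_adapt(theta, obj, tk$support, cfg$inner_lr,
                          cfg$inner_steps_train,
                          grad_clip_norm = train_cfg$grad_clip_norm)
        query_accuracy(th, obj, model, tk$query)
      }, numeric(1)))
      log <- rbind(log, data.frame(
        epoch = epoch, episode = episode,
        query_loss = mean(st$query_losses),
        pre_acc = pre_acc, post_acc = post_acc))
    }
  }
  model$params <- unflatten_params(theta, model$params)
  list(model = model, log = log)
}

query_accuracy <- function(theta, obj, model, data) {
  params <- unflatten_params(theta, model$params)
  fw <- network_forward(params, data$X, model$config, training = FALSE)
  mean(max.col(t(fw$logits)) == data$y)
}

#' Few-shot evaluation of an initialization on one subject task
#'
#' Evaluates the query set before adaptation and after \code{steps} inner
#' gradient steps on the support set, for each requested step count.
#'
#' @param model An [mi_model()] holding the initialization.
#' @param task A \code{meta_task}.
#' @param steps Integer vector of inner step counts.
#' @param alpha Inner step size.
#' @param grad_clip_norm Global-norm clip on each adaptation gradient
#'   (default 1, the training regimen's clip).
#' @return List with \code{pre} (an \code{mi_metrics}) and \code{post}, a
#'   data frame with one row per step count (accuracy, macro-F1).
#' @export
few_shot_evaluate <- function(model, task, steps = c(5L, 10L, 20L),
                              alpha = 0.01, grad_clip_norm = 1.0) {
  obj <- network_objective(model$config, model$params)
  theta <- flatten_params(model$params)
  sb <- as_batch(task$support)
  pre <- evaluate_model(model, task$query)
  post <- data.frame()
  for (s in steps) {
    th <- inner_adapt(theta, obj, sb, alpha, s, grad_clip_norm)
    m <- model
    m$params <- unflatten_params(th, model$params)
    met <- evaluate_model(m, task$query)
    post <- rbind(post, data.frame(steps = s, accuracy = met$accuracy,
                                   macro_f1 = met$macro_f1))
  }
  list(pre = pre, post = post, subject = task$subject_id)
}
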