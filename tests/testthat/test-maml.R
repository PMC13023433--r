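test_that("inner adaptation leaves the initialization untouched", {
  obj <- quadratic_objective()
  theta <- c(1, -2, 0.5)
  checksum <- sum(theta)
  th1 <- inner_adapt(theta, obj, c(0, 0, 0), alpha = 0.1, steps = 7)
  expect_identical(sum(theta), checksum)
  expect_false(identical(th1, theta))
  expect_identical(inner_adapt(theta, obj, c(0, 0, 0), 0.1, 0), theta)
  expect_identical(inner_adapt(theta, obj, c(0, 0, 0), 0, 5), theta)
})

test_that("inner and outer updates match hand-derived closed forms", {
  obj <- quadratic_objective()
  # one step on L = 0.5 (theta - 0)^2 from theta = 1 with alpha = 0.01
  expect_equal(inner_adapt(1, obj, 0, 0.01, 1), 0.99, tolerance = 1e-12)
  # k steps contract by (1 - alpha)^k
  expect_equal(inner_adapt(1, obj, 0, 0.1, 5), 0.9^5, tolerance = 1e-12)

  task <- list(list(support = 0, query = 0))
  # second order: outer grad = (1 - alpha) * (theta' - c)
  cfg <- meta_config(inner_lr = 0.01, outer_lr = 0.1, inner_steps_train = 1,
                     second_order = TRUE)
  so <- meta_step(1, task, obj, cfg)
  expect_equal(so$theta, 1 - 0.1 * 0.99 * 0.99, tolerance = 1e-8)
  # first order: outer grad = theta' - c
  cfg$second_order <- FALSE
  fo <- meta_step(1, task, obj, cfg)
  expect_equal(fo$theta, 1 - 0.1 * 0.99, tolerance = 1e-12)
  # beta = 0 leaves theta unchanged
  cfg0 <- meta_config(inner_lr = 0.01, outer_lr = 0, inner_steps_train = 1)
  expect_identical(meta_step(1, task, obj, cfg0)$theta, 1)
  # multi-step second order: the adapted parameter is theta * (1-alpha)^k
  # and the chain rule contributes another (1-alpha)^k
  cfgk <- meta_config(inner_lr = 0.05, outer_lr = 1, inner_steps_train = 3,
                      second_order = TRUE)
  sk <- meta_step(2, list(list(support = 0, query = 0)), obj, cfgk)
  expect_equal(sk$meta_grad, 2 * (1 - 0.05)^6, tolerance = 1e-6)
})

test_that("first- and second-order meta-gradients agree as alpha -> 0", {
  obj <- quadratic_objective()
  task <- list(list(support = 0.5, query = 1.5))
  rel <- vapply(c(1e-2, 1e-3, 1e-4), function(a) {
    c1 <- meta_config(inner_lr = a, outer_lr = 0.1, inner_steps_train = 3,
                      second_order = TRUE)
    c2 <- c1; c2$second_order <- FALSE
    g1 <- meta_step(2, task, obj, c1)$meta_grad
    g2 <- meta_step(2, task, obj, c2)$meta_grad
    abs(g1 - g2) / abs(g2)
  }, numeric(1))
  expect_true(all(diff(rel) < 0))      # strictly shrinking
  expect_lt(rel[3], 1e-3)
})

test_that("the network objective validates support data and adapts", {
  cfg <- tiny_model_config()
  params <- init_model_parameters(cfg, seed = 3)
  obj <- network_objective(cfg, params)
  theta <- flatten_params(params)
  set.seed(51)
  d <- list(X = array(rnorm(3 * 48 * 6), c(3, 48, 6)),
            y = rep(1:3, 2))
  l0 <- obj$loss(theta, d)
  # network gradients at random init have norm >> 1 and sharp curvature;
  # small clipped steps descend
  th1 <- inner_adapt(theta, obj, d, alpha = 0.001, steps = 5,
                     grad_clip_norm = 1)
  expect_lt(obj$loss(th1, d), l0)        # descent on the support loss
  expect_identical(theta, flatten_params(params))  # untouched
  empty <- list(X = NULL, y = integer())
  expect_error(inner_adapt(theta, obj, empty, 0.05, 2), "empty")
})

test_that("meta-training enforces subject separation and logs episodes", {
  ds <- fixture_dataset()
  tasks <- make_meta_tasks(ds, k_shot = 4, seed = 2)
  mc <- tiny_model_config(n_channels = 22, n_samples = 1000,
                          patch_size = 24, stride = 12, n_classes = 4)
  model <- mi_model(mc, seed = 2)
  expect_error(
    meta_train(model, tasks, meta_config(meta_epochs = 1),
               train_config(), held_out_subjects = tasks[[1]]$subject_id),
    "overlap")
  cfg <- meta_config(meta_epochs = 2, meta_batch = 2, warm_start_epochs = 0,
                     inner_steps_train = 1, second_order = FALSE)
  mt <- meta_train(model, tasks, cfg, train_config(seed = 2))
  # both subjects in every epoch; 1 episode of 2 tasks per epoch
  expect_identical(nrow(mt$log), 2L)
  expect_true(all(c("pre_acc", "post_acc", "query_loss") %in% names(mt$log)))
  expect_false(identical(flatten_params(mt$model$params),
                         flatten_params(model$params)))
})

test_that("few-shot evaluation reports pre/post for each step count", {
  ds <- fixture_dataset()
  tasks <- make_meta_tasks(ds, k_shot = 4, seed = 5)
  mc <- tiny_model_config(n_channels = 22, n_samples = 1000,
                          patch_size = 24, stride = 12, n_classes = 4)
  model <- mi_model(mc, seed = 9)
  fe <- few_shot_evaluate(model, tasks[[1]], steps = c(0L, 2L), alpha = 0.01)
  expect_identical(fe$post$steps, c(0L, 2L))
  # zero steps: post equals pre exactly
  expect_equal(fe$post$accuracy[1], fe$pre$accuracy)
  expect_equal(fe$post$macro_f1[1], fe$pre$macro_f1)
})
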