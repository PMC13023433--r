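# Desk-scale experiments shared by the acceptance tests. Problem sizes are
# the ones stated in the methods vignette.

# Within-subject and LOSO protocols on a 3-subject, 40-trials-per-class
# cohort with ERD depth 0.6. Returns the two mean accuracies.
desk_protocol_experiment <- function(master_seed = 1) {
  cfg <- sim_config(n_subjects = 3, trials_per_class = 40, erd_depth = 0.6,
                    master_seed = master_seed)
  ds <- zscore_trials(generate_dataset(cfg))
  mc <- compact_model_config()
  tc <- compact_train_config(seed = master_seed)
  ws <- within_subject_protocol(ds, tc, mc, runs = 1)
  lo <- loso_protocol(ds, tc, mc, runs = 1)
  list(within = ws$mean_accuracy, loso = lo$mean_accuracy,
       within_records = ws$records, loso_records = lo$records)
}

# Meta-trained initialization vs its jointly trained (warm-start) baseline
# on an 8-subject population: the baseline is supervised training on the
# pooled subjects; meta-training continues from that same checkpoint with
# the episodic phase. Both initializations are then adapted identically
# (5 inner steps on 5 shots per class) and scored on the query sets.
meta_vs_joint_experiment <- function(seed) {
  cfg <- sim_config(n_subjects = 8, trials_per_class = 12, erd_depth = 0.4,
                    master_seed = seed)
  ds <- zscore_trials(generate_dataset(cfg))
  tasks <- make_meta_tasks(ds, k_shot = 5, seed = seed)
  mc <- compact_model_config(conv_out_channels = c(4, 6, 8, 8),
                             lstm_hidden = 8, embed_dim = 16, ff_dim = 32)
  tc <- compact_train_config(seed = seed)
  pooled <- do.call(combine_trials, lapply(tasks, function(t)
    combine_trials(t$support, t$query)))
  cv <- midecode:::carve_validation(pooled, 0.2, derive_seed(seed, "warm"))
  wcfg <- tc
  wcfg$max_epochs <- 15L
  wcfg$early_stop_patience <- 15L
  joint <- train_supervised(mi_model(mc, seed = seed), cv$train, cv$val,
                            wcfg)$model
  mcfg <- meta_config(outer_lr = 0.01, meta_epochs = 10,
                      warm_start_epochs = 0, second_order = FALSE,
                      inner_steps_train = 5, meta_batch = 4)
  mt <- meta_train(joint, tasks, mcfg, tc)
  post_acc <- function(m) {
    mean(vapply(tasks, function(tk) {
      few_shot_evaluate(m, tk, steps = 5L, alpha = 0.01)$post$accuracy
    }, numeric(1)))
  }
  c(meta = post_acc(mt$model), joint = post_acc(joint))
}

# Convex analytic error over (p, d, L) plus the closed-form latency and
# parameter objectives: a fully enumerable landscape with a known Pareto set.
analytic_nas_objective <- function(base = compact_model_config()) {
  function(g) {
    cfgg <- genome_to_config(g, base)
    list(error = 0.2 + ((g$p - 24) / 8)^2 + ((log2(g$d) - 7) / 2)^2 +
           0.05 * (g$L - 1),
         latency = estimate_macs(cfgg)$total,
         params = count_parameters(cfgg)$total)
  }
}
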