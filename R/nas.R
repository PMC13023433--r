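# Multi-objective evolutionary architecture search (NSGA-II) over the
# decoder's discrete search space, with a deterministic MAC-count latency
# surrogate and exact parameter counting.

#' The architecture search space
#'
#' Discrete candidate sets: BiLSTM hidden size dh in {64, 128, 256},
#' Transformer depth L in {1, 2, 3}, attention heads h in {2, 4, 6}, patch
#' size p in {16, 20, 24} with stride fixed at p/2 (50% overlap), embedding
#' dimension d in {64, 128, 256}. 3^5 = 243 raw combinations; candidates
#' with d not divisible by h are repaired by resampling h.
#'
#' @return Named list of candidate vectors.
#' @export
nas_space <- function() {
  list(dh = c(64L, 128L, 256L), L = c(1L, 2L, 3L), h = c(2L, 4L, 6L),
       p = c(16L, 20L, 24L), d = c(64L, 128L, 256L))
}

genome_key <- function(g) paste(g$dh, g$L, g$h, g$p, g$d, sep = "-")

repair_genome <- function(g, space = nas_space()) {
  while (g$d %% g$h != 0L) {
    g$h <- sample(space$h, 1L)
  }
  g
}

new_genome <- function(dh, L, h, p, d) {
  structure(list(dh = as.integer(dh), L = as.integer(L), h = as.integer(h),
                 p = as.integer(p), d = as.integer(d)),
            class = "nas_genome")
}

#' @export
print.nas_genome <- function(x, ...) {
  cat(sprintf("<genome dh=%d L=%d h=%d p=%d (s=%d) d=%d>\n",
              x$dh, x$L, x$h, x$p, x$p %/% 2L, x$d))
  invisible(x)
}

#' Sample a genome uniformly from the search space
#'
#' @param seed Integer seed, or NULL to use the current RNG stream.
#' @return A repaired \code{nas_genome}.
#' @export
sample_genome <- function(seed = NULL) {
  draw <- function() {
    space <- nas_space()
    g <- new_genome(sample(space$dh, 1L), sample(space$L, 1L),
                    sample(space$h, 1L), sample(space$p, 1L),
                    sample(space$d, 1L))
    repair_genome(g, space)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Mutate a genome
#'
#' Resamples each gene independently with probability \code{p_mut} (from the
#' gene's full candidate set), then repairs divisibility.
#'
#' @param g A \code{nas_genome}.
#' @param p_mut Per-gene mutation probability.
#' @param seed Optional seed (NULL = current RNG stream).
#' @return The mutated genome.
#' @export
mutate_genome <- function(g, p_mut = 0.2, seed = NULL) {
  do_mut <- function() {
    space <- nas_space()
    for (gene in names(space)) {
      if (stats::runif(1) < p_mut) g[[gene]] <- sample(space[[gene]], 1L)
    }
    repair_genome(g, space)
  }
  if (is.null(seed)) do_mut() else with_seed(seed, do_mut())
}

#' Uniform crossover of two genomes
#'
#' With probability \code{p_x} the parents recombine: each gene is exchanged
#' between the children with probability 1/2. Children are repaired.
#'
#' @param g1,g2 Parent genomes.
#' @param p_x Crossover probability.
#' @param seed Optional seed (NULL = current RNG stream).
#' @return List of two child genomes.
#' @export
crossover_genomes <- function(g1, g2, p_x = 0.8, seed = NULL) {
  do_x <- function() {
    space <- nas_space()
    c1 <- g1; c2 <- g2
    if (stats::runif(1) < p_x) {
      for (gene in names(space)) {
        if (stats::runif(1) < 0.5) {
          tmp <- c1[[gene]]; c1[[gene]] <- c2[[gene]]; c2[[gene]] <- tmp
        }
      }
    }
    list(repair_genome(c1, space), repair_genome(c2, space))
  }
  if (is.null(seed)) do_x() else with_seed(seed, do_x())
}

#' Instantiate a model configuration from a genome
#'
#' Genome fields override the corresponding architecture fields; stride is
#' p/2 (50% patch overlap) and the feed-forward width tracks 2 * d. All other
#' fields come from \code{base}.
#'
#' @param g A \code{nas_genome}.
#' @param base A [model_config()] supplying the non-searched fields.
#' @return A [model_config()].
#' @export
genome_to_config <- function(g, base = model_config()) {
  model_config(
    n_channels = base$n_channels, n_samples = base$n_samples,
    conv_out_channels = base$conv_out_channels,
    conv_kernel = base$conv_kernel, pool_size = base$pool_size,
    conv_dropout = base$conv_dropout,
    lstm_hidden = g$dh, lstm_layers = base$lstm_layers,
    lstm_dropout = base$lstm_dropout,
    patch_size = g$p, stride = g$p %/% 2L,
    embed_dim = g$d, tf_layers = g$L, n_heads = g$h,
    ff_dim = 2L * g$d, tf_dropout = base$tf_dropout,
    n_classes = base$n_classes, head_activation = base$head_activation)
}

#' Enumerate all valid genomes
#'
#' The full Cartesian space restricted to divisible (d, h) pairs — the
#' candidates reachable after repair. Small enough for exhaustive oracles.
#'
#' @return List of \code{nas_genome}s.
#' @export
enumerate_genomes <- function() {
  space <- nas_space()
  out <- list()
  for (dh in space$dh) for (L in space$L) for (h in space$h)
    for (p in space$p) for (d in space$d) {
      if (d %% h == 0L) out[[length(out) + 1L]] <- new_genome(dh, L, h, p, d)
    }
  out
}

#' Search configuration
#'
#' The reference search protocol uses a population of 20 for 50 generations with
#' mutation probability 0.2 and crossover probability 0.8, candidate proxy
#' training of 50 epochs on 80% of subjects, and scalar-fitness weights
#' (0.6, 0.3, 0.1) on error/latency/parameters. Desk-scale runs pass smaller
#' \code{generations} and \code{proxy_epochs}.
#'
#' @param population Population size.
#' @param generations Number of generations.
#' @param mutation_p Per-gene mutation probability.
#' @param crossover_p Crossover probability.
#' @param proxy_epochs Training epochs per candidate on the proxy split.
#' @param proxy_subject_fraction Fraction of subjects in the proxy training
#'   split (the rest estimate candidate error).
#' @param weights Scalar-fitness weights (error, latency, params); must sum
#'   to 1.
#' @param seed Search seed.
#' @return An object of class \code{nas_config}.
#' @export
nas_config <- function(population = 20L, generations = 50L,
                       mutation_p = 0.2, crossover_p = 0.8,
                       proxy_epochs = 50L, proxy_subject_fraction = 0.8,
                       weights = c(0.6, 0.3, 0.1), seed = 1L) {
  stopifnot(population >= 2, generations >= 1,
            mutation_p >= 0, mutation_p <= 1,
            crossover_p >= 0, crossover_p <= 1,
            abs(sum(weights) - 1) < 1e-9, length(weights) == 3L)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 mutation_p = mutation_p, crossover_p = crossover_p,
                 proxy_epochs = as.integer(proxy_epochs),
                 proxy_subject_fraction = proxy_subject_fraction,
                 weights = weights, seed = as.integer(seed)),
            class = "nas_config")
}

#' Evaluate one candidate architecture
#'
#' Builds the model configuration from the genome; the error objective comes
#' from short supervised training on a subject-level proxy split (candidates
#' are trained on \code{proxy_subject_fraction} of the subjects and scored on
#' the held-out proxy subjects), the latency objective is the deterministic
#' MAC surrogate, and the params objective is the exact total parameter
#' count. With \code{proxy_epochs = 0} the untrained network is scored
#' (useful for smoke runs).
#'
#' @param g A \code{nas_genome}.
#' @param proxy A multi-subject [trial_set()].
#' @param cfg A [nas_config()].
#' @param base A [model_config()] for the non-searched fields.
#' @param train_cfg A [train_config()] template for proxy training.
#' @return List with \code{error}, \code{latency}, \code{params}.
#' @export
evaluate_candidate <- function(g, proxy, cfg = nas_config(),
                               base = model_config(),
                               train_cfg = train_config()) {
  config <- genome_to_config(g, base)
  latency <- estimate_macs(config)$total
  params <- count_parameters(config)$total
  subjects <- unique(proxy$subject_ids)
  seed <- derive_seed(cfg$seed, "cand", genome_key(g))
  if (length(subjects) >= 2L) {
    n_train <- max(1L, round(cfg$proxy_subject_fraction * length(subjects)))
    train_subj <- with_seed(seed, sample(subjects, n_train))
    hold <- setdiff(subjects, train_subj)
    if (length(hold) == 0L) {
      hold <- train_subj[length(train_subj)]
      train_subj <- setdiff(train_subj, hold)
    }
    tr_ts <- subset_trials(proxy, which(proxy$subject_ids %in% train_subj))
    te_ts <- subset_trials(proxy, which(proxy$subject_ids %in% hold))
  } else {
    sp <- stratified_split(proxy, 0.7, seed)
    tr_ts <- subset_trials(proxy, sp$first)
    te_ts <- subset_trials(proxy, sp$second)
  }
  model <- mi_model(config, seed = seed)
  if (cfg$proxy_epochs > 0L) {
    cv <- carve_validation(tr_ts, 0.25, derive_seed(seed, "val"))
    tcfg <- train_cfg
    tcfg$max_epochs <- cfg$proxy_epochs
    tcfg$early_stop_patience <- min(tcfg$early_stop_patience,
                                    cfg$proxy_epochs)
    tcfg$seed <- seed
    model <- train_supervised(model, cv$train, cv$val, tcfg)$model
  }
  acc <- evaluate_model(model, te_ts)$accuracy
  list(error = 1 - acc, latency = latency, params = params)
}

#' Objective bounds over the search space
#'
#' Exact (closed-form) minima and maxima of the latency and parameter
#' objectives over all valid genomes, for min-max normalization of the
#' scalar fitness.
#'
#' @param base A [model_config()] for the non-searched fields.
#' @return List with \code{latency} and \code{params}, each c(min, max).
#' @export
nas_bounds <- function(base = model_config()) {
  genomes <- enumerate_genomes()
  lat <- vapply(genomes, function(g)
    estimate_macs(genome_to_config(g, base))$total, numeric(1))
  par <- vapply(genomes, function(g)
    count_parameters(genome_to_config(g, base))$total, numeric(1))
  list(latency = range(lat), params = range(par))
}

#' Scalar fitness of an objective triple
#'
#' score = w1 * error + w2 * latency_norm + w3 * params_norm, with latency
#' and parameter counts min-max normalized to [0, 1] over the search-space
#' bounds. Used for logging and selection tie-breaks; survival follows
#' NSGA-II rank + crowding.
#'
#' @param o Objectives list (\code{error}, \code{latency}, \code{params}).
#' @param weights Length-3 weights summing to 1.
#' @param bounds Bounds from [nas_bounds()].
#' @return The scalar score.
#' @export
scalar_fitness <- function(o, weights = c(0.6, 0.3, 0.1),
                           bounds = nas_bounds()) {
  stopifnot(abs(sum(weights) - 1) < 1e-9)
  norm <- function(x, r) if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else 0
  weights[1] * o$error + weights[2] * norm(o$latency, bounds$latency) +
    weights[3] * norm(o$params, bounds$params)
}

# a dominates b iff a is no worse in every objective and better in one.
dominates <- function(a, b) all(a <= b) && any(a < b)

#' Fast non-dominated sorting
#'
#' Deb's algorithm: partitions candidates into Pareto fronts (front 1 is the
#' non-dominated set) under minimization of all columns.
#'
#' @param objmat Numeric matrix, one row per candidate, one column per
#'   objective.
#' @return List of integer index vectors, one per front.
#' @export
fast_non_dominated_sort <- function(objmat) {
  n <- nrow(objmat)
  S <- vector("list", n)
  counts <- integer(n)
  fronts <- list()
  first <- integer()
  for (i in seq_len(n)) {
    S[[i]] <- integer()
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(objmat[i, ], objmat[j, ])) S[[i]] <- c(S[[i]], j)
      else if (dominates(objmat[j, ], objmat[i, ])) counts[i] <- counts[i] + 1L
    }
    if (counts[i] == 0L) first <- c(first, i)
  }
  fronts[[1]] <- first
  k <- 1L
  while (length(fronts[[k]]) > 0L) {
    nxt <- integer()
    for (i in fronts[[k]]) {
      for (j in S[[i]]) {
        counts[j] <- counts[j] - 1L
        if (counts[j] == 0L) nxt <- c(nxt, j)
      }
    }
    k <- k + 1L
    fronts[[k]] <- nxt
  }
  fronts[lengths(fronts) > 0L]
}

#' Crowding distance within one front
#'
#' Per-objective normalized gap between each candidate's neighbors on the
#' sorted front; boundary candidates get infinite distance.
#'
#' @param objmat Objective matrix restricted to one front.
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(objmat) {
  n <- nrow(objmat)
  if (n <= 2L) return(rep(Inf, n))
  dist <- numeric(n)
  for (m in seq_len(ncol(objmat))) {
    ord <- order(objmat[, m])
    rng <- objmat[ord[n], m] - objmat[ord[1], m]
    dist[ord[1]] <- Inf
    dist[ord[n]] <- Inf
    if (rng > 0) {
      for (i in 2:(n - 1L)) {
        dist[ord[i]] <- dist[ord[i]] +
          (objmat[ord[i + 1L], m] - objmat[ord[i - 1L], m]) / rng
      }
    }
  }
  dist
}

obj_to_row <- function(o) c(o$error, o$latency, o$params)

#' NSGA-II architecture search
#'
#' Standard generational loop: binary tournament selection on (rank,
#' crowding distance), uniform crossover and per-gene mutation, elitist
#' merge of parents and offspring with front-wise survival. Every genome is
#' evaluated at most once (evaluations are cached by genome). Deterministic
#' under a fixed \code{cfg$seed}.
#'
#' @param cfg A [nas_config()].
#' @param proxy A proxy [trial_set()] (ignored when \code{evaluate} is
#'   supplied).
#' @param evaluate Optional objective function \code{function(genome) ->
#'   list(error, latency, params)}; defaults to [evaluate_candidate()] on
#'   \code{proxy}.
#' @param base A [model_config()] for non-searched fields.
#' @param train_cfg Proxy-training template.
#' @return List with \code{front} (list of \code{list(genome, objectives,
#'   fitness)}), \code{history} (per-generation best/mean scalar fitness),
#'   \code{n_evaluations}, and \code{cache_hits}.
#' @export
nsga2_search <- function(cfg = nas_config(), proxy = NULL, evaluate = NULL,
                         base = model_config(), train_cfg = train_config()) {
  if (is.null(evaluate)) {
    if (is.null(proxy)) stop("either a proxy trial_set or an evaluate function is required")
    evaluate <- function(g) evaluate_candidate(g, proxy, cfg, base, train_cfg)
  }
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L; n_hit <- 0L
  eval_cached <- function(g) {
    key <- genome_key(g)
    if (!is.null(cache[[key]])) {
      n_hit <<- n_hit + 1L
      return(cache[[key]])
    }
    o <- evaluate(g)
    n_eval <<- n_eval + 1L
    cache[[key]] <- o
    o
  }
  bounds <- nas_bounds(base)

  set.seed(cfg$seed)
  pop <- lapply(seq_len(cfg$population), function(i) sample_genome())
  objs <- lapply(pop, eval_cached)
  history <- data.frame()

  rank_crowd <- function(objmat) {
    fronts <- fast_non_dominated_sort(objmat)
    rank <- integer(nrow(objmat))
    crowd <- numeric(nrow(objmat))
    for (fi in seq_along(fronts)) {
      idx <- fronts[[fi]]
      rank[idx] <- fi
      crowd[idx] <- crowding_distance(objmat[idx, , drop = FALSE])
    }
    list(rank = rank, crowd = crowd, fronts = fronts)
  }

  for (gen in seq_len(cfg$generations)) {
    objmat <- do.call(rbind, lapply(objs, obj_to_row))
    rc <- rank_crowd(objmat)
    tournament <- function() {
      cand <- sample(length(pop), 2L)
      a <- cand[1]; b <- cand[2]
      if (rc$rank[a] < rc$rank[b]) a
      else if (rc$rank[b] < rc$rank[a]) b
      else if (rc$crowd[a] >= rc$crowd[b]) a else b
    }
    children <- list()
    while (length(children) < cfg$population) {
      p1 <- pop[[tournament()]]
      p2 <- pop[[tournament()]]
      kids <- crossover_genomes(p1, p2, cfg$crossover_p)
      kids <- lapply(kids, mutate_genome, p_mut = cfg$mutation_p)
      children <- c(children, kids)
    }
    children <- children[seq_len(cfg$population)]
    child_objs <- lapply(children, eval_cached)

    all_pop <- c(pop, children)
    all_objs <- c(objs, child_objs)
    # deduplicate by genome: in a small discrete space duplicates otherwise
    # crowd unique front members out of the survival selection
    keys <- vapply(all_pop, genome_key, character(1))
    uniq <- !duplicated(keys)
    all_pop <- all_pop[uniq]
    all_objs <- all_objs[uniq]
    tries <- 0L
    while (length(all_pop) < cfg$population && tries < 200L) {
      tries <- tries + 1L
      g <- sample_genome()
      if (genome_key(g) %in% vapply(all_pop, genome_key, character(1))) next
      all_pop <- c(all_pop, list(g))
      all_objs <- c(all_objs, list(eval_cached(g)))
    }
    allmat <- do.call(rbind, lapply(all_objs, obj_to_row))
    rc_all <- rank_crowd(allmat)
    keep <- integer()
    for (idx in rc_all$fronts) {
      if (length(keep) + length(idx) <= cfg$population) {
        keep <- c(keep, idx)
      } else {
        need <- cfg$population - length(keep)
        cd <- rc_all$crowd[idx]
        keep <- c(keep, idx[order(cd, decreasing = TRUE)][seq_len(need)])
        break
      }
    }
    pop <- all_pop[keep]
    objs <- all_objs[keep]
    fits <- vapply(objs, scalar_fitness, numeric(1),
                   weights = cfg$weights, bounds = bounds)
    history <- rbind(history, data.frame(
      generation = gen, best_fitness = min(fits), mean_fitness = mean(fits),
      evaluations = n_eval, cache_hits = n_hit))
  }

  objmat <- do.call(rbind, lapply(objs, obj_to_row))
  front_idx <- fast_non_dominated_sort(objmat)[[1]]
  # deduplicate identical genomes on the returned front
  seen <- character()
  front <- list()
  for (i in front_idx) {
    key <- genome_key(pop[[i]])
    if (key %in% seen) next
    seen <- c(seen, key)
    front[[length(front) + 1L]] <- list(
      genome = pop[[i]], objectives = objs[[i]],
      fitness = scalar_fitness(objs[[i]], cfg$weights, bounds))
  }
  list(front = front, history = history, n_evaluations = n_eval,
       cache_hits = n_hit)
}
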