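test_that("sampled genomes stay in the (repaired) search space", {
  space <- nas_space()
  set.seed(71)
  for (i in 1:200) {
    g <- sample_genome()
    expect_true(g$dh %in% space$dh)
    expect_true(g$L %in% space$L)
    expect_true(g$h %in% space$h)
    expect_true(g$p %in% space$p)
    expect_true(g$d %in% space$d)
    expect_identical(g$d %% g$h, 0L)
  }
  expect_identical(sample_genome(seed = 5), sample_genome(seed = 5))
  # gene marginals roughly uniform (chi-square sanity on dh)
  set.seed(72)
  dhs <- vapply(1:1000, function(i) sample_genome()$dh, integer(1))
  expect_gt(stats::chisq.test(table(dhs))$p.value, 1e-4)
})

test_that("mutation and crossover respect their probabilities", {
  g <- sample_genome(seed = 1)
  expect_identical(mutate_genome(g, p_mut = 0, seed = 3), g)
  twins <- crossover_genomes(g, g, p_x = 1, seed = 4)
  expect_identical(twins[[1]], g)
  expect_identical(twins[[2]], g)
  untouched <- crossover_genomes(g, sample_genome(seed = 2), p_x = 0,
                                 seed = 5)
  expect_identical(untouched[[1]], g)

  # Monte-Carlo per-gene change rate: p_mut * (1 - 1/|set|) for genes whose
  # candidate set is free of repair (use L and p; h/d interact via repair)
  set.seed(73)
  n <- 10000
  base <- new_genome <- midecode:::new_genome(128, 2, 4, 20, 128)
  changed_L <- 0; changed_p <- 0
  for (i in seq_len(n)) {
    m <- mutate_genome(base, p_mut = 0.2)
    changed_L <- changed_L + (m$L != base$L)
    changed_p <- changed_p + (m$p != base$p)
  }
  expected <- 0.2 * (1 - 1 / 3)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(changed_L / n - expected), 3 * se + 1e-9)
  expect_lt(abs(changed_p / n - expected), 3 * se + 1e-9)
})

test_that("genome-derived configurations count parameters exactly", {
  # the reference optimum: dh=128, L=2, h=4, p=24 (s=12), d=128
  g <- midecode:::new_genome(128, 2, 4, 24, 128)
  cfg <- genome_to_config(g)
  expect_identical(cfg$stride, 12L)
  expect_identical(as.integer(count_parameters(cfg)$total), 1866212L)

  # params objective is monotone in the embedding dimension
  totals <- vapply(nas_space()$d, function(d) {
    count_parameters(genome_to_config(
      midecode:::new_genome(128, 2, 4, 24, d)))$total
  }, numeric(1))
  expect_true(all(diff(totals) > 0))
})

test_that("candidate evaluation ties objectives to the accounting functions", {
  ds <- fixture_dataset()
  g <- midecode:::new_genome(64, 1, 2, 16, 64)
  base <- compact_model_config()
  cfg <- nas_config(proxy_epochs = 0L, seed = 3)
  o <- evaluate_candidate(g, ds, cfg, base = base)
  built <- genome_to_config(g, base)
  expect_identical(o$params, count_parameters(built)$total)
  expect_identical(o$latency, estimate_macs(built)$total)
  expect_gte(o$error, 0)
  expect_lte(o$error, 1)
})

test_that("scalar fitness normalizes and weights objectives", {
  bounds <- list(latency = c(0, 10), params = c(0, 100))
  expect_equal(scalar_fitness(list(error = 0, latency = 0, params = 0),
                              c(0.6, 0.3, 0.1), bounds), 0)
  expect_equal(scalar_fitness(list(error = 0.5, latency = 10, params = 100),
                              c(0.6, 0.3, 0.1), bounds), 0.7)
  expect_error(scalar_fitness(list(error = 0, latency = 0, params = 0),
                              c(0.5, 0.3, 0.1), bounds))
  expect_error(nas_config(weights = c(0.5, 0.4, 0.2)))
})

test_that("non-dominated sorting agrees with a brute-force Pareto filter", {
  brute_front <- function(m) {
    which(vapply(seq_len(nrow(m)), function(i) {
      !any(vapply(seq_len(nrow(m)), function(j) {
        j != i && all(m[j, ] <= m[i, ]) && any(m[j, ] < m[i, ])
      }, logical(1)))
    }, logical(1)))
  }
  expect_identical(fast_non_dominated_sort(matrix(c(1, 2, 3), 1))[[1]], 1L)
  two <- rbind(c(1, 1, 1), c(2, 2, 2))
  fr <- fast_non_dominated_sort(two)
  expect_identical(fr[[1]], 1L)
  expect_identical(fr[[2]], 2L)
  for (seed in 1:20) {
    set.seed(seed)
    m <- matrix(runif(50 * 3), 50, 3)
    expect_setequal(fast_non_dominated_sort(m)[[1]], brute_front(m))
  }
})

test_that("crowding distance rewards boundary and isolated candidates", {
  m <- cbind(c(0, 0.5, 0.9, 1), c(1, 0.5, 0.1, 0))
  cd <- crowding_distance(m)
  expect_identical(cd[1], Inf)
  expect_identical(cd[4], Inf)
  expect_true(all(is.finite(cd[2:3])))
  expect_identical(crowding_distance(m[1:2, , drop = FALSE]), c(Inf, Inf))
})

test_that("the search recovers the exhaustive Pareto set of an analytic landscape", {
  # convex error in (p, d) plus the closed-form latency/params objectives:
  # the full 243-point (162 valid) space is enumerable, giving a global oracle
  analytic <- function(g) {
    cfgg <- genome_to_config(g, compact_model_config())
    list(error = 0.2 + ((g$p - 24) / 8)^2 + ((log2(g$d) - 7) / 2)^2 +
           0.05 * (g$L - 1),
         latency = estimate_macs(cfgg)$total,
         params = count_parameters(cfgg)$total)
  }
  all_g <- enumerate_genomes()
  allmat <- do.call(rbind, lapply(all_g, function(g)
    midecode:::obj_to_row(analytic(g))))
  oracle_keys <- sort(unique(vapply(
    all_g[fast_non_dominated_sort(allmat)[[1]]],
    midecode:::genome_key, character(1))))

  cfg <- nas_config(population = 20, generations = 10, seed = 11)
  sr <- nsga2_search(cfg, evaluate = analytic, base = compact_model_config())
  found_keys <- sort(vapply(sr$front, function(f)
    midecode:::genome_key(f$genome), character(1)))
  expect_setequal(found_keys, oracle_keys)

  # internal non-domination of the returned front
  fmat <- do.call(rbind, lapply(sr$front, function(f)
    midecode:::obj_to_row(f$objectives)))
  expect_length(fast_non_dominated_sort(fmat), 1)

  # evaluation budget: each unique genome evaluated at most once
  expect_lte(sr$n_evaluations, cfg$population * (cfg$generations + 1))
  expect_lte(sr$n_evaluations, length(all_g))
  expect_gt(sr$cache_hits, 0)

  # determinism under a fixed seed
  sr2 <- nsga2_search(cfg, evaluate = analytic,
                      base = compact_model_config())
  expect_identical(found_keys,
                   sort(vapply(sr2$front, function(f)
                     midecode:::genome_key(f$genome), character(1))))
})
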