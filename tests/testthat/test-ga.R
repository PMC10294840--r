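test_that("initial population satisfies the chromosome invariants", {
  cfg <- ga_config(population_size = 40, chromosome_length = 192,
                   max_generations = 0)
  withr::with_seed(1, {
    pop <- init_population(cfg, n_channels = 512)
    expect_equal(dim(pop$genes), c(40, 192))
    for (i in 1:40) {
      g <- pop$genes[i, ]
      expect_false(anyDuplicated(g) > 0)
      expect_true(all(g >= 1 & g <= 512))
    }
  })
  # chromosome length equal to channel count forces the full index set
  full <- withr::with_seed(2, init_population(
    ga_config(population_size = 5, chromosome_length = 6), n_channels = 6))
  for (i in 1:5) expect_setequal(full$genes[i, ], 1:6)
  expect_error(init_population(ga_config(chromosome_length = 10),
                               n_channels = 6), "exceeds")
  expect_identical(withr::with_seed(3, init_population(cfg, 512)),
                   withr::with_seed(3, init_population(cfg, 512)))
})

test_that("fitness rewards chromosomes holding the planted channels", {
  ft <- planted_features(600, 6, 2, effect_size = 2, seed = 13)
  est <- list(split = split_indices(ft_labels(ft), seed = 13),
              cost = 1, standardize = TRUE)
  planted <- informative_channels(ft)
  nulls <- setdiff(1:6, planted)
  expect_gt(evaluate_fitness(planted, ft, est),
            evaluate_fitness(nulls[1:2], ft, est))
})

test_that("constant labels give prevalence fitness; all channels give the baseline", {
  x <- matrix(rnorm(60), 20, 3)
  ft <- feature_table(x, c(rep(1L, 12), rep(0L, 4), rep(1L, 4)))
  est <- list(split = list(train = 1:12, test = 13:20), cost = 1,
              standardize = TRUE)
  expect_equal(evaluate_fitness(1:3, ft, est), mean(ft_labels(ft)[13:20] == 1))

  ft2 <- planted_features(150, 5, 2, effect_size = 1, seed = 17)
  split <- split_indices(ft_labels(ft2), seed = 17)
  est2 <- list(split = split, cost = 1, standardize = TRUE)
  expect_equal(evaluate_fitness(1:5, ft2, est2), svm_accuracy(ft2, split))
})

test_that("parent selection follows the fitness weights", {
  pop <- list(genes = matrix(1:12, 4, 3), fitness = c(1, 0, 0, 0))
  withr::local_seed(1)
  picks <- select_parents(pop, "proportionate", n_pairs = 50)
  expect_true(all(picks == 1))

  pop$fitness <- rep(0.5, 4)
  freq <- tabulate(select_parents(pop, "proportionate", n_pairs = 5000), 4)
  expect_true(all(abs(freq / 10000 - 0.25) < 0.02))

  pop2 <- list(genes = matrix(1:6, 2, 3), fitness = c(0.75, 0.25))
  freq2 <- tabulate(select_parents(pop2, "proportionate", n_pairs = 5000), 2)
  expect_lt(abs(freq2[1] / 10000 - 0.75), 0.02)

  # rank selection never inverts the ordering
  pop3 <- list(genes = matrix(1:9, 3, 3), fitness = c(0.9, 0.6, 0.3))
  freq3 <- tabulate(select_parents(pop3, "rank", n_pairs = 3000), 3)
  expect_true(all(diff(freq3) < 0))

  pop$fitness <- rep(0, 4)
  expect_warning(select_parents(pop, "proportionate", n_pairs = 10),
                 "uniform")
})

test_that("uniform crossover routes genes positionwise and repairs duplicates", {
  p1 <- c(1L, 2L, 3L); p2 <- c(4L, 5L, 6L)
  kids <- withr::with_seed(1, uniform_crossover(p1, p2, cr = 1, n_channels = 6))
  expect_identical(kids$child1, p1)
  expect_identical(kids$child2, p2)

  same <- withr::with_seed(2, uniform_crossover(p1, p1, cr = 0.5, n_channels = 6))
  expect_identical(same$child1, p1)
  expect_identical(same$child2, p1)

  # without repair, each position holds exactly the two parental genes
  for (s in 1:50) {
    kids <- withr::with_seed(s, uniform_crossover(p1, p2, cr = 0.5,
                                                  n_channels = 6,
                                                  repair = FALSE))
    for (i in 1:3) {
      expect_setequal(c(kids$child1[i], kids$child2[i]), c(p1[i], p2[i]))
    }
  }

  # overlapping parents: repair restores distinctness without losing length,
  # and only introduces genes absent from the unrepaired child
  q1 <- c(1L, 2L, 3L); q2 <- c(3L, 4L, 5L)
  for (s in 1:50) {
    withr::local_seed(s)
    raw <- uniform_crossover(q1, q2, cr = 0.5, n_channels = 6, repair = FALSE)
    withr::local_seed(s)
    rep_kids <- uniform_crossover(q1, q2, cr = 0.5, n_channels = 6)
    for (side in c("child1", "child2")) {
      child <- rep_kids[[side]]
      expect_length(child, 3)
      expect_false(anyDuplicated(child) > 0)
      expect_true(all(child %in% 1:6))
      # repair replaced exactly the duplicated positions and kept the rest
      expect_true(all(unique(raw[[side]]) %in% child))
      expect_length(setdiff(child, raw[[side]]), sum(duplicated(raw[[side]])))
    }
  }
})

test_that("mutation preserves uniqueness and respects MR", {
  g <- c(2L, 5L, 7L)
  expect_identical(withr::with_seed(1, mutate_chromosome(g, 0, 10)), g)
  # no foreign index exists: forced identity even at MR = 1
  full <- 1:6
  expect_identical(withr::with_seed(1, mutate_chromosome(full, 1, 6)), full)

  withr::local_seed(3)
  replaced <- 0
  for (i in 1:1000) {
    out <- mutate_chromosome(c(1L, 2L), 1, 10)
    expect_false(anyDuplicated(out) > 0)
    expect_true(all(out >= 1 & out <= 10))
    replaced <- replaced + sum(out != c(1L, 2L))
  }
  expect_equal(replaced / 2000, 1)  # every gene replaced at MR = 1
})

test_that("elitist replacement makes best fitness non-decreasing", {
  ft <- tiny_planted(seed = 4)
  fit <- run_ga(ft, ga_config(population_size = 10, chromosome_length = 2,
                              max_generations = 15), seed = 4)
  expect_false(is.unsorted(fit$trace$best_fitness))
  # invariants hold for the final population and every best snapshot
  for (i in seq_len(nrow(fit$population$genes))) {
    g <- fit$population$genes[i, ]
    expect_length(unique(g), 2)
    expect_true(all(g %in% 1:6))
  }
  for (g in fit$trace$best_genes) expect_false(anyDuplicated(g) > 0)

  # constant fitness landscape: best fitness never moves
  flat <- feature_table(matrix(rnorm(40 * 4), 40, 4), rep(1L, 40))
  flat_fit <- run_ga(flat, ga_config(population_size = 8,
                                     chromosome_length = 2,
                                     max_generations = 10), seed = 1)
  expect_true(all(flat_fit$trace$best_fitness == flat_fit$trace$best_fitness[1]))
})

test_that("runs are exactly replayable and max_generations = 0 returns the initial best", {
  ft <- tiny_planted(seed = 6)
  cfg <- ga_config(population_size = 8, chromosome_length = 2,
                   max_generations = 10)
  f1 <- run_ga(ft, cfg, seed = 99)
  f2 <- run_ga(ft, cfg, seed = 99)
  expect_identical(f1$best_genes, f2$best_genes)
  expect_identical(f1$trace, f2$trace)

  f0 <- run_ga(ft, ga_config(population_size = 8, chromosome_length = 2,
                             max_generations = 0), seed = 5)
  expect_equal(nrow(f0$trace), 1)
  expect_equal(f0$trace$generation, 0L)
  expect_equal(f0$best_fitness, max(f0$population$fitness))
})

test_that("the GA finds the brute-force optimum on a tiny planted problem", {
  ft <- tiny_planted(seed = 12)
  fit <- run_ga(ft, ga_config(population_size = 12, chromosome_length = 2,
                              max_generations = 50), seed = 12)
  expect_equal(fit$best_fitness, brute_force_best(ft, 2, fit$estimator))
})

test_that("the GA recovers planted channels when accuracy does not saturate", {
  ft <- planted_features(240, 24, 4, effect_size = 1.5, seed = 1)
  fit <- run_ga(ft, ga_config(population_size = 20, chromosome_length = 4,
                              max_generations = 60), seed = 1)
  recall <- length(intersect(fit$best_genes, informative_channels(ft))) / 4
  expect_gte(recall, 0.5)  # random selection would average 4/24
})

test_that("the GA beats pure random search on the planted design", {
  ft <- planted_features(240, 24, 4, effect_size = 1.5, seed = 2)
  ga <- run_ga(ft, ga_config(population_size = 16, chromosome_length = 4,
                             max_generations = 50), seed = 2)
  # random search: no crossover, every gene resampled each generation
  rs <- run_ga(ft, ga_config(population_size = 16, chromosome_length = 4,
                             crossover_rate = 0, mutation_rate = 1,
                             max_generations = 50), seed = 2)
  expect_gt(ga$trace$mean_fitness[51], rs$trace$mean_fitness[51])
})

test_that("tidy, glance and autoplot summarise a fit", {
  fit <- run_ga(tiny_planted(seed = 3),
                ga_config(population_size = 8, chromosome_length = 2,
                          max_generations = 5), seed = 3)
  td <- tidy(fit)
  expect_named(td, c("generation", "best_fitness", "mean_fitness"))
  expect_equal(nrow(td), 6)
  gl <- glance(fit)
  expect_equal(gl$best_fitness, fit$best_fitness)
  expect_equal(gl$n_selected, 2)
  expect_s3_class(autoplot(fit), "ggplot")
})
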