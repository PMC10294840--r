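test_that("layer sweep statistics match a direct recomputation of its runs", {
  tabs <- list(only = planted_features(150, 4, 2, effect_size = 1, seed = 31))
  sw <- layer_sweep(tabs, n_runs = 4, seed = 2)
  runs <- attr(sw, "runs")
  expect_equal(nrow(runs), 4)
  expect_equal(sw$mean, mean(runs$accuracy))
  expect_equal(sw$max, max(runs$accuracy))
  expect_equal(sw$min, min(runs$accuracy))
  expect_equal(sw$median, median(runs$accuracy))
  expect_equal(sw$std, sd(runs$accuracy))
  expect_true(sw$min <= sw$median && sw$median <= sw$max)

  one <- layer_sweep(tabs, n_runs = 1, seed = 2)
  expect_equal(one$std, 0)  # reported as 0 by convention for a single run
  expect_s3_class(autoplot(sw), "ggplot")
})

test_that("sweep ranking follows the planted effect size", {
  tabs <- list(
    weak = planted_features(2000, 6, 3, effect_size = 0.2, seed = 1),
    mid = planted_features(2000, 6, 3, effect_size = 0.6, seed = 2),
    strong = planted_features(2000, 6, 3, effect_size = 1.5, seed = 3)
  )
  sw <- layer_sweep(tabs, n_runs = 5, seed = 5)
  expect_equal(sw$layer, c("strong", "mid", "weak"))
  expect_equal(sw$rank, 1:3)
})

test_that("multirun results are seeded and counted correctly", {
  ft <- planted_features(150, 5, 2, effect_size = 1, seed = 41)
  a <- multirun_ga(ft, n_runs = 20, mode = "baseline_all_maps", seed = 3)
  b <- multirun_ga(ft, n_runs = 20, mode = "baseline_all_maps", seed = 3)
  expect_equal(nrow(a$runs), 20)
  expect_identical(a$runs$accuracy, b$runs$accuracy)
  expect_equal(a$summary$mean, mean(a$runs$accuracy))
  expect_equal(a$summary$std, sd(a$runs$accuracy))

  cfg <- ga_config(population_size = 6, chromosome_length = 2,
                   max_generations = 3)
  g <- multirun_ga(ft, cfg, n_runs = 2, mode = "ga_selected", seed = 4)
  expect_equal(nrow(g$runs), 2)
  expect_true(all(lengths(g$runs$chromosome) == 2))
  expect_s3_class(g$runs$trace[[1]], "tbl_df")
})

test_that("GA selection beats the all-maps baseline when noise channels dominate", {
  ft <- planted_features(320, 256, 8, effect_size = 1, seed = 7)
  cfg <- ga_config(population_size = 20, chromosome_length = 8,
                   max_generations = 30, fitness_folds = NULL)
  ga <- multirun_ga(ft, cfg, n_runs = 5, mode = "ga_selected", seed = 11)
  bl <- multirun_ga(ft, cfg, n_runs = 5, mode = "baseline_all_maps", seed = 11)
  expect_gte(ga$summary$mean, bl$summary$mean)
})

test_that("gain arithmetic reproduces the reference report exactly", {
  ref <- reference_layer_means()
  g <- gain_report(ref$proposed_mean, ref$baseline_mean, layer = ref$layer)
  expect_equal(g$difference,
               c(0.1732, 0.1636, 0.1615, 0.1436, 0.1359))
  expect_equal(g$gain_pct, c(25.28, 23.84, 23.72, 20.74, 19.73))
  same <- gain_report(0.7, 0.7)
  expect_equal(same$difference, 0)
  expect_equal(same$gain_pct, 0)
  expect_error(gain_report(0.8, 0), "baseline")
})

test_that("Wilcoxon signed-rank matches the exact null and the stats oracle", {
  expect_equal(wilcoxon_signed_rank(1:6 + 0.5, rep(0.5, 6)), 2 / 2^6)
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), 1)
  # cross-check against the independent base-R implementation (no ties)
  for (s in 1:6) {
    withr::local_seed(s)
    n <- sample(c(8, 12, 20), 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(wilcoxon_signed_rank(x, y),
                 suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                              exact = TRUE)$p.value))
    expect_equal(wilcoxon_signed_rank(x, y), wilcoxon_signed_rank(y, x))
  }
  # above the exact cutoff: normal approximation agrees with the oracle
  withr::local_seed(9)
  x <- rnorm(40); y <- rnorm(40, 0.3)
  expect_equal(wilcoxon_signed_rank(x, y),
               wilcox.test(x, y, paired = TRUE, exact = FALSE,
                           correct = TRUE)$p.value,
               tolerance = 1e-10)
  # zero differences are excluded before ranking
  expect_equal(wilcoxon_signed_rank(c(5, 5, 1:6), c(5, 5, rep(0, 6))), 2 / 2^6)
  expect_warning(wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0)), "fewer than 5")
  p <- suppressWarnings(wilcoxon_signed_rank(c(1, 2), c(3, 4)))
  expect_true(p > 0 && p <= 1)
})

test_that("the pairwise p-value matrix is symmetric with unit diagonal", {
  withr::local_seed(2)
  runs <- list(a = rnorm(12, 0.70, 0.02), b = rnorm(12, 0.72, 0.02),
               c = rnorm(12, 0.80, 0.02))
  m <- wilcoxon_matrix(runs)
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m, t(m))
  expect_true(all(m > 0 & m <= 1))
  mh <- wilcoxon_matrix(runs, holm = TRUE)
  expect_true(all(mh >= m))
})

test_that("relative computational time is a plain ratio", {
  expect_equal(ct_metric(10, 2), 5)
  expect_equal(ct_metric(3.3, 3.3), 1)
  # invariant under a uniform host slowdown
  expect_equal(ct_metric(10 * 7, 2 * 7), ct_metric(10, 2))
  expect_error(ct_metric(-1, 2), "positive")
  expect_error(ct_metric(1, 0), "positive")
  expect_gt(reference_benchmark(length = 1e5, passes = 5), 0)
})
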