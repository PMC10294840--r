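#' Genetic-algorithm configuration
#'
#' Control parameters of the subset search. Defaults are the published
#' operating point of the corneal-ulcer pipeline: population 40, chromosome
#' length 192 (maps kept out of 512), uniform crossover with CR = 0.5,
#' uniqueness-preserving mutation with MR = 0.1, and 1000 generations.
#'
#' Fitness is linear-SVM accuracy on the gene-indexed channels. By default
#' it is pooled stratified `fitness_folds`-fold cross-validated accuracy
#' within the table handed to [run_ga()] (use the training partition there to
#' avoid test-set leakage): pooling the fold predictions gives fitness a
#' resolution of one misclassification in the whole table, which keeps
#' selection pressure alive when accuracies saturate. Set
#' `fitness_folds = NULL` for a single internal stratified holdout
#' (`holdout_fraction`), or pass `fitness_split` to evaluate fitness on a
#' fixed, externally chosen split -- including the outer test split, if you
#' want the literal protocol in which selection sees test accuracy.
#'
#' @param population_size number of chromosomes (>= 2).
#' @param chromosome_length number of distinct feature-map indices per
#'   chromosome.
#' @param crossover_rate per-gene probability CR that the uniform crossover
#'   routes parent 1's gene to child 1.
#' @param mutation_rate per-gene probability MR of replacement by a uniform
#'   index not already in the chromosome.
#' @param max_generations number of generations.
#' @param selection `"proportionate"` (sampling probability proportional to
#'   fitness) or `"rank"` (proportional to fitness rank; useful when
#'   accuracies cluster tightly).
#' @param plateau_generations optional early stop: halt when the best
#'   fitness has not improved for this many generations (off by default).
#' @param fitness_folds number of stratified cross-validation folds for the
#'   fitness estimate (default 5); NULL switches to a single holdout.
#' @param holdout_fraction fraction of the table held out internally for
#'   fitness evaluation when `fitness_folds` and `fitness_split` are NULL.
#' @param fitness_split optional list with `train`/`test` indices on which
#'   every fitness is evaluated (overrides the other two).
#' @param cost,standardize passed to the SVM ([train_svm()]).
#' @return list of class `ga_config`.
#' @export
ga_config <- function(population_size = 40, chromosome_length = 192,
                      crossover_rate = 0.5, mutation_rate = 0.1,
                      max_generations = 1000,
                      selection = c("proportionate", "rank"),
                      plateau_generations = NULL, fitness_folds = 5,
                      holdout_fraction = 0.3, fitness_split = NULL,
                      cost = 1, standardize = TRUE) {
  selection <- match.arg(selection)
  stopifnot(population_size >= 2, chromosome_length >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            max_generations >= 0,
            is.null(fitness_folds) || fitness_folds >= 2,
            holdout_fraction > 0, holdout_fraction < 1)
  structure(list(
    population_size = as.integer(population_size),
    chromosome_length = as.integer(chromosome_length),
    crossover_rate = crossover_rate, mutation_rate = mutation_rate,
    max_generations = as.integer(max_generations), selection = selection,
    plateau_generations = plateau_generations,
    fitness_folds = fitness_folds,
    holdout_fraction = holdout_fraction, fitness_split = fitness_split,
    cost = cost, standardize = standardize
  ), class = "ga_config")
}

#' Fitness estimator: the data and settings every chromosome is scored on
#'
#' Fixes the evaluation design (stratified cross-validation folds or a single
#' stratified holdout, drawn once) and the SVM settings so that fitness is a
#' deterministic function of the gene set for the whole run.
#'
#' @param table the feature table fitness is computed on.
#' @param config a [ga_config()].
#' @return list with either `folds` (fold id per sample) or `split`
#'   (`train`/`test` indices), plus `cost` and `standardize`.
#' @export
fitness_estimator <- function(table, config = ga_config()) {
  est <- list(cost = config$cost, standardize = config$standardize)
  if (!is.null(config$fitness_split)) {
    est$split <- config$fitness_split
  } else if (!is.null(config$fitness_folds)) {
    est$folds <- stratified_folds(ft_labels(table), config$fitness_folds)
  } else {
    est$split <- split_indices(ft_labels(table),
                               train_fraction = 1 - config$holdout_fraction,
                               stratified = TRUE)
  }
  est
}

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) abort("a class has fewer samples than fitness folds.")
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Fitness of a chromosome
#'
#' Accuracy of a linear SVM trained and evaluated on exactly the gene-indexed
#' channels under the estimator's fixed design: pooled accuracy over the
#' cross-validation folds (one prediction per sample), or test accuracy of
#' the single split. If a training fold holds a single class, the
#' majority-class predictor is scored for that fold (its accuracy is the
#' class's prevalence in the evaluation fold).
#'
#' @param genes integer vector of distinct channel indices (a chromosome).
#' @param table feature table whose columns the genes index.
#' @param estimator a [fitness_estimator()].
#' @return fitness in [0, 1].
#' @export
evaluate_fitness <- function(genes, table, estimator) {
  key <- NULL
  if (!is.null(estimator$cache)) {
    # fitness is deterministic given the estimator, so per-run memoization
    # by gene set is exact
    key <- paste(sort(genes), collapse = ",")
    hit <- estimator$cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  value <- evaluate_fitness_impl(genes, table, estimator)
  if (!is.null(key)) estimator$cache[[key]] <- value
  value
}

evaluate_fitness_impl <- function(genes, table, estimator) {
  channels <- channel_ids(table)[genes]
  if (!is.null(estimator$folds)) {
    y <- ft_labels(table)
    correct <- 0L
    for (f in sort(unique(estimator$folds))) {
      split <- list(train = which(estimator$folds != f),
                    test = which(estimator$folds == f))
      correct <- correct + split_correct(table, split, channels, estimator)
    }
    return(correct / length(y))
  }
  split_correct(table, estimator$split, channels, estimator) /
    length(estimator$split$test)
}

# number of correctly classified test samples for one split
split_correct <- function(table, split, channels, estimator) {
  y <- ft_labels(table)
  if (length(unique(y[split$train])) < 2) {
    return(sum(y[split$test] == y[split$train][1]))
  }
  model <- train_svm(table, split$train, channels = channels,
                     cost = estimator$cost,
                     standardize = estimator$standardize)
  pred <- predict(model, table, indices = split$test)
  sum(pred == y[split$test])
}

#' Random initial population
#'
#' Each chromosome is a uniform random sample of `chromosome_length`
#' distinct indices from `1:n_channels`; all fitnesses are evaluated.
#'
#' @param config a [ga_config()].
#' @param n_channels number of available feature maps.
#' @param table,estimator data and estimator used to evaluate fitness; if
#'   `table` is NULL the population is returned unevaluated (fitness NA).
#' @return list with `genes` (matrix, one chromosome per row) and `fitness`.
#' @export
init_population <- function(config, n_channels, table = NULL,
                            estimator = NULL) {
  if (config$chromosome_length > n_channels) {
    abort("chromosome_length exceeds the number of available channels.")
  }
  genes <- t(vapply(seq_len(config$population_size), function(i) {
    sample.int(n_channels, config$chromosome_length)
  }, integer(config$chromosome_length)))
  fitness <- rep(NA_real_, config$population_size)
  if (!is.null(table)) {
    fitness <- vapply(seq_len(nrow(genes)), function(i) {
      evaluate_fitness(genes[i, ], table, estimator)
    }, numeric(1))
  }
  list(genes = genes, fitness = fitness)
}

#' Select parent pairs
#'
#' Fitness-proportionate (roulette-wheel) or rank-proportional sampling with
#' replacement. An all-zero fitness vector falls back to uniform sampling
#' with a warning.
#'
#' @param population list with `genes` and evaluated `fitness`.
#' @param scheme `"proportionate"` or `"rank"`.
#' @param n_pairs number of parent pairs to draw.
#' @return integer matrix `n_pairs x 2` of population row indices.
#' @export
select_parents <- function(population, scheme = "proportionate",
                           n_pairs = nrow(population$genes) %/% 2) {
  f <- population$fitness
  if (anyNA(f)) abort("population must be evaluated before selection.")
  if (any(f < 0)) abort("selection requires non-negative fitness.")
  w <- switch(scheme,
    proportionate = f,
    rank = rank(f, ties.method = "average"),
    abort(sprintf("unknown selection scheme '%s'.", scheme))
  )
  if (sum(w) <= 0) {
    warn("all fitnesses are zero; falling back to uniform parent sampling.")
    w <- rep(1, length(f))
  }
  matrix(sample.int(length(f), 2 * n_pairs, replace = TRUE, prob = w / sum(w)),
         ncol = 2)
}

#' Uniform crossover with uniqueness repair
#'
#' At each gene position a uniform draw routes parent 1's gene to child 1
#' and parent 2's to child 2 (draw < CR), or vice versa. Because the
#' chromosomes encode *sets*, positionwise routing of two distinct parents
#' can duplicate a gene within a child; with `repair = TRUE` (the default)
#' each duplicate is replaced by a uniform draw from the indices absent from
#' that child, restoring the distinctness invariant.
#'
#' @param p1,p2 parent chromosomes (equal-length integer vectors).
#' @param cr crossover rate CR.
#' @param n_channels total number of channels (needed for repair draws).
#' @param repair restore gene uniqueness (set FALSE only for diagnostics).
#' @return list with `child1` and `child2`.
#' @export
uniform_crossover <- function(p1, p2, cr = 0.5, n_channels, repair = TRUE) {
  stopifnot(length(p1) == length(p2))
  to1 <- runif(length(p1)) < cr
  child1 <- ifelse(to1, p1, p2)
  child2 <- ifelse(to1, p2, p1)
  if (repair) {
    child1 <- repair_duplicates(child1, n_channels)
    child2 <- repair_duplicates(child2, n_channels)
  }
  list(child1 = child1, child2 = child2)
}

repair_duplicates <- function(genes, n_channels) {
  dup <- which(duplicated(genes))
  if (length(dup) == 0) return(genes)
  pool <- setdiff(seq_len(n_channels), genes)
  replacement <- pool[sample.int(length(pool), length(dup))]
  genes[dup] <- replacement
  genes
}

#' Uniqueness-preserving mutation
#'
#' Each gene is, with probability MR, replaced by a uniformly chosen index
#' not currently present in the chromosome. When no replacement index exists
#' (chromosome spans all channels) the gene is left unchanged.
#'
#' @param genes chromosome (integer vector of distinct indices).
#' @param mr mutation rate MR.
#' @param n_channels total number of channels.
#' @return mutated chromosome; distinctness is preserved.
#' @export
mutate_chromosome <- function(genes, mr, n_channels) {
  hit <- which(runif(length(genes)) < mr)
  for (i in hit) {
    pool <- setdiff(seq_len(n_channels), genes)
    if (length(pool) == 0) next
    genes[i] <- pool[sample.int(length(pool), 1)]
  }
  genes
}

# deterministic ordering: fitness descending, ties by ascending lexicographic
# order of the sorted gene vectors
population_order <- function(genes, fitness) {
  key <- apply(genes, 1, function(g) paste(sprintf("%06d", sort(g)), collapse = ""))
  order(-fitness, key)
}

#' One GA generation
#'
#' Selection, crossover and mutation produce `population_size` offspring,
#' which are evaluated; the combined parent+offspring pool is then truncated
#' to `population_size` by fitness. Truncation realizes both replacement of
#' the least fit and elitism (the best chromosome always survives), so best
#' fitness is non-decreasing.
#'
#' @param population evaluated population (`genes` + `fitness`).
#' @param config a [ga_config()].
#' @param table,estimator fitness data and estimator.
#' @return list with the new `population` and a one-row `record` tibble
#'   (best/mean fitness, best chromosome).
#' @export
step_generation <- function(population, config, table, estimator) {
  n_channels <- ncol(ft_matrix(table))
  n_pairs <- ceiling(config$population_size / 2)
  pairs <- select_parents(population, config$selection, n_pairs)
  offspring <- vector("list", 2 * n_pairs)
  for (k in seq_len(n_pairs)) {
    kids <- uniform_crossover(population$genes[pairs[k, 1], ],
                              population$genes[pairs[k, 2], ],
                              cr = config$crossover_rate,
                              n_channels = n_channels)
    offspring[[2 * k - 1]] <- mutate_chromosome(kids$child1,
                                                config$mutation_rate, n_channels)
    offspring[[2 * k]] <- mutate_chromosome(kids$child2,
                                            config$mutation_rate, n_channels)
  }
  offspring <- offspring[seq_len(config$population_size)]
  off_genes <- do.call(rbind, offspring)
  off_fitness <- vapply(seq_len(nrow(off_genes)), function(i) {
    evaluate_fitness(off_genes[i, ], table, estimator)
  }, numeric(1))
  genes <- rbind(population$genes, off_genes)
  fitness <- c(population$fitness, off_fitness)
  keep <- population_order(genes, fitness)[seq_len(config$population_size)]
  new_pop <- list(genes = genes[keep, , drop = FALSE], fitness = fitness[keep])
  record <- tibble::tibble(
    best_fitness = new_pop$fitness[1],
    mean_fitness = mean(new_pop$fitness),
    best_genes = list(sort(new_pop$genes[1, ]))
  )
  list(population = new_pop, record = record)
}

#' Run the genetic algorithm
#'
#' Full subset search: random initial population, then
#' selection/crossover/mutation/replacement for `max_generations`
#' generations (or until the optional plateau criterion fires). One seeded
#' generator drives every stochastic stage, so a run is exactly replayable.
#'
#' @param table feature table to select channels from (use the training
#'   partition; fitness is measured on an internal holdout unless
#'   `config$fitness_split` says otherwise).
#' @param config a [ga_config()].
#' @param seed integer seed for the whole run.
#' @return object of class `corneal_ga`: `best_genes` (sorted channel ids of
#'   the best chromosome ever seen), `best_fitness`, `trace` (tibble with one
#'   row per generation: `generation`, `best_fitness`, `mean_fitness`,
#'   `best_genes`), `population`, `estimator`, `config`, `seed`. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' ft <- planted_features(n_samples = 80, n_channels = 6, k_informative = 2,
#'                        effect_size = 4, seed = 1)
#' fit <- run_ga(ft, ga_config(population_size = 10, chromosome_length = 2,
#'                             max_generations = 5), seed = 1)
#' glance(fit)
run_ga <- function(table, config = ga_config(), seed = NULL) {
  n_channels <- ncol(ft_matrix(table))
  if (config$chromosome_length > n_channels) {
    abort("chromosome_length exceeds the table width.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  estimator <- fitness_estimator(table, config)
  estimator$cache <- new.env(parent = emptyenv())
  population <- init_population(config, n_channels, table, estimator)
  ord <- population_order(population$genes, population$fitness)
  trace <- tibble::tibble(
    generation = 0L,
    best_fitness = population$fitness[ord[1]],
    mean_fitness = mean(population$fitness),
    best_genes = list(sort(population$genes[ord[1], ]))
  )
  stall <- 0L
  for (g in seq_len(config$max_generations)) {
    stepped <- step_generation(population, config, table, estimator)
    population <- stepped$population
    rec <- stepped$record
    improved <- rec$best_fitness > trace$best_fitness[nrow(trace)]
    trace <- dplyr::bind_rows(trace, dplyr::mutate(rec, generation = g,
                                                   .before = 1))
    stall <- if (improved) 0L else stall + 1L
    if (!is.null(config$plateau_generations) &&
        stall >= config$plateau_generations) break
  }
  best_row <- which.max(trace$best_fitness)
  structure(list(
    best_genes = channel_ids(table)[trace$best_genes[[best_row]]],
    best_fitness = trace$best_fitness[best_row],
    trace = trace,
    population = population,
    estimator = estimator,
    config = config,
    seed = seed
  ), class = "corneal_ga")
}

#' @export
print.corneal_ga <- function(x, ...) {
  cat(sprintf(
    "<corneal_ga> %d generations, best fitness %.4f, %d selected maps\n",
    max(x$trace$generation), x$best_fitness, length(x$best_genes)))
  invisible(x)
}
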