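#' Subset the rows of a feature table
#'
#' Keeps channel/layer provenance attributes, which plain `[`-subsetting of a
#' tibble would drop.
#'
#' @param table a [feature_table()].
#' @param rows integer row indices.
#' @return a feature table with the selected rows.
#' @export
ft_rows <- function(table, rows) {
  out <- feature_table(ft_matrix(table)[rows, , drop = FALSE],
                       ft_labels(table)[rows],
                       channel_ids = channel_ids(table),
                       layer = attr(table, "layer"))
  attr(out, "informative_channels") <- attr(table, "informative_channels")
  out
}

#' Layer sweep: baseline accuracy statistics per layer
#'
#' The first stage of the protocol: for every candidate layer, all channel
#' means are fed to the linear SVM (no selection) over `n_runs` independent
#' stratified 70/30 splits, and min/max/mean/median/std of the accuracy are
#' tabulated. Layers are ranked by mean accuracy (descending, ties broken by
#' layer name).
#'
#' @param tables named list of feature tables, one per layer.
#' @param n_runs number of independent runs per layer (default 20); each run
#'   re-draws the split with its own seed.
#' @param train_fraction training fraction of each split.
#' @param seed base seed; run `r` uses `seed + r - 1`.
#' @param cost,standardize SVM settings.
#' @return A tibble of class `layer_sweep` with columns `rank`, `layer`,
#'   `mean`, `max`, `min`, `median`, `std` (0 by convention when
#'   `n_runs = 1`); the per-run accuracies are in the `runs` attribute.
#' @export
layer_sweep <- function(tables, n_runs = 20, train_fraction = 0.7, seed = 1,
                        cost = 1, standardize = TRUE) {
  stopifnot(n_runs >= 1, length(tables) >= 1, !is.null(names(tables)))
  seeds <- seed + seq_len(n_runs) - 1
  runs <- purrr::imap_dfr(tables, function(tbl, nm) {
    labels <- ft_labels(tbl)
    acc <- vapply(seeds, function(s) {
      svm_accuracy(tbl, split_indices(labels, train_fraction, seed = s),
                   cost = cost, standardize = standardize)
    }, numeric(1))
    tibble::tibble(layer = nm, run = seq_len(n_runs), seed = seeds,
                   accuracy = acc)
  })
  report <- runs |>
    dplyr::group_by(layer) |>
    dplyr::summarise(
      mean = mean(accuracy), max = max(accuracy), min = min(accuracy),
      median = stats::median(accuracy),
      std = if (dplyr::n() > 1) sd(accuracy) else 0,
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(mean), layer) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  attr(report, "runs") <- runs
  class(report) <- c("layer_sweep", class(report))
  report
}

#' Repeated runs of the GA pipeline (or its no-selection baseline)
#'
#' Each run draws an independent stratified 70/30 split; in `"ga_selected"`
#' mode the GA searches the training partition (fitness on an internal
#' holdout of that partition) and the best chromosome's channels are scored
#' on the untouched test partition; in `"baseline_all_maps"` mode all
#' channels are scored directly.
#'
#' @param table a feature table.
#' @param config a [ga_config()] (ignored in baseline mode).
#' @param n_runs number of independent runs (default 20).
#' @param mode `"ga_selected"` or `"baseline_all_maps"`.
#' @param train_fraction outer split training fraction.
#' @param seed base seed; run `r` uses `seed + r - 1` for both split and GA.
#' @return list with `runs` (tibble: `run`, `seed`, `mode`, `accuracy`, and
#'   in GA mode list-columns `chromosome`, `trace`) and `summary` (one-row
#'   tibble of mean/max/min/median/std).
#' @export
multirun_ga <- function(table, config = ga_config(), n_runs = 20,
                        mode = c("ga_selected", "baseline_all_maps"),
                        train_fraction = 0.7, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_runs >= 1)
  labels <- ft_labels(table)
  seeds <- seed + seq_len(n_runs) - 1
  runs <- purrr::map_dfr(seq_len(n_runs), function(r) {
    split <- split_indices(labels, train_fraction, seed = seeds[r])
    if (mode == "baseline_all_maps") {
      acc <- svm_accuracy(table, split, cost = config$cost,
                          standardize = config$standardize)
      return(tibble::tibble(run = r, seed = seeds[r], mode = mode,
                            accuracy = acc))
    }
    fit <- run_ga(ft_rows(table, split$train), config, seed = seeds[r])
    acc <- svm_accuracy(table, split, channels = fit$best_genes,
                        cost = config$cost, standardize = config$standardize)
    tibble::tibble(run = r, seed = seeds[r], mode = mode, accuracy = acc,
                   chromosome = list(fit$best_genes), trace = list(fit$trace))
  })
  summary <- tibble::tibble(
    mean = mean(runs$accuracy), max = max(runs$accuracy),
    min = min(runs$accuracy), median = stats::median(runs$accuracy),
    std = if (n_runs > 1) sd(runs$accuracy) else 0
  )
  list(runs = runs, summary = summary)
}

#' Percent gain of the selected-subset pipeline over the baseline
#'
#' `difference = proposed - baseline` and
#' `gain_pct = 100 * difference / baseline`, reported to 2 decimals (the
#' difference to 4).
#'
#' @param proposed_mean mean accuracy of the GA-selected pipeline (vector).
#' @param baseline_mean mean accuracy of the all-maps feed-forward baseline.
#' @param layer optional layer labels.
#' @return tibble with `layer` (if given), `proposed_mean`, `baseline_mean`,
#'   `difference`, `gain_pct`.
#' @export
#' @examples
#' gain_report(0.8582, 0.685)  # difference 0.1732, gain 25.28
gain_report <- function(proposed_mean, baseline_mean, layer = NULL) {
  stopifnot(length(proposed_mean) == length(baseline_mean),
            all(baseline_mean > 0))
  out <- tibble::tibble(
    proposed_mean = proposed_mean,
    baseline_mean = baseline_mean,
    difference = round(proposed_mean - baseline_mean, 4),
    gain_pct = round(100 * (proposed_mean - baseline_mean) / baseline_mean, 2)
  )
  if (!is.null(layer)) out <- dplyr::mutate(out, layer = layer, .before = 1)
  out
}

#' Wilcoxon signed-rank test for paired accuracy samples
#'
#' Two-sided test of symmetry of the paired differences around zero. Zero
#' differences are excluded before ranking; ties in the absolute differences
#' receive midranks. For `n <= exact_max_n` nonzero pairs the p-value comes
#' from the exact null distribution of the positive-rank sum (computed by
#' shift convolution over the midranks, so it stays exact under ties); above
#' that, a normal approximation with tie correction and continuity
#' correction is used. Identical samples give p = 1.
#'
#' @param a,b equal-length paired samples (e.g. per-run accuracies of two
#'   layers). At least 5 nonzero differences are recommended; fewer give a
#'   warning.
#' @param exact_max_n largest n for the exact distribution (default 25).
#' @return two-sided p-value in (0, 1].
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), rep(0, 6))  # 0.03125
wilcoxon_signed_rank <- function(a, b, exact_max_n = 25) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  if (n < 5) warn("fewer than 5 nonzero differences; the signed-rank test has little power.")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max_n) {
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    # exact distribution of the (doubled) positive-rank sum over all 2^n signs
    f <- numeric(total + 1)
    f[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(total + 1 - ri)])
      f <- f + shifted
    }
    f <- f / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(f[seq_len(w2 + 1)])
    p_ge <- sum(f[(w2 + 1):(total + 1)])
    return(min(1, 2 * min(p_le, p_ge)))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (w == mu || sigma2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Pairwise Wilcoxon p-value matrix over layers
#'
#' Mirrors the published significance matrix: symmetric, diagonal 1. No
#' multiple-testing correction is applied by default; `holm = TRUE` adjusts
#' the off-diagonal p-values with Holm's method.
#'
#' @param runs_by_layer named list (or data frame) of equal-length per-run
#'   accuracy vectors.
#' @param holm apply Holm correction across the pairwise comparisons.
#' @return symmetric numeric matrix of p-values.
#' @export
wilcoxon_matrix <- function(runs_by_layer, holm = FALSE) {
  runs_by_layer <- as.list(runs_by_layer)
  k <- length(runs_by_layer)
  nms <- names(runs_by_layer)
  m <- matrix(1, k, k, dimnames = list(nms, nms))
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  p <- apply(pairs, 1, function(ij) {
    wilcoxon_signed_rank(runs_by_layer[[ij[1]]], runs_by_layer[[ij[2]]])
  })
  if (holm) p <- stats::p.adjust(p, method = "holm")
  m[upper.tri(m)] <- p
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Relative computational time
#'
#' Computing time expressed as the ratio of the method's wall time to the
#' wall time of a fixed reference program measured on the same host in the
#' same session, making timings comparable across hosts up to a uniform
#' slowdown (the ratio is invariant to scaling both timings).
#'
#' @param method_time method wall time in seconds (> 0).
#' @param reference_time reference-program wall time in seconds (> 0),
#'   typically [reference_benchmark()].
#' @return the ratio `method_time / reference_time`.
#' @export
#' @examples
#' ct_metric(10, 2)  # 5
ct_metric <- function(method_time, reference_time) {
  if (any(method_time <= 0) || any(reference_time <= 0)) {
    abort("timings must be positive.")
  }
  method_time / reference_time
}

#' Reference floating-point benchmark
#'
#' A fixed, documented arithmetic workload (repeated multiply-add-sqrt
#' passes over a numeric vector; `2 * passes * length` floating-point
#' kernel evaluations) timed on the current host. Its elapsed time is the
#' denominator of [ct_metric()], so relative times are comparable within one
#' session of this package (not across publications using other reference
#' programs).
#'
#' @param length vector length of the workload.
#' @param passes number of passes over the vector.
#' @return elapsed wall time in seconds (> 0).
#' @export
reference_benchmark <- function(length = 1e6, passes = 40) {
  x <- seq(0, 1, length.out = length)
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(passes)) {
    x <- sqrt(x * 0.999 + 1e-4)
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  max(elapsed, .Machine$double.eps)
}
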