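#' Tidy the convergence trace of a GA run
#'
#' @param x a `corneal_ga` object from [run_ga()].
#' @param ... unused.
#' @return tibble with `generation`, `best_fitness`, `mean_fitness`.
#' @method tidy corneal_ga
#' @export
tidy.corneal_ga <- function(x, ...) {
  x$trace[c("generation", "best_fitness", "mean_fitness")]
}

#' One-row summary of a GA run
#'
#' @param x a `corneal_ga` object.
#' @param ... unused.
#' @return tibble with `best_fitness`, `generations`, `chromosome_length`,
#'   `n_selected`, `seed`.
#' @method glance corneal_ga
#' @export
glance.corneal_ga <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$best_fitness,
    generations = max(x$trace$generation),
    chromosome_length = x$config$chromosome_length,
    n_selected = length(x$best_genes),
    seed = x$seed %||% NA_integer_
  )
}

#' Convergence plot of a GA run
#'
#' Best and mean population fitness per generation.
#'
#' @param object a `corneal_ga` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot corneal_ga
#' @export
autoplot.corneal_ga <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(c("best_fitness", "mean_fitness"),
                        names_to = "series", values_to = "fitness")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(best_fitness = "#2c7fb8", mean_fitness = "#aaaaaa"),
      labels = c(best_fitness = "best", mean_fitness = "population mean"),
      name = NULL) +
    ggplot2::labs(x = "generation", y = "fitness (SVM accuracy)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
#' @method autoplot layer_sweep
#' @export
autoplot.layer_sweep <- function(object, ...) {
  runs <- attr(object, "runs")
  runs$layer <- factor(runs$layer, levels = rev(object$layer))
  ggplot2::ggplot(runs, ggplot2::aes(x = .data$layer, y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "#deebf7") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "accuracy over runs") +
    ggplot2::theme_minimal()
}
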