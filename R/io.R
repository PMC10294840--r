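# Delimited/JSON formats tying the pipeline stages together. Every file
# carries a provenance header (config hash, seed, package version) so a run
# can be replayed.

provenance_lines <- function(extra = list()) {
  info <- c(list(package = paste0("cornealga ", as.character(utils::packageVersion("cornealga"))),
                 index_base = 1), extra)
  vapply(names(info), function(k) sprintf("# %s: %s", k, paste(info[[k]], collapse = ",")),
         character(1))
}

#' Write / read a feature table as tab-delimited text
#'
#' One row per image, one column per channel mean, trailing `label` column.
#' Commented header lines record the source layer, index base and package
#' version.
#'
#' @param table a [feature_table()].
#' @param path output path (`.tsv`).
#' @param extra named list of additional provenance fields.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the feature table.
#' @export
write_feature_table <- function(table, path, extra = list()) {
  layer <- attr(table, "layer")
  prov <- list()
  if (!is.null(layer)) {
    prov$layer_name <- layer$name
    prov$layer_index <- layer$index
  }
  prov$channel_ids <- channel_ids(table)
  header <- provenance_lines(c(prov, extra))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(as.data.frame(table), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  header <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, 1)
    if (!startsWith(line, "#")) break
    header <- c(header, line)
  }
  cols <- strsplit(line, "\t")[[1]]
  body <- utils::read.table(con, sep = "\t", col.names = cols, header = FALSE)
  meta <- parse_provenance(header)
  ids <- if (!is.null(meta$channel_ids)) {
    as.integer(strsplit(meta$channel_ids, ",")[[1]])
  } else NULL
  layer <- if (!is.null(meta$layer_name)) {
    list(name = meta$layer_name,
         index = suppressWarnings(as.integer(meta$layer_index)))
  } else NULL
  feature_table(as.matrix(body[setdiff(cols, "label")]), body$label,
                channel_ids = ids, layer = layer)
}

parse_provenance <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  kv <- strsplit(lines, ":\\s*")
  out <- lapply(kv, function(p) paste(p[-1], collapse = ":"))
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}

#' Serialize / load a selected chromosome as JSON
#'
#' Records the 1-based channel indices of the best chromosome together with
#' its fitness, the run seed and a hash of the GA configuration.
#'
#' @param fit a `corneal_ga` object from [run_ga()].
#' @param path output `.json` path.
#' @return `write_chromosome()` returns `path` invisibly;
#'   `read_chromosome()` the parsed list.
#' @export
write_chromosome <- function(fit, path) {
  layer <- attr(fit, "layer")
  payload <- list(
    channels = as.integer(sort(fit$best_genes)),
    index_base = 1L,
    fitness = fit$best_fitness,
    generations = max(fit$trace$generation),
    seed = fit$seed,
    config_hash = rlang::hash(fit$config),
    package = as.character(utils::packageVersion("cornealga"))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_chromosome
#' @export
read_chromosome <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a GA convergence trace as tab-delimited text
#'
#' @param fit a `corneal_ga` object.
#' @param path output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path) {
  tr <- fit$trace[c("generation", "best_fitness", "mean_fitness")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(list(seed = fit$seed,
                                   config_hash = rlang::hash(fit$config))), con)
  utils::write.table(as.data.frame(tr), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON) file whose keys mirror the published control-parameter
#' table: `backbone`, `layer`, `population_size`, `chromosome_length`,
#' `crossover_rate`, `mutation_rate`, `max_generations`, `train_fraction`,
#' `n_runs`, `seed`, `weights_seed`, `output_dir`. Missing keys fall back to
#' the package defaults.
#'
#' @param path config file path.
#' @return list with `ga` (a [ga_config()]) and the pipeline-level fields.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ga_keys <- intersect(names(raw), names(formals(ga_config)))
  defaults <- list(backbone = "resnet18", layer = "pool5",
                   train_fraction = 0.7, n_runs = 20, seed = 1,
                   weights_seed = 1, output_dir = ".")
  pipeline <- modifyList(defaults, raw[setdiff(names(raw), ga_keys)])
  pipeline$ga <- do.call(ga_config, raw[ga_keys])
  pipeline
}

#' Published mean accuracy rates of the five best layers
#'
#' The bundled reference table of per-layer mean accuracy rates (GA-selected
#' pipeline vs all-maps feed-forward baseline, 20 runs each) used by the
#' gain and significance reporting examples.
#'
#' @return tibble with `layer`, `proposed_mean`, `baseline_mean`.
#' @export
reference_layer_means <- function() {
  path <- system.file("extdata", "best5_layer_means.tsv",
                      package = "cornealga")
  tibble::as_tibble(utils::read.delim(path, comment.char = "#"))
}
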