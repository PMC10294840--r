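#' Assemble a feature table
#'
#' A feature table is the hand-off object of the pipeline: one row per image
#' (sample), one column per feature map holding that map's spatial mean, and
#' a trailing `label` column with the binary class (0 = no ulcer, 1 = ulcer).
#' Channel provenance (original map indices, source layer) travels in
#' attributes so a table restricted to selected channels remembers where its
#' columns came from.
#'
#' @param values numeric matrix, samples x channels.
#' @param labels integer/factor vector of 0/1 class labels, one per row.
#' @param channel_ids integer vector of original (1-based) feature-map
#'   indices, one per column. Defaults to `1:ncol(values)`.
#' @param layer optional list describing the source layer (as one row of
#'   [enumerate_layers()], or any list with `name`/`index`).
#' @return A tibble with channel columns `ch_*` and a `label` column, plus
#'   `channel_ids` and `layer` attributes.
#' @export
#' @examples
#' ft <- feature_table(matrix(rnorm(20), 5, 4), labels = c(0, 1, 0, 1, 1))
#' channel_ids(ft)
feature_table <- function(values, labels, channel_ids = NULL, layer = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(labels)) {
    abort("`labels` must have one entry per row of `values`.")
  }
  labels <- as.integer(as.character(labels))
  if (!all(labels %in% c(0L, 1L))) {
    abort("labels must be binary (0/1).")
  }
  channel_ids <- as.integer(channel_ids %||% seq_len(ncol(values)))
  if (length(channel_ids) != ncol(values) || anyDuplicated(channel_ids)) {
    abort("`channel_ids` must be distinct, one per column.")
  }
  colnames(values) <- sprintf("ch_%04d", channel_ids)
  out <- tibble::as_tibble(values)
  out$label <- labels
  attr(out, "channel_ids") <- channel_ids
  attr(out, "layer") <- layer
  out
}

#' Accessors for feature tables
#'
#' @param table a feature table built by [feature_table()] (or any data frame
#'   with `ch_*` columns and a `label` column).
#' @param channels optional integer vector of original channel ids to keep.
#' @return `ft_matrix()` the numeric matrix of channel means; `ft_labels()`
#'   the integer label vector; `channel_ids()` the original map indices.
#' @export
ft_matrix <- function(table, channels = NULL) {
  ids <- channel_ids(table)
  cols <- setdiff(names(table), "label")
  x <- as.matrix(table[cols])
  if (!is.null(channels)) {
    pos <- match(channels, ids)
    if (anyNA(pos)) abort("some requested channels are not in the table.")
    x <- x[, pos, drop = FALSE]
  }
  x
}

#' @rdname ft_matrix
#' @export
ft_labels <- function(table) {
  as.integer(table[["label"]])
}

#' @rdname ft_matrix
#' @export
channel_ids <- function(table) {
  ids <- attr(table, "channel_ids")
  if (is.null(ids)) {
    cols <- setdiff(names(table), "label")
    ids <- suppressWarnings(as.integer(sub("^ch_", "", cols)))
    if (anyNA(ids)) ids <- seq_along(cols)
  }
  ids
}
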