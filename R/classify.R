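#' Stratified train/test split
#'
#' Splits sample indices into disjoint, exhaustive train and test sets. The
#' training size is `floor(train_fraction * n)`; under stratification it is
#' apportioned across classes by largest remainder (ties broken towards the
#' larger class, then by label order), so class proportions are preserved
#' within rounding. With 712 samples at 0.70 the training set has 498
#' samples.
#'
#' @param labels 0/1 class labels.
#' @param train_fraction fraction of samples used for training, in (0, 1).
#' @param stratified preserve class proportions (default TRUE).
#' @param seed integer seed; the same seed yields the identical partition.
#' @return list with integer vectors `train` and `test`.
#' @export
#' @examples
#' split_indices(rep(c(0, 1), each = 5), seed = 1)
split_indices <- function(labels, train_fraction = 0.7, stratified = TRUE,
                          seed = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  labels <- as.integer(labels)
  n <- length(labels)
  n_train <- floor(train_fraction * n)
  if (!is.null(seed)) withr::local_seed(seed)
  if (!stratified) {
    train <- sort(sample.int(n, n_train))
    return(list(train = train, test = setdiff(seq_len(n), train)))
  }
  counts <- table(labels)
  if (any(counts < 2)) {
    abort("each class needs at least 2 samples for a stratified split.")
  }
  quota <- as.numeric(counts) * train_fraction
  take <- floor(quota)
  left <- n_train - sum(take)
  if (left > 0) {
    frac <- quota - take
    ord <- order(-frac, -as.numeric(counts), as.integer(names(counts)))
    take[ord[seq_len(left)]] <- take[ord[seq_len(left)]] + 1
  }
  train <- integer(0)
  for (k in seq_along(counts)) {
    idx <- which(labels == as.integer(names(counts))[k])
    train <- c(train, sample(idx, take[k]))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[!is.finite(sdev) | sdev < .Machine$double.eps] <- 1
  list(mean = mu, sd = sdev)
}

standardize_apply <- function(x, std) {
  sweep(sweep(x, 2, std$mean, "-"), 2, std$sd, "/")
}

#' Train a linear-kernel SVM on (a channel subset of) a feature table
#'
#' Fits a binary linear SVM (class 1 = ulcer present, the positive class).
#' Feature standardization (zero mean, unit variance) is estimated on the
#' training rows only and stored with the model; margins are scale-sensitive
#' so it is on by default.
#'
#' @param table a [feature_table()].
#' @param train integer vector of training row indices.
#' @param channels optional channel ids to restrict to (a chromosome).
#' @param cost SVM regularization constant C (default 1).
#' @param standardize standardize features from training statistics
#'   (default TRUE).
#' @return An object of class `corneal_svm` usable with [predict()] and
#'   [confusion_counts()].
#' @export
train_svm <- function(table, train, channels = NULL, cost = 1,
                      standardize = TRUE) {
  x <- ft_matrix(table, channels)[train, , drop = FALSE]
  y <- ft_labels(table)[train]
  if (length(unique(y)) < 2) abort("training set contains a single class.")
  std <- NULL
  if (standardize) {
    std <- standardize_fit(x)
    x <- standardize_apply(x, std)
  }
  fit <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "linear",
                    cost = cost, scale = FALSE)
  structure(list(fit = fit, std = std, channels = channels, cost = cost),
            class = "corneal_svm")
}

#' @export
predict.corneal_svm <- function(object, table, indices = NULL, ...) {
  x <- ft_matrix(table, object$channels)
  if (!is.null(indices)) x <- x[indices, , drop = FALSE]
  if (!is.null(object$std)) x <- standardize_apply(x, object$std)
  as.integer(as.character(predict(object$fit, x)))
}

#' Confusion counts against true labels
#'
#' Class 1 ("ulcer present") is the positive class.
#'
#' @param truth true 0/1 labels.
#' @param predicted predicted 0/1 labels.
#' @return one-row tibble with `TP`, `TN`, `FP`, `FN`.
#' @export
#' @examples
#' confusion_counts(c(1, 1, 1, 0, 0), rep(1, 5))  # TP 3, FP 2
confusion_counts <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  stopifnot(length(truth) == length(predicted))
  tibble::tibble(
    TP = sum(truth == 1 & predicted == 1),
    TN = sum(truth == 0 & predicted == 0),
    FP = sum(truth == 0 & predicted == 1),
    FN = sum(truth == 1 & predicted == 0)
  )
}

#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / (TP + TN + FP + FN)` -- the fraction of evaluated samples
#' classified correctly.
#'
#' @param counts a one-row tibble/list with `TP`, `TN`, `FP`, `FN`.
#' @return accuracy in [0, 1].
#' @export
#' @examples
#' accuracy_from_counts(list(TP = 50, TN = 40, FP = 5, FN = 5))  # 0.9
accuracy_from_counts <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) abort("empty confusion counts.")
  (counts$TP + counts$TN) / total
}

#' Train-and-evaluate accuracy for one split
#'
#' Convenience chain: fit a linear SVM on the training rows (optionally on a
#' channel subset) and return its accuracy on the test rows. This is exactly
#' the quantity the GA uses as fitness.
#'
#' @inheritParams train_svm
#' @param split list with `train` and `test` indices ([split_indices()]).
#' @return accuracy in [0, 1].
#' @export
svm_accuracy <- function(table, split, channels = NULL, cost = 1,
                         standardize = TRUE) {
  model <- train_svm(table, split$train, channels = channels, cost = cost,
                     standardize = standardize)
  pred <- predict(model, table, indices = split$test)
  accuracy_from_counts(confusion_counts(ft_labels(table)[split$test], pred))
}
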