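# R-level interface to the compiled random-forest classifier.
#
# The forest is a standard binary classification probability forest: CART
# trees on bootstrap resamples, Gini split criterion, mtry features tried per
# node (default floor(sqrt(p))), nodes split down to min_node_size, and class
# probabilities averaged over the leaf class fractions of all trees. All randomness flows from an
# explicit seed through a package-internal generator, so results are
# bit-identical across platforms and independent of R's RNG state.

#' Cross-validated random-forest AUC
#'
#' Runs stratified `n_folds` cross-validation: for each fold, a forest is
#' trained on the remaining folds and its out-of-sample class-probability
#' scores for the held-out observations are summarized as a Mann-Whitney AUC
#' (tied scores credit 0.5 per tied pair). The per-fold AUCs are averaged,
#' which is robust to fold-size imbalance; with `n_repeats > 1` the fold
#' partition is re-randomized each repeat.
#'
#' @param X Numeric matrix, observations x features.
#' @param y Binary labels (0/1, logical, or a two-level factor).
#' @param n_folds Number of CV folds (default 3).
#' @param n_trees Trees per forest (default 100).
#' @param n_repeats Number of independent CV repetitions (default 1).
#' @param mtry Features tried per split; default `floor(sqrt(ncol(X)))`.
#' @param min_node_size Minimal node size to attempt a split (default 10,
#'   the probability-forest convention; terminal nodes may be smaller).
#'   Set to 2 to grow trees to purity.
#' @param seed RNG seed for fold assignment, bootstraps, and feature
#'   sampling.
#' @return Numeric vector of length `n_repeats` with one AUC per repeat.
#' @export
rf_cv_auc <- function(X, y, n_folds = 3, n_trees = 100, n_repeats = 1,
                      mtry = NULL, min_node_size = 10, seed = 1) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as_binary_labels(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (length(y) < n_folds) stop("need at least n_folds observations")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  .rf_cv_auc_cpp(X, y, as.integer(n_folds), as.integer(n_trees),
                 as.integer(n_repeats), as.integer(mtry),
                 as.integer(min_node_size), as.double(seed))
}

#' Train a forest and predict class probabilities
#'
#' Lower-level access to the same forest used by [rf_cv_auc()], for callers
#' that need the out-of-sample scores themselves (e.g. to audit the AUC
#' computation).
#'
#' @param X_train,y_train Training observations and binary labels.
#' @param X_test Observations to score.
#' @inheritParams rf_cv_auc
#' @return Numeric vector of class-1 probabilities for `X_test` rows.
#' @export
rf_fit_predict <- function(X_train, y_train, X_test, n_trees = 100,
                           mtry = NULL, min_node_size = 10, seed = 1) {
  X_train <- as.matrix(X_train); storage.mode(X_train) <- "double"
  X_test <- as.matrix(X_test); storage.mode(X_test) <- "double"
  y <- as_binary_labels(y_train)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X_train))))
  .rf_fit_predict_cpp(X_train, y, X_test, as.integer(n_trees),
                      as.integer(mtry), as.integer(min_node_size),
                      as.double(seed))
}

#' Mann-Whitney AUC with midrank tie handling
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (1 = positive).
#' @return AUC in \[0, 1\]; `NA` if only one class is present.
#' @export
mann_whitney_auc <- function(scores, labels) {
  .auc_cpp(as.double(scores), as_binary_labels(labels))
}

#' Stratified fold assignment
#'
#' Shuffles each class and deals it round-robin across folds (class c starts
#' at fold c), so fold sizes differ by at most one per class and by at most
#' one overall for balanced two-class input.
#'
#' @param y Binary labels.
#' @param n_folds Number of folds.
#' @param seed Seed for the shuffle.
#' @return Integer fold assignment in `1:n_folds`, one per observation.
#' @export
stratified_folds <- function(y, n_folds, seed = 1) {
  .stratified_folds_cpp(as_binary_labels(y), as.integer(n_folds),
                        as.double(seed)) + 1L
}

as_binary_labels <- function(y) {
  if (is.factor(y)) {
    if (nlevels(droplevels(y)) > 2) stop("labels must have exactly two levels")
    y <- as.integer(droplevels(y)) - 1L
  } else if (is.logical(y)) {
    y <- as.integer(y)
  } else if (is.character(y)) {
    u <- sort(unique(y))
    if (length(u) > 2) stop("labels must have exactly two levels")
    y <- as.integer(y == u[length(u)])
  } else {
    y <- as.integer(y)
    if (!all(y %in% c(0L, 1L))) stop("numeric labels must be 0/1")
  }
  y
}
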