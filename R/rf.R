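#' Random-forest configuration
#'
#' Settings shared by the importance and selection steps.  Defaults are the
#' community conventions for small-sample binary classification: 500 trees,
#' `mtry = floor(sqrt(m))`, and a stratified bootstrap over the two classes.
#' All randomness derives from `seed` through a counter-based stream-splitting
#' scheme, so every trial is reproducible and independent of R's global RNG.
#'
#' @param ntree Trees per forest (>= 1).
#' @param mtry Variables tried per split: a positive integer or `"sqrt"` for
#'   `floor(sqrt(m))`.
#' @param n_trials Number of repeated forest trials for importance estimation.
#' @param seed Integer master seed.
#'
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(ntree = 500, mtry = "sqrt", n_trials = 1000, seed = 1) {
  stopifnot(is.numeric(ntree), ntree >= 1, is.numeric(n_trials), n_trials >= 1,
            is.numeric(seed), length(seed) == 1)
  if (!(identical(mtry, "sqrt") || (is.numeric(mtry) && mtry >= 1))) {
    rlang::abort("`mtry` must be a positive integer or \"sqrt\"")
  }
  structure(
    list(ntree = as.integer(ntree), mtry = mtry,
         n_trials = as.integer(n_trials), seed = as.numeric(seed)),
    class = "rf_config"
  )
}

resolve_mtry <- function(mtry, m) {
  if (identical(mtry, "sqrt")) max(1L, as.integer(floor(sqrt(m)))) else
    min(as.integer(mtry), m)
}

# stream offsets keep the seed streams of distinct pipeline stages disjoint
STREAM_VIM <- 0
STREAM_NESTED <- 1e7
STREAM_FOREST <- 5e7
STREAM_FOREST_VIM <- 9e7

prepare_xy <- function(table, labels) {
  check_index_table(table)
  labels <- hydropathy_labels(labels, scheme_name = label_scheme_name(labels))
  x <- index_matrix(table)
  y <- labels_as_int(labels)
  if (length(unique(y)) < 2) rlang::abort("degenerate labels: only one class present")
  list(x = x, y = y, tie_class = as.integer(sum(y) > length(y) / 2),
       scheme_name = label_scheme_name(labels))
}

#' Fit a bare random forest on a sample-by-variable matrix
#'
#' Low-level access to the forest engine used by [permutation_vim()] and
#' [nested_selection()], exposed so that single trees with hand-built
#' bootstraps can be inspected and verified.  Trees are CART trees grown to
#' purity with Gini splits; the bootstrap is stratified per class unless an
#' explicit `inbag` count matrix is supplied.
#'
#' @param x Numeric matrix, samples in rows.
#' @param y 0/1 integer vector (or two-level factor) of length `nrow(x)`.
#' @param ntree,mtry,seed See [rf_config()].
#' @param inbag Optional `nrow(x)` x `ntree` integer matrix of in-bag counts
#'   fixing the bootstrap of every tree.
#' @param stream Integer stream counter separating independent fits that share
#'   a seed.
#'
#' @return An object of class `rf_forest`: a list with `trees`, `inbag`,
#'   and the fitting parameters.
#' @export
rf_forest <- function(x, y, ntree = 500, mtry = "sqrt", seed = 1,
                      inbag = NULL, stream = 0) {
  x <- as.matrix(x)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  tie_class <- as.integer(sum(y) > length(y) / 2)
  fit <- cpp_grow_forest(x, y, as.integer(ntree),
                         resolve_mtry(mtry, ncol(x)),
                         as.numeric(seed), STREAM_FOREST + stream, tie_class,
                         if (is.null(inbag)) NULL else
                           matrix(as.integer(inbag), nrow(x)))
  structure(
    list(trees = fit$trees, inbag = fit$inbag, x = x, y = y,
         ntree = as.integer(ntree), mtry = resolve_mtry(mtry, ncol(x)),
         seed = seed, stream = stream, tie_class = tie_class),
    class = "rf_forest"
  )
}

#' Per-tree predictions of a fitted forest
#'
#' @param forest An [rf_forest()] fit.
#' @param newx Matrix of samples to predict (defaults to the training matrix).
#' @return Integer matrix, one column of 0/1 predictions per tree.
#' @export
predict_trees <- function(forest, newx = forest$x) {
  stopifnot(inherits(forest, "rf_forest"))
  cpp_predict_trees(forest$trees, forest$inbag, as.matrix(newx))
}

#' Permutation importance of one fitted forest
#'
#' For each variable, the mean over trees of the difference between the
#' out-of-bag misclassification count after permuting that variable's OOB
#' values and the unpermuted count.  Variables a tree never splits on
#' contribute exactly zero for that tree.
#'
#' @param forest An [rf_forest()] fit.
#' @param permutations Optional explicit permutations: a list with one element
#'   per tree, each a list with one integer vector per variable giving a
#'   permutation of that tree's OOB positions (ascending row order).  When
#'   `NULL`, permutations are drawn from the forest's seed stream.
#' @return Numeric vector of per-variable importance scores (count units).
#' @export
forest_vim <- function(forest, permutations = NULL) {
  stopifnot(inherits(forest, "rf_forest"))
  cpp_forest_vim(forest$trees, forest$inbag, forest$x, forest$y,
                 as.numeric(forest$seed), STREAM_FOREST_VIM + forest$stream,
                 permutations)
}

#' Ensemble out-of-bag error of a fitted forest
#'
#' Each sample is predicted by majority vote over the trees holding it out of
#' bag (vote ties go to the overall majority class); the error is the percent
#' misclassified among samples that were out of bag at least once.
#'
#' @param forest An [rf_forest()] fit.
#' @return Error percentage in `[0, 100]`.
#' @export
forest_oob_error <- function(forest) {
  stopifnot(inherits(forest, "rf_forest"))
  cpp_forest_oob_error(forest$trees, forest$inbag, forest$x, forest$y,
                       forest$tie_class)
}
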