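# End-to-end convenience wrapper: encode, split, grid-search, select, score.

#' Train and select a sparse domain-class classifier
#'
#' Runs the full classification protocol on a labelled alignment: one-hot
#' encoding, stratified 75/25 train/test split, hyperparameter grid search
#' with stratified k-fold cross-validation scored by negative mean squared
#' error, selection of the sparsest model within `ci_multiplier` standard
#' errors of the best grid point, and evaluation of that model (refit on
#' the full training set) on the held-out test set.
#'
#' @param aln An `aa_aln` with class labels (or pass `labels`).
#' @param labels Optional character vector of class labels per record.
#' @param test_fraction Held-out fraction (default 0.25).
#' @param k Cross-validation folds (default 5).
#' @param seed Integer seed driving the split and the fold assignment.
#' @param lambda_grid,l1_ratio_grid Hyperparameter grids.
#' @param ci_multiplier Standard-error multiplier of the selection rule.
#' @param anchor Selection anchor, see [select_parsimonious()].
#' @param tol,max_iter Solver settings.
#' @return List with `fm`, `split`, `path`, `selection`, `fit` (the selected
#'   model), `train_accuracy`, `test_accuracy` and `confusion` (test-set
#'   confusion table).
#' @export
train_classifier <- function(aln, labels = aln$class_label,
                             test_fraction = 0.25, k = 5L, seed = 1L,
                             lambda_grid = default_lambda_grid(),
                             l1_ratio_grid = default_l1_ratio_grid(),
                             ci_multiplier = 1.96,
                             anchor = c("best", "least_regularized"),
                             tol = 1e-8, max_iter = 2000L) {
  anchor <- match.arg(anchor)
  fm <- one_hot_encode(aln, labels)
  split <- split_train_test(fm, test_fraction = test_fraction,
                            seed = derive_seed(seed, 11L))
  path <- cross_validate_grid(split$train, lambda_grid = lambda_grid,
                              l1_ratio_grid = l1_ratio_grid, k = k,
                              seed = derive_seed(seed, 23L), tol = tol,
                              max_iter = max_iter)
  sel <- select_parsimonious(path, ci_multiplier = ci_multiplier,
                             anchor = anchor)
  fit <- sel$fit
  multi <- length(fm$classes) > 2L
  pred <- if (multi) classify_multi(fit, split$test) else
    classify(fit, split$test)
  truth <- if (multi) split$test$classes[split$test$y] else split$test$y
  list(fm = fm, split = split, path = path, selection = sel, fit = fit,
       train_accuracy = accuracy(fit, split$train),
       test_accuracy = accuracy(fit, split$test),
       confusion = table(predicted = pred, observed = truth))
}
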