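# One-hot encoding of alignment columns into the indicator feature matrix
# used by the penalized classifiers.

#' One-hot encode an alignment
#'
#' Each alignment column becomes a block of 20 indicator features, one per
#' amino acid in the fixed order of [AA_ALPHABET]; a residue sets exactly one
#' indicator in its block to 1 and a gap leaves the whole block at 0. A model
#' over an alignment of length `L` therefore has `1 + 20 L` parameters
#' including the intercept.
#'
#' For a two-class problem the positive class (coded 1) is `"modular"` when
#' present among the labels, otherwise the lexicographically last class; for
#' three or more classes the class coding follows sorted label order.
#'
#' @param x An `aa_aln` alignment.
#' @param labels Character vector of class labels, one per record; defaults
#'   to `x$class_label`. Must be defined (non-`NA`) for every record.
#' @return An object of class `feature_matrix`: list with `X` (n x 20L
#'   indicator matrix, rows named by sequence id), `y` (integer class codes:
#'   0/1 for binary, 1..K otherwise), `labels`, `classes` (label of each
#'   code, in code order), `column_index` (data frame `feature`, `column`,
#'   `aa`) and `L` (alignment length).
#' @export
one_hot_encode <- function(x, labels = x$class_label) {
  stopifnot(inherits(x, "aa_aln"))
  L <- aln_length(x)
  labels <- as.character(labels)
  if (length(labels) != length(x$id) || anyNA(labels)) {
    stop("every record must have a class label")
  }
  mat <- aln_matrix(x$seq)
  bad <- setdiff(unique(as.vector(mat)), c(AA_ALPHABET, GAP))
  if (length(bad)) {
    stop(sprintf("unknown symbol(s) in alignment: %s (run filter_ambiguous first)",
                 paste(bad, collapse = ", ")))
  }
  n <- nrow(mat)
  X <- matrix(0, nrow = n, ncol = 20L * L)
  aa_idx <- match(as.vector(mat), AA_ALPHABET)      # NA for gaps
  cols <- rep(seq_len(L), each = n)                 # column of each cell
  keep <- !is.na(aa_idx)
  feature <- (cols[keep] - 1L) * 20L + aa_idx[keep]
  X[cbind(rep(seq_len(n), L)[keep], feature)] <- 1
  column_index <- data.frame(
    feature = seq_len(20L * L),
    column = rep(seq_len(L), each = 20L),
    aa = rep(AA_ALPHABET, L),
    stringsAsFactors = FALSE)
  colnames(X) <- sprintf("c%d_%s", column_index$column, column_index$aa)
  rownames(X) <- x$id

  classes <- sort(unique(labels), method = "radix")
  if (length(classes) < 2L) stop("at least two classes are required")
  if (length(classes) == 2L) {
    positive <- if ("modular" %in% classes) "modular" else classes[2L]
    classes <- c(setdiff(classes, positive), positive)
    y <- as.integer(labels == positive)
  } else {
    y <- match(labels, classes)
  }
  structure(
    list(X = X, y = y, labels = labels, classes = classes,
         column_index = column_index, L = L),
    class = "feature_matrix")
}

#' Number of model parameters for a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @return `1 + 20 L` (indicator features plus the intercept) for the binary
#'   model.
#' @export
n_parameters <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  1L + ncol(fm$X)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d sequences x %d indicators (L = %d), %d classes: %s\n",
              nrow(x$X), ncol(x$X), x$L, length(x$classes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

# Subset a feature matrix by row index, keeping the class coding.
fm_subset <- function(fm, i) {
  out <- fm
  out$X <- fm$X[i, , drop = FALSE]
  out$y <- fm$y[i]
  out$labels <- fm$labels[i]
  out
}

#' Stratified train/test split
#'
#' Splits a feature matrix into disjoint training and testing sets,
#' stratified by class: within each class, `round(test_fraction * n_class)`
#' rows (at least 1) are drawn for the test set under the given seed.
#'
#' @param fm A `feature_matrix`.
#' @param test_fraction Fraction of rows held out; default 0.25.
#' @param seed Integer seed making the split reproducible.
#' @return List with `train` and `test` feature matrices and the integer
#'   index vectors `train_idx`, `test_idx`.
#' @export
split_train_test <- function(fm, test_fraction = 0.25, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must lie strictly between 0 and 1")
  }
  n <- nrow(fm$X)
  if (n < 4L) stop("need at least 4 sequences to split")
  test_idx <- integer()
  with_seed(seed, {
    for (k in sort(unique(fm$y))) {
      rows <- which(fm$y == k)
      n_test <- max(1L, round(test_fraction * length(rows)))
      if (n_test >= length(rows)) {
        stop("a class would be absent from the training set; too few sequences")
      }
      test_idx <- c(test_idx, sample(rows, n_test))
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  if (length(unique(fm$y[train_idx])) < length(unique(fm$y)) ||
      length(unique(fm$y[test_idx])) < length(unique(fm$y))) {
    stop("a class is absent from one side of the split; too few sequences")
  }
  list(train = fm_subset(fm, train_idx), test = fm_subset(fm, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}
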