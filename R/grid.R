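# Hyperparameter grid search with stratified k-fold cross-validation scored
# by negative mean squared error, and the confidence-interval
# sparsest-model selection rule.

#' Default hyperparameter grids
#'
#' `default_lambda_grid()` is 10 log-spaced points on `[1e-4, 10]`;
#' `default_l1_ratio_grid()` is `{0.1, 0.3, 0.5, 0.7, 0.9, 1.0}`. The
#' smallest lambda stands in for the (near-)unregularized endpoint: a true
#' `lambda = 0` fit diverges on separable data.
#'
#' @return Numeric vector of grid values.
#' @export
default_lambda_grid <- function() {
  10^seq(log10(1e-4), log10(10), length.out = 10L)
}

#' @rdname default_lambda_grid
#' @export
default_l1_ratio_grid <- function() {
  c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over the k folds, so every fold sees every class whenever each
# class has >= k members.
make_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      rows <- which(y == cl)
      if (length(rows) < k) {
        stop(sprintf("class %s has fewer members (%d) than folds (%d)",
                     cl, length(rows), k))
      }
      fold[rows] <- rep(seq_len(k), length.out = length(rows))[
        order(sample.int(length(rows)))]
    }
  })
  fold
}

# Negative mean squared error between predicted probabilities and labels.
# Binary: single positive-class probability against the 0/1 label.
# Multiclass: mean over all class-indicator entries.
neg_mse_binary <- function(prob, y) -mean((prob - y)^2)
neg_mse_multi <- function(P, y_idx) {
  Y <- matrix(0, nrow(P), ncol(P))
  Y[cbind(seq_len(nrow(P)), y_idx)] <- 1
  -mean((P - Y)^2)
}

#' Grid search with k-fold cross-validation
#'
#' For every (lambda, l1_ratio) pair: fits the penalized model on each of
#' `k` stratified folds' complements, scores the held-out predicted
#' probabilities by negative mean squared error against the labels, and
#' refits on the full training set. Fits are warm-started along decreasing
#' lambda within each `l1_ratio`, which does not change the optima (the
#' objective is convex) but speeds convergence. The highest-scoring grid
#' point is the one with maximal `cv_mean_score` (ties broken toward larger
#' lambda, then larger l1_ratio).
#'
#' Works for binary (logistic) and three-or-more-class (softmax) feature
#' matrices alike; for the multiclass case the score is the negative mean
#' squared error over all one-hot class-indicator entries.
#'
#' @param fm Training `feature_matrix`.
#' @param lambda_grid,l1_ratio_grid Numeric grids (defaults
#'   [default_lambda_grid()] / [default_l1_ratio_grid()]).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param tol,max_iter Solver settings for the grid fits.
#' @return An object of class `reg_path`: list with `grid` (data frame
#'   `lambda`, `l1_ratio`, `cv_mean_score`, `cv_score_se`, `nonzero_count`,
#'   `converged`), `fits` (refit models, one per grid row), `best_index`,
#'   `k`, `seed` and `classes`.
#' @export
cross_validate_grid <- function(fm, lambda_grid = default_lambda_grid(),
                                l1_ratio_grid = default_l1_ratio_grid(),
                                k = 5L, seed = 1L, tol = 1e-8,
                                max_iter = 2000L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (k < 2L) stop("`k` must be at least 2")
  if (!length(lambda_grid) || !length(l1_ratio_grid)) {
    stop("hyperparameter grids must be nonempty")
  }
  multi <- length(fm$classes) > 2L
  fold <- make_folds(fm$y, k, seed)

  fit_one <- function(sub, lambda, l1, init, smax_sq) {
    if (multi) {
      fit_multinomial(sub, lambda, l1, tol = tol, max_iter = max_iter,
                      init = init, smax_sq = smax_sq)
    } else {
      fit_elastic_net_logistic(sub, lambda, l1, tol = tol,
                               max_iter = max_iter, init = init,
                               smax_sq = smax_sq)
    }
  }
  score_fold <- function(fit, sub) {
    if (multi) neg_mse_multi(predict_prob_multi(fit, sub), sub$y)
    else neg_mse_binary(predict_prob(fit, sub), as.numeric(sub$y))
  }
  as_init <- function(fit) {
    if (is.null(fit)) NULL
    else if (multi) list(weights = fit$weights, intercepts = fit$intercepts)
    else list(w = fit$weights, intercept = fit$intercept)
  }

  fold_fm <- lapply(seq_len(k), function(f) {
    list(train = fm_subset(fm, which(fold != f)),
         test = fm_subset(fm, which(fold == f)))
  })
  # spectral norms reused across the whole grid
  smax_full <- aug_spectral_norm_sq(fm$X, 100L)
  smax_fold <- vapply(fold_fm, function(ff)
    aug_spectral_norm_sq(ff$train$X, 100L), numeric(1))

  lambda_desc <- sort(lambda_grid, decreasing = TRUE)
  rows <- list()
  fits <- list()
  for (l1 in sort(l1_ratio_grid)) {
    warm_fold <- vector("list", k)
    warm_full <- NULL
    for (lambda in lambda_desc) {
      scores <- numeric(k)
      ok <- TRUE
      for (f in seq_len(k)) {
        ft <- withCallingHandlers(
          fit_one(fold_fm[[f]]$train, lambda, l1, as_init(warm_fold[[f]]),
                  smax_fold[f]),
          warning = function(w) {
            if (grepl("did not converge", conditionMessage(w))) {
              ok <<- FALSE
              invokeRestart("muffleWarning")
            }
          })
        warm_fold[[f]] <- ft
        scores[f] <- score_fold(ft, fold_fm[[f]]$test)
      }
      refit <- withCallingHandlers(
        fit_one(fm, lambda, l1, as_init(warm_full), smax_full),
        warning = function(w) {
          if (grepl("did not converge", conditionMessage(w))) {
            ok <<- FALSE
            invokeRestart("muffleWarning")
          }
        })
      warm_full <- refit
      rows[[length(rows) + 1L]] <- data.frame(
        lambda = lambda, l1_ratio = l1,
        cv_mean_score = mean(scores),
        cv_score_se = stats::sd(scores) / sqrt(k),
        nonzero_count = refit$nonzero_count,
        converged = ok)
      fits[[length(fits) + 1L]] <- refit
    }
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  # argmax with deterministic tie-breaks: larger lambda, then larger l1_ratio
  ord <- order(-grid$cv_mean_score, -grid$lambda, -grid$l1_ratio)
  best_index <- ord[1L]
  structure(
    list(grid = grid, fits = fits, best_index = best_index, k = k,
         seed = seed, classes = fm$classes),
    class = "reg_path")
}

#' @export
print.reg_path <- function(x, ...) {
  cat(sprintf("<reg_path> %d grid points, %d-fold CV; best: lambda = %g, l1_ratio = %g (score %.5f)\n",
              nrow(x$grid), x$k, x$grid$lambda[x$best_index],
              x$grid$l1_ratio[x$best_index],
              x$grid$cv_mean_score[x$best_index]))
  invisible(x)
}

#' Select the sparsest model within a confidence band of the best
#'
#' Implements the confidence-interval variant of the one-standard-error
#' rule: the qualification threshold is the anchor model's cross-validated
#' score minus `ci_multiplier` times its standard error (1.96 standard
#' errors approximates a two-sided 95% confidence interval), and among all
#' grid points scoring at or above the threshold the one with the fewest
#' nonzero parameters is chosen (ties broken toward higher score, then
#' larger lambda).
#'
#' @param path A `reg_path`.
#' @param ci_multiplier Standard-error multiplier; default `1.96`.
#' @param anchor `"best"` anchors the band at the highest-scoring grid point
#'   (the default); `"least_regularized"` anchors it at the smallest-lambda
#'   point, the near-unregularized endpoint of the path.
#' @return List with `index` (row in `path$grid`), `grid` (that row),
#'   `fit` (the refit model), `threshold` and `anchor_index`.
#' @export
select_parsimonious <- function(path, ci_multiplier = 1.96,
                                anchor = c("best", "least_regularized")) {
  stopifnot(inherits(path, "reg_path"))
  anchor <- match.arg(anchor)
  g <- path$grid
  anchor_index <- if (anchor == "best") {
    path$best_index
  } else {
    ord <- order(g$lambda, -g$cv_mean_score)
    ord[1L]
  }
  threshold <- g$cv_mean_score[anchor_index] -
    ci_multiplier * g$cv_score_se[anchor_index]
  qual <- which(g$cv_mean_score >= threshold)
  ord <- qual[order(g$nonzero_count[qual], -g$cv_mean_score[qual],
                    -g$lambda[qual])]
  idx <- ord[1L]
  list(index = idx, grid = g[idx, , drop = FALSE], fit = path$fits[[idx]],
       threshold = threshold, anchor_index = anchor_index)
}

#' Classification accuracy of a fit on a feature matrix
#'
#' @param fit A `modfree_fit` or `modfree_multifit`.
#' @param fm A `feature_matrix`.
#' @return Fraction of correctly classified sequences.
#' @export
accuracy <- function(fit, fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (inherits(fit, "modfree_multifit")) {
    mean(classify_multi(fit, fm) == fm$classes[fm$y])
  } else {
    mean(classify(fit, fm) == fm$y)
  }
}
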