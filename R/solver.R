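# Elastic-net penalized logistic and multinomial regression, fitted by an
# accelerated proximal gradient method (soft-thresholding gives exact zeros;
# the intercept is never penalized, and the 0/1 indicator features are used
# unstandardized).

# Lipschitz constant of the smooth part (logistic or softmax loss + ridge)
# over the intercept-augmented design. `curv` is 1/4 for logistic, 1/2 for
# softmax.
lipschitz_const <- function(X, lambda, l1_ratio, curv, smax_sq = NULL) {
  if (is.null(smax_sq)) smax_sq <- aug_spectral_norm_sq(X, 100L)
  curv * smax_sq / nrow(X) + lambda * (1 - l1_ratio) + 1e-12
}

#' Fit an elastic-net penalized logistic regression
#'
#' Minimizes mean logistic loss plus
#' `lambda * (l1_ratio * sum(|w|) + (1 - l1_ratio)/2 * sum(w^2))` over the
#' weights (the intercept is unpenalized) by FISTA proximal gradient descent
#' with soft-thresholding, so retained coefficients are exact zeros or not.
#'
#' @param fm A binary `feature_matrix` (or any list with numeric matrix `X`
#'   and 0/1 vector `y`).
#' @param lambda Regularization strength, `>= 0`. `lambda = 0` is permitted
#'   but relies on the iteration cap: on separable data the unpenalized
#'   optimum diverges.
#' @param l1_ratio Mix between L1 (`1`) and ridge (`0`) penalties.
#' @param tol Relative objective-decrease convergence tolerance.
#' @param max_iter Iteration cap.
#' @param init Optional warm start: list with `w`, `intercept`.
#' @param smax_sq Optional precomputed squared spectral norm of the
#'   intercept-augmented design (reused across a grid for speed).
#' @return An object of class `modfree_fit`: `intercept`, `weights` (named
#'   numeric, exact zeros where eliminated), `lambda`, `l1_ratio`,
#'   `nonzero_count`, `converged`, `objective`, `iterations`, and the
#'   `column_index`/`classes` carried over from `fm` when present.
#' @export
fit_elastic_net_logistic <- function(fm, lambda, l1_ratio, tol = 1e-9,
                                     max_iter = 5000L, init = NULL,
                                     smax_sq = NULL) {
  X <- fm$X
  y <- as.numeric(fm$y)
  stopifnot(is.matrix(X), all(y %in% c(0, 1)))
  if (!is.numeric(lambda) || lambda < 0) stop("`lambda` must be >= 0")
  if (l1_ratio < 0 || l1_ratio > 1) stop("`l1_ratio` must lie in [0, 1]")
  w0 <- if (is.null(init)) numeric(ncol(X)) else as.numeric(init$w)
  b0 <- if (is.null(init)) 0 else init$intercept
  lip <- lipschitz_const(X, lambda, l1_ratio, curv = 0.25, smax_sq = smax_sq)
  res <- enet_logistic_fista(X, y, lambda, l1_ratio, w0, b0, lip, tol,
                             as.integer(max_iter))
  if (!is.finite(res$objective)) stop("objective became non-finite")
  if (!res$converged) {
    warning(sprintf("solver did not converge in %d iterations (lambda = %g, l1_ratio = %g)",
                    max_iter, lambda, l1_ratio))
  }
  w <- as.numeric(res$w)
  names(w) <- colnames(X)
  structure(
    list(intercept = res$b, weights = w, lambda = lambda,
         l1_ratio = l1_ratio, nonzero_count = sum(w != 0),
         converged = res$converged, objective = res$objective,
         iterations = res$iterations,
         column_index = fm$column_index, classes = fm$classes),
    class = "modfree_fit")
}

#' @export
print.modfree_fit <- function(x, ...) {
  cat(sprintf("<modfree_fit> lambda = %g, l1_ratio = %g, %d nonzero weight(s), intercept = %.4g%s\n",
              x$lambda, x$l1_ratio, x$nonzero_count, x$intercept,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Penalized objective value of a binary fit
#'
#' Mean logistic loss plus the elastic-net penalty, evaluated at the fit's
#' coefficients on the data in `fm`. Exposed mainly for diagnostics and
#' solver verification.
#'
#' @param fit A `modfree_fit`.
#' @param fm The feature matrix it was fitted on.
#' @return The penalized objective (a scalar).
#' @export
penalized_objective <- function(fit, fm) {
  m <- fit$intercept + drop(fm$X %*% fit$weights)
  loss <- mean(ifelse(m > 0, m + log1p(exp(-m)), log1p(exp(m))) -
                 as.numeric(fm$y) * m)
  loss + fit$lambda * ((1 - fit$l1_ratio) / 2 * sum(fit$weights^2) +
                         fit$l1_ratio * sum(abs(fit$weights)))
}

#' Predict log-odds, probabilities and classes
#'
#' The decision log-odds of a sequence is exactly the intercept plus the sum
#' of the weights of the (column, residue) pairs present in the sequence;
#' gaps contribute nothing.
#'
#' @param fit A `modfree_fit`.
#' @param newdata A `feature_matrix` or an indicator matrix with the same
#'   feature layout as the training data.
#' @return `predict_logodds`: numeric vector; `predict_prob`: probabilities
#'   of the positive (modular) class; `classify`: integer 0/1 calls at the
#'   0.5 probability threshold.
#' @export
predict_logodds <- function(fit, newdata) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$X else newdata
  if (!is.matrix(X) || ncol(X) != length(fit$weights)) {
    stop(sprintf("feature dimension mismatch: model has %d features, data has %s",
                 length(fit$weights),
                 if (is.matrix(X)) ncol(X) else "non-matrix input"))
  }
  fit$intercept + drop(X %*% fit$weights)
}

#' @rdname predict_logodds
#' @export
predict_prob <- function(fit, newdata) {
  plogis(predict_logodds(fit, newdata))
}

#' @rdname predict_logodds
#' @param threshold Probability threshold for a positive call.
#' @export
classify <- function(fit, newdata, threshold = 0.5) {
  as.integer(predict_prob(fit, newdata) >= threshold)
}

#' Fit an elastic-net penalized multinomial (softmax) regression
#'
#' Softmax regression over `K >= 3` classes with the elastic-net penalty
#' applied to every class weight vector (class intercepts unpenalized);
#' fitted by the same proximal gradient machinery as the binary model.
#'
#' @inheritParams fit_elastic_net_logistic
#' @param fm A `feature_matrix` with three or more classes.
#' @return An object of class `modfree_multifit`: `intercepts` (length K),
#'   `weights` (p x K matrix), `classes`, `lambda`, `l1_ratio`,
#'   `nonzero_count` (over all classes), `converged`, `objective`,
#'   `iterations`.
#' @export
fit_multinomial <- function(fm, lambda, l1_ratio, tol = 1e-9,
                            max_iter = 5000L, init = NULL, smax_sq = NULL) {
  X <- fm$X
  K <- length(fm$classes)
  if (K < 3L) stop("multinomial fit requires at least 3 classes; use fit_elastic_net_logistic")
  yidx <- fm$y - 1L                      # 0-based class index for C++
  stopifnot(all(yidx %in% 0:(K - 1L)))
  if (!is.numeric(lambda) || lambda < 0) stop("`lambda` must be >= 0")
  if (l1_ratio < 0 || l1_ratio > 1) stop("`l1_ratio` must lie in [0, 1]")
  W0 <- if (is.null(init)) matrix(0, ncol(X), K) else init$weights
  b0 <- if (is.null(init)) rep(0, K) else init$intercepts
  lip <- lipschitz_const(X, lambda, l1_ratio, curv = 0.5, smax_sq = smax_sq)
  res <- enet_multinomial_fista(X, yidx, K, lambda, l1_ratio, W0,
                                matrix(b0, nrow = 1L), lip, tol,
                                as.integer(max_iter))
  if (!is.finite(res$objective)) stop("objective became non-finite")
  if (!res$converged) {
    warning(sprintf("solver did not converge in %d iterations (lambda = %g, l1_ratio = %g)",
                    max_iter, lambda, l1_ratio))
  }
  W <- res$W
  dimnames(W) <- list(colnames(X), fm$classes)
  structure(
    list(intercepts = setNames(as.numeric(res$b), fm$classes), weights = W,
         classes = fm$classes, lambda = lambda, l1_ratio = l1_ratio,
         nonzero_count = sum(W != 0), converged = res$converged,
         objective = res$objective, iterations = res$iterations,
         column_index = fm$column_index),
    class = "modfree_multifit")
}

#' @export
print.modfree_multifit <- function(x, ...) {
  cat(sprintf("<modfree_multifit> %d classes, lambda = %g, l1_ratio = %g, %d nonzero weight(s)%s\n",
              length(x$classes), x$lambda, x$l1_ratio, x$nonzero_count,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Class probabilities from a multinomial fit
#'
#' @param fit A `modfree_multifit`.
#' @param newdata A `feature_matrix` or indicator matrix.
#' @return `predict_prob_multi`: n x K matrix of softmax probabilities (rows
#'   sum to 1); `classify_multi`: character vector of argmax class labels
#'   (ties broken toward the earlier class in sorted order).
#' @export
predict_prob_multi <- function(fit, newdata) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$X else newdata
  if (ncol(X) != nrow(fit$weights)) stop("feature dimension mismatch")
  M <- sweep(X %*% fit$weights, 2L, fit$intercepts, "+")
  M <- M - apply(M, 1L, max)
  P <- exp(M)
  P / rowSums(P)
}

#' @rdname predict_prob_multi
#' @export
classify_multi <- function(fit, newdata) {
  P <- predict_prob_multi(fit, newdata)
  fit$classes[apply(P, 1L, which.max)]
}

#' Penalized objective value of a multinomial fit
#'
#' @param fit A `modfree_multifit`.
#' @param fm The feature matrix it was fitted on.
#' @return Mean softmax cross-entropy plus the elastic-net penalty.
#' @export
penalized_objective_multi <- function(fit, fm) {
  M <- sweep(fm$X %*% fit$weights, 2L, fit$intercepts, "+")
  mx <- apply(M, 1L, max)
  lse <- mx + log(rowSums(exp(M - mx)))
  loss <- mean(lse - M[cbind(seq_len(nrow(M)), fm$y)])
  loss + fit$lambda * ((1 - fit$l1_ratio) / 2 * sum(fit$weights^2) +
                         fit$l1_ratio * sum(abs(fit$weights)))
}
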