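test_that("separable one-column toy is solved with the expected geometry", {
  fm <- toy_binary_fm()
  fit <- fit_elastic_net_logistic(fm, lambda = 0.01, l1_ratio = 0.5,
                                  tol = 1e-12, max_iter = 20000)
  expect_true(fit$converged)
  expect_gt(fit$weights[["c1_A"]], 0)
  expect_lt(fit$weights[["c1_G"]], 0)
  expect_equal(accuracy(fit, fm), 1.0)
  # by symmetry of the design the intercept vanishes
  expect_lt(abs(fit$intercept), 1e-6)

  # independent reference solver (glmnet) reaches the same objective
  skip_if_not_installed("glmnet")
  g <- glmnet::glmnet(fm$X, fm$y, family = "binomial", alpha = 0.5,
                      lambda = c(1, 0.1, 0.01), standardize = FALSE,
                      thresh = 1e-14)
  co <- as.numeric(glmnet::coef.glmnet(g, s = 0.01, exact = TRUE,
                                       x = fm$X, y = fm$y))
  ours <- enet_objective(fm$X, fm$y, fit$intercept, fit$weights,
                         0.01, 0.5)
  theirs <- enet_objective(fm$X, fm$y, co[1], co[-1], 0.01, 0.5)
  expect_lt(abs(ours - theirs), 1e-3)
  # and the package's own objective accessor agrees with the oracle
  expect_equal(penalized_objective(fit, fm), ours, tolerance = 1e-12)
})

test_that("solver matches brute-force minimization on small toys", {
  cases <- list(
    list(lambda = 0.01, l1 = 0.5),
    list(lambda = 0.05, l1 = 1.0),
    list(lambda = 0.2, l1 = 0.1)
  )
  fm <- toy_binary_fm()
  active <- match(c("c1_A", "c1_G"), colnames(fm$X))
  for (cs in cases) {
    fit <- fit_elastic_net_logistic(fm, cs$lambda, cs$l1, tol = 1e-13,
                                    max_iter = 50000)
    ours <- enet_objective(fm$X, fm$y, fit$intercept, fit$weights,
                           cs$lambda, cs$l1)
    ref <- dense_grid_min(fm$X, fm$y, active, cs$lambda, cs$l1)
    expect_lt(abs(ours - ref$objective), 1e-4)
    expect_lte(ours, ref$objective + 1e-6)   # never worse than the grid
  }
})

test_that("fully penalized limit zeroes all weights, intercept = log odds", {
  # unbalanced classes: 12 modular, 8 free
  aln <- make_aln(stats::setNames(rep(c("AC", "GC"), c(12, 8)),
                                  sprintf("s%02d", 1:20)),
                  classes = rep(c("modular", "free"), c(12, 8)))
  fm <- one_hot_encode(aln)
  fit <- fit_elastic_net_logistic(fm, lambda = 1e3, l1_ratio = 0.5,
                                  tol = 1e-14, max_iter = 20000)
  expect_equal(fit$nonzero_count, 0L)
  expect_identical(unname(fit$weights), rep(0, 40))
  expect_equal(fit$intercept, log(12 / 8), tolerance = 1e-5)
})

test_that("fitted points satisfy the elastic-net KKT conditions", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 30
    L <- sample(2:3, 1)
    seqs <- replicate(n, paste(sample(c("A", "C", "D", "G"), L,
                                      replace = TRUE), collapse = ""))
    classes <- sample(c("modular", "free"), n, replace = TRUE)
    if (length(unique(classes)) < 2) classes[1:2] <- c("modular", "free")
    fm <- one_hot_encode(make_aln(stats::setNames(
      seqs, sprintf("s%03d", 1:n)), classes = classes))
    lambda <- stats::runif(1, 0.01, 0.2)
    l1 <- sample(c(0.3, 0.7, 1.0), 1)
    fit <- fit_elastic_net_logistic(fm, lambda, l1, tol = 1e-14,
                                    max_iter = 50000)
    g <- numeric_smooth_grad(fm$X, fm$y, fit$intercept, fit$weights,
                             lambda, l1)
    expect_lt(abs(g$b), 1e-5)
    nz <- fit$weights != 0
    if (any(nz)) {
      expect_lt(max(abs(g$w[nz] + lambda * l1 * sign(fit$weights[nz]))),
                1e-5)
    }
    if (any(!nz)) {
      expect_lt(max(abs(g$w[!nz])), lambda * l1 + 1e-5)
    }
  }
})

test_that("log-odds predictions are exactly additive in matched weights", {
  fm <- toy_binary_fm()
  fit <- fit_elastic_net_logistic(fm, 0.01, 0.5)
  lo <- predict_logodds(fit, fm)
  manual <- fit$intercept + drop(fm$X %*% fit$weights)
  expect_identical(lo, manual)

  # hand-checkable single-weight model
  toy <- fit
  toy$weights[] <- 0
  toy$weights["c1_A"] <- 2
  toy$intercept <- 0
  xa <- fm$X[1, , drop = FALSE]       # sequence with A at column 1
  expect_equal(unname(predict_logodds(toy, xa)), 2)
  expect_equal(unname(predict_prob(toy, xa)), stats::plogis(2),
               tolerance = 1e-12)
  expect_equal(round(unname(predict_prob(toy, xa)), 4), 0.8808)
  # a gap contributes nothing
  gap_row <- matrix(0, 1, ncol(fm$X))
  expect_equal(predict_logodds(toy, gap_row), 0)
  expect_equal(predict_prob(toy, gap_row), 0.5)
  # null model predicts 0.5 everywhere
  null <- toy; null$weights[] <- 0
  expect_true(all(predict_prob(null, fm) == 0.5))
  expect_error(predict_logodds(fit, matrix(0, 1, 7)), "dimension mismatch")
})

test_that("multinomial fit separates three privately marked classes", {
  set.seed(9)
  n_per <- 30; L <- 12
  classes <- rep(c("modular", "free_first", "free_internal"), each = n_per)
  marks <- c(modular = 1L, free_first = 2L, free_internal = 3L)
  residues <- c("W", "H", "M")
  seqs <- vapply(seq_along(classes), function(i) {
    s <- sample(c("A", "C", "D", "G"), L, replace = TRUE)
    s[marks[[classes[i]]]] <- residues[marks[[classes[i]]]]
    paste(s, collapse = "")
  }, character(1))
  fm <- one_hot_encode(make_aln(stats::setNames(
    seqs, sprintf("s%03d", seq_along(seqs))), classes = classes))
  expect_equal(length(fm$classes), 3L)
  fit <- fit_multinomial(fm, lambda = 0.005, l1_ratio = 0.5, tol = 1e-10,
                         max_iter = 20000)
  # per-class diagnostic weights are positive for their own class
  expect_gt(fit$weights["c1_W", "modular"], 0)
  expect_gt(fit$weights["c2_H", "free_first"], 0)
  expect_gt(fit$weights["c3_M", "free_internal"], 0)
  expect_equal(accuracy(fit, fm), 1.0)
  # probabilities sum to one for arbitrary inputs
  P <- predict_prob_multi(fit, fm)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-12)
  rand <- matrix(stats::rbinom(5 * ncol(fm$X), 1, 0.05), nrow = 5)
  expect_equal(unname(rowSums(predict_prob_multi(fit, rand))), rep(1, 5),
               tolerance = 1e-12)
})

test_that("multinomial objective matches the reference solver's solution", {
  skip_if_not_installed("glmnet")
  set.seed(21)
  n <- 60; L <- 6
  classes <- rep(c("modular", "free_first", "free_internal"), each = n / 3)
  seqs <- replicate(n, paste(sample(c("A", "C", "G", "W"), L, replace = TRUE),
                             collapse = ""))
  seqs[classes == "modular"] <- sub("^.", "W", seqs[classes == "modular"])
  fm <- one_hot_encode(make_aln(stats::setNames(seqs, sprintf("s%03d", 1:n)),
                                classes = classes))
  lambda <- 0.02; l1 <- 0.5
  fit <- fit_multinomial(fm, lambda, l1, tol = 1e-13, max_iter = 50000)
  g <- glmnet::glmnet(fm$X, factor(fm$classes[fm$y], levels = fm$classes),
                      family = "multinomial", alpha = l1,
                      lambda = c(0.5, 0.1, lambda), standardize = FALSE,
                      thresh = 1e-14)
  co <- glmnet::coef.glmnet(g, s = lambda)
  ref <- fit
  ref$weights <- do.call(cbind, lapply(co, function(m) as.numeric(m)[-1]))
  dimnames(ref$weights) <- dimnames(fit$weights)
  ref$intercepts[] <- vapply(co, function(m) as.numeric(m)[1], numeric(1))
  ours <- penalized_objective_multi(fit, fm)
  theirs <- penalized_objective_multi(ref, fm)
  expect_lt(abs(ours - theirs), 1e-3)
})

test_that("collapsing two classes reproduces the binary decisions", {
  set.seed(31)
  n_per <- 25; L <- 10
  classes3 <- rep(c("modular", "free_first", "free_internal"), each = n_per)
  seqs <- vapply(classes3, function(cl) {
    s <- sample(c("A", "C", "D", "G"), L, replace = TRUE)
    # strong modular mark; the two free classes share the background
    if (cl == "modular") s[1] <- "W" else s[1] <- "C"
    paste(s, collapse = "")
  }, character(1))
  aln <- make_aln(stats::setNames(seqs, sprintf("s%03d", seq_along(seqs))))
  fm3 <- one_hot_encode(aln, classes3)
  fit3 <- fit_multinomial(fm3, 0.01, 0.5, tol = 1e-10, max_iter = 20000)
  pred3 <- classify_multi(fit3, fm3) == "modular"
  classes2 <- ifelse(classes3 == "modular", "modular", "free")
  fm2 <- one_hot_encode(aln, classes2)
  fit2 <- fit_elastic_net_logistic(fm2, 0.01, 0.5, tol = 1e-10,
                                   max_iter = 20000)
  pred2 <- classify(fit2, fm2) == 1
  expect_equal(pred3, pred2)
})

test_that("solver input validation", {
  fm <- toy_binary_fm(4)
  expect_error(fit_elastic_net_logistic(fm, -1, 0.5), "lambda")
  expect_error(fit_elastic_net_logistic(fm, 0.1, 1.5), "l1_ratio")
  expect_warning(fit_elastic_net_logistic(fm, 1e-6, 0.5, max_iter = 3),
                 "did not converge")
})
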