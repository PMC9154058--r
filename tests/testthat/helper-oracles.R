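# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately written without reaching into the package
# internals it checks.

make_aln <- function(seqs, classes = NULL, orthogroups = NULL) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_along(seqs))
  aa_alignment(unname(seqs), id = ids, orthogroup = orthogroups,
               class_label = classes)
}

# Random master alignment with the structure a representative-guided merge
# asserts: shared core columns (each supported by at least one
# representative), group rows carrying residues only at core columns where
# their own representative has a residue, and group-private insertion
# columns placed directly after their anchoring core column. With
# block_order = "lexicographic" co-anchored insertion blocks follow the
# canonical group order, so split-then-merge must reproduce the master
# exactly (up to all-gap columns); with "random" order, up to the canonical
# reordering of co-anchored blocks.
random_master <- function(seed, n_core = 14, n_groups = 3,
                          rows_per_group = 3,
                          block_order = c("random", "lexicographic")) {
  block_order <- match.arg(block_order)
  set.seed(seed)
  labels <- sprintf("og%02d", seq_len(n_groups))
  rchar <- function(n) sample(modfree::AA_ALPHABET, n, replace = TRUE)

  # representative residue mask per group over the core columns
  rep_mask <- sapply(labels, function(g) runif(n_core) < 0.7)
  for (g in seq_len(n_groups)) {
    while (sum(rep_mask[, g]) < 4) rep_mask[sample(n_core, 1), g] <- TRUE
  }
  for (j in seq_len(n_core)) {             # every core column rep-supported
    if (!any(rep_mask[j, ])) rep_mask[j, sample(n_groups, 1)] <- TRUE
  }

  # group-private insertions: anchored at 0 or at a core column where the
  # group's representative has a residue; width 1-2 columns
  insertions <- lapply(seq_len(n_groups), function(g) {
    k <- sample(0:2, 1)
    if (k == 0) return(data.frame(anchor = integer(), width = integer()))
    anchors <- unique(sample(c(0, which(rep_mask[, g])), k))
    data.frame(anchor = sort(anchors),
               width = sample(1:2, length(anchors), replace = TRUE))
  })

  # column layout: each anchor (a core column or position 0) is followed by
  # the insertion blocks anchored at it, in canonical or shuffled order
  cols <- list()
  for (a in 0:n_core) {
    if (a >= 1) cols[[length(cols) + 1L]] <- list(type = "core", core = a)
    order_g <- if (block_order == "lexicographic") seq_len(n_groups) else
      sample(n_groups)
    for (g in order_g) {
      ins <- insertions[[g]]
      w <- ins$width[ins$anchor == a]
      if (length(w)) {
        for (x in seq_len(w)) {
          cols[[length(cols) + 1L]] <- list(type = "ins", group = g)
        }
      }
    }
  }

  n_rows <- n_groups * rows_per_group
  groups <- rep(labels, each = rows_per_group)
  is_rep <- rep(c(TRUE, rep(FALSE, rows_per_group - 1)), n_groups)
  mat <- matrix("-", nrow = n_rows, ncol = length(cols))
  for (ci in seq_along(cols)) {
    cl <- cols[[ci]]
    if (cl$type == "core") {
      for (i in seq_len(n_rows)) {
        g <- match(groups[i], labels)
        if (rep_mask[cl$core, g] && (is_rep[i] || runif(1) < 0.7)) {
          mat[i, ci] <- rchar(1)
        }
      }
    } else {
      rows <- which(groups == labels[cl$group] & !is_rep)
      filled <- rows[runif(length(rows)) < 0.8]
      if (!length(filled)) filled <- rows[sample.int(length(rows), 1)]
      mat[filled, ci] <- rchar(length(filled))
    }
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  ids <- sprintf("%s_r%02d", groups,
                 rep(seq_len(rows_per_group), n_groups))
  make_aln(stats::setNames(seqs, ids), orthogroups = groups)
}

# Literal enumeration of the Benjamini-Hochberg step-up rule: hypothesis i
# is rejected iff some rank k at or after its own satisfies p(k) <= k/m*alpha.
brute_force_bh <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ranks <- match(seq_len(m), ord)
  sapply(seq_len(m), function(i) {
    any(sapply(seq_len(m), function(k) {
      k >= ranks[i] && p[ord[k]] <= k / m * alpha
    }))
  })
}

# Penalized logistic objective evaluated directly (independent of the
# package's own penalized_objective).
enet_objective <- function(X, y, b, w, lambda, l1) {
  m <- b + as.numeric(X %*% w)
  loss <- mean(log1p(exp(-abs(m))) + pmax(m, 0) - y * m)
  loss + lambda * (l1 * sum(abs(w)) + (1 - l1) / 2 * sum(w^2))
}

# Coarse-to-fine grid minimization of the penalized objective over the
# intercept and a small set of active coordinates (all other weights held
# at zero, which is optimal for features that are identically zero in X).
dense_grid_min <- function(X, y, active, lambda, l1, half_width = 6,
                           points = 13, rounds = 9) {
  d <- length(active) + 1
  center <- rep(0, d)
  hw <- half_width
  best <- Inf
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(d), function(j) {
      seq(center[j] - hw, center[j] + hw, length.out = points)
    })
    pts <- as.matrix(expand.grid(grids))
    vals <- apply(pts, 1, function(th) {
      w <- rep(0, ncol(X)); w[active] <- th[-1]
      enet_objective(X, y, th[1], w, lambda, l1)
    })
    k <- which.min(vals)
    best <- vals[k]
    center <- pts[k, ]
    hw <- hw * 2 / (points - 1) * 1.5   # shrink around the incumbent
  }
  list(objective = best, theta = center)
}

# Central-difference gradient of the smooth (loss + ridge) part of the
# objective at the fitted point.
numeric_smooth_grad <- function(X, y, b, w, lambda, l1, eps = 1e-6) {
  f <- function(bb, ww) {
    m <- bb + as.numeric(X %*% ww)
    mean(log1p(exp(-abs(m))) + pmax(m, 0) - y * m) +
      lambda * (1 - l1) / 2 * sum(ww^2)
  }
  gb <- (f(b + eps, w) - f(b - eps, w)) / (2 * eps)
  gw <- vapply(seq_along(w), function(j) {
    wp <- w; wp[j] <- wp[j] + eps
    wm <- w; wm[j] <- wm[j] - eps
    (f(b, wp) - f(b, wm)) / (2 * eps)
  }, numeric(1))
  list(b = gb, w = gw)
}

# Monte-Carlo oracle for the divergent-pair estimator: simulates observed
# difference fractions directly from the probability model (site rates,
# total substitution events, 19/20 visible-change factor), with no sequence
# objects involved, and returns the expected gamma-corrected estimate and
# its spread.
mc_pair_oracle <- function(d, shape, n_sites, n_pairs, reps = 60,
                           seed = 424242) {
  set.seed(seed)
  est <- replicate(reps, {
    dhat <- replicate(n_pairs, {
      r <- rgamma(n_sites, shape = shape, rate = shape)
      p_site <- 19 / 20 * (1 - exp(-d * r))
      p_hat <- mean(runif(n_sites) < p_site)
      shape * ((1 - p_hat)^(-1 / shape) - 1)
    })
    mean(dhat)
  })
  list(mean = mean(est), sd = sd(est))
}

# Tiny separable binary fixture: class "modular" all A at the single
# column, class "free" all G.
toy_binary_fm <- function(n_per = 10) {
  aln <- make_aln(c(rep("A", n_per), rep("G", n_per)),
                  classes = rep(c("modular", "free"), each = n_per))
  one_hot_encode(aln)
}
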