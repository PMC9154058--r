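# Generators with planted ground truth: class-labelled alignments with
# diagnostic columns, orthogroup splits of a known master alignment (the
# reconstruction oracle for merging), and sequence pairs diverged by a known
# expected number of substitutions per site.

#' Describe a planted-signal alignment design
#'
#' Defines the ground truth for [simulate_classed_alignment()]: which
#' columns are diagnostic for which class (each held at a fixed planted
#' residue within that class), the background residue profile everywhere
#' else, and the gap rate. The default design plants 8 modular-diagnostic
#' and 2 free-diagnostic columns in a 100-column alignment with 200
#' sequences per class and a 5% gap rate, i.i.d. uniform background.
#'
#' @param length Alignment length in columns.
#' @param n_per_class Sequences per class.
#' @param n_diagnostic Named integer vector: diagnostic columns per class.
#'   Names are the class labels; for two classes use `modular` and `free`,
#'   for three `modular`, `free_first`, `free_internal`.
#' @param background_profile Amino-acid frequency vector of length 20
#'   (normalized internally); default uniform.
#' @param gap_rate Per-cell gap probability outside diagnostic columns, in
#'   `[0, 1)`.
#' @param fidelity Probability that a sequence carries its class's planted
#'   residue at a diagnostic column (default 1 = invariant).
#' @param seed Integer seed; diagnostic column positions and residues are
#'   drawn from it, so a truth object is a pure function of its arguments.
#' @return An object of class `planted_truth` with fields
#'   `diagnostic_columns` (data frame `column`, `class`, `residue`),
#'   `classes`, and the remaining design parameters.
#' @export
planted_truth <- function(length = 100L, n_per_class = 200L,
                          n_diagnostic = c(modular = 8L, free = 2L),
                          background_profile = rep(1 / 20, 20L),
                          gap_rate = 0.05, fidelity = 1, seed = 7L) {
  if (is.null(names(n_diagnostic)) || anyDuplicated(names(n_diagnostic))) {
    stop("`n_diagnostic` must be named by distinct class labels")
  }
  if (gap_rate < 0 || gap_rate >= 1) stop("`gap_rate` must lie in [0, 1)")
  if (fidelity < 0 || fidelity > 1) stop("`fidelity` must lie in [0, 1]")
  if (length < sum(n_diagnostic)) {
    stop("alignment length smaller than the number of diagnostic columns")
  }
  if (length(background_profile) != 20L || any(background_profile < 0) ||
      sum(background_profile) <= 0) {
    stop("`background_profile` must be 20 nonnegative frequencies")
  }
  background_profile <- background_profile / sum(background_profile)
  classes <- names(n_diagnostic)
  diag_cols <- with_seed(seed, {
    cols <- sample.int(length, sum(n_diagnostic))
    data.frame(
      column = cols,
      class = rep(classes, times = n_diagnostic),
      residue = sample(AA_ALPHABET, sum(n_diagnostic), replace = TRUE),
      stringsAsFactors = FALSE)
  })
  structure(
    list(diagnostic_columns = diag_cols, classes = classes,
         length = as.integer(length), n_per_class = as.integer(n_per_class),
         background_profile = background_profile, gap_rate = gap_rate,
         fidelity = fidelity, seed = as.integer(seed)),
    class = "planted_truth")
}

#' Simulate a class-labelled alignment with planted diagnostic columns
#'
#' Each sequence carries its own class's planted residue at that class's
#' diagnostic columns (with probability `fidelity`, default invariant);
#' every other position - including other classes' diagnostic columns - is
#' an i.i.d. draw from the background profile. Gaps are inserted i.i.d. at
#' the design gap rate, never inside diagnostic columns. Deterministic
#' under the truth's seed.
#'
#' @param truth A [planted_truth()] design.
#' @return List with `alignment` (an `aa_aln` with `class_label` set),
#'   `labels` (data frame `id`, `class_label`) and `truth`.
#' @export
simulate_classed_alignment <- function(truth) {
  stopifnot(inherits(truth, "planted_truth"))
  n_cls <- length(truth$classes)
  n <- truth$n_per_class * n_cls
  L <- truth$length
  labels <- rep(truth$classes, each = truth$n_per_class)
  with_seed(derive_seed(truth$seed, 1L), {
    mat <- matrix(sample(AA_ALPHABET, n * L, replace = TRUE,
                         prob = truth$background_profile),
                  nrow = n, ncol = L)
    dc <- truth$diagnostic_columns
    for (r in seq_len(nrow(dc))) {
      rows <- which(labels == dc$class[r])
      planted <- runif(length(rows)) < truth$fidelity
      mat[rows[planted], dc$column[r]] <- dc$residue[r]
    }
    if (truth$gap_rate > 0) {
      open_cols <- setdiff(seq_len(L), dc$column)
      if (length(open_cols)) {
        sub <- mat[, open_cols, drop = FALSE]
        sub[matrix(runif(length(sub)) < truth$gap_rate,
                   nrow = n)] <- GAP
        mat[, open_cols] <- sub
      }
    }
  })
  ids <- sprintf("seq%04d_%s", seq_len(n), labels)
  aln <- aa_alignment(apply(mat, 1L, paste, collapse = ""), id = ids,
                      class_label = labels)
  list(alignment = aln,
       labels = data.frame(id = ids, class_label = labels,
                           stringsAsFactors = FALSE),
       truth = truth)
}

#' Split a master alignment into orthogroups (merge oracle)
#'
#' Inverse construction for [merge_alignments()]: rows of a known master
#' alignment are partitioned into orthogroups, each orthogroup's local
#' alignment is the group's rows with all-gap columns stripped, and the
#' representative of a group is its first row by id (C collation). The
#' representative alignment is the representative rows in master
#' coordinates, again with all-gap columns stripped.
#'
#' @param master An `aa_aln` alignment.
#' @param groups Character vector assigning each master row to an
#'   orthogroup.
#' @return List with `orthogroups` (named list of `aa_aln`), `reps` (the
#'   representative `aa_aln`) and `rep_ids` (named character vector).
#' @export
simulate_orthogroup_split <- function(master, groups) {
  stopifnot(inherits(master, "aa_aln"))
  groups <- as.character(groups)
  if (length(groups) != length(master$id) || anyNA(groups)) {
    stop("every master row needs a group label")
  }
  labels <- sort(unique(groups), method = "radix")
  orthogroups <- list()
  rep_ids <- character()
  for (g in labels) {
    rows <- which(groups == g)
    og <- strip_empty_columns(master[rows])
    orthogroups[[g]] <- og
    rep_ids[[g]] <- og$id[order_c(og$id)][1L]
  }
  rep_rows <- match(unname(rep_ids), master$id)
  reps <- strip_empty_columns(master[rep_rows])
  list(orthogroups = orthogroups, reps = reps, rep_ids = rep_ids)
}

#' Simulate sequence pairs at a known expected divergence
#'
#' Equal-input substitution model with gamma rate heterogeneity: for each
#' pair, an ancestor is drawn i.i.d. uniform over the 20 amino acids; each
#' site gets a rate `r ~ Gamma(shape = a, mean = 1)` shared by both
#' lineages; each lineage accumulates `Poisson(d/2 * r)` substitution
#' events per site, every event replacing the residue by a uniform draw
#' from all 20 amino acids (so a fraction 19/20 of events are visible).
#' The expected observed difference fraction is
#' `p* = (19/20) * (1 - (1 + d/a)^(-a))`.
#'
#' @param d True expected substitutions per site separating a pair
#'   (`d/2` on each lineage).
#' @param shape Gamma shape `a > 0` of the site-rate distribution.
#' @param n_sites Number of sites per sequence.
#' @param n_pairs Number of independent pairs.
#' @param seed Integer seed.
#' @return List with `pairs` (list of `list(a =, b =)` sequence strings)
#'   and `truth` (the parameters, including the derived `expected_p`).
#' @export
simulate_divergent_pairs <- function(d = 1.0, shape = 1.0, n_sites = 5000L,
                                     n_pairs = 50L, seed = 7L) {
  if (d < 0) stop("`d` must be nonnegative")
  if (shape <= 0) stop("`shape` must be positive")
  pairs <- with_seed(seed, {
    lapply(seq_len(n_pairs), function(i) {
      anc <- sample(AA_ALPHABET, n_sites, replace = TRUE)
      r <- rgamma(n_sites, shape = shape, rate = shape)   # mean 1
      evolve <- function() {
        k <- rpois(n_sites, d / 2 * r)
        out <- anc
        hit <- k > 0L
        # after >= 1 uniform replacement the end state is uniform over 20
        out[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
        out
      }
      list(a = paste(evolve(), collapse = ""),
           b = paste(evolve(), collapse = ""))
    })
  })
  expected_p <- 19 / 20 * (1 - (1 + d / shape)^(-shape))
  list(pairs = pairs,
       truth = list(d = d, shape = shape, n_sites = as.integer(n_sites),
                    n_pairs = as.integer(n_pairs), seed = as.integer(seed),
                    expected_p = expected_p))
}
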