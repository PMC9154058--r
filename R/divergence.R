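# Corrected amino-acid distances within and between orthogroups, plus the
# species-presence filter.

#' Proportion of differing residues (p-distance)
#'
#' Compares two aligned, equal-length sequences over comparable columns
#' (residues in both rows; pairwise deletion of gap columns).
#'
#' @param a,b Aligned sequence strings of equal length.
#' @return Fraction of differing comparable columns, or `NA` (with a
#'   warning) when no column is comparable.
#' @export
p_distance <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences must be aligned to equal length")
  ca <- seq_chars(a); cb <- seq_chars(b)
  comparable <- ca != GAP & cb != GAP
  if (!any(comparable)) {
    warning("no comparable columns; p-distance undefined")
    return(NA_real_)
  }
  sum(ca[comparable] != cb[comparable]) / sum(comparable)
}

#' Poisson-corrected distance
#'
#' Corrects an observed difference fraction for multiple substitutions at a
#' site assuming a uniform rate: `d = -ln(1 - p)`.
#'
#' @param p Observed difference fraction(s) in `[0, 1)`.
#' @return Corrected distance(s); `NA` where `p >= 1` (saturation).
#' @export
poisson_distance <- function(p) {
  if (any(p < 0, na.rm = TRUE)) stop("`p` must be nonnegative")
  out <- ifelse(!is.na(p) & p < 1, -log(1 - p), NA_real_)
  if (any(!is.na(p) & p >= 1)) {
    warning("saturated p-distance(s) (p >= 1) flagged as NA")
  }
  out
}

#' Gamma-corrected Poisson distance
#'
#' Poisson correction with gamma-distributed rate variation among sites
#' (shape `a`): `d = a * ((1 - p)^(-1/a) - 1)`. As `a` grows the correction
#' approaches the plain Poisson correction.
#'
#' @param p Observed difference fraction(s) in `[0, 1)`.
#' @param shape Gamma shape parameter `a > 0` (default 1).
#' @return Corrected distance(s); `NA` where `p >= 1`.
#' @export
gamma_poisson_distance <- function(p, shape = 1) {
  if (!is.numeric(shape) || length(shape) != 1L || shape <= 0) {
    stop("`shape` must be a single positive number")
  }
  if (any(p < 0, na.rm = TRUE)) stop("`p` must be nonnegative")
  out <- ifelse(!is.na(p) & p < 1, shape * ((1 - p)^(-1 / shape) - 1),
                NA_real_)
  if (any(!is.na(p) & p >= 1)) {
    warning("saturated p-distance(s) (p >= 1) flagged as NA")
  }
  out
}

#' Mean corrected distances within and between orthogroups
#'
#' Builds the symmetric group-by-group matrix of mean pairwise corrected
#' distances: diagonal cells average all unordered within-group pairs,
#' off-diagonal cells all cross pairs. Saturated pairs (undefined corrected
#' distance) are excluded from the means and counted separately.
#'
#' @param x An `aa_aln` alignment with orthogroup labels (or supply
#'   `groups`).
#' @param groups Character vector of group labels per row; defaults to
#'   `x$orthogroup`.
#' @param correction `"gamma"` (default), `"poisson"` or `"p"` (uncorrected).
#' @param shape Gamma shape parameter, echoed in the result.
#' @return An object of class `group_dist`: list with `labels`, `mean`
#'   (symmetric matrix, `NA` where no defined pair), `n_pairs` (pairs per
#'   cell), `n_excluded` (saturated/undefined pairs per cell), `correction`,
#'   `shape`.
#' @export
group_mean_distances <- function(x, groups = x$orthogroup,
                                 correction = c("gamma", "poisson", "p"),
                                 shape = 1) {
  stopifnot(inherits(x, "aa_aln"))
  correction <- match.arg(correction)
  groups <- as.character(groups)
  if (length(groups) != length(x$id) || anyNA(groups)) {
    stop("every row needs a group label")
  }
  labels <- sort(unique(groups), method = "radix")
  if (length(labels) < 2L) stop("need at least two groups")
  aln_length(x)
  G <- length(labels)
  dsum <- matrix(0, G, G, dimnames = list(labels, labels))
  nok <- matrix(0L, G, G, dimnames = list(labels, labels))
  nexc <- matrix(0L, G, G, dimnames = list(labels, labels))
  gi <- match(groups, labels)
  n <- length(x$seq)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- suppressWarnings(p_distance(x$seq[i], x$seq[j]))
      d <- if (is.na(p)) NA_real_ else suppressWarnings(switch(
        correction,
        gamma = gamma_poisson_distance(p, shape),
        poisson = poisson_distance(p),
        p = p))
      a <- gi[i]; b <- gi[j]
      lo <- min(a, b); hi <- max(a, b)
      if (is.na(d)) {
        nexc[lo, hi] <- nexc[lo, hi] + 1L
      } else {
        dsum[lo, hi] <- dsum[lo, hi] + d
        nok[lo, hi] <- nok[lo, hi] + 1L
      }
    }
  }
  mean_mat <- ifelse(nok > 0L, dsum / nok, NA_real_)
  # symmetrize the upper-triangle accumulators
  mean_mat[lower.tri(mean_mat)] <- t(mean_mat)[lower.tri(mean_mat)]
  npairs <- nok + nexc
  npairs[lower.tri(npairs)] <- t(npairs)[lower.tri(npairs)]
  nexc[lower.tri(nexc)] <- t(nexc)[lower.tri(nexc)]
  sizes <- table(factor(groups, levels = labels))
  if (any(sizes < 2L)) {
    warning(sprintf("group(s) of size 1 have undefined within-group means: %s",
                    paste(labels[sizes < 2L], collapse = ", ")))
  }
  structure(
    list(labels = labels, mean = mean_mat, n_pairs = npairs,
         n_excluded = nexc, correction = correction,
         shape = if (correction == "gamma") shape else NA_real_),
    class = "group_dist")
}

#' @export
print.group_dist <- function(x, ...) {
  cat(sprintf("<group_dist> %d groups, correction = %s%s\n",
              length(x$labels), x$correction,
              if (!is.na(x$shape)) sprintf(" (shape = %g)", x$shape) else ""))
  print(round(x$mean, 4))
  invisible(x)
}

#' Filter species by orthogroup presence
#'
#' Retains the species that occur in at least `min_count` orthogroups.
#'
#' @param presence Logical or numeric matrix / data frame, species in rows
#'   (rownames), orthogroups in columns; nonzero/`TRUE` means present.
#' @param min_count Minimum number of orthogroups (default 10, boundary
#'   inclusive).
#' @return Character vector of retained species names (possibly empty).
#' @export
filter_species_by_presence <- function(presence, min_count = 10L) {
  if (is.data.frame(presence)) presence <- as.matrix(presence)
  if (length(presence) == 0L || nrow(presence) == 0L) return(character())
  if (is.null(rownames(presence))) stop("`presence` needs species rownames")
  counts <- rowSums(presence != 0 & !is.na(presence))
  rownames(presence)[counts >= min_count]
}
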