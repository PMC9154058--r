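# LOGO-style tables: raw model weights per (column, amino acid), and
# per-column residue frequencies with information content for clade subsets.

#' Export nonzero model weights as a LOGO-style table
#'
#' One row per retained (column, amino acid) weight, with the sign class:
#' a positive weight raises the log-odds of the positive (modular) class,
#' a negative one favours the free class. The intercept is reported as a
#' final row with `column = NA`, `aa = "(intercept)"`.
#'
#' @param fit A `modfree_fit`.
#' @return Data frame with columns `column`, `aa`, `weight`, `sign_class`.
#' @export
export_logo_weights <- function(fit) {
  stopifnot(inherits(fit, "modfree_fit"))
  nz <- which(fit$weights != 0)
  ci <- fit$column_index
  if (is.null(ci)) {
    stop("fit carries no column index; fit from a one_hot_encode feature matrix")
  }
  body <- data.frame(
    column = ci$column[nz],
    aa = ci$aa[nz],
    weight = unname(fit$weights[nz]),
    sign_class = ifelse(fit$weights[nz] > 0, "modular-associated",
                        "free-associated"),
    stringsAsFactors = FALSE)
  body <- body[order(body$column, body$aa), , drop = FALSE]
  out <- rbind(body, data.frame(
    column = NA_integer_, aa = "(intercept)", weight = fit$intercept,
    sign_class = NA_character_, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Per-column residue frequencies and information content
#'
#' For a (sub)alignment, computes for every column the amino-acid
#' frequencies over non-gap rows, the gap fraction, and the information
#' content `log2(20) - H` in bits, where `H` is the Shannon entropy of the
#' residue frequencies. An all-gap column is reported with gap fraction 1,
#' zero frequencies and zero information content.
#'
#' @param x An `aa_aln` alignment (typically a clade subset).
#' @return Data frame with columns `column`, `gap_fraction`, `ic`, and one
#'   frequency column per amino acid (`freq_A` ... `freq_Y`).
#' @export
clade_frequency_logo <- function(x) {
  stopifnot(inherits(x, "aa_aln"))
  if (length(x$id) == 0L) stop("empty alignment subset")
  L <- aln_length(x)
  mat <- aln_matrix(x$seq)
  freq <- matrix(0, nrow = L, ncol = 20L,
                 dimnames = list(NULL, paste0("freq_", AA_ALPHABET)))
  gap_fraction <- numeric(L)
  ic <- numeric(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    gap_fraction[j] <- mean(col == GAP)
    res <- col[col != GAP]
    if (length(res) == 0L) next      # all-gap: freq 0, ic 0
    f <- tabulate(match(res, AA_ALPHABET), nbins = 20L) / length(res)
    freq[j, ] <- f
    h <- -sum(f[f > 0] * log2(f[f > 0]))
    ic[j] <- log2(20) - h
  }
  cbind(data.frame(column = seq_len(L), gap_fraction = gap_fraction,
                   ic = ic),
        as.data.frame(freq))
}
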