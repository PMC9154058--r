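# Internal helpers shared across modules.

#' @useDynLib modfree, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats plogis pchisq rgamma rpois runif rbinom sd setNames
#' @importFrom utils head read.delim
NULL

#' The canonical amino-acid alphabet
#'
#' The 20 canonical amino acids in fixed alphabetical one-letter order. This
#' ordering defines the feature layout of [one_hot_encode()] and is relied on
#' throughout the package; it is exported so downstream code can index weight
#' tables consistently.
#'
#' @format A character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP <- "-"

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
# All stochastic entry points funnel through this so identical seeds give
# byte-identical results.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed, keeping the result inside the
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

# Locale-independent lexicographic ordering (C collation), used wherever a
# deterministic tie-break on identifiers is promised.
order_c <- function(...) order(..., method = "radix")

ungap <- function(x) gsub(GAP, "", x, fixed = TRUE)

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# n x L character matrix view of a set of equal-length sequences.
aln_matrix <- function(seqs) {
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}
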