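# Sequence/alignment data model, FASTA round-trip, ambiguity filtering and
# greedy identity dereplication.

#' Construct a sequence set or alignment
#'
#' The central container of the package: an ordered set of amino-acid
#' sequences (possibly gapped with `-`) with unique ids and optional
#' orthogroup and class-label metadata. When all sequences have equal length
#' the object behaves as an alignment; operations that require an alignment
#' check this explicitly.
#'
#' @param seq Character vector of sequences (upper-cased on construction).
#' @param id Character vector of unique, nonempty ids (defaults to names of
#'   `seq`).
#' @param orthogroup Optional character vector of orthogroup labels (`NA`
#'   allowed).
#' @param class_label Optional character vector of class labels, each one of
#'   `"modular"`, `"free"`, `"free_first"`, `"free_internal"` or `NA`.
#' @return An object of class `aa_aln` with fields `id`, `seq`,
#'   `orthogroup`, `class_label`.
#' @export
aa_alignment <- function(seq, id = names(seq), orthogroup = NULL,
                         class_label = NULL) {
  if (length(seq) == 0L) stop("alignment must contain at least one record")
  seq <- toupper(unname(as.character(seq)))
  if (is.null(id)) stop("sequence ids are required")
  id <- as.character(id)
  if (anyNA(id) || any(!nzchar(id))) stop("all ids must be nonempty strings")
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1L]
    stop(sprintf("duplicate sequence id: '%s'", dup))
  }
  if (any(grepl(".", seq, fixed = TRUE))) {
    stop("'.' gap characters are not supported; use '-' as the only gap symbol")
  }
  check_meta <- function(x, what) {
    if (is.null(x)) return(rep(NA_character_, length(seq)))
    x <- as.character(x)
    if (length(x) != length(seq)) {
      stop(sprintf("`%s` must have one entry per sequence", what))
    }
    x
  }
  class_label <- check_meta(class_label, "class_label")
  known <- c("modular", "free", "free_first", "free_internal")
  bad <- setdiff(unique(class_label[!is.na(class_label)]), known)
  if (length(bad)) {
    stop(sprintf("unknown class label(s): %s", paste(bad, collapse = ", ")))
  }
  structure(
    list(id = id, seq = seq,
         orthogroup = check_meta(orthogroup, "orthogroup"),
         class_label = class_label),
    class = "aa_aln"
  )
}

#' @export
length.aa_aln <- function(x) length(x$id)

#' Number of columns of an alignment
#'
#' @param x An `aa_aln` object.
#' @return Column count; errors if the sequences are not all of equal length.
#' @export
aln_length <- function(x) {
  stopifnot(inherits(x, "aa_aln"))
  len <- unique(nchar(x$seq))
  if (length(len) != 1L) {
    stop("sequences have unequal lengths; not an alignment")
  }
  len
}

#' @export
`[.aa_aln` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$id)
  if (anyNA(i)) stop("unknown sequence id in subset")
  aa_alignment(x$seq[i], id = x$id[i], orthogroup = x$orthogroup[i],
               class_label = x$class_label[i])
}

#' @export
print.aa_aln <- function(x, ...) {
  len <- unique(nchar(x$seq))
  cat(sprintf("<aa_aln> %d sequence(s), %s\n", length(x$id),
              if (length(len) == 1L) sprintf("%d columns", len)
              else "unequal lengths"))
  show <- utils::head(seq_along(x$id), 5L)
  for (i in show) {
    s <- x$seq[i]
    if (nchar(s) > 50L) s <- paste0(substr(s, 1L, 50L), "...")
    cat(sprintf("  %-15s %s\n", x$id[i], s))
  }
  if (length(x$id) > 5L) cat(sprintf("  ... and %d more\n", length(x$id) - 5L))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Ids are taken from the header up to the first whitespace; sequences are
#' upper-cased and may be line-wrapped in the file. Duplicate ids, empty
#' files and `.` gap characters are rejected.
#'
#' @param path Path to a plain FASTA file.
#' @return An [aa_alignment()] object (sequences need not be equal length).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("no FASTA records in %s", path))
  ids <- sub("\\s.*$", "", names(set))
  aa_alignment(as.character(set), id = ids)
}

#' Write sequences to a FASTA file
#'
#' Sequences are wrapped at 60 columns. Reading the file back with
#' [read_fasta()] reproduces ids and sequences exactly.
#'
#' @param x An `aa_aln` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "aa_aln"))
  if (length(x$id) == 0L) stop("refusing to write an empty record set")
  set <- Biostrings::BStringSet(x$seq)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read a label table
#'
#' Reads a TSV with columns `id`, `orthogroup`, `class_label` and attaches
#' the metadata to an alignment by id.
#'
#' @param x An `aa_aln` object.
#' @param path Path to the TSV label table.
#' @return `x` with `orthogroup`/`class_label` filled in for matching ids.
#' @export
attach_labels <- function(x, path) {
  stopifnot(inherits(x, "aa_aln"))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "orthogroup", "class_label")
  if (!all(need %in% names(tab))) {
    stop("label table must have columns id, orthogroup, class_label")
  }
  m <- match(x$id, tab$id)
  if (anyNA(m)) {
    stop(sprintf("no label for sequence id '%s'", x$id[which(is.na(m))[1L]]))
  }
  aa_alignment(x$seq, id = x$id, orthogroup = tab$orthogroup[m],
               class_label = tab$class_label[m])
}

#' Remove sequences with ambiguous characters
#'
#' Keeps only records whose sequences are drawn entirely from the 20
#' canonical amino acids plus the gap `-`; anything else (X, B, Z, J, U, O,
#' `*`, ...) disqualifies the whole record. Order is preserved and the
#' number of removed records is reported as an attribute.
#'
#' @param x An `aa_aln` object.
#' @return The filtered `aa_aln` (possibly empty, returned as a plain empty
#'   structure), with attribute `n_removed` and `removed_ids`.
#' @export
filter_ambiguous <- function(x) {
  stopifnot(inherits(x, "aa_aln"))
  allowed <- paste0("^[", paste(AA_ALPHABET, collapse = ""), GAP, "]*$")
  keep <- grepl(allowed, x$seq)
  removed <- x$id[!keep]
  if (length(removed)) {
    message(sprintf("filter_ambiguous: removed %d record(s) with ambiguous characters",
                    length(removed)))
  }
  out <- if (any(keep)) x[which(keep)] else
    structure(list(id = character(), seq = character(),
                   orthogroup = character(), class_label = character()),
              class = "aa_aln")
  attr(out, "n_removed") <- length(removed)
  attr(out, "removed_ids") <- removed
  out
}

#' Pairwise sequence identity
#'
#' Fraction of matching positions among comparable positions. If the two
#' sequences have equal (gapped) length they are treated as rows of a shared
#' alignment and compared over columns where both carry a residue. Otherwise
#' both are gap-stripped and compared position-by-position over the shorter
#' ungapped length (a deliberate simplification of word-based clustering
#' identity: no pairwise alignment is performed).
#'
#' @param a,b Sequence strings (may contain `-`).
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  ua <- ungap(a); ub <- ungap(b)
  if (!nzchar(ua) && !nzchar(ub)) {
    stop("both sequences are empty after removing gaps")
  }
  if (nchar(a) == nchar(b)) {
    ca <- seq_chars(a); cb <- seq_chars(b)
    comparable <- ca != GAP & cb != GAP
    if (!any(comparable)) return(0)
    return(sum(ca[comparable] == cb[comparable]) / sum(comparable))
  }
  ca <- seq_chars(ua); cb <- seq_chars(ub)
  n <- min(length(ca), length(cb))
  if (n == 0L) return(0)
  sum(ca[seq_len(n)] == cb[seq_len(n)]) / n
}

#' Greedy dereplication at an identity threshold
#'
#' Simplified redundancy filter in the spirit of CD-Hit: records are
#' processed in decreasing order of ungapped length (ties broken by id, C
#' collation) and a record is retained only if its identity to every
#' previously retained record is at or below `threshold`. The `>` is strict,
#' so records at exactly the threshold are kept.
#'
#' @param x An `aa_aln` object.
#' @param threshold Identity threshold in `(0, 1]`; default `0.90`.
#' @return List with `kept` (an `aa_aln`, in processing order) and `removed`
#'   (data frame `id`, `matched_id`, `identity` recording, for each removed
#'   record, one retained record it exceeded the threshold against).
#' @export
dereplicate <- function(x, threshold = 0.90) {
  stopifnot(inherits(x, "aa_aln"))
  if (length(x$id) == 0L) stop("no records to dereplicate")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("`threshold` must lie in (0, 1]")
  }
  ord <- order_c(-nchar(ungap(x$seq)), x$id)
  kept_idx <- integer()
  removed <- list()
  for (i in ord) {
    hit <- 0L
    hit_ident <- NA_real_
    for (j in kept_idx) {
      ident <- pairwise_identity(x$seq[i], x$seq[j])
      if (ident > threshold) { hit <- j; hit_ident <- ident; break }
    }
    if (hit == 0L) {
      kept_idx <- c(kept_idx, i)
    } else {
      removed[[length(removed) + 1L]] <-
        data.frame(id = x$id[i], matched_id = x$id[hit],
                   identity = hit_ident, stringsAsFactors = FALSE)
    }
  }
  list(
    kept = x[kept_idx],
    removed = if (length(removed)) do.call(rbind, removed) else
      data.frame(id = character(), matched_id = character(),
                 identity = numeric(), stringsAsFactors = FALSE)
  )
}
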