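# Representative-guided merging of per-orthogroup alignments into one master
# alignment by propagating the gap structure of a structurally aligned set of
# representatives.

#' Map local alignment columns onto master columns
#'
#' Given the representative's row in the master (representative) alignment
#' and the same representative's row inside its orthogroup alignment, map
#' every local column either to the master column carrying the corresponding
#' residue, or to an insertion slot anchored at the nearest preceding
#' representative-residue master column (anchor 0 means before the first
#' residue column).
#'
#' @param master_row Gapped representative sequence in master coordinates.
#' @param local_row Gapped representative sequence in orthogroup coordinates.
#' @return A data frame with one row per local column: `local` (column
#'   index), `type` (`"residue"` or `"insertion"`), `master` (master column
#'   for residues, `NA` for insertions) and `anchor` (anchoring master column
#'   for insertions, `NA` for residues).
#' @export
build_column_map <- function(master_row, local_row) {
  master_row <- toupper(master_row)
  local_row <- toupper(local_row)
  um <- ungap(master_row)
  ul <- ungap(local_row)
  if (um != ul) {
    cm <- seq_chars(um); cl <- seq_chars(ul)
    n <- min(length(cm), length(cl))
    first <- if (n > 0 && any(cm[seq_len(n)] != cl[seq_len(n)])) {
      which(cm[seq_len(n)] != cl[seq_len(n)])[1L]
    } else n + 1L
    stop(sprintf(
      "representative rows disagree after removing gaps (first difference at ungapped residue %d)",
      first))
  }
  mc <- seq_chars(master_row)
  lc <- seq_chars(local_row)
  # master column holding the k-th residue of the representative
  res_to_master <- which(mc != GAP)
  type <- ifelse(lc == GAP, "insertion", "residue")
  master <- rep(NA_integer_, length(lc))
  anchor <- rep(NA_integer_, length(lc))
  k <- cumsum(lc != GAP)           # residue count up to each local column
  master[type == "residue"] <- res_to_master[k[type == "residue"]]
  # anchor of an insertion slot: master column of the last preceding residue
  anchor[type == "insertion"] <-
    ifelse(k[type == "insertion"] == 0L, 0L,
           res_to_master[pmax(k[type == "insertion"], 1L)])
  data.frame(local = seq_along(lc), type = type,
             master = master, anchor = anchor, stringsAsFactors = FALSE)
}

#' Merge orthogroup alignments through a representative alignment
#'
#' Realises the gap-propagation concatenation step: every orthogroup
#' alignment is lifted into master coordinates through its representative's
#' column map; local columns where the representative is gapped become
#' insertion columns placed immediately after their anchoring master column.
#' Insertion blocks from different orthogroups sharing an anchor are laid
#' out side by side in lexicographic orthogroup order (C collation), and
#' rows from other orthogroups carry gaps across foreign insertion blocks.
#' The ungapped content of every row is preserved exactly.
#'
#' @param orthogroups Named list of `aa_aln` objects, one per orthogroup.
#' @param reps An `aa_aln` of the representative rows in master coordinates;
#'   ids must be the representative ids.
#' @param rep_ids Named character vector mapping orthogroup label to the
#'   representative id present in that orthogroup's alignment.
#' @return An `aa_aln` containing all rows of all orthogroups (groups in
#'   lexicographic label order, original row order within each), with
#'   attribute `provenance`: a data frame with one row per merged column
#'   (`column`, `source` = `"master"` or the inserting orthogroup label,
#'   `anchor`).
#' @export
merge_alignments <- function(orthogroups, reps, rep_ids) {
  stopifnot(is.list(orthogroups), inherits(reps, "aa_aln"))
  labels <- names(orthogroups)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("`orthogroups` must be a named list with unique labels")
  }
  if (is.null(names(rep_ids)) || !setequal(names(rep_ids), labels)) {
    stop("`rep_ids` must be named by the orthogroup labels")
  }
  master_len <- aln_length(reps)
  labels <- labels[order_c(labels)]

  maps <- list()
  for (g in labels) {
    og <- orthogroups[[g]]
    stopifnot(inherits(og, "aa_aln"))
    aln_length(og)
    rid <- rep_ids[[g]]
    li <- which(og$id == rid)
    if (length(li) != 1L) {
      stop(sprintf("representative '%s' not found exactly once in orthogroup '%s'",
                   rid, g))
    }
    mi <- which(reps$id == rid)
    if (length(mi) != 1L) {
      stop(sprintf("representative '%s' of orthogroup '%s' missing from the representative alignment",
                   rid, g))
    }
    maps[[g]] <- build_column_map(reps$seq[mi], og$seq[li])
  }

  # number of insertion columns each group needs at each anchor (0..master_len)
  ins_count <- matrix(0L, nrow = length(labels), ncol = master_len + 1L,
                      dimnames = list(labels, NULL))
  for (g in labels) {
    m <- maps[[g]]
    ins <- m$anchor[m$type == "insertion"]
    if (length(ins)) {
      tab <- table(ins)
      ins_count[g, as.integer(names(tab)) + 1L] <- as.integer(tab)
    }
  }

  # global layout: for each anchor a (0..master_len): the master column a
  # itself (if a >= 1), then the insertion blocks in group order.
  total_len <- master_len + sum(ins_count)
  source_lab <- character(total_len)
  anchor_of <- integer(total_len)
  master_pos <- integer(master_len)        # global index of master column j
  ins_start <- matrix(0L, nrow = length(labels), ncol = master_len + 1L,
                      dimnames = list(labels, NULL))
  pos <- 0L
  for (a in 0:master_len) {
    if (a >= 1L) {
      pos <- pos + 1L
      master_pos[a] <- pos
      source_lab[pos] <- "master"
      anchor_of[pos] <- a
    }
    for (g in labels) {
      k <- ins_count[g, a + 1L]
      if (k > 0L) {
        ins_start[g, a + 1L] <- pos + 1L
        source_lab[(pos + 1L):(pos + k)] <- g
        anchor_of[(pos + 1L):(pos + k)] <- a
        pos <- pos + k
      }
    }
  }

  out_id <- character(); out_seq <- character()
  out_og <- character(); out_cl <- character()
  for (g in labels) {
    og <- orthogroups[[g]]
    m <- maps[[g]]
    # global destination of each local column
    dest <- integer(nrow(m))
    dest[m$type == "residue"] <- master_pos[m$master[m$type == "residue"]]
    ins_rows <- which(m$type == "insertion")
    if (length(ins_rows)) {
      # consecutive slot within this group's block at each anchor, in local order
      for (a in unique(m$anchor[ins_rows])) {
        rows <- ins_rows[m$anchor[ins_rows] == a]
        dest[rows] <- ins_start[g, a + 1L] + seq_along(rows) - 1L
      }
    }
    mat <- aln_matrix(og$seq)
    out <- matrix(GAP, nrow = nrow(mat), ncol = total_len)
    out[, dest] <- mat
    out_id <- c(out_id, og$id)
    out_seq <- c(out_seq, apply(out, 1L, paste, collapse = ""))
    out_og <- c(out_og, ifelse(is.na(og$orthogroup), g, og$orthogroup))
    out_cl <- c(out_cl, og$class_label)
  }

  merged <- aa_alignment(out_seq, id = out_id, orthogroup = out_og,
                         class_label = out_cl)
  attr(merged, "provenance") <- data.frame(
    column = seq_len(total_len), source = source_lab, anchor = anchor_of,
    stringsAsFactors = FALSE)
  merged
}

#' Remove all-gap columns from an alignment
#'
#' @param x An `aa_aln` alignment.
#' @return The alignment with every column that is a gap in all rows
#'   removed; errors if no column would remain.
#' @export
strip_empty_columns <- function(x) {
  stopifnot(inherits(x, "aa_aln"))
  aln_length(x)
  mat <- aln_matrix(x$seq)
  keep <- colSums(mat != GAP) > 0L
  if (!any(keep)) stop("all columns are gap-only; nothing would remain")
  aa_alignment(apply(mat[, keep, drop = FALSE], 1L, paste, collapse = ""),
               id = x$id, orthogroup = x$orthogroup,
               class_label = x$class_label)
}
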