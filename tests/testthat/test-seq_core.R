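test_that("FASTA reading parses headers, wraps, and normalizes case", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a extra header words", "ACD", ">b", "A-", "D"), f)
  aln <- read_fasta(f)
  expect_s3_class(aln, "aa_aln")
  expect_equal(aln$id, c("a", "b"))
  expect_equal(aln$seq, c("ACD", "A-D"))
  expect_equal(aln_length(aln), 3L)

  writeLines(c(">lc", "acd"), f)
  expect_equal(read_fasta(f)$seq, "ACD")
})

test_that("FASTA reading rejects duplicates, empty files, and dot gaps", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD", ">a", "ACD"), f)
  expect_error(read_fasta(f), "duplicate sequence id: 'a'")
  writeLines(character(), f)
  expect_error(read_fasta(f), "no FASTA records")
  writeLines(c(">a", "A.D"), f)
  expect_error(read_fasta(f), "'\\.' gap")
  expect_error(read_fasta(file.path(tempdir(), "nope.fasta")), "not found")
})

test_that("FASTA round-trip is the identity on (id, sequence) pairs", {
  set.seed(11)
  seqs <- replicate(7, paste(sample(c(AA_ALPHABET, "-"), 130, replace = TRUE),
                             collapse = ""))
  aln <- make_aln(stats::setNames(seqs, sprintf("seq_%d", 1:7)))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(aln, f)
  back <- read_fasta(f)
  expect_identical(back$id, aln$id)
  expect_identical(back$seq, aln$seq)
  # 60-column wrap on write
  expect_true(all(nchar(readLines(f)) <= 60))
  expect_error(write_fasta(structure(list(id = character(), seq = character(),
                                          orthogroup = character(),
                                          class_label = character()),
                                     class = "aa_aln"), f),
               "empty")
})

test_that("ambiguity filtering removes exactly the offending records, idempotently", {
  aln <- make_aln(c(a = "ACD", b = "AXD", c = "A-D"))
  expect_message(out <- filter_ambiguous(aln), "removed 1")
  expect_equal(out$id, c("a", "c"))
  expect_equal(attr(out, "n_removed"), 1L)
  expect_equal(attr(out, "removed_ids"), "b")
  # idempotent
  again <- filter_ambiguous(out)
  expect_equal(again$id, out$id)
  expect_equal(attr(again, "n_removed"), 0L)
  # all records ambiguous -> empty result allowed
  expect_message(none <- filter_ambiguous(make_aln(c(z = "BXZ*"))))
  expect_length(none$id, 0)
  expect_equal(attr(none, "n_removed"), 1L)
  # clean input untouched
  clean <- filter_ambiguous(make_aln(c(a = "ACD")))
  expect_equal(clean$seq, "ACD")
  expect_equal(attr(clean, "n_removed"), 0L)
})

test_that("pairwise identity counts matches over comparable positions", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  # aligned with a shared gap column: 3 comparable columns, all matching
  expect_equal(pairwise_identity("ACD-", "ACD-"), 1.0)
  # gap in one row only excludes the column
  expect_equal(pairwise_identity("AC-D", "ACWD"), 1.0)
  # unaligned inputs: ungapped prefix comparison over the shorter length
  expect_equal(pairwise_identity("ACDEF", "ACD"), 1.0)
  expect_equal(pairwise_identity("A-CDEF", "GCD"), 2 / 3)
  expect_error(pairwise_identity("---", "--"), "empty")
  expect_equal(pairwise_identity("ACDE", "ACDE"),
               pairwise_identity("ACDE", "ACDE"))
})

test_that("dereplication removes records above the identity threshold", {
  a20 <- strrep("A", 20)
  a19t <- paste0(strrep("A", 19), "T")
  c20 <- strrep("C", 20)
  res <- dereplicate(make_aln(c(x = a20, y = a19t, z = c20)), threshold = 0.90)
  expect_setequal(res$kept$id, c("x", "z"))
  expect_equal(res$removed$id, "y")
  expect_equal(res$removed$identity, 0.95)
  # dissimilar records are both kept; a single record is kept
  both <- dereplicate(make_aln(c(p = "AAAA", q = "CCCC")), 0.90)
  expect_setequal(both$kept$id, c("p", "q"))
  one <- dereplicate(make_aln(c(solo = "ACDE")), 0.90)
  expect_equal(one$kept$id, "solo")
  # exactly-at-threshold records are retained (> is strict)
  at <- dereplicate(make_aln(c(u = strrep("A", 10),
                               v = paste0(strrep("A", 9), "C"))), 0.90)
  expect_setequal(at$kept$id, c("u", "v"))
  expect_error(dereplicate(make_aln(c(a = "AC")), 0), "threshold")
  expect_error(dereplicate(make_aln(c(a = "AC")), 1.2), "threshold")
})

test_that("dereplication is order-independent and its removals are justified", {
  set.seed(42)
  base <- replicate(6, sample(AA_ALPHABET, 30, replace = TRUE),
                    simplify = FALSE)
  # six originals plus six near-copies differing at 1-12 positions
  mutants <- lapply(1:6, function(i) {
    s <- base[[i]]
    pos <- sample(30, sample(c(1, 2, 6, 12), 1))
    s[pos] <- sample(AA_ALPHABET, length(pos), replace = TRUE)
    s
  })
  pool <- vapply(c(base, mutants), paste, character(1), collapse = "")
  ids <- sprintf("r%02d", 1:12)
  for (perm_seed in 1:4) {
    set.seed(perm_seed)
    perm <- sample(12)
    res <- dereplicate(make_aln(stats::setNames(pool[perm], ids[perm])), 0.7)
    if (perm_seed == 1) kept_ref <- sort(res$kept$id)
    expect_equal(sort(res$kept$id), kept_ref)
    # every removed record exceeds the threshold against a retained one
    for (i in seq_len(nrow(res$removed))) {
      rid <- res$removed$id[i]
      idents <- vapply(res$kept$id, function(k) {
        pairwise_identity(pool[ids == rid], pool[ids == k])
      }, numeric(1))
      expect_true(any(idents > 0.7))
    }
  }
})

test_that("label tables attach by id and reject incomplete tables", {
  aln <- make_aln(c(a = "ACD", b = "AGD"))
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(id = c("b", "a"), orthogroup = c("og2", "og1"),
               class_label = c("free", "modular")),
    f, sep = "\t", row.names = FALSE, quote = FALSE)
  out <- attach_labels(aln, f)
  expect_equal(out$orthogroup, c("og1", "og2"))
  expect_equal(out$class_label, c("modular", "free"))
  utils::write.table(data.frame(id = "a", orthogroup = "og1",
                                class_label = "modular"),
                     f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(attach_labels(aln, f), "no label for sequence id 'b'")
})
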