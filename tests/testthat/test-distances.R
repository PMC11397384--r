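mk_aln <- function(...) {
  rows <- list(...)
  msa_alignment(names(rows), unlist(rows))
}

test_that("pairwise base differences follow the gap policy", {
  aln <- mk_aln(a = "ACGU", b = "ACGU")
  expect_equal(pairwise_base_differences(aln, "a", "b")$n_diff, 0L)

  aln <- mk_aln(a = "ACGU", b = "ACGA")
  expect_equal(pairwise_base_differences(aln, "a", "b")$n_diff, 1L)

  aln <- mk_aln(a = "AC-GU", b = "ACAGU")
  expect_equal(pairwise_base_differences(aln, "a", "b", "gap-is-diff")$n_diff, 1L)
  expect_equal(pairwise_base_differences(aln, "a", "b",
                                         "ignore-gap-columns")$n_diff, 0L)

  expect_error(pairwise_base_differences(aln, "a", "zz"), "unknown id")
})

test_that("terminal gap overhangs and gap-gap columns are never counted", {
  aln <- mk_aln(a = "--ACGU--", b = "CCACGAUU")
  d <- pairwise_base_differences(aln, "a", "b")
  expect_equal(d$n_diff, 1L)          # only the U/A mismatch inside the overlap
  expect_equal(d$columns_counted, 4L)

  aln <- mk_aln(a = "AC--GU", b = "AC--GU")
  d <- pairwise_base_differences(aln, "a", "b")
  expect_equal(d$columns_counted, 4L) # gap-gap columns dropped
  expect_equal(d$n_diff, 0L)
})

test_that("pairwise differences are symmetric in the two ids", {
  set.seed(5)
  a <- random_rna(60); b <- random_rna(60)
  aln <- mk_aln(x = a, y = b)
  expect_equal(pairwise_base_differences(aln, "x", "y")$n_diff,
               pairwise_base_differences(aln, "y", "x")$n_diff)
})

test_that("variable positions count each varying column once", {
  expect_equal(variable_positions(mk_aln(a = "AAAA", b = "AAAA", c = "AAAA"),
                                  c("a", "b", "c"))$n_diff, 0L)
  expect_equal(variable_positions(mk_aln(a = "AAAA", b = "AAAA", c = "AATA"),
                                  c("a", "b", "c"))$n_diff, 1L)
  expect_equal(variable_positions(mk_aln(a = "AG", b = "AC", c = "AA"),
                                  c("a", "b", "c"))$n_diff, 1L)
  expect_error(variable_positions(mk_aln(a = "AG", b = "AC"), "a"),
               "at least 2")
})

test_that("variable positions equal pairwise count for two rows and bound it for more", {
  set.seed(9)
  for (k in 1:10) {
    a <- random_rna(50); b <- random_rna(50); c <- random_rna(50)
    aln <- mk_aln(a = a, b = b, c = c)
    expect_equal(variable_positions(aln, c("a", "b"))$n_diff,
                 pairwise_base_differences(aln, "a", "b")$n_diff)
    pairsum <- pairwise_base_differences(aln, "a", "b")$n_diff +
      pairwise_base_differences(aln, "a", "c")$n_diff +
      pairwise_base_differences(aln, "b", "c")$n_diff
    expect_lte(variable_positions(aln, c("a", "b", "c"))$n_diff, pairsum)
  }
})

test_that("intron detection reports insertions in reference numbering", {
  ref <- annotated_seq("ref", "AAAACCCCGGGG")
  q <- annotated_seq("q", "AAAACCCCUUUUUUGGGG")  # 6 nt after position 8
  calls <- detect_introns(q, ref, min_intron_length = 5L)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$reference_position, 8L)
  expect_equal(calls$length, 6L)

  expect_equal(nrow(detect_introns(ref, ref, min_intron_length = 5L)), 0L)
})

test_that("multiple insertions are called in 5' to 3' order", {
  set.seed(31)
  # U-free core with poly-U inserts: the insertion boundaries are then
  # unambiguous under any optimal alignment
  core <- paste(sample(c("A", "C", "G"), 300, replace = TRUE), collapse = "")
  ref <- annotated_seq("ref", core)
  ins1 <- strrep("U", 60); ins2 <- strrep("U", 70)
  qseq <- paste0(substr(core, 1, 100), ins1, substr(core, 101, 220),
                 ins2, substr(core, 221, 300))
  q <- annotated_seq("q", qseq)
  calls <- detect_introns(q, ref, min_intron_length = 50L)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$reference_position, c(100L, 220L))
  expect_equal(calls$length, c(60L, 70L))
})

test_that("intron detection on identical sequences is empty for any input", {
  set.seed(77)
  for (k in 1:5) {
    x <- annotated_seq("x", random_rna(80 + 40 * k))
    expect_equal(nrow(detect_introns(x, x)), 0L)
  }
})

test_that("a non-homologous reference is refused", {
  set.seed(101)
  q <- annotated_seq("q", strrep("AC", 150))
  ref <- annotated_seq("ref", strrep("GU", 150))
  expect_error(detect_introns(q, ref), "wrong reference")
})

test_that("coding differences count nucleotides and amino acids", {
  a <- annotated_seq("a", "AUGGGUAAAUAA")
  expect_equal(coding_differences(a, a)[c("nt_diff", "aa_diff")],
               list(nt_diff = 0L, aa_diff = 0L), ignore_attr = TRUE)

  # synonymous third-position change GGU -> GGC
  b <- annotated_seq("b", "AUGGGCAAAUAA")
  d <- coding_differences(a, b)
  expect_equal(d$nt_diff, 1L)
  expect_equal(d$aa_diff, 0L)

  # first-position change GGU -> AGU (Gly -> Ser)
  b <- annotated_seq("b", "AUGAGUAAAUAA")
  d <- coding_differences(a, b)
  expect_equal(d$nt_diff, 1L)
  expect_equal(d$aa_diff, 1L)
})

test_that("internal stop codons warn with their position", {
  a <- annotated_seq("a", "AUGUAAAAAUAA")   # codon 2 is a stop
  w <- capture_warnings(coding_differences(a, a))
  expect_match(w, "internal stop codon.*codon 2", all = FALSE)
})

test_that("amino-acid differences never exceed the affected-codon count", {
  set.seed(55)
  for (k in 1:20) {
    n_codons <- 30L
    a <- random_rna(3L * n_codons)
    b_ch <- strsplit(a, "")[[1]]
    nmut <- sample(1:10, 1)
    sites <- sample(length(b_ch), nmut)
    for (s in sites) b_ch[s] <- sample(setdiff(ORACLE_BASES, b_ch[s]), 1)
    b <- paste(b_ch, collapse = "")
    d <- suppressWarnings(coding_differences(annotated_seq("a", a),
                                             annotated_seq("b", b)))
    affected <- length(unique((sites - 1L) %/% 3L))
    expect_lte(d$aa_diff, affected)
    expect_equal(d$nt_diff, length(sites))
  }
})
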