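pos <- function(b5, b3, code) list(base5 = b5, base3 = b3, code = code)

test_that("change classification matches the definition on spot cases", {
  expect_equal(classify_change(pos("A", "U", 1L), pos("G", "C", 3L)), "CBC")
  expect_equal(classify_change(pos("A", "U", 1L), pos("G", "U", 5L)), "HCBC")
  # A-U vs U-A: both strands differ, pairing kept on both sides
  expect_equal(classify_change(pos("A", "U", 1L), pos("U", "A", 2L)), "CBC")
  expect_equal(classify_change(pos("G", "C", 3L), NULL), "indel_unpaired")
  expect_equal(classify_change(pos("C", "G", 4L), pos("C", "G", 4L)), "identical")
  expect_equal(classify_change(pos("A", "G", 7L), pos("A", "U", 1L)),
               "mismatch_change")
  expect_equal(classify_change(pos("A", "-", 8L), pos("A", "U", 1L)),
               "indel_unpaired")
  expect_equal(classify_change(pos("N", "U", NA_integer_), pos("A", "U", 1L)),
               "ambiguous")
  expect_error(classify_change(NULL, NULL), "gap-gap")
})

test_that("classification agrees with the brute-force truth table", {
  # all ordered pairs of codes {1..8} x {1..8} over representative base
  # states, plus gap rows, against the independently derived oracle
  n_checked <- 0L
  for (cA in 1:8) {
    for (cB in 1:8) {
      for (sA in oracle_states_for_code(cA)) {
        for (sB in oracle_states_for_code(cB)) {
          got <- classify_change(pos(sA$b5, sA$b3, sA$code),
                                 pos(sB$b5, sB$b3, sB$code))
          want <- oracle_classify(sA, sB)
          expect_equal(got, want,
                       info = sprintf("%s%s(%d) vs %s%s(%d)", sA$b5, sA$b3,
                                      cA, sB$b5, sB$b3, cB))
          n_checked <- n_checked + 1L
        }
      }
    }
  }
  for (c1 in 1:8) {
    for (s in oracle_states_for_code(c1)) {
      expect_equal(classify_change(pos(s$b5, s$b3, s$code), NULL),
                   "indel_unpaired")
      expect_equal(classify_change(NULL, pos(s$b5, s$b3, s$code)),
                   "indel_unpaired")
      n_checked <- n_checked + 2L
    }
  }
  expect_gt(n_checked, 256)
})

test_that("homology matches by helix and rank with tip-ward gaps", {
  a <- generate_its2(1, helix_stems = c(5L, 5L, 5L, 5L))
  mA <- annotate_four_helix(decompose_helices(a$structure))
  bcA <- make_barcode(a$seq, a$structure, conserved_region(mA))
  hom <- align_structures(bcA, bcA)
  expect_equal(nrow(hom), 20L)
  expect_true(!any(is.na(hom$idxA) | is.na(hom$idxB)))
  expect_equal(hom$idxA, hom$idxB)

  # one helix shortened by one pair: rank 5 of the longer taxon meets a gap
  mu <- plant_mutations(a$seq, a$structure, n_pair_indel = 1L, seed = 2L)
  mB <- annotate_four_helix(decompose_helices(mu$structure))
  bcB <- make_barcode(mu$seq, mu$structure, conserved_region(mB))
  hom <- align_structures(bcA, bcB)
  expect_equal(sum(is.na(hom$idxB)), 1L)
  gap_row <- hom[is.na(hom$idxB), ]
  expect_equal(gap_row$rank, 5L)
})

test_that("a taxon missing one helix matches all its positions to gaps", {
  db4 <- paste(rep("((...))", 4), collapse = ".")
  db3 <- paste0(paste(rep("((...))", 3), collapse = "."), strrep(".", 8))
  seq4 <- "GGAAACC.GGAAACC.GGAAACC.GGAAACC"
  seq4 <- gsub(".", "A", seq4, fixed = TRUE)
  stA <- secondary_structure(dotbracket_to_pairs(db4))
  stB <- secondary_structure(dotbracket_to_pairs(db3))
  A <- annotated_seq("A", seq4)
  B <- annotated_seq("B", seq4)
  mA <- annotate_four_helix(decompose_helices(stA), strict = FALSE)
  mB <- annotate_four_helix(decompose_helices(stB), strict = FALSE)
  bcA <- make_barcode(A, stA, conserved_region(mA))
  bcB <- make_barcode(B, stB, conserved_region(mB))
  hom <- align_structures(bcA, bcB)
  expect_equal(sum(is.na(hom$idxB)), 2L)  # helix IV has 2 pairs
  expect_equal(unique(hom$helix[is.na(hom$idxB)]), "IV")
})

test_that("self-comparison yields zero changes and no barcode evidence", {
  g <- generate_its2(5)
  rep <- compare_taxa(g$seq, g$structure, g$seq, g$structure)
  expect_equal(rep$counts$total_changes, 0L)
  expect_equal(rep$counts$cbc, 0L)
  expect_equal(unclass(rep$verdict)[1], "no-barcode-evidence")
})

test_that("planted changes with true structures are recovered exactly", {
  g <- generate_its2(17)
  mu <- plant_mutations(g$seq, g$structure, n_cbc = 2L, n_hcbc = 1L,
                        n_unpaired = 0L, n_pair_indel = 3L, seed = 18L)
  rep <- compare_taxa(g$seq, g$structure, mu$seq, mu$structure)
  expect_equal(rep$counts$cbc, 2L)
  expect_equal(rep$counts$hcbc, 1L)
  expect_equal(rep$counts$mismatch, 0L)
  expect_equal(rep$counts$indel_unpaired, 3L)
})

test_that("comparison is symmetric in its arguments", {
  for (seed in c(3L, 21L)) {
    g <- generate_its2(seed)
    mu <- plant_mutations(g$seq, g$structure, 1L, 2L, 3L, 2L,
                          seed = seed + 500L)
    ab <- compare_taxa(g$seq, g$structure, mu$seq, mu$structure)
    ba <- compare_taxa(mu$seq, mu$structure, g$seq, g$structure)
    expect_equal(ab$counts, ba$counts)
    expect_equal(unclass(ab$verdict)[1], unclass(ba$verdict)[1])
  }
})

test_that("classification counts conserve the number of homology rows", {
  g <- generate_its2(8)
  mu <- plant_mutations(g$seq, g$structure, 2L, 2L, 4L, 1L, seed = 9L)
  rep <- compare_taxa(g$seq, g$structure, mu$seq, mu$structure)
  ct <- rep$counts
  expect_equal(ct$identical + ct$cbc + ct$hcbc + ct$mismatch +
                 ct$indel_unpaired + ct$ambiguous, nrow(rep$table))
})

test_that("scope mismatch between barcodes is refused", {
  g <- generate_its2(2)
  m <- annotate_four_helix(decompose_helices(g$structure))
  r <- conserved_region(m)
  bc_plain <- make_barcode(g$seq, g$structure, r)
  bc_unp <- make_barcode(g$seq, g$structure, r, emit_unpaired = TRUE, model = m)
  expect_error(align_structures(bc_plain, bc_unp), "scope mismatch")
})

test_that("the verdict rule never escalates hemi-CBCs to species rank", {
  fake <- function(cbc, hcbc, mism, indel) {
    list(counts = list(cbc = cbc, hcbc = hcbc, mismatch = mism,
                       indel_unpaired = indel,
                       total_changes = cbc + hcbc + mism + indel))
  }
  # the published evidence pattern: 1 CBC, 2 HCBCs, 9 other changes
  v <- delimit(fake(1, 2, 0, 9))
  expect_equal(unclass(v)[1], "distinct-species-supported")
  expect_match(attr(v, "statement"), "1 CBC, 2 hemi-CBC")
  expect_equal(unclass(delimit(fake(0, 0, 0, 0)))[1], "no-barcode-evidence")
  expect_equal(unclass(delimit(fake(0, 3, 0, 0)))[1], "suggestive")
  expect_equal(unclass(delimit(fake(0, 3, 5, 5), hcbc_threshold = 4))[1],
               "no-barcode-evidence")
})
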