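test_that("generated taxa have the requested four-helix geometry", {
  g <- generate_its2(1, helix_stems = c(5L, 5L, 5L, 5L))
  m <- decompose_helices(g$structure)
  expect_length(m$helices, 4L)
  expect_equal(vapply(m$helices, function(h) nrow(h$basepairs), integer(1)),
               rep(5L, 4))
  # all stem pairs are drawn from the allowed pair set
  ch <- strsplit(g$seq$seq, "")[[1]]
  i <- which(g$structure$pairs > seq_along(g$structure$pairs))
  expect_true(all(paste0(ch[i], ch[g$structure$pairs[i]]) %in% ORACLE_ALLOWED))
})

test_that("generation is deterministic and seed-sensitive", {
  a <- generate_its2(42)
  b <- generate_its2(42)
  c <- generate_its2(43)
  expect_identical(a$seq$seq, b$seq$seq)
  expect_identical(a$structure$pairs, b$structure$pairs)
  expect_false(identical(a$seq$seq, c$seq$seq))
  # seeding is local: the global RNG stream is untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generate_its2(7)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("gc_bias = 1 makes every stem pair G-C or C-G", {
  g <- generate_its2(3, gc_bias = 1)
  ch <- strsplit(g$seq$seq, "")[[1]]
  i <- which(g$structure$pairs > seq_along(g$structure$pairs))
  expect_true(all(paste0(ch[i], ch[g$structure$pairs[i]]) %in% c("GC", "CG")))
})

test_that("impossible geometry is refused", {
  expect_error(generate_its2(1, loop_lengths = c(2L, 7L, 7L, 7L)),
               "impossible geometry")
  expect_error(generate_its2(1, helix_stems = c(1L, 5L, 5L, 5L)), ">= 2")
})

test_that("an all-zero mutation request is the identity", {
  g <- generate_its2(4)
  mu <- plant_mutations(g$seq, g$structure, 0L, 0L, 0L, 0L, seed = 1L)
  expect_equal(mu$seq$seq, g$seq$seq)
  expect_equal(mu$structure$pairs, g$structure$pairs)
  expect_equal(nrow(mu$ledger$records), 0L)
})

test_that("the ledger records every planted mutation with its bases", {
  g <- generate_its2(6)
  mu <- plant_mutations(g$seq, g$structure, n_cbc = 1L, n_hcbc = 0L,
                        n_unpaired = 0L, n_pair_indel = 0L, seed = 2L)
  rec <- mu$ledger$records
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$kind, "cbc")
  expect_true(paste0(rec$before5, rec$before3) %in% ORACLE_ALLOWED)
  expect_true(paste0(rec$after5, rec$after3) %in% ORACLE_ALLOWED)
  expect_true(rec$before5 != rec$after5 && rec$before3 != rec$after3)
  expect_equal(mu$ledger$totals$cbc, 1L)
})

test_that("every planted substitution classifies as its own kind", {
  for (seed in c(2L, 12L, 31L)) {
    g <- generate_its2(seed)
    mu <- plant_mutations(g$seq, g$structure, 3L, 3L, 2L, 1L,
                          seed = seed + 100L)
    rec <- mu$ledger$records
    for (r in seq_len(nrow(rec))) {
      a <- list(base5 = rec$before5[r], base3 = rec$before3[r],
                code = encode_position(rec$before5[r], rec$before3[r],
                                       rec$segment[r] == "P"))
      b <- list(base5 = rec$after5[r], base3 = rec$after3[r],
                code = if (rec$kind[r] == "pair-indel") NULL else
                  encode_position(rec$after5[r], rec$after3[r],
                                  rec$segment[r] == "P"))
      got <- switch(rec$kind[r],
                    "cbc" = classify_change(a, b),
                    "hcbc" = classify_change(a, b),
                    "unpaired-sub" = classify_change(a, b),
                    "pair-indel" = classify_change(a, NULL))
      want <- switch(rec$kind[r],
                     "cbc" = "CBC", "hcbc" = "HCBC",
                     "unpaired-sub" = "indel_unpaired",
                     "pair-indel" = "indel_unpaired")
      expect_equal(got, want, info = paste(seed, rec$kind[r], r))
    }
  }
})

test_that("mutation requests beyond capacity error with the class name", {
  g <- generate_its2(9, helix_stems = c(3L, 3L, 3L, 3L))
  expect_error(plant_mutations(g$seq, g$structure, n_pair_indel = 20L,
                               seed = 1L),
               "pair-indel")
  expect_error(plant_mutations(g$seq, g$structure, n_unpaired = 50L,
                               seed = 1L),
               "unpaired-sub")
})

test_that("fixture sets land on disk and reproduce their planted totals", {
  dir <- withr::local_tempdir()
  fx <- make_fixture_set(dir, "ramosa-like", seed = 7L)
  expect_true(all(file.exists(fx$fasta, fx$dbn, fx$ledger_json)))

  # end to end from the files, not the in-memory objects
  seqs <- read_fasta(fx$fasta)
  expect_length(seqs, 2L)
  led <- jsonlite::read_json(fx$ledger_json)
  expect_equal(led$totals$cbc, 1L)
  expect_equal(led$totals$hcbc, 2L)
  expect_equal(led$totals$unpaired_sub + led$totals$pair_indel, 9L)

  # two seeds: different sequences, same totals
  fx2 <- make_fixture_set(dir, "ramosa-like", seed = 8L)
  seqs2 <- read_fasta(fx2$fasta)
  expect_false(identical(seqs[[1]]$seq, seqs2[[1]]$seq))
  expect_equal(jsonlite::read_json(fx2$ledger_json)$totals,
               led$totals)
})

test_that("fixture regeneration is byte-identical for identical seeds", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- make_fixture_set(d1, "pseudomarvania-like", seed = 3L)
  f2 <- make_fixture_set(d2, "pseudomarvania-like", seed = 3L)
  expect_identical(readLines(f1$fasta), readLines(f2$fasta))
  expect_identical(readLines(f1$dbn), readLines(f2$dbn))
  expect_identical(readLines(f1$ledger_json), readLines(f2$ledger_json))
})
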