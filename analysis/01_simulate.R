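#!/usr/bin/env Rscript
# Step 1: generate the two synthetic ITS-2 taxon-pair fixtures.
#
# Each fixture is a four-helix ITS-2-like taxon plus a mutated partner with
# planted, ledgered changes. The planted magnitudes mirror the two published
# comparisons this package is built around: a "ramosa-like" pair with
# 1 CBC + 2 hemi-CBCs + 9 other changes, and a "pseudomarvania-like" pair
# with 8 CBCs + 4 hemi-CBCs + 30 other changes.

library(its2cbc)

seed <- 2024L
out <- "results/fixtures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (profile in c("ramosa-like", "pseudomarvania-like")) {
  fx <- make_fixture_set(out, profile, seed = seed)
  led <- fx$ledger
  cat(sprintf("%-22s seed %d: planted %d CBC, %d HCBC, %d unpaired-sub, %d pair-indel\n",
              profile, seed, led$totals$cbc, led$totals$hcbc,
              led$totals$unpaired_sub, led$totals$pair_indel))
  cat(sprintf("  taxon A: %d nt, %d pairs; files: %s\n",
              nchar(fx$taxonA$seq$seq),
              sum(fx$taxonA$structure$pairs > 0) / 2,
              paste(basename(c(fx$fasta, fx$dbn, fx$ledger_json)),
                    collapse = ", ")))
}
cat(sprintf("fixtures written under %s\n", out))
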