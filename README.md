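# its2cbc

Species delimitation from ITS-2 secondary structures by the CBC approach,
for phycologists and other systematists working on green algae and similar
groups where the internal transcribed spacer 2 (ITS-2) folds into a
conserved four-helix structure.

## The method

Two ribosomal pairing partners can both change while the base pair itself
survives. When, at a homologous paired position of the ITS-2 structure, both
nucleotides differ between two taxa and each taxon still forms a
canonical or wobble pair (e.g. A–U vs G–C), that is a **compensatory base
change (CBC)** — the classical structural signal that two lineages are
distinct biological species. If only one partner changes while pairing is
kept (e.g. G–C vs G·U), it is a **hemi-CBC (HCBC)**, a weaker signal.

The pipeline implemented here:

1. **Fold** the ITS-2 sequence into a pseudoknot-free secondary structure.
   The built-in folder maximises `#pairs + β · #stacked pairs` (β = 0.5 by
   default) by dynamic programming over the pair set
   {A–U, U–A, G–C, C–G, G·U, U·G} with a minimum hairpin loop of 3 nt;
   structures folded externally (mfold, ViennaRNA) can be imported instead
   via `read_structure()`.
2. **Decompose** the structure into helix domains and label the canonical
   four helices I–IV in 5'→3' order (`decompose_helices()`,
   `annotate_four_helix()`).
3. **Encode** the conserved paired region as an 8-state numeric **barcode**
   (`make_barcode()`): 1 = A–U, 2 = U–A, 3 = G–C, 4 = C–G, 5 = G·U,
   6 = U·G, 7 = mismatch, 8 = deletion/single/unpaired.
4. **Compare** two taxa position by position (`compare_taxa()`): helices are
   matched by label, pairs by rank from the helix base, surplus tip-ward
   positions meet gaps; every change is classified as CBC, hemi-CBC,
   mismatch, or indel/unpaired, and a delimitation verdict is issued
   (≥ 1 CBC → distinct species supported; hemi-CBCs alone are at most
   suggestive).

Around this core, the package provides the accompanying sequence
computations — pairwise and group-wise base-difference counts on alignments
under explicit gap policies, group I intron detection as large insertions
against an intron-free SSU reference in reference (E. coli) numbering, and
nucleotide/amino-acid difference counts for plastid genes (rbcL, tufA;
translation table 11) — plus a synthetic-data generator
(`generate_its2()`, `plant_mutations()`) that plants ledgered changes so the
whole pipeline is testable offline.

## Worked example

```r
library(its2cbc)

g <- generate_its2(seed = 1)        # a four-helix ITS-2-like taxon
g$structure
#> <secondary_structure> 145 nt, 48 pairs
#> .....((((((((((.......))))))))))...((((((((((((.......))))))))))))...((((((((((((((((((.........))))))))))))))))))...((((((((.......)))))))).....

m  <- annotate_four_helix(decompose_helices(g$structure))
bc <- make_barcode(g$seq, g$structure, conserved_region(m))
bc
#> <its2_barcode> synthetic_its2_seed1: 48 positions
#> 261144413234323313421232132344431136333132532332

mu  <- plant_mutations(g$seq, g$structure, n_cbc = 1, n_hcbc = 2,
                       n_unpaired = 6, n_pair_indel = 3, seed = 2)
rep <- compare_taxa(g$seq, g$structure, mu$seq, mu$structure)
rep
#> <comparison_report> synthetic_its2_seed1 vs synthetic_its2_seed1_mut
#>   1 CBC, 2 hemi-CBC, 0 mismatch, 9 indel/unpaired (12 changes in total): distinct-species-supported
```

The barcode digits read helix I to IV, base to tip (`2` = U–A, `6` = U·G,
…). The planted mutations are recovered exactly: one CBC (enough to support
two species), two hemi-CBCs, and nine further changes in the
deleted/single/unpaired bucket — the evidence pattern that in the original
study separated a sloth-hair alga from its closest relative by 12 barcode
changes.

The `analysis/` directory walks through the same workflow as numbered
scripts (simulate → fold → barcode/compare → distances → optional GenBank
validation), writing tables under `results/`.

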