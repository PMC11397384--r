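---
title: "Methods: ITS-2 barcodes and CBC-based species delimitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ITS-2 barcodes and CBC-based species delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(its2cbc)
```

## The model

The second internal transcribed spacer (ITS-2) of the nuclear ribosomal
cistron folds, across green algae and many other eukaryotes, into a
conserved arrangement of four helices rooted on a common exterior loop.
Because the molecule functions through its structure, paired positions
evolve under pairing constraints: a substitution on one strand is often
followed by a compensating substitution on the other. A **compensatory base
change (CBC)** between two taxa is a homologous paired position at which
*both* nucleotides differ while each taxon retains an allowed pair (the
Watson–Crick pairs plus the G·U wobble); a **hemi-CBC (HCBC)** changes
exactly one strand while keeping pairing. The presence of at least one CBC
in the conserved ITS-2 region is the classical structural criterion for
ranking two lineages as distinct biological species; hemi-CBCs alone are
treated as suggestive, never conclusive. This package operationalises that
criterion as an explicit, deterministic pipeline:

fold → decompose into helices → encode the 8-state barcode → align
positions → classify changes → count → verdict.

All coordinates are 1-based and inclusive, sequences are canonicalised to
the RNA alphabet (T read as U), and IUPAC ambiguity codes are carried
through as an explicit "ambiguous" sentinel that can never create or
destroy a CBC.

## Folding

`fold_maxpair()` maximises

$$ S(\text{structure}) = \#\text{pairs} + \beta \cdot \#\text{stacked pairs} $$

over all pseudoknot-free structures whose hairpin loops contain at least
`min_hairpin` (default 3) unpaired bases, where a pair $(i, j)$ is stacked
if $(i+1, j-1)$ is also paired. Allowed pairs are A–U, U–A, G–C, C–G, G·U,
U·G; ambiguity codes are unpairable. The recursion is the standard
interval dynamic programme over $M(i,j)$ (best score of the subsequence)
and $P(i,j)$ (best score given $i$ pairs $j$), $O(n^3)$ time and $O(n^2)$
memory — comfortable for spacer sequences of a few hundred nucleotides.

This is deliberately *not* a thermodynamic folder: no free energies, no
ensembles, no pseudoknots. What the barcode needs from a structure is the
set of paired positions organised into helices, and pair-plus-stacking
maximisation reproduces helix-dominated topologies while staying exactly
reproducible. The stacking bonus $\beta$ (default 0.5 per stacked pair)
discourages scattered isolated pairs in favour of contiguous stems; at
$\beta = 0$ the objective degenerates to plain pair maximisation. Users who
prefer thermodynamic structures (mfold, RNAfold) import them with
`read_structure()` — Vienna dot-bracket and CT formats — and every
downstream step treats imported and internal structures identically.

Ties among co-optimal structures are broken deterministically in the
traceback: at equal score, pairing the 5'-most open position is preferred
over leaving it unpaired, and among equally scoring partners the smallest
3' partner wins; inside a closed pair the stacked continuation is
preferred. (The leftmost-pair preference alone does not discriminate
between co-optimal partners that share a 5' index, hence the
smallest-partner refinement.) `fold_constrained()` applies the same
objective under per-position constraints — forced unpaired or forced
paired with a named partner — validating constraint consistency (allowed
pair, hairpin spacing, no crossings) before folding, so a user can pin a
known four-helix scaffold and let the folder fill in the rest.

Correctness is checked against an independent brute-force enumerator of
all pseudoknot-free structures: exhaustively for every sequence up to
length 8 (87,380 sequences) and for 500 random sequences of length 9–12,
the DP objective equals the enumerated maximum, and the traceback's
structure achieves it.

## Helix decomposition and the four-helix annotation

`decompose_helices()` turns the pair table into helix domains: a helix is
a maximal unbranched run of nested pairs, interrupted only by bulges and
internal loops, ending at its apical loop or at a multiloop. Multi-branched
domains are split at the multiloop and sub-helices are numbered depth-first,
so every helix has a well-defined base-to-tip pair order — the order the
homology rule depends on. `annotate_four_helix()` labels the exterior
branches I–IV in 5'→3' order; a branch count other than four is an error in
strict mode and a recorded warning otherwise (labels continue I, II, …).
Sub-helices past a multiloop get dotted labels ("II.1").

The boundaries of "the conserved region" entering the barcode are a
genuinely open design point: published figures shade it, but no algorithmic
definition exists. The default here is *all base pairs of all labelled
helices*, with `conserved_region(scope = ...)` restricting to named helices
for sensitivity analysis. This is the least arbitrary choice and the one
under which the synthetic fixtures reproduce their planted counts; users
comparing against a drawn figure should restrict scope to match it.

## The 8-state barcode

Each position is encoded by `encode_position()` as

| code | state |
|------|----------------------|
| 1 | A–U |
| 2 | U–A |
| 3 | G–C |
| 4 | C–G |
| 5 | G·U |
| 6 | U·G |
| 7 | mismatch (both bases present, non-pairing) |
| 8 | deletion, single or unpaired bases |

Codes 1–6 read the 5' base first: 3 is G on the 5' strand against C on the
3' strand, mirroring the 1-vs-2 distinction. By default the barcode emits
one position per base pair (helix I→IV, base→tip). With
`emit_unpaired = TRUE` the single-stranded bases inside the scoped helices
(internal loops and apical loops) are appended per helix as code-8
positions; `compare_taxa()` turns this on by default so substitutions at
unpaired sites are visible to the "deleted, single or unpaired" bucket, as
in the published tallies. Whether a printed barcode string should include
those code-8 positions is ambiguous in the source material; both behaviours
are supported and the comparison counts are identical either way, because
homology is segment-aware (see below).

## Homology and change classification

No alignment rule for structure positions is published; comparisons in the
literature are done by eye on drawn structures. The default rule here is
**rank-from-base matching**: helices are matched by label; within a helix,
positions are matched by rank separately per segment — paired ranks ("P"),
internal-loop bases ("L"), apical-loop bases ("A") — and the surplus
tip-ward positions of the longer taxon are matched to gaps. Anchoring at
the helix base reflects the observation that ITS-2 stem indels accumulate
apically. The rule is deterministic, symmetric, and total: every barcode
position of each taxon appears exactly once, and gap–gap rows cannot occur.
A taxon missing a helix entirely (non-strict annotation) has all of that
helix's positions matched to gaps.

`classify_change()` then applies, in order: ambiguity sentinel on either
side → `ambiguous`; one side gap → `indel_unpaired`; both codes 1–6 → count
differing strands (2 → `CBC`, 1 → `HCBC`, 0 → `identical`); a code 7 on
either side with differing states → `mismatch_change`; a code 8 with
differing states → `indel_unpaired`; otherwise `identical`. The
mismatch rule is tested before the indel rule, so a 7-vs-8 transition
counts as a mismatch change. The classifier is verified against a
brute-force truth table over all ordered combinations of representative
states for codes 1–8 plus gaps.

Aggregation distinguishes `mismatch` from `indel_unpaired` but also reports
their sum (`other_combined`), because the published prose buckets all
non-CBC/non-HCBC changes as "deleted, single or unpaired bases" while the
figure legend separates codes 7 and 8; both views are available in every
report. `delimit()` issues the verdict: ≥ 1 CBC →
`distinct-species-supported`; otherwise ≥ `hcbc_threshold` (default 1)
hemi-CBCs → `suggestive`; otherwise `no-barcode-evidence`. The threshold is
a reporting knob only — hemi-CBCs can never escalate to the species-rank
verdict.

## The synthetic generator

`generate_its2()` builds a four-hairpin molecule: stems of 10, 12, 18 and 8
pairs (helix III longest, helix IV shortest, as in green-algal ITS-2),
apical loops of 7, 7, 9 and 7 nt, short single-stranded spacers, ~145 nt in
total — the scale of a real ITS-2. Stem pairs are drawn from the six
allowed classes with `gc_bias` (default 0.5) setting the G–C fraction, the
remainder split 80/20 between A–U/U–A and wobbles. The true structure is
returned with the sequence, and everything is reproducible from the seed
(a locally seeded Mersenne–Twister; the caller's RNG stream is untouched).

`plant_mutations()` converts a taxon into a diverged partner with an exact
truth ledger: CBCs re-draw a pair class changing both bases, hemi-CBCs
change one strand keeping an allowed pair, unpaired substitutions hit
apical-loop bases, and pair indels delete tip-ward pairs (removing both
nucleotides and updating the structure). Two guarantees matter for
testability: mutated sites are never adjacent to one another (tip-deletion
blocks count as one site), and unpaired substitutions are placed inside
helix loops rather than exterior spacers, so every planted change falls
within the region the comparison scores. Under these guarantees,
`compare_taxa()` with the true structures recovers the planted
(CBC, HCBC, other) totals *exactly* — the suite asserts this for 100 seeded
pairs — and the two `make_fixture_set()` profiles reproduce the published
magnitudes end to end: ramosa-like 1/2/9 (12 changes), pseudomarvania-like
8/4/30 (42 changes), for any seed.

What the generator does **not** emulate: substitution-model realism, rate
heterogeneity, phylogenetic structure, compensatory substitution dynamics,
sequencing error, or structural rearrangements beyond tip truncation.
Passing the recovery tests therefore demonstrates that the measurement
machinery is exact when homology and structures are known — not that
re-folded structures of real, divergent sequences always yield the drawn
structure's counts. The `analysis/02_fold.R` step quantifies exactly that
gap on the fixtures: re-folding inflates the pair set (spurious spacer
pairs, extra helices) and perturbs the counts, which is why imported
curated structures are first-class inputs.

## Sequence-difference computations

*Base differences.* `pairwise_base_differences()` and
`variable_positions()` compare alignment columns with terminal gap
overhangs excluded and gap–gap columns never counted. Internal gap/base
columns follow an explicit policy — `gap-is-diff` (default) or
`ignore-gap-columns` — because the published totals (99, 98, 229) do not
state their gap convention; the validation recipe reports both and notes
which matches.

*Introns.* `detect_introns()` globally aligns query against an intron-free
homologous reference (match 1, mismatch −1, gap open 10, gap extend 0.5,
via Biostrings) and calls every reference-gap run of ≥ 50 nt (tunable) as
an insertion, positioned at the reference residue immediately 5' of the
run. Using an E. coli SSU reference yields the community's conventional
intron positions (1506, 943). An identity floor of 50% outside gaps guards
against a wrong reference. Class assignment ("group I") is a label tied to
the conserved positions, not an inference from intron structure.

*Coding genes.* `coding_differences()` counts nucleotide differences column
by column (aligning first if lengths differ; gap columns excluded from both
counts and flagged) and amino-acid differences by codon-wise translation
under NCBI table 11, the bacterial/plastid code appropriate for rbcL and
tufA. Internal stop codons warn with their codon position.

## Numerical and degenerate-input choices

- Folding tie-breaks as above; scores are small rationals (multiples of
  0.5), so floating-point comparison is exact in practice; the traceback
  tolerance of 1e-9 is belt-and-braces.
- Empty structures decompose to an empty model; empty regions give empty
  barcodes; self-comparison gives all-identical rows and the
  `no-barcode-evidence` verdict.
- A forced-pair constraint set that admits no structure errors out rather
  than returning a partial result.
- GenBank locations limited to simple and complement spans; anything else
  errors loudly rather than guessing.
- Problem sizes in the routine test run: exhaustive fold verification to
  length 8 plus 500 random sequences to length 12; 100 synthetic pairs for
  recovery; fixtures of ~145 nt. These sizes make the full property suite
  complete in about a minute while keeping the exhaustive tiers genuinely
  exhaustive.

## Validation against published sequence data

The package ships no third-party sequence data. The published counts it is
designed to reproduce — the 1/2/9 and 8/4/30 ITS-2 change patterns, the
99/98/229 base differences, the intron calls 1506:447, 1506:508, 943:1762,
and the rbcL/tufA 22 nt/3 aa and 21 nt differences — are scored on real
GenBank records only after the user downloads them;
`analysis/05_validate_genbank.R` documents the expected files and runs the
whole panel, and four dedicated test blocks perform the same checks (and
fail, by design, while the data are absent). Two caveats are inherited from
the source material: the ITS accessions of most strains appear only in a
figure, and one of the two KM462862 citations is likely a typographical
slip — the file-name contract of the recipe lets the user substitute the
correct records without touching code.

## Known limitations

- The folder is a pair-maximisation model; its structures can differ from
  thermodynamic ones, especially in AU-rich spacers. Curated or
  thermodynamic structures should be imported for publication-grade
  comparisons.
- Rank-from-base homology is a deterministic stand-in for expert
  structure alignment; large internal indels that shift helix registers
  will be scored as runs of indel/unpaired changes rather than re-aligned.
- Pairwise comparisons only; no multi-taxon barcode matrix.
- Absence of CBCs is never evidence of conspecificity, and the package
  never claims it is.
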