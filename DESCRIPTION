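Package: its2cbc
Title: ITS-2 Secondary-Structure Barcodes and Compensatory Base Change
    Species Delimitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the ITS-2/CBC approach to species delimitation in
    green algae and other eukaryotes. Folds internal transcribed spacer
    sequences into pseudoknot-free secondary structures by base-pair
    maximisation with a stacking bonus, decomposes structures into the
    canonical four-helix ITS-2 arrangement, encodes the conserved paired
    region as an 8-state numeric barcode (1 = A-U, 2 = U-A, 3 = G-C,
    4 = C-G, 5 = G.U, 6 = U.G, 7 = mismatch, 8 = deletion/single/unpaired),
    classifies inter-taxon changes as compensatory base changes (CBCs),
    hemi-CBCs, mismatches or indel/unpaired changes, and issues a
    delimitation verdict. Also provides the accompanying sequence-difference
    computations (pairwise and group-wise base differences on alignments,
    group I intron detection against an intron-free reference, and
    nucleotide/amino-acid difference counts for plastid coding genes), plus
    a synthetic-data generator that plants ledgered CBC/hemi-CBC/indel
    changes for fully offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
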