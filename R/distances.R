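# Sequence-difference computations: column-wise base differences on
# alignments (pairwise and group-wise), group I intron detection as large
# query-only insertions against an intron-free reference, and
# nucleotide/amino-acid difference counts for plastid coding genes.

aln_row <- function(aln, id) {
  if (!id %in% aln$ids) stop(sprintf("unknown id '%s' in alignment", id))
  strsplit(aln$seqs[[id]], "")[[1]]
}

nongap_span <- function(ch) {
  ng <- which(ch != "-")
  if (!length(ng)) stop("all-gap row")
  c(ng[1], ng[length(ng)])
}

#' Count base differences between two alignment rows
#'
#' Column-by-column comparison. Gap-gap columns are never counted and
#' terminal gap overhangs (columns before either row's first residue or
#' after its last) are excluded. The gap policy governs internal gap-base
#' columns: `"gap-is-diff"` counts them as differences, and
#' `"ignore-gap-columns"` drops them from the comparison.
#'
#' @param aln An [msa_alignment].
#' @param idA,idB Row ids.
#' @param gap_policy `"gap-is-diff"` (default) or `"ignore-gap-columns"`.
#' @return Object of class `difference_count`: `ids`, `n_diff`,
#'   `columns_counted`, `gap_policy`, `positions` (differing column
#'   indices).
#' @export
pairwise_base_differences <- function(aln, idA, idB,
                                      gap_policy = c("gap-is-diff",
                                                     "ignore-gap-columns")) {
  gap_policy <- match.arg(gap_policy)
  a <- aln_row(aln, idA); b <- aln_row(aln, idB)
  sa <- nongap_span(a); sb <- nongap_span(b)
  cols <- seq(max(sa[1], sb[1]), min(sa[2], sb[2]))
  a <- a[cols]; b <- b[cols]
  keep <- !(a == "-" & b == "-")
  if (gap_policy == "ignore-gap-columns") keep <- keep & a != "-" & b != "-"
  diff <- keep & a != b
  structure(list(ids = c(idA, idB), n_diff = sum(diff),
                 columns_counted = sum(keep), gap_policy = gap_policy,
                 positions = cols[diff]),
            class = "difference_count")
}

#' @export
print.difference_count <- function(x, ...) {
  cat(sprintf("<difference_count> %s: %d differences over %d columns (%s)\n",
              paste(x$ids, collapse = " / "), x$n_diff, x$columns_counted,
              x$gap_policy))
  invisible(x)
}

#' Count variable alignment columns across a set of rows
#'
#' A column is variable if the rows are not all identical at it, under the
#' same gap policy and terminal-overhang exclusion as
#' [pairwise_base_differences]; each variable column is counted once
#' regardless of how many states it shows.
#'
#' @inheritParams pairwise_base_differences
#' @param ids Two or more row ids.
#' @return A `difference_count`.
#' @export
variable_positions <- function(aln, ids,
                               gap_policy = c("gap-is-diff",
                                              "ignore-gap-columns")) {
  gap_policy <- match.arg(gap_policy)
  if (length(ids) < 2L) stop("need at least 2 ids")
  rows <- lapply(ids, aln_row, aln = aln)
  spans <- vapply(rows, nongap_span, integer(2))
  cols <- seq(max(spans[1, ]), min(spans[2, ]))
  mat <- do.call(rbind, lapply(rows, `[`, cols))
  allgap <- colSums(mat != "-") == 0L
  keep <- !allgap
  if (gap_policy == "ignore-gap-columns") keep <- keep & colSums(mat == "-") == 0L
  varying <- keep & apply(mat, 2, function(cc) length(unique(cc)) > 1L)
  structure(list(ids = ids, n_diff = sum(varying),
                 columns_counted = sum(keep), gap_policy = gap_policy,
                 positions = cols[varying]),
            class = "difference_count")
}

rna_to_dna <- function(x) chartr("Uu", "Tt", x)

global_align <- function(qseq, rseq) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(rna_to_dna(qseq)),
    Biostrings::DNAString(rna_to_dna(rseq)),
    type = "global", substitutionMatrix = sm,
    gapOpening = 10, gapExtension = 0.5)
  list(q = strsplit(as.character(Biostrings::alignedPattern(aln))[[1]], "")[[1]],
       r = strsplit(as.character(Biostrings::alignedSubject(aln))[[1]], "")[[1]])
}

#' Detect group I intron candidates against an intron-free reference
#'
#' Globally aligns the query to an intron-free homologous reference (match
#' 1, mismatch -1, gap open 10, gap extend 0.5) and reports every maximal
#' run of reference gaps (query-only insertion) of at least
#' `min_intron_length` nucleotides. Positions follow the reference
#' numbering: `reference_position` is the reference residue immediately 5'
#' of the insertion, so calling against an E. coli SSU reference yields the
#' conventional intron positions (e.g. 1506, 943).
#'
#' @param query,reference [annotated_seq] objects (unaligned).
#' @param min_intron_length Minimum insertion length to call (default 50).
#' @return `data.frame` with columns `host`, `reference`,
#'   `reference_position`, `length`, `class_hint`, in 5' to 3' order.
#' @export
detect_introns <- function(query, reference, min_intron_length = 50L) {
  al <- global_align(query$seq, reference$seq)
  both <- al$q != "-" & al$r != "-"
  if (sum(both) && mean(al$q[both] == al$r[both]) < 0.5)
    stop("query and reference share < 50% identity outside gaps; wrong reference?")
  gaps <- rle(al$r == "-")
  ends <- cumsum(gaps$lengths)
  starts <- ends - gaps$lengths + 1L
  refpos_before <- cumsum(al$r != "-")
  out <- data.frame(host = character(), reference = character(),
                    reference_position = integer(), length = integer(),
                    class_hint = character(), stringsAsFactors = FALSE)
  for (k in which(gaps$values & gaps$lengths >= min_intron_length)) {
    out <- rbind(out, data.frame(
      host = query$id, reference = reference$id,
      reference_position = if (starts[k] == 1L) 0L else refpos_before[starts[k] - 1L],
      length = gaps$lengths[k],
      class_hint = "group I intron candidate (length-based call)",
      stringsAsFactors = FALSE))
  }
  out[order(out$reference_position), , drop = FALSE]
}

#' Nucleotide and amino-acid differences between two coding sequences
#'
#' Sequences of unequal length are first globally aligned; gap columns are
#' excluded from both counts and flagged. Nucleotide differences are counted
#' column by column; amino-acid differences by codon-wise translation under
#' the given genetic code (default table 11, bacterial/plastid).
#'
#' @param cdsA,cdsB [annotated_seq] coding sequences, same reading frame.
#' @param genetic_code NCBI translation table id as a string (default
#'   `"11"`).
#' @return List with `nt_diff`, `aa_diff`, `n_codons`,
#'   `gap_columns_excluded`, and the two translations. Internal stop codons
#'   raise a warning naming the codon position.
#' @export
coding_differences <- function(cdsA, cdsB, genetic_code = "11") {
  a <- cdsA$seq; b <- cdsB$seq
  gap_cols <- 0L
  if (nchar(a) != nchar(b)) {
    al <- global_align(a, b)
    keep <- al$q != "-" & al$r != "-"
    gap_cols <- sum(!keep)
    warning(sprintf("sequences differ in length; %d gap columns excluded from both counts",
                    gap_cols))
    a <- paste(al$q[keep], collapse = "")
    b <- paste(al$r[keep], collapse = "")
  }
  nt_diff <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  trim <- nchar(a) %% 3L
  if (trim) {
    warning(sprintf("length %d not divisible by 3; trimming %d trailing nt",
                    nchar(a), trim))
    a <- substr(a, 1L, nchar(a) - trim)
    b <- substr(b, 1L, nchar(b) - trim)
  }
  code <- Biostrings::getGeneticCode(genetic_code)
  translate1 <- function(x, id) {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(rna_to_dna(x)), genetic.code = code,
      if.fuzzy.codon = "X"))
    internal_stop <- which(strsplit(aa, "")[[1]] == "*")
    internal_stop <- internal_stop[internal_stop < nchar(aa)]
    if (length(internal_stop))
      warning(sprintf("internal stop codon in '%s' at codon %d", id,
                      internal_stop[1]))
    aa
  }
  aaA <- translate1(a, cdsA$id)
  aaB <- translate1(b, cdsB$id)
  aa_diff <- sum(strsplit(aaA, "")[[1]] != strsplit(aaB, "")[[1]])
  list(nt_diff = nt_diff, aa_diff = aa_diff, n_codons = nchar(aaA),
       gap_columns_excluded = gap_cols, aaA = aaA, aaB = aaB)
}
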