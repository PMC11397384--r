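# The 8-state numeric code for a (possibly absent) base pair:
#   1 = A-U, 2 = U-A, 3 = G-C, 4 = C-G, 5 = G.U, 6 = U.G,
#   7 = mismatch (both bases present, non-pairing),
#   8 = deletion, single or unpaired bases.
# Codes 1-6 read 5' base first, following the same 5'->3' orientation that
# distinguishes 1 = A-U from 2 = U-A.

PAIR_CODES <- c(AU = 1L, UA = 2L, GC = 3L, CG = 4L, GU = 5L, UG = 6L)

#' Encode one structural position as the 8-state barcode code
#'
#' @param base5,base3 Canonical nucleotide (`A`, `C`, `G`, `U`) or `"-"` for
#'   an absent base. T is accepted and read as U.
#' @param paired Is the position a base pair in the structure?
#' @return Integer code 1-8, or `NA` (the "ambiguous" sentinel) if either
#'   side carries an IUPAC ambiguity code; ambiguous positions are never
#'   classified as CBCs downstream.
#' @export
encode_position <- function(base5, base3, paired = TRUE) {
  base5 <- canonicalize_rna(base5)
  base3 <- canonicalize_rna(base3)
  for (b in c(base5, base3)) {
    if (!(b %in% c(CANONICAL_RNA, "-"))) {
      if (b %in% IUPAC_RNA) return(NA_integer_)
      stop(sprintf("invalid base '%s'", b))
    }
  }
  if (base5 == "-" || base3 == "-" || !paired) return(8L)
  code <- PAIR_CODES[paste0(base5, base3)]
  if (is.na(code)) 7L else unname(code)
}

barcode_row <- function(helix, segment, rank, pos5, pos3, base5, base3, code) {
  data.frame(helix = helix, segment = segment, rank = rank,
             pos5 = pos5, pos3 = pos3, base5 = base5, base3 = base3,
             code = code, stringsAsFactors = FALSE)
}

#' Build the ITS-2 barcode of a taxon
#'
#' One position per base pair of the region, ordered helix I to IV and
#' base to tip; each position carries its 8-state code and the underlying
#' bases. With `emit_unpaired = TRUE`, single-stranded bases inside the
#' scoped helices (bulges/internal loops, segment `"L"`, and apical loops,
#' segment `"A"`) are appended per helix as code-8 positions, which makes
#' substitutions at unpaired sites visible to the comparison step.
#'
#' @param aseq The taxon's [annotated_seq].
#' @param st Its [secondary_structure].
#' @param region Region specification from [conserved_region] (columns
#'   `helix`, `rank`, `pos5`, `pos3`).
#' @param emit_unpaired Also emit unpaired in-helix positions as code 8.
#' @param model The annotated `helix_model`; required when
#'   `emit_unpaired = TRUE`.
#' @return Object of class `its2_barcode` with fields `taxon`, `positions`
#'   (data frame: helix, segment, rank, pos5, pos3, base5, base3, code) and
#'   `digits` (the code string; ambiguous positions print as `?`).
#' @export
make_barcode <- function(aseq, st, region, emit_unpaired = FALSE, model = NULL) {
  if (st$n != nchar(aseq$seq))
    stop("structure length disagrees with sequence length")
  ch <- seq_chars(aseq)
  rows <- list()
  if (nrow(region)) {
    if (any(region$pos5 > st$n | region$pos3 > st$n | region$pos5 < 1))
      stop("region references a position outside the structure")
    if (any(st$pairs[region$pos5] != region$pos3))
      stop("region cites a base pair not present in the structure")
  }
  for (h in unique(region$helix)) {
    rr <- region[region$helix == h, , drop = FALSE]
    rr <- rr[order(rr$rank), , drop = FALSE]
    codes <- mapply(function(p5, p3) encode_position(ch[p5], ch[p3], TRUE),
                    rr$pos5, rr$pos3)
    rows[[length(rows) + 1L]] <-
      barcode_row(h, "P", rr$rank, rr$pos5, rr$pos3, ch[rr$pos5], ch[rr$pos3],
                  as.integer(codes))
    if (emit_unpaired) {
      if (is.null(model))
        stop("emit_unpaired = TRUE requires the helix model")
      k <- which(helix_labels(model) == h)[1]
      if (is.na(k)) stop(sprintf("helix '%s' absent from model", h))
      hx <- model$helices[[k]]
      for (seg in c("L", "A")) {
        pos <- sort(if (seg == "L") hx$loops else hx$apical)
        if (length(pos))
          rows[[length(rows) + 1L]] <-
            barcode_row(h, seg, seq_along(pos), pos, NA_integer_,
                        ch[pos], "-", rep(8L, length(pos)))
      }
    }
  }
  positions <- if (length(rows)) do.call(rbind, rows) else
    barcode_row(character(), character(), integer(), integer(), integer(),
                character(), character(), integer())
  digits <- paste(ifelse(is.na(positions$code), "?", positions$code),
                  collapse = "")
  structure(list(taxon = aseq$id, positions = positions, digits = digits),
            class = "its2_barcode")
}

#' @export
print.its2_barcode <- function(x, ...) {
  cat(sprintf("<its2_barcode> %s: %d positions\n%s\n",
              x$taxon, nrow(x$positions), x$digits))
  invisible(x)
}
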