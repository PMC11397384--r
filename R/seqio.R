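# Nucleotide alphabet handling. Sequences are canonicalized to the RNA
# alphabet (T -> U) on input; IUPAC ambiguity codes are accepted but flagged
# so downstream modules can refuse to classify through them.

IUPAC_RNA <- c("A", "C", "G", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")
CANONICAL_RNA <- c("A", "C", "G", "U")

canonicalize_rna <- function(x) {
  chartr("acgutT", "ACGUUU", x)
}

#' Construct an annotated nucleotide sequence
#'
#' The basic sequence container of the package: an id, an uppercase
#' RNA-alphabet sequence (T is converted to U), optional region annotations
#' with 1-based inclusive coordinates, and free-text provenance.
#'
#' @param id Non-empty identifier.
#' @param seq Nucleotide string over the IUPAC alphabet (T or U accepted).
#' @param regions `data.frame` with columns `label`, `start`, `end` and
#'   optionally `strand` (`"+"` or `"-"`); 1-based inclusive coordinates.
#' @param source Free-text provenance (file name, accession).
#' @return An object of class `annotated_seq`.
#' @export
annotated_seq <- function(id, seq, regions = NULL, source = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty string")
  seq <- canonicalize_rna(seq)
  bad <- which(!strsplit(seq, "")[[1]] %in% IUPAC_RNA)
  if (length(bad))
    stop(sprintf("sequence '%s' contains non-nucleotide character at position %d",
                 id, bad[1]))
  if (is.null(regions)) {
    regions <- data.frame(label = character(), start = integer(),
                          end = integer(), strand = character(),
                          stringsAsFactors = FALSE)
  } else {
    if (!"strand" %in% names(regions)) regions$strand <- "+"
    n <- nchar(seq)
    ok <- regions$start >= 1L & regions$end <= n & regions$start <= regions$end
    if (any(!ok))
      stop(sprintf("region '%s' [%d, %d] outside sequence of length %d",
                   regions$label[!ok][1], regions$start[!ok][1],
                   regions$end[!ok][1], n))
  }
  structure(list(id = id, seq = seq, regions = regions, source = source),
            class = "annotated_seq")
}

#' @export
print.annotated_seq <- function(x, ...) {
  cat(sprintf("<annotated_seq> %s (%d nt)\n", x$id, nchar(x$seq)))
  if (nrow(x$regions))
    for (k in seq_len(nrow(x$regions)))
      cat(sprintf("  %s: %d..%d (%s)\n", x$regions$label[k],
                  x$regions$start[k], x$regions$end[k], x$regions$strand[k]))
  invisible(x)
}

seq_chars <- function(aseq) strsplit(aseq$seq, "")[[1]]

has_ambiguity <- function(aseq) {
  any(!seq_chars(aseq) %in% CANONICAL_RNA)
}

#' Read a FASTA file into annotated sequences
#'
#' Ids are taken from the header up to the first whitespace; T is
#' canonicalized to U. Duplicate ids and non-IUPAC characters are errors.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return Named list of [annotated_seq] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate sequence id '%s' in %s", dup[1], path))
  out <- lapply(seq_along(set), function(k)
    annotated_seq(ids[k], as.character(set[[k]]), source = path))
  names(out) <- ids
  out
}

#' Write annotated sequences to FASTA
#'
#' @param seqs A single [annotated_seq] or a list of them.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "annotated_seq")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    sq <- s$seq
    starts <- seq(1L, nchar(sq), by = width)
    writeLines(substring(sq, starts, pmin(starts + width - 1L, nchar(sq))), con)
  }
  invisible(path)
}

#' Read a GenBank flat file
#'
#' Minimal reader for single-record GenBank flat files: the ORIGIN sequence
#' is extracted, and feature-table entries with simple `a..b` or
#' `complement(a..b)` locations (keys rRNA, misc_RNA, intron, CDS, and other
#' plain keys) are mapped into region annotations. `join`/`order` and other
#' compound locations are unsupported and raise an error rather than being
#' guessed at.
#'
#' @param path Path to a GenBank flat file.
#' @return An [annotated_seq] with regions from the feature table.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1])),
                                    "\\s+")[[1]][1] else basename(path)
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc)) {
    a <- strsplit(trimws(sub("^ACCESSION", "", acc[1])), "\\s+")[[1]][1]
    if (nzchar(a) && a != ".") id <- a
  }
  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop(sprintf("no ORIGIN block in %s", path))
  end <- grep("^//", lines)
  end <- if (length(end)) end[end > ori[1]][1] else length(lines) + 1L
  seqlines <- lines[(ori[1] + 1L):(end - 1L)]
  seq <- toupper(gsub("[0-9 /]", "", paste(seqlines, collapse = "")))

  regions <- data.frame(label = character(), start = integer(),
                        end = integer(), strand = character(),
                        stringsAsFactors = FALSE)
  fstart <- grep("^FEATURES", lines)
  if (length(fstart)) {
    feat <- lines[(fstart[1] + 1L):(ori[1] - 1L)]
    # feature headers have the key starting in column 6 and a location
    hdr <- grep("^\\s{1,10}\\S+\\s+\\S", feat)
    hdr <- hdr[!grepl("^\\s*/", feat[hdr])]   # drop qualifier lines
    for (k in hdr) {
      parts <- strsplit(trimws(feat[k]), "\\s+")[[1]]
      if (length(parts) < 2L) next
      key <- parts[1]
      if (key == "source") next
      loc <- parts[2]
      if (grepl("^(join|order)\\(", loc))
        stop(sprintf("unsupported compound location '%s' for feature '%s'",
                     loc, key))
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      if (grepl("^(join|order)\\(", loc))
        stop(sprintf("unsupported compound location for feature '%s'", key))
      loc <- gsub("[<>]", "", loc)
      if (grepl("^[0-9]+\\.\\.[0-9]+$", loc)) {
        se <- as.integer(strsplit(loc, "\\.\\.")[[1]])
      } else if (grepl("^[0-9]+$", loc)) {
        se <- rep(as.integer(loc), 2L)
      } else {
        stop(sprintf("unsupported location '%s' for feature '%s'", loc, key))
      }
      regions <- rbind(regions,
                       data.frame(label = key, start = se[1], end = se[2],
                                  strand = strand, stringsAsFactors = FALSE))
    }
  }
  annotated_seq(id, seq, regions = regions, source = path)
}

#' Extract an annotated region from a sequence
#'
#' Returns the subsequence of the first region with the given label;
#' minus-strand regions are reverse-complemented (RNA alphabet).
#'
#' @param aseq An [annotated_seq].
#' @param label Region label (feature key), e.g. `"CDS"` or `"intron"`.
#' @param which If several regions share the label, the 1-based index.
#' @return An [annotated_seq] holding the extracted (oriented) subsequence.
#' @export
extract_region <- function(aseq, label, which = 1L) {
  hit <- which(aseq$regions$label == label)
  if (length(hit) < which)
    stop(sprintf("no region '%s' (#%d) in '%s'", label, which, aseq$id))
  r <- aseq$regions[hit[which], ]
  sub <- substr(aseq$seq, r$start, r$end)
  if (r$strand == "-") sub <- revcomp_rna(sub)
  annotated_seq(paste0(aseq$id, ":", label), sub, source = aseq$source)
}

revcomp_rna <- function(x) {
  comp <- chartr("ACGURYSWKMBDHVN", "UGCAYRSWMKVHDBN", x)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

#' Construct a multiple sequence alignment
#'
#' @param ids Character vector of row ids.
#' @param seqs Character vector of equal-length gapped sequences
#'   (gap `-`; `.` converted to `-`).
#' @return Object of class `msa_alignment` with fields `ids`, `seqs`,
#'   `length`.
#' @export
msa_alignment <- function(ids, seqs) {
  seqs <- gsub(".", "-", canonicalize_rna(seqs), fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != lens[1])[1]
    stop(sprintf("ragged alignment: row '%s' has length %d, row '%s' has length %d",
                 ids[1], lens[1], ids[bad], lens[bad]))
  }
  if (any(gsub("-", "", seqs) == ""))
    stop("alignment contains an all-gap row")
  if (anyDuplicated(ids)) stop("duplicate ids in alignment")
  structure(list(ids = ids, seqs = stats::setNames(seqs, ids),
                 length = unname(lens[1])),
            class = "msa_alignment")
}

#' Read a multiple sequence alignment
#'
#' Aligned FASTA or relaxed PHYLIP (sequential or interleaved; names are
#' whitespace-delimited, any length). `.` gaps are converted to `-`.
#'
#' @param path File path.
#' @param format `"fasta"` or `"phylip"`.
#' @return An [msa_alignment].
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (!length(set)) stop(sprintf("empty alignment file: %s", path))
    return(msa_alignment(sub("\\s.*$", "", names(set)), as.character(set)))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) < 2L || anyNA(hdr))
    stop(sprintf("malformed PHYLIP header in %s", path))
  ntaxa <- hdr[1]; ncols <- hdr[2]
  body <- lines[-1]
  ids <- character(ntaxa)
  seqs <- character(ntaxa)
  row <- 0L
  first_block <- TRUE
  for (ln in body) {
    row <- row + 1L
    if (row > ntaxa) { row <- 1L; first_block <- FALSE }
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (first_block) {
      ids[row] <- toks[1]
      seqs[row] <- paste(toks[-1], collapse = "")
    } else {
      seqs[row] <- paste0(seqs[row], paste(toks, collapse = ""))
    }
  }
  lens <- nchar(seqs)
  if (any(lens != ncols)) {
    bad <- which(lens != ncols)[1]
    stop(sprintf("ragged alignment: row '%s' has length %d, header says %d",
                 ids[bad], lens[bad], ncols))
  }
  msa_alignment(ids, seqs)
}
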