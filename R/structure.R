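# Secondary structures are stored as a pair table: an integer vector pt of
# length n with pt[i] = j if (i, j) is a base pair and 0 if i is unpaired.
# The table is involutive (pt[pt[i]] == i) and pseudoknot-free.

ALLOWED_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

pair_allowed <- function(b5, b3) paste0(b5, b3) %in% ALLOWED_PAIRS

#' Construct a secondary structure from a pair table
#'
#' @param pairs Integer vector: `pairs[i] = j` if i pairs with j, 0 if
#'   unpaired. Must be involutive and pseudoknot-free.
#' @param n Sequence length; defaults to `length(pairs)`.
#' @return Object of class `secondary_structure` with fields `n`, `pairs`,
#'   `dotbracket`.
#' @export
secondary_structure <- function(pairs, n = length(pairs)) {
  pairs <- as.integer(pairs)
  if (length(pairs) != n) stop("pair table length disagrees with n")
  paired <- which(pairs > 0L)
  if (any(pairs[paired] < 1L | pairs[paired] > n))
    stop("pair partner outside sequence")
  if (any(pairs[pairs[paired]] != paired))
    stop("pair table is not involutive")
  if (any(pairs[paired] == paired)) stop("position paired with itself")
  # pseudoknot check on pairs stored once (i < j)
  ij <- cbind(paired[pairs[paired] > paired], pairs[paired[pairs[paired] > paired]])
  if (nrow(ij) > 1L) {
    ord <- order(ij[, 1])
    ij <- ij[ord, , drop = FALSE]
    for (a in seq_len(nrow(ij) - 1L)) {
      for (b in (a + 1L):nrow(ij)) {
        if (ij[b, 1] < ij[a, 2] && ij[b, 2] > ij[a, 2])
          stop(sprintf("pseudoknot: pairs (%d,%d) and (%d,%d) cross",
                       ij[a, 1], ij[a, 2], ij[b, 1], ij[b, 2]))
      }
    }
  }
  structure(list(n = n, pairs = pairs,
                 dotbracket = pairs_to_dotbracket(pairs)),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d nt, %d pairs\n%s\n",
              x$n, sum(x$pairs > 0) / 2L, x$dotbracket))
  invisible(x)
}

#' Parse dot-bracket notation into a pair table
#'
#' Only round brackets are accepted (pseudoknot-free structures); any other
#' bracket type is rejected as a pseudoknot annotation.
#'
#' @param db Dot-bracket string over `.`, `(`, `)`.
#' @return Integer pair table.
#' @export
dotbracket_to_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  if (any(ch %in% c("[", "]", "{", "}", "<", ">")))
    stop("pseudoknot bracket types are not supported")
  bad <- which(!ch %in% c(".", "(", ")"))
  if (length(bad))
    stop(sprintf("invalid dot-bracket character '%s' at position %d",
                 ch[bad[1]], bad[1]))
  pairs <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack))
        stop(sprintf("unbalanced ')' at position %d", i))
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j; pairs[j] <- i
    }
  }
  if (length(stack))
    stop(sprintf("unbalanced '(' at position %d", stack[length(stack)]))
  pairs
}

#' Render a pair table as dot-bracket notation
#'
#' @param pairs Integer pair table.
#' @return Dot-bracket string.
#' @export
pairs_to_dotbracket <- function(pairs) {
  ch <- rep(".", length(pairs))
  ch[pairs > seq_along(pairs)] <- "("
  ch[pairs > 0 & pairs < seq_along(pairs)] <- ")"
  paste(ch, collapse = "")
}

#' Read a structure file (Vienna dot-bracket or CT)
#'
#' Vienna: optional `>name` header, sequence line, dot-bracket line.
#' CT: header line with the length, then one row per position
#' (`index base prev next pair index`); non-reciprocal pairing columns are an
#' error.
#'
#' @param path File path.
#' @param dialect `"vienna"` or `"ct"`.
#' @return List with elements `seq` ([annotated_seq]) and `structure`
#'   ([secondary_structure]).
#' @export
read_structure <- function(path, dialect = c("vienna", "ct")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("empty structure file: %s", path))
  if (dialect == "vienna") {
    id <- basename(path)
    if (startsWith(lines[1], ">")) {
      id <- sub("\\s.*$", "", sub("^>", "", lines[1]))
      lines <- lines[-1]
    }
    if (length(lines) < 2L) stop("Vienna record needs sequence and structure lines")
    seqline <- trimws(lines[1])
    db <- sub("\\s.*$", "", trimws(lines[2]))   # energies after whitespace ignored
    if (nchar(db) != nchar(seqline))
      stop("sequence and structure lines have different lengths")
    aseq <- annotated_seq(id, seqline, source = path)
    st <- secondary_structure(dotbracket_to_pairs(db))
    return(list(seq = aseq, structure = st))
  }
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(n)) stop(sprintf("malformed CT header in %s", path))
  rows <- lines[2:(1 + n)]
  bases <- character(n)
  pairs <- integer(n)
  for (k in seq_len(n)) {
    f <- strsplit(trimws(rows[k]), "\\s+")[[1]]
    if (length(f) < 6L) stop(sprintf("malformed CT row %d", k))
    bases[k] <- f[2]
    pairs[k] <- as.integer(f[5])
  }
  paired <- which(pairs > 0L)
  bad <- paired[pairs[pairs[paired]] != paired]
  if (length(bad))
    stop(sprintf("CT row %d cites partner %d which does not reciprocate",
                 bad[1], pairs[bad[1]]))
  id <- if (length(hdr) > 1L) hdr[length(hdr)] else basename(path)
  list(seq = annotated_seq(id, paste(bases, collapse = ""), source = path),
       structure = secondary_structure(pairs))
}

#' Write a sequence/structure pair in Vienna format
#'
#' @param aseq An [annotated_seq].
#' @param st A [secondary_structure] over the same sequence.
#' @param path Output path.
#' @param append Append to an existing file (multi-record output).
#' @export
write_structure <- function(aseq, st, path, append = FALSE) {
  if (st$n != nchar(aseq$seq)) stop("structure length disagrees with sequence")
  cat(sprintf(">%s\n%s\n%s\n", aseq$id, aseq$seq, st$dotbracket),
      file = path, append = append)
  invisible(path)
}

#' Write a sequence/structure pair in CT format
#'
#' @inheritParams write_structure
#' @export
write_ct <- function(aseq, st, path) {
  if (st$n != nchar(aseq$seq)) stop("structure length disagrees with sequence")
  ch <- seq_chars(aseq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %s", st$n, aseq$id), con)
  for (i in seq_len(st$n))
    writeLines(sprintf("%d %s %d %d %d %d", i, ch[i], i - 1L,
                       if (i < st$n) i + 1L else 0L, st$pairs[i], i), con)
  invisible(path)
}
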