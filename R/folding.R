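# Deterministic secondary-structure prediction by base-pair maximisation.
#
# The objective is (number of pairs) + stacking_bonus * (number of stacked
# adjacent pairs), maximised over all pseudoknot-free structures whose
# hairpin loops have at least min_hairpin unpaired bases. This is a
# base-pair-counting stand-in for thermodynamic folding: it reproduces
# helix-dominated topologies (which is what the barcode needs) without
# free-energy estimation. Imported structures from external folders are
# accepted everywhere downstream via read_structure().
#
# Tie-break: traceback prefers pairing the 5'-most open position over
# leaving it unpaired, and among co-optimal partners prefers the smallest
# 3' partner; within a closed pair a stacked continuation is preferred.

NEG <- -1e9

fold_engine <- function(bases, min_hairpin, stacking, cn) {
  n <- length(bases)
  canonical <- bases %in% CANONICAL_RNA
  # partner lists: k > i, allowed pair, hairpin span, constraint-compatible
  partners <- vector("list", n)
  for (i in seq_len(n)) {
    ks <- seq_len(n)
    ks <- ks[ks > i + min_hairpin]
    if (length(ks)) {
      ok <- canonical[i] & canonical[ks] &
        paste0(bases[i], bases[ks]) %in% ALLOWED_PAIRS &
        (is.na(cn[i]) | cn[i] == ks) &
        (is.na(cn[ks]) | cn[ks] == i)
      if (!is.na(cn[i]) && cn[i] == 0L) ok[] <- FALSE
      ok[!is.na(cn[ks]) & cn[ks] == 0L] <- FALSE
      ks <- ks[ok]
    }
    partners[[i]] <- ks
  }
  M <- matrix(0, n, n)   # best score for interval [i, j]
  P <- matrix(NEG, n, n) # best score for [i, j] given i pairs j
  Mget <- function(i, j) if (i > j) 0 else M[i, j]
  can_unpair <- is.na(cn) | cn == 0L

  for (len in 2:max(2L, n)) {
    if (n < 2L) break
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      if (j - i > min_hairpin && length(partners[[i]]) && j %in% partners[[i]]) {
        x <- i + 1L; y <- j - 1L
        inner <- if (x > y) 0 else M[x, y]
        if (x <= y && P[x, y] > NEG / 2) inner <- max(inner, P[x, y] + stacking)
        P[i, j] <- 1 + inner
      }
      best <- if (can_unpair[i]) Mget(i + 1L, j) else NEG
      ks <- partners[[i]]
      ks <- ks[ks <= j]
      for (k in ks) {
        s <- P[i, k] + Mget(k + 1L, j)
        if (s > best) best <- s
      }
      M[i, j] <- best
    }
  }

  pt <- integer(n)
  tb_P <- function(i, j) {
    pt[i] <<- j; pt[j] <<- i
    x <- i + 1L; y <- j - 1L
    if (x > y) return(invisible())
    sp <- if (P[x, y] > NEG / 2) P[x, y] + stacking else NEG
    if (sp >= M[x, y] && sp > NEG / 2) tb_P(x, y) else tb_M(x, y)
  }
  tb_M <- function(i, j) {
    while (i <= j) {
      target <- Mget(i, j)
      if (target <= NEG / 2)
        stop("constraints cannot be satisfied by any structure")
      ks <- partners[[i]]
      ks <- ks[ks <= j]
      paired_here <- FALSE
      for (k in ks) {                      # smallest partner first
        if (P[i, k] + Mget(k + 1L, j) >= target - 1e-9) {
          tb_P(i, k)
          i <- k + 1L
          paired_here <- TRUE
          break
        }
      }
      if (!paired_here) i <- i + 1L
    }
    invisible()
  }
  total <- if (n >= 2L) M[1, n] else 0
  if (total <= NEG / 2)
    stop("constraints cannot be satisfied by any structure")
  if (n >= 2L) tb_M(1L, n)
  list(pairs = pt, objective = total)
}

prepare_fold_input <- function(seq) {
  if (inherits(seq, "annotated_seq")) seq <- seq$seq
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("sequence must be a non-empty nucleotide string")
  strsplit(canonicalize_rna(seq), "")[[1]]
}

#' Fold a sequence by base-pair maximisation
#'
#' Dynamic-programming maximisation of pair count plus a stacking bonus over
#' all pseudoknot-free structures. Pairs are restricted to the canonical set
#' A-U, U-A, G-C, C-G plus the G.U/U.G wobbles; positions carrying IUPAC
#' ambiguity codes are left unpaired. The result is deterministic under the
#' documented traceback tie-break.
#'
#' @param seq Nucleotide string or [annotated_seq] (case and T/U spelling
#'   are irrelevant).
#' @param min_hairpin Minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @param stacking_bonus Bonus added to the objective per pair stacked
#'   directly on another (default 0.5); must be >= 0.
#' @return A [secondary_structure]; the achieved objective value is attached
#'   as attribute `"objective"`.
#' @examples
#' fold_maxpair("GGGAAACCC")$dotbracket   # "(((...)))"
#' @export
fold_maxpair <- function(seq, min_hairpin = 3L, stacking_bonus = 0.5) {
  bases <- prepare_fold_input(seq)
  if (stacking_bonus < 0) stop("stacking_bonus must be >= 0")
  res <- fold_engine(bases, as.integer(min_hairpin), stacking_bonus,
                     rep(NA_integer_, length(bases)))
  st <- secondary_structure(res$pairs)
  attr(st, "objective") <- res$objective
  st
}

#' Fold under per-position constraints
#'
#' Same objective and tie-break as [fold_maxpair], restricted to structures
#' satisfying every constraint. A constraint is per position: forced
#' unpaired, forced paired with a named partner, or free.
#'
#' @inheritParams fold_maxpair
#' @param constraints Integer vector of length `nchar(seq)`: `NA` = free,
#'   `0` = forced unpaired, `j > 0` = forced paired with position `j`
#'   (must be reciprocal or one-sided; one-sided is completed).
#' @return A [secondary_structure] with attribute `"objective"`.
#' @export
fold_constrained <- function(seq, constraints, min_hairpin = 3L,
                             stacking_bonus = 0.5) {
  bases <- prepare_fold_input(seq)
  n <- length(bases)
  cn <- as.integer(constraints)
  if (length(cn) != n) stop("constraints must have one entry per position")
  # complete one-sided forced pairs, then validate
  for (i in seq_len(n)) {
    j <- cn[i]
    if (!is.na(j) && j > 0L) {
      if (j < 1L || j > n)
        stop(sprintf("constraint at position %d names partner %d outside sequence", i, j))
      if (is.na(cn[j])) cn[j] <- i
      if (cn[j] != i)
        stop(sprintf("contradictory constraints: pair (%d,%d) conflicts with (%d,%d)",
                     i, j, j, cn[j]))
    }
  }
  forced <- which(!is.na(cn) & cn > seq_len(n))
  for (i in forced) {
    j <- cn[i]
    if (j - i <= min_hairpin)
      stop(sprintf("contradictory constraints: forced pair (%d,%d) violates the min_hairpin=%d rule",
                   i, j, min_hairpin))
    if (!(bases[i] %in% CANONICAL_RNA) || !(bases[j] %in% CANONICAL_RNA) ||
        !pair_allowed(bases[i], bases[j]))
      stop(sprintf("contradictory constraints: forced pair (%d,%d) is %s-%s, not an allowed pair",
                   i, j, bases[i], bases[j]))
  }
  if (length(forced) > 1L) {
    for (a in seq_len(length(forced) - 1L)) {
      for (b in (a + 1L):length(forced)) {
        i1 <- forced[a]; j1 <- cn[forced[a]]
        i2 <- forced[b]; j2 <- cn[forced[b]]
        if (i2 < j1 && j2 > j1)
          stop(sprintf("contradictory constraints: forced pairs (%d,%d) and (%d,%d) cross",
                       i1, j1, i2, j2))
      }
    }
  }
  res <- fold_engine(bases, as.integer(min_hairpin), stacking_bonus, cn)
  st <- secondary_structure(res$pairs)
  attr(st, "objective") <- res$objective
  st
}
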