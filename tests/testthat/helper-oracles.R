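# Independent brute-force oracles. These deliberately re-derive everything
# from first principles (explicit enumeration, literal lookup tables) and
# never call into the package's folding or classification code paths.

ORACLE_ALLOWED <- c("AU", "UA", "GC", "CG", "GU", "UG")
ORACLE_BASES <- c("A", "C", "G", "U")

# every pseudoknot-free set of pairs over positions 1..n with hairpin loops
# of at least minh unpaired bases; returned as two-column matrices
enum_structs <- local({
  cache <- new.env(parent = emptyenv())
  function(n, minh = 3L) {
    key <- paste(n, minh)
    if (!is.null(cache[[key]])) return(cache[[key]])
    rec <- function(i, j) {
      if (i >= j) return(list(matrix(integer(0), ncol = 2)))
      out <- rec(i + 1L, j)                    # i unpaired
      if (i + minh + 1L <= j) {
        for (k in (i + minh + 1L):j) {
          for (inner in rec(i + 1L, k - 1L))
            for (outer in rec(k + 1L, j))
              out[[length(out) + 1L]] <- rbind(c(i, k), inner, outer)
        }
      }
      out
    }
    res <- lapply(rec(1L, n), function(m) {
      nstack <- 0L
      if (nrow(m) > 1L) {
        key2 <- paste(m[, 1], m[, 2])
        nstack <- sum(paste(m[, 1] + 1L, m[, 2] - 1L) %in% key2)
      }
      list(pairs = m, nstack = nstack)
    })
    cache[[key]] <- res
    res
  }
})

# maximum of (pairs + stacking * stacked pairs) over all valid structures
oracle_fold_objective <- function(seq, minh = 3L, stacking = 0.5) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  best <- 0
  for (s in enum_structs(length(ch), minh)) {
    m <- s$pairs
    if (nrow(m) && !all(paste0(ch[m[, 1]], ch[m[, 2]]) %in% ORACLE_ALLOWED))
      next
    best <- max(best, nrow(m) + stacking * s$nstack)
  }
  best
}

# objective of one concrete structure (validity check for traceback output)
oracle_score_structure <- function(seq, pairs_table, stacking = 0.5) {
  ch <- strsplit(seq, "")[[1]]
  i <- which(pairs_table > seq_along(pairs_table))
  j <- pairs_table[i]
  stopifnot(all(paste0(ch[i], ch[j]) %in% ORACLE_ALLOWED))
  nstack <- sum(paste(i + 1L, j - 1L) %in% paste(i, j))
  length(i) + stacking * nstack
}

random_rna <- function(n) paste(sample(ORACLE_BASES, n, replace = TRUE),
                                collapse = "")

# literal 8-state code table from the barcode legend
oracle_code <- function(b5, b3, paired) {
  if (b5 == "-" || b3 == "-" || !paired) return(8L)
  tab <- c(AU = 1, UA = 2, GC = 3, CG = 4, GU = 5, UG = 6)
  code <- tab[paste0(b5, b3)]
  if (is.na(code)) 7L else as.integer(code)
}

# first-principles change classification over two (b5, b3, code) states;
# NULL denotes a gap in the homology
oracle_classify <- function(a, b) {
  if (is.null(a) || is.null(b)) {
    if (is.null(a) && is.null(b)) stop("gap-gap")
    return("indel_unpaired")
  }
  same <- a$code == b$code && a$b5 == b$b5 && a$b3 == b$b3
  if (a$code <= 6 && b$code <= 6) {
    nd <- (a$b5 != b$b5) + (a$b3 != b$b3)
    return(switch(nd + 1L, "identical", "HCBC", "CBC"))
  }
  if (a$code == 7 || b$code == 7)
    return(if (same) "identical" else "mismatch_change")
  if (same) "identical" else "indel_unpaired"
}

# representative (b5, b3) states per code, enumerated from the legend
oracle_states_for_code <- function(code) {
  states <- list()
  if (code <= 6) {
    p <- ORACLE_ALLOWED[code]
    states[[1]] <- list(b5 = substr(p, 1, 1), b3 = substr(p, 2, 2), code = code)
  } else if (code == 7) {
    for (b5 in ORACLE_BASES) for (b3 in ORACLE_BASES)
      if (!paste0(b5, b3) %in% ORACLE_ALLOWED)
        states[[length(states) + 1L]] <- list(b5 = b5, b3 = b3, code = 7L)
  } else {
    for (b5 in ORACLE_BASES)
      states[[length(states) + 1L]] <- list(b5 = b5, b3 = "-", code = 8L)
  }
  states
}
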