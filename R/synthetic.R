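# Synthetic ITS-2-like sequence/structure pairs with planted, ledgered
# changes. The generator is the offline ground truth for the comparison
# machinery: every planted CBC / hemi-CBC / unpaired substitution /
# pair indel is recorded, and compare_taxa() on the generated pair (with
# the true structures) must recover the ledger totals exactly.
#
# All randomness goes through R's Mersenne-Twister, seeded explicitly at
# every entry point and restored afterwards (no global-state leakage).

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  force(code)
}

sample_pair_classes <- function(n, gc_bias) {
  # gc_bias is the G-C/C-G frequency; the remainder splits 80% Watson-Crick
  # A-U/U-A and 20% G.U/U.G wobbles
  p <- c(AU = (1 - gc_bias) * 0.4, UA = (1 - gc_bias) * 0.4,
         GC = gc_bias / 2, CG = gc_bias / 2,
         GU = (1 - gc_bias) * 0.1, UG = (1 - gc_bias) * 0.1)
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Generate a synthetic ITS-2-like sequence with a four-helix structure
#'
#' Four hairpin helices of the requested stem lengths, joined by
#' single-stranded spacers, with all stem pairs drawn from the six allowed
#' pair classes (`gc_bias` controls the G-C frequency). The true structure
#' is returned alongside the sequence; output is fully reproducible from
#' the seed.
#'
#' @param seed Integer seed.
#' @param helix_stems Four stem lengths in base pairs (each >= 2); defaults
#'   mirror a green-algal ITS-2 with helix III longest.
#' @param loop_lengths Four apical-loop lengths (each >= 3).
#' @param gc_bias Fraction of stem pairs that are G-C/C-G (default 0.5).
#' @param spacer_lengths Five single-stranded segment lengths (5' end,
#'   three inter-helix spacers, 3' end).
#' @param id Sequence id.
#' @return List with `seq` ([annotated_seq]) and `structure`
#'   ([secondary_structure]).
#' @export
generate_its2 <- function(seed, helix_stems = c(10L, 12L, 18L, 8L),
                          loop_lengths = c(7L, 7L, 9L, 7L), gc_bias = 0.5,
                          spacer_lengths = c(5L, 3L, 3L, 3L, 5L),
                          id = sprintf("synthetic_its2_seed%d", seed)) {
  if (length(helix_stems) != 4L || any(helix_stems < 2L))
    stop("helix_stems must be four integers >= 2")
  if (length(loop_lengths) != 4L || any(loop_lengths < 3L))
    stop("impossible geometry: apical loops must be >= 3 nt")
  if (length(spacer_lengths) != 5L || any(spacer_lengths < 0L))
    stop("spacer_lengths must be five non-negative integers")
  with_seed(seed, {
    n <- sum(2L * helix_stems) + sum(loop_lengths) + sum(spacer_lengths)
    bases <- character(n)
    pt <- integer(n)
    pos <- 1L
    rand_bases <- function(k) sample(CANONICAL_RNA, k, replace = TRUE)
    if (spacer_lengths[1] > 0L) {
      bases[pos:(pos + spacer_lengths[1] - 1L)] <- rand_bases(spacer_lengths[1])
      pos <- pos + spacer_lengths[1]
    }
    for (h in 1:4) {
      s <- helix_stems[h]; L <- loop_lengths[h]
      cls <- sample_pair_classes(s, gc_bias)
      b5 <- substr(cls, 1, 1); b3 <- substr(cls, 2, 2)
      for (r in seq_len(s)) {
        p5 <- pos + r - 1L
        p3 <- pos + 2L * s + L - r
        bases[p5] <- b5[r]; bases[p3] <- b3[r]
        pt[p5] <- p3; pt[p3] <- p5
      }
      bases[(pos + s):(pos + s + L - 1L)] <- rand_bases(L)
      pos <- pos + 2L * s + L
      sp <- spacer_lengths[h + 1L]
      if (sp > 0L) {
        bases[pos:(pos + sp - 1L)] <- rand_bases(sp)
        pos <- pos + sp
      }
    }
    list(seq = annotated_seq(id, paste(bases, collapse = ""),
                             source = "synthetic generator"),
         structure = secondary_structure(pt))
  })
}

cbc_neighbors <- function(b5, b3) {
  ok <- substr(ALLOWED_PAIRS, 1, 1) != b5 & substr(ALLOWED_PAIRS, 2, 2) != b3
  ALLOWED_PAIRS[ok]
}

hcbc_neighbors <- function(b5, b3) {
  d5 <- substr(ALLOWED_PAIRS, 1, 1) != b5
  d3 <- substr(ALLOWED_PAIRS, 2, 2) != b3
  ALLOWED_PAIRS[xor(d5, d3)]
}

#' Plant ledgered mutations into a synthetic taxon
#'
#' CBC mutations replace a base pair by a pair class in which both bases
#' differ; hemi-CBC mutations change exactly one base while keeping an
#' allowed pair; unpaired substitutions hit apical-loop bases; pair indels
#' delete a tip-ward pair (both nucleotides removed, structure updated).
#' Mutated sites are never adjacent to one another (deleted tip blocks
#' count as one site), so re-folding perturbations stay local; this is a
#' generator guarantee, not a model of ITS-2 evolution. Everything is
#' recorded in a mutation ledger.
#'
#' @param aseq,st The taxon to mutate ([annotated_seq],
#'   [secondary_structure]).
#' @param n_cbc,n_hcbc,n_unpaired,n_pair_indel Planted counts per class.
#' @param seed Integer seed.
#' @return List with `seq` (mutated), `structure` (mutated), `ledger`
#'   (class `mutation_ledger`: `seed`, `records` data frame, `totals`).
#' @export
plant_mutations <- function(aseq, st, n_cbc = 0L, n_hcbc = 0L,
                            n_unpaired = 0L, n_pair_indel = 0L, seed = 1L) {
  model <- annotate_four_helix(decompose_helices(st), strict = FALSE)
  nh <- length(model$helices)
  if (!nh && (n_cbc + n_hcbc + n_unpaired + n_pair_indel) > 0L)
    stop("insufficient positions: structure has no helices")
  labs <- helix_labels(model)
  stems <- vapply(model$helices, function(h) nrow(h$basepairs), integer(1))

  # allocate tip deletions round-robin, never below 2 remaining pairs
  del <- integer(nh)
  left <- n_pair_indel
  while (left > 0L) {
    progressed <- FALSE
    for (h in seq_len(nh)) {
      if (left > 0L && stems[h] - del[h] > 2L) {
        del[h] <- del[h] + 1L; left <- left - 1L; progressed <- TRUE
      }
    }
    if (!progressed)
      stop("insufficient positions for class 'pair-indel'")
  }

  # pre-spaced candidate pools (pairwise distance >= 2 guaranteed)
  sub_pool <- do.call(rbind, lapply(seq_len(nh), function(h) {
    lim <- stems[h] - del[h] - 1L
    if (lim < 1L) return(NULL)
    data.frame(h = h, rank = seq(1L, lim, by = 2L))
  }))
  loop_pool <- do.call(rbind, lapply(seq_len(nh), function(h) {
    ap <- sort(model$helices[[h]]$apical)
    L <- length(ap)
    if (!L) return(NULL)
    idx <- if (del[h] > 0L) {
      if (L < 3L) integer(0) else seq(2L, L - 1L, by = 2L)
    } else seq(1L, L, by = 2L)
    if (!length(idx)) return(NULL)
    data.frame(h = h, loop_index = idx, pos = ap[idx])
  }))

  with_seed(seed, {
    if (n_cbc + n_hcbc > NROW(sub_pool))
      stop(sprintf("insufficient positions for class '%s'",
                   if (NROW(sub_pool) < n_cbc) "cbc" else "hcbc"))
    if (n_unpaired > NROW(loop_pool))
      stop("insufficient positions for class 'unpaired-sub'")
    chars <- seq_chars(aseq)
    pt <- st$pairs
    rec <- list()
    add_rec <- function(helix, segment, rank, kind, before, after)
      rec[[length(rec) + 1L]] <<- data.frame(
        helix = helix, segment = segment, rank = rank, kind = kind,
        before5 = before[1], before3 = before[2],
        after5 = after[1], after3 = after[2], stringsAsFactors = FALSE)

    picks <- if (NROW(sub_pool)) sub_pool[sample.int(NROW(sub_pool)), ,
                                          drop = FALSE] else sub_pool
    kinds <- c(rep("cbc", n_cbc), rep("hcbc", n_hcbc))
    for (m in seq_along(kinds)) {
      h <- picks$h[m]; r <- picks$rank[m]
      bp <- model$helices[[h]]$basepairs[r, ]
      before <- c(chars[bp[1]], chars[bp[2]])
      opts <- if (kinds[m] == "cbc") cbc_neighbors(before[1], before[2])
      else hcbc_neighbors(before[1], before[2])
      newcls <- if (length(opts) == 1L) opts else sample(opts, 1L)
      after <- c(substr(newcls, 1, 1), substr(newcls, 2, 2))
      chars[bp[1]] <- after[1]; chars[bp[2]] <- after[2]
      add_rec(labs[h], "P", r, kinds[m], before, after)
    }
    if (n_unpaired > 0L) {
      lp <- loop_pool[sample.int(NROW(loop_pool), n_unpaired), , drop = FALSE]
      for (m in seq_len(n_unpaired)) {
        p <- lp$pos[m]
        before <- chars[p]
        after <- sample(setdiff(CANONICAL_RNA, before), 1L)
        chars[p] <- after
        add_rec(labs[lp$h[m]], "A", lp$loop_index[m], "unpaired-sub",
                c(before, "-"), c(after, "-"))
      }
    }
    drop <- logical(length(chars))
    for (h in seq_len(nh)) {
      if (del[h] == 0L) next
      s <- stems[h]
      for (r in seq(s, s - del[h] + 1L)) {
        bp <- model$helices[[h]]$basepairs[r, ]
        drop[bp] <- TRUE
        pt[bp] <- 0L
        add_rec(labs[h], "P", r, "pair-indel",
                c(chars[bp[1]], chars[bp[2]]), c("-", "-"))
      }
    }
    keep <- !drop
    newpos <- cumsum(keep)
    newpt <- integer(sum(keep))
    for (i in which(keep))
      newpt[newpos[i]] <- if (pt[i] > 0L) newpos[pt[i]] else 0L
    records <- if (length(rec)) do.call(rbind, rec) else data.frame(
      helix = character(), segment = character(), rank = integer(),
      kind = character(), before5 = character(), before3 = character(),
      after5 = character(), after3 = character(), stringsAsFactors = FALSE)
    ledger <- structure(
      list(seed = as.integer(seed), records = records,
           totals = list(cbc = n_cbc, hcbc = n_hcbc,
                         unpaired_sub = n_unpaired,
                         pair_indel = n_pair_indel)),
      class = "mutation_ledger")
    list(seq = annotated_seq(paste0(aseq$id, "_mut"),
                             paste(chars[keep], collapse = ""),
                             source = "synthetic generator (mutated)"),
         structure = secondary_structure(newpt),
         ledger = ledger)
  })
}

#' @export
print.mutation_ledger <- function(x, ...) {
  cat(sprintf("<mutation_ledger> seed %d: %d CBC, %d HCBC, %d unpaired-sub, %d pair-indel\n",
              x$seed, x$totals$cbc, x$totals$hcbc, x$totals$unpaired_sub,
              x$totals$pair_indel))
  invisible(x)
}

FIXTURE_PROFILES <- list(
  # magnitudes of the two published comparisons:
  # 1 CBC + 2 HCBC + 9 other, and 8 CBC + 4 HCBC + 30 other
  "ramosa-like" = list(n_cbc = 1L, n_hcbc = 2L, n_unpaired = 6L,
                       n_pair_indel = 3L),
  "pseudomarvania-like" = list(n_cbc = 8L, n_hcbc = 4L, n_unpaired = 12L,
                               n_pair_indel = 18L))

#' Write a synthetic taxon-pair fixture set to disk
#'
#' Generates a four-helix ITS-2-like taxon, plants the profile's mutation
#' counts into a second taxon, and writes FASTA, Vienna dot-bracket and a
#' JSON truth ledger. Running the comparison pipeline end to end on the
#' fixture reproduces the profile's planted totals: the ramosa-like profile
#' plants 1 CBC + 2 hemi-CBCs + 9 other changes, the pseudomarvania-like
#' profile 8 + 4 + 30.
#'
#' @param out_dir Output directory (created if absent).
#' @param profile `"ramosa-like"` or `"pseudomarvania-like"`.
#' @param seed Integer seed.
#' @return List with the file paths (`fasta`, `dbn`, `ledger_json`) and the
#'   in-memory objects (`taxonA`, `taxonB`, `ledger`).
#' @export
make_fixture_set <- function(out_dir, profile = c("ramosa-like",
                                                  "pseudomarvania-like"),
                             seed = 1L) {
  profile <- match.arg(profile)
  pars <- FIXTURE_PROFILES[[profile]]
  gen <- generate_its2(seed, id = sprintf("%s_A_seed%d",
                                          gsub("-", "_", profile), seed))
  mut <- plant_mutations(gen$seq, gen$structure,
                         n_cbc = pars$n_cbc, n_hcbc = pars$n_hcbc,
                         n_unpaired = pars$n_unpaired,
                         n_pair_indel = pars$n_pair_indel,
                         seed = seed + 1000L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(out_dir, sprintf("%s_seed%d.fasta", profile, seed))
  dbn <- file.path(out_dir, sprintf("%s_seed%d.dbn", profile, seed))
  ledger_json <- file.path(out_dir, sprintf("%s_seed%d_ledger.json", profile, seed))
  write_fasta(list(gen$seq, mut$seq), fasta)
  write_structure(gen$seq, gen$structure, dbn)
  write_structure(mut$seq, mut$structure, dbn, append = TRUE)
  jsonlite::write_json(
    list(seed = mut$ledger$seed, profile = profile,
         totals = mut$ledger$totals, records = mut$ledger$records),
    ledger_json, auto_unbox = TRUE, digits = NA)
  list(fasta = fasta, dbn = dbn, ledger_json = ledger_json,
       taxonA = gen, taxonB = mut[c("seq", "structure")],
       ledger = mut$ledger)
}
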