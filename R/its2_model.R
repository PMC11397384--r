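# Helix decomposition of a pseudoknot-free structure. A helix domain is a
# maximal unbranched stem: a run of nested pairs interrupted only by bulges
# and internal loops, ending at a hairpin (apical) loop or at a multiloop.
# Multi-branched domains are split at the multiloop and the sub-helices are
# numbered depth-first, so every reported helix has a well-defined
# base-to-tip pair order — the ordering the barcode and the homology rule
# rely on.

# top-level pairs strictly inside [a, b]
toplevel_pairs <- function(pt, a, b) {
  out <- NULL
  i <- a
  while (i <= b) {
    if (pt[i] > i) {
      out <- rbind(out, c(i, pt[i]))
      i <- pt[i] + 1L
    } else i <- i + 1L
  }
  out
}

#' Decompose a secondary structure into helix domains
#'
#' @param st A [secondary_structure].
#' @return Object of class `helix_model`: a list with `helices` (each helix
#'   carrying `label`, `branch`, `basepairs` (two-column matrix, base to
#'   tip), `loops` (bulge/internal-loop positions) and `apical` (apical-loop
#'   positions)), `n`, and `warnings`.
#' @export
decompose_helices <- function(st) {
  pt <- st$pairs
  helices <- list()
  walk <- function(pair, branch) {
    bp <- matrix(pair, ncol = 2)
    loops <- integer(0)
    cur <- pair
    repeat {
      ch <- toplevel_pairs(pt, cur[1] + 1L, cur[2] - 1L)
      if (is.null(ch)) {
        apical <- if (cur[2] - cur[1] > 1L) (cur[1] + 1L):(cur[2] - 1L) else integer(0)
        helices[[length(helices) + 1L]] <<-
          list(label = NA_character_, branch = branch, basepairs = bp,
               loops = loops, apical = apical)
        return(invisible())
      }
      if (nrow(ch) == 1L) {
        if (ch[1, 1] > cur[1] + 1L) loops <- c(loops, (cur[1] + 1L):(ch[1, 1] - 1L))
        if (ch[1, 2] < cur[2] - 1L) loops <- c(loops, (ch[1, 2] + 1L):(cur[2] - 1L))
        bp <- rbind(bp, ch[1, ])
        cur <- ch[1, ]
      } else {
        helices[[length(helices) + 1L]] <<-
          list(label = NA_character_, branch = branch, basepairs = bp,
               loops = loops, apical = integer(0))
        for (k in seq_len(nrow(ch))) walk(ch[k, ], branch)
        return(invisible())
      }
    }
  }
  tl <- toplevel_pairs(pt, 1L, st$n)
  if (!is.null(tl))
    for (b in seq_len(nrow(tl))) walk(tl[b, ], b)
  structure(list(helices = helices, n = st$n, warnings = character()),
            class = "helix_model")
}

#' @export
print.helix_model <- function(x, ...) {
  cat(sprintf("<helix_model> %d helices\n", length(x$helices)))
  for (h in x$helices)
    cat(sprintf("  %s: %d pairs, base (%d,%d), tip (%d,%d)\n",
                if (is.na(h$label)) sprintf("branch %d", h$branch) else h$label,
                nrow(h$basepairs), h$basepairs[1, 1], h$basepairs[1, 2],
                h$basepairs[nrow(h$basepairs), 1],
                h$basepairs[nrow(h$basepairs), 2]))
  if (length(x$warnings)) cat("  warnings:", x$warnings, "\n")
  invisible(x)
}

n_exterior_branches <- function(model) {
  if (!length(model$helices)) 0L else max(vapply(model$helices, `[[`,
                                                 integer(1), "branch"))
}

#' Label the helices of an ITS-2 model I-IV
#'
#' Green-algal ITS-2 folds into four helices rooted on the exterior loop.
#' With exactly four exterior branches the helices are labelled I-IV in
#' 5' to 3' order (sub-helices past a multiloop get dotted sub-labels, e.g.
#' "II.1"). A different branch count is an error in strict mode and a
#' recorded warning otherwise.
#'
#' @param model A `helix_model` from [decompose_helices].
#' @param strict Error if the exterior branch count differs from 4.
#' @return The model with `label` filled in for every helix.
#' @export
annotate_four_helix <- function(model, strict = FALSE) {
  nb <- n_exterior_branches(model)
  if (nb != 4L) {
    msg <- sprintf("expected 4 helices, found %d", nb)
    if (strict) stop(msg)
    model$warnings <- c(model$warnings, msg)
  }
  sub_counter <- integer(max(nb, 1L))
  seen_branch <- logical(max(nb, 1L))
  for (k in seq_along(model$helices)) {
    b <- model$helices[[k]]$branch
    if (!seen_branch[b]) {
      model$helices[[k]]$label <- as.character(utils::as.roman(b))
      seen_branch[b] <- TRUE
    } else {
      sub_counter[b] <- sub_counter[b] + 1L
      model$helices[[k]]$label <-
        sprintf("%s.%d", as.character(utils::as.roman(b)), sub_counter[b])
    }
  }
  model
}

#' Helix labels of a model, in 5' order
#'
#' @param model A `helix_model`.
#' @return Character vector of labels (`NA` before annotation).
#' @export
helix_labels <- function(model) {
  vapply(model$helices, `[[`, character(1), "label")
}

#' Barcode region of one or more ITS-2 models
#'
#' Returns, per taxon, the ordered paired positions entering the barcode:
#' by default every base pair of every labelled helix, or only the helices
#' named in `scope`. The boundaries of the conserved region are not inferred
#' from sequence conservation; restricting `scope` is the user's call.
#'
#' @param models A single annotated `helix_model` or a named list of them.
#' @param scope `NULL` (all helices) or a character vector of helix labels.
#' @return Per taxon, a `data.frame` with columns `helix`, `rank`, `pos5`,
#'   `pos3` (base-to-tip order within each helix); a list of such frames if
#'   several models were supplied.
#' @export
conserved_region <- function(models, scope = NULL) {
  single <- inherits(models, "helix_model")
  if (single) models <- list(models)
  if (!is.null(scope)) {
    for (m in models) {
      missing_lab <- setdiff(scope, helix_labels(m))
      if (length(missing_lab))
        stop(sprintf("helix label '%s' absent from a model", missing_lab[1]))
    }
  }
  out <- lapply(models, function(m) {
    labs <- helix_labels(m)
    if (anyNA(labs)) stop("model must be annotated (see annotate_four_helix)")
    keep <- if (is.null(scope)) seq_along(m$helices) else which(labs %in% scope)
    if (!length(keep))
      return(data.frame(helix = character(), rank = integer(),
                        pos5 = integer(), pos3 = integer(),
                        stringsAsFactors = FALSE))
    rows <- lapply(keep, function(k) {
      bp <- m$helices[[k]]$basepairs
      data.frame(helix = labs[k], rank = seq_len(nrow(bp)),
                 pos5 = bp[, 1], pos3 = bp[, 2], stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
  if (single) out[[1]] else out
}
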