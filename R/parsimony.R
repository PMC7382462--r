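## Ancestral allele reconstruction by parsimony over a 5-letter alphabet
## (A, C, G, T and gap as an ordinary fifth state), with the gap-column
## filter applied before reconstruction.

.PARS_ALPHABET <- c("A", "C", "G", "T", "-")

#' Discard alignment columns with more than one gap
#'
#' Columns (sites) with two or more gap states are discarded as
#' alignment-uncertain; zero or one gap is retained. Species absent at a
#' site (`NA`) do not count as gaps.
#'
#' @param columns Character matrix, sites x species (see
#'   [readTipStates()]).
#' @return The retained rows of `columns`; the number discarded is logged
#'   and attached as attribute `n_discarded`.
#' @export
filterGapColumns <- function(columns) {
  gaps <- rowSums(columns == "-", na.rm = TRUE)
  keep <- gaps <= 1L
  if (any(!keep))
    message("filterGapColumns: discarded ", sum(!keep),
            " column(s) with >1 gap")
  out <- columns[keep, , drop = FALSE]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Unit-cost Sankoff parsimony with MPR state sets
#'
#' Minimum-change ancestral reconstruction of one site over a rooted tree
#' (multifurcations handled natively) with the 5-state alphabet
#' \{A, C, G, T, -\}, all substitutions at unit cost. Tips absent from
#' `states` (or `NA`) are fully ambiguous. Returns the parsimony score and,
#' for every node, the set of states attained by at least one
#' minimum-change labeling (the MPR sets, from the standard up/down
#' dynamic program).
#'
#' @param tree A rooted `ape::phylo`.
#' @param states Named character vector, tip label -> state; values in
#'   `A`, `C`, `G`, `T`, `-` or `NA`.
#' @return List with `score` (integer), `sets` (list over all nodes, tips
#'   first then internal nodes in ape numbering, each a character vector
#'   of states), and `root` (root node number).
#' @export
fitchStates <- function(tree, states) {
  ## the basal node is taken as the root (a basal multifurcation — which
  ## ape reports as unrooted — is treated as a rooted polytomy)
  tips <- tree$tip.label
  missing_tips <- setdiff(tips, names(states))
  extra <- setdiff(names(states), tips)
  if (length(extra))
    stop("tip label mismatch: ", paste(extra, collapse = ", "),
         " not in tree")
  bad <- !is.na(states) & !states %in% .PARS_ALPHABET
  if (any(bad))
    stop("invalid state(s): ", paste(unique(states[bad]), collapse = ", "))

  S <- length(.PARS_ALPHABET)
  ntip <- length(tips)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  cost <- matrix(0, nnode, S)
  for (i in seq_len(ntip)) {
    st <- if (tips[i] %in% names(states)) states[[tips[i]]] else NA
    if (!is.na(st)) {
      cost[i, ] <- Inf
      cost[i, match(st, .PARS_ALPHABET)] <- 0
    }
  }

  edge <- ape::reorder.phylo(tree, "postorder")$edge
  ## contribution of each child to its parent's cost vector, by edge
  contrib <- matrix(NA_real_, nrow(edge), S)
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    contrib[e, ] <- pmin(cost[ch, ], min(cost[ch, ]) + 1)
    cost[par, ] <- cost[par, ] + contrib[e, ]
  }
  score <- min(cost[root, ])

  ## down pass: D[v, s] = min cost of the rest of the tree given v = s
  D <- matrix(Inf, nnode, S)
  D[root, ] <- 0
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    rest <- D[par, ] + cost[par, ] - contrib[e, ]
    m <- min(rest)
    D[ch, ] <- pmin(rest, m + 1)
  }
  sets <- lapply(seq_len(nnode), function(v)
    .PARS_ALPHABET[D[v, ] + cost[v, ] == score])
  names(sets) <- c(tips, paste0("node", seq_len(tree$Nnode) + ntip))
  list(score = as.integer(score), sets = sets, root = root)
}

#' Per-site parsimony reconstruction table
#'
#' Applies the gap-column filter, then [fitchStates()] per retained site.
#'
#' @param tree A rooted `ape::phylo`.
#' @param tip_states Character matrix, sites x species.
#' @return `data.frame`: `site_id`, `score`, `root_states` (states of the
#'   root MPR set joined with `|`).
#' @export
parsimonyTable <- function(tree, tip_states) {
  kept <- filterGapColumns(tip_states)
  rows <- lapply(rownames(kept), function(sid) {
    fs <- fitchStates(tree, kept[sid, ])
    data.frame(site_id = sid, score = fs$score,
               root_states = paste(fs$sets[[fs$root]], collapse = "|"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(), score = integer(),
               root_states = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
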