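# Irreversible-gain (Dollo) counting on binary characters, and the
# vertical-inheritance loss count that the transfer scenarios compete against.

#' Minimum gains of an irreversible binary character
#'
#' For a character that, once gained, is never reversed (the model used here
#' for the pufL+pufM gene fusion), the minimum number of independent 0->1
#' gains on a rooted tree equals the number of maximal subtrees whose leaves
#' all carry the derived state.
#'
#' @param tree A rooted `phylo` object.
#' @param states Named vector (0/1, logical, or "0"/"1") with one entry per
#'   leaf of `tree`.
#' @return List with `count` (minimum number of gains) and `gain_branches`
#'   (character labels of the branches on which the gains are placed).
#' @examples
#' t <- parse_newick("((A,B),(C,D));")
#' dollo_gains(t, c(A = 1, B = 0, C = 0, D = 1))$count # 2
#' @export
dollo_gains <- function(tree, states) {
  stopifnot(inherits(tree, "phylo"))
  states <- ph_check_states(states, tree$tip.label)
  rt <- ph_rtree(tree)
  ones <- ph_mask_of(rt, names(states)[states == 1L])
  if (ones == 0L) return(list(count = 0L, gain_branches = character(0)))
  all1 <- bitwAnd(rt$mask, ones) == rt$mask
  maximal <- vapply(seq_len(rt$nnode), function(v) {
    all1[v] && (v == rt$root || !all1[rt$parent[v]])
  }, logical(1))
  nodes <- which(maximal)
  list(
    count = length(nodes),
    gain_branches = vapply(nodes, function(v) ph_branch_label(rt, v), character(1))
  )
}

ph_check_states <- function(states, tips) {
  if (is.logical(states)) states <- as.integer(states)
  if (is.character(states)) states <- as.integer(states)
  if (!is.numeric(states) || is.null(names(states))) {
    ph_stop("input_error", "states must be a named 0/1 vector")
  }
  missing <- setdiff(tips, names(states))
  if (length(missing)) {
    ph_stop("input_error", sprintf("states missing for leaf (leaves): %s",
                                   paste(missing, collapse = ", ")))
  }
  states <- as.integer(states[tips])
  if (anyNA(states) || !all(states %in% c(0L, 1L))) {
    ph_stop("input_error", "states must be 0 or 1 for every leaf")
  }
  stats::setNames(states, tips)
}

#' Minimum losses under single-origin vertical inheritance
#'
#' The competing hypothesis to horizontal transfer: the gene originates once
#' at the most recent common ancestor of the present leaves and descends
#' vertically, so every present/absent pattern must be explained by losses.
#' The minimum equals the number of maximal gene-free subtrees under that
#' ancestor.
#'
#' @param species_tree A rooted `phylo` object.
#' @param present Non-empty character vector of leaves carrying the gene.
#' @return List with `count`, `origin_branch` (label of the origin branch)
#'   and `loss_branches` (labels of the pruned subtree stems).
#' @examples
#' s <- parse_newick("(((A,B),C),D);")
#' min_vertical_losses(s, c("A", "D"))$count # 2
#' @export
min_vertical_losses <- function(species_tree, present) {
  stopifnot(inherits(species_tree, "phylo"))
  present <- unique(as.character(present))
  if (length(present) == 0L) ph_stop("input_error", "present must be non-empty")
  rt <- ph_rtree(species_tree)
  pmask <- ph_mask_of(rt, present)
  origin <- ph_mrca_node(rt, pmask)
  losses <- ph_count_losses(rt, origin, pmask)
  list(
    count = losses$count,
    origin_branch = ph_branch_label(rt, origin),
    loss_branches = vapply(losses$nodes, function(v) ph_branch_label(rt, v), character(1))
  )
}
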