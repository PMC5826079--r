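# Internal rooted-tree representation for the reconciliation search.
#
# Leaf sets are encoded as integer bitmasks (one bit per species-tree leaf),
# which caps supported trees at 30 leaves -- ample for the pathway-subset
# comparisons this package targets and orders of magnitude below where the
# exact search would be feasible anyway.

PH_MAX_LEAVES <- 30L

# Build the internal structure from an ape phylo. `tip_index` optionally maps
# tip labels to bit positions of an enclosing (species) tree so that gene-tree
# clades share the species bit space.
ph_rtree <- function(phy, tip_index = NULL) {
  stopifnot(inherits(phy, "phylo"))
  ntip <- length(phy$tip.label)
  if (is.null(tip_index)) {
    if (ntip > PH_MAX_LEAVES) {
      ph_stop("input_error", sprintf(
        "trees with more than %d leaves are not supported by the event search",
        PH_MAX_LEAVES))
    }
    tip_index <- stats::setNames(seq_len(ntip), phy$tip.label)
  } else {
    missing <- setdiff(phy$tip.label, names(tip_index))
    if (length(missing)) {
      ph_stop("input_error", sprintf("leaf (leaves) absent from species tree: %s",
                                     paste(missing, collapse = ", ")))
    }
  }
  nn <- ntip + phy$Nnode
  children <- vector("list", nn)
  parent <- integer(nn)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    children[[p]] <- c(children[[p]], ch)
    parent[ch] <- p
  }
  mask <- integer(nn)
  for (i in seq_len(ntip)) {
    mask[i] <- bitwShiftL(1L, tip_index[[phy$tip.label[i]]] - 1L)
  }
  for (e in ape::postorder(phy)) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    mask[p] <- bitwOr(mask[p], mask[ch])
  }
  nleaf <- vapply(mask, ph_popcount, integer(1))
  list(
    phy = phy, ntip = ntip, nnode = nn, root = ntip + 1L,
    children = children, parent = parent,
    mask = mask, nleaf = nleaf,
    tip_labels = phy$tip.label, tip_index = tip_index
  )
}

ph_popcount <- function(x) sum(as.integer(intToBits(x)))

ph_mask_of <- function(rt, leaves) {
  idx <- rt$tip_index[leaves]
  if (anyNA(idx)) {
    ph_stop("input_error", sprintf("unknown leaf label(s): %s",
      paste(leaves[is.na(idx)], collapse = ", ")))
  }
  Reduce(bitwOr, bitwShiftL(1L, as.integer(idx) - 1L), 0L)
}

ph_mask_leaves <- function(rt, mask) {
  pos <- which(as.logical(intToBits(mask)))
  names(sort(rt$tip_index[rt$tip_index %in% pos]))
}

# a subset of b (as leaf-set masks)?
ph_subset <- function(a, b) bitwAnd(a, b) == a

# Node whose clade is the smallest superset of `mask` (MRCA if mask spans
# several leaves; the tip itself for singletons).
ph_mrca_node <- function(rt, mask) {
  cand <- which(bitwAnd(rt$mask, mask) == mask)
  cand[which.min(rt$nleaf[cand])]
}

# Human-readable branch label: tip name for pendant edges, else the clade's
# leaf list (abbreviated beyond 4 names).
ph_branch_label <- function(rt, node) {
  leaves <- sort(ph_mask_leaves(rt, rt$mask[node]))
  if (length(leaves) == 1L) return(leaves)
  if (length(leaves) <= 4L) {
    sprintf("branch_to{%s}", paste(leaves, collapse = ","))
  } else {
    sprintf("branch_to{%s,...+%d}", paste(leaves[1:3], collapse = ","),
            length(leaves) - 3L)
  }
}

# Clade masks of the induced (suppressed) topology on the leaves in `m`,
# within the subtree rooted at `v`. Includes singletons and the full set.
ph_induced_clades <- function(rt, v, m) {
  sub <- which(bitwAnd(rt$mask, rt$mask[v]) == rt$mask)
  cl <- bitwAnd(rt$mask[sub], m)
  unique(cl[cl != 0L])
}

# Count maximal surviving-copy-free subtrees ("loss events") below node v,
# ignoring the excluded region `dead_space` (leaf mask of nested blocks whose
# copies were replaced by later transfers). Returns list(count, nodes).
ph_count_losses <- function(rt, v, surv, dead_space = 0L) {
  loss_nodes <- integer(0)
  rec <- function(u) {
    mu <- rt$mask[u]
    if (bitwAnd(mu, bitwNot(dead_space)) == 0L) return(NA) # fully excluded
    if (bitwAnd(mu, surv) == 0L) return(FALSE)             # absent region
    kids <- rt$children[[u]]
    if (length(kids) == 0L) return(TRUE)                   # surviving leaf
    for (k in kids) {
      res <- rec(k)
      if (identical(res, FALSE)) loss_nodes <<- c(loss_nodes, k)
    }
    TRUE
  }
  top <- rec(v)
  if (identical(top, FALSE)) {
    # no survivor at all below v: one loss spanning the whole block
    return(list(count = 1L, nodes = v))
  }
  list(count = length(loss_nodes), nodes = loss_nodes)
}
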