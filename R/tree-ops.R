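# Newick I/O and topology utilities: the substrate for congruence tests
# between organismal and pathway gene trees. Trees are ape "phylo" objects.

#' Parse a newick string into a rooted tree
#'
#' Wraps [ape::read.tree()] with validation: balanced parentheses (reported
#' with the character position of the first imbalance), unique leaf labels,
#' non-negative branch lengths. Quoted labels and absent branch lengths are
#' supported.
#'
#' @param text A single newick string (trailing `;` optional).
#' @return An [ape::read.tree()] `phylo` object.
#' @examples
#' parse_newick("((A,B),C);")
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    ph_stop("parse_error", "text must be a single newick string")
  }
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        ph_stop("parse_error", sprintf("unbalanced ')' at position %d", i))
      }
    }
  }
  if (depth != 0L) {
    ph_stop("parse_error", sprintf(
      "unbalanced parentheses: %d '(' left open at end of string", depth))
  }
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    ph_stop("parse_error", "malformed newick string")
  }
  tree$tip.label <- gsub("^'(.*)'$", "\\1", tree$tip.label)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) {
    ph_stop("parse_error", sprintf("duplicate leaf label(s): %s",
                                   paste(unique(dup), collapse = ", ")))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE)) {
    ph_stop("parse_error", "negative branch length")
  }
  tree
}

#' Serialize a tree to a newick string
#'
#' `parse_newick(serialize_newick(t))` reproduces the topology; on
#' canonicalized strings the round trip is the identity.
#'
#' @param tree A `phylo` object.
#' @return A single newick string terminated by `;`.
#' @export
serialize_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Restrict a tree to a subset of leaves
#'
#' Induced topology on `keep`: pruned leaves are removed, degree-2 internal
#' nodes are suppressed, and branch lengths (if any) are summed across
#' suppressed nodes.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of leaf labels to retain, `|keep| >= 2`.
#' @return The induced `phylo` tree.
#' @examples
#' restrict_to_leaves(parse_newick("((A,B),(C,D));"), c("A", "C", "D"))
#' @export
restrict_to_leaves <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    ph_stop("input_error", sprintf("unknown leaf label(s): %s",
                                   paste(unknown, collapse = ", ")))
  }
  if (length(keep) < 2L) ph_stop("input_error", "keep must contain at least 2 leaves")
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

# Non-trivial bipartitions of an unrooted topology, canonicalized so each
# split is named by the side not containing the alphabetically first leaf.
ph_bipartitions <- function(tree) {
  labs <- sort(tree$tip.label)
  anchor <- labs[1L]
  ntip <- length(tree$tip.label)
  desc <- ph_clade_leafsets(tree)
  splits <- character(0)
  for (s in desc) {
    side <- if (anchor %in% s) setdiff(labs, s) else s
    if (length(side) >= 2L && length(side) <= ntip - 2L) {
      splits <- c(splits, paste(sort(side), collapse = "\r"))
    }
  }
  unique(splits)
}

# Leaf set below every internal node (excluding the root's full set is kept;
# harmless for split purposes).
ph_clade_leafsets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) { # children accumulated before parents
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    sets[[par]] <- c(sets[[par]], sets[[child]])
  }
  lapply(sets[(ntip + 1L):(ntip + nnode)], sort)
}

#' Robinson-Foulds distance between two trees on the same leaves
#'
#' Symmetric-difference count of non-trivial bipartitions (unrooted sense);
#' zero iff the unrooted topologies are identical. Multifurcations are
#' treated as soft polytomies.
#'
#' @param t1,t2 `phylo` objects on identical leaf sets.
#' @return Non-negative integer count.
#' @examples
#' rf_distance(parse_newick("((A,B),(C,D));"), parse_newick("((A,C),(B,D));")) # 2
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label)) {
    ph_stop("input_error", sprintf(
      "leaf sets differ (only in t1: %s; only in t2: %s)",
      paste(setdiff(t1$tip.label, t2$tip.label), collapse = ",") ,
      paste(setdiff(t2$tip.label, t1$tip.label), collapse = ",")))
  }
  b1 <- ph_bipartitions(t1)
  b2 <- ph_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Test whether a leaf group is monophyletic (rooted sense)
#'
#' TRUE iff some clade of the rooted tree contains exactly `group`.
#' Singletons are trivially monophyletic.
#'
#' @param tree A rooted `phylo` object.
#' @param group Non-empty character vector of leaf labels.
#' @return Logical.
#' @examples
#' is_monophyletic(parse_newick("((A,B),(C,D));"), c("A", "D")) # FALSE
#' @export
is_monophyletic <- function(tree, group) {
  stopifnot(inherits(tree, "phylo"))
  group <- unique(as.character(group))
  if (length(group) == 0L) ph_stop("input_error", "group must be non-empty")
  unknown <- setdiff(group, tree$tip.label)
  if (length(unknown)) {
    ph_stop("input_error", sprintf("unknown leaf label(s): %s",
                                   paste(unknown, collapse = ", ")))
  }
  if (length(group) == 1L) return(TRUE)
  if (setequal(group, tree$tip.label)) return(TRUE)
  key <- paste(sort(group), collapse = "\r")
  any(vapply(ph_clade_leafsets(tree),
             function(s) paste(s, collapse = "\r") == key, logical(1)))
}
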