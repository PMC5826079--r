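# Independent oracles. These deliberately avoid the package's internal
# machinery (bitmask trees, peeling): trees are nested lists, sets are
# character vectors, and minima are found by naive enumeration.

## ---- hypergeometric: subset enumeration ----------------------------------

# P(x of the r marked genes land in the n sampled) by enumerating every
# C(T, r) placement of the marked genes. Feasible for T <= 12.
oracle_hyper <- function(T, n, r, x) {
  placements <- utils::combn(T, r)
  hits <- colSums(placements <= n) # genes 1..n are the sampled ones
  mean(hits == x)
}

## ---- Dollo gains: brute force over internal states -----------------------

# Minimum 0->1 gains with no reversals, enumerating all internal-node state
# assignments. Tree given as ape phylo.
oracle_dollo_gains <- function(phy, states) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  leaf_state <- as.integer(states[phy$tip.label])
  internals <- (ntip + 1L):nn
  best <- Inf
  grid <- expand.grid(rep(list(0:1), length(internals)))
  for (gi in seq_len(nrow(grid))) {
    st <- integer(nn)
    st[seq_len(ntip)] <- leaf_state
    st[internals] <- as.integer(grid[gi, ])
    ok <- TRUE
    gains <- st[ntip + 1L] # gain on the root stem if root is derived
    for (e in seq_len(nrow(phy$edge))) {
      p <- st[phy$edge[e, 1]]; ch <- st[phy$edge[e, 2]]
      if (p == 1L && ch == 0L) { ok <- FALSE; break } # reversal forbidden
      if (p == 0L && ch == 1L) gains <- gains + 1L
    }
    if (ok) best <- min(best, gains)
  }
  best
}

## ---- nested-list trees for the reconciliation oracle ---------------------

or_from_phylo <- function(phy) {
  ntip <- length(phy$tip.label)
  kids <- vector("list", ntip + phy$Nnode)
  for (e in seq_len(nrow(phy$edge))) {
    kids[[phy$edge[e, 1]]] <- c(kids[[phy$edge[e, 1]]], phy$edge[e, 2])
  }
  rec <- function(v) {
    if (v <= ntip) return(phy$tip.label[v])
    lapply(kids[[v]], rec)
  }
  rec(ntip + 1L)
}

or_leaves <- function(t) if (is.character(t)) t else unlist(lapply(t, or_leaves))

or_canon <- function(t) {
  if (is.character(t)) return(t)
  paste0("(", paste(sort(vapply(t, or_canon, character(1))), collapse = ","), ")")
}

# every subtree (including leaves and the whole tree)
or_subtrees <- function(t) {
  out <- list(t)
  if (!is.character(t)) for (ch in t) out <- c(out, or_subtrees(ch))
  out
}

# induced topology on `keep`; NULL when empty
or_restrict <- function(t, keep) {
  if (is.character(t)) return(if (t %in% keep) t else NULL)
  kept <- Filter(Negate(is.null), lapply(t, or_restrict, keep = keep))
  if (length(kept) == 0L) return(NULL)
  if (length(kept) == 1L) return(kept[[1L]])
  kept
}

# drop every subtree whose leaf set exactly matches one of `cut_sets`
or_cut <- function(t, cut_sets) {
  for (cs in cut_sets) if (setequal(or_leaves(t), cs)) return(NULL)
  if (is.character(t)) return(t)
  kept <- Filter(Negate(is.null), lapply(t, or_cut, cut_sets = cut_sets))
  if (length(kept) == 0L) return(NULL)
  if (length(kept) == 1L) return(kept[[1L]])
  kept
}

# number of maximal subtrees of t containing no survivor
or_losses <- function(t, survivors) {
  n <- 0L
  has <- function(u) {
    lv <- or_leaves(u)
    if (!any(lv %in% survivors)) return(FALSE)
    if (!is.character(u)) {
      for (ch in u) if (!has(ch)) n <<- n + 1L
    }
    TRUE
  }
  if (!has(t)) 1L else n
}

# all trees obtained by attaching `graft` as sister to some subtree of t
or_attach_everywhere <- function(t, graft) {
  out <- list(list(t, graft))
  if (!is.character(t)) {
    for (i in seq_along(t)) {
      for (sub in or_attach_everywhere(t[[i]], graft)) {
        t2 <- t
        t2[[i]] <- sub
        out <- c(out, list(t2))
      }
    }
  }
  out
}

# Naive minimum-event reconciliation: enumerate origin subtree + recipient
# subtree sets (<= kmax transfers), claim leaves by the innermost block,
# count losses per block, and try every attachment order/position of the
# recipient block trees, comparing against the observed gene tree.
# Returns list(cost, transfers, losses) or NULL when nothing is found.
oracle_reconcile <- function(species_phy, gene_phy, present = NULL, kmax = 2L) {
  S <- or_from_phylo(species_phy)
  G <- or_from_phylo(gene_phy)
  if (is.null(present)) present <- or_leaves(G)
  target <- or_canon(G)
  subtrees <- or_subtrees(S)
  keys <- vapply(subtrees, function(s) paste(sort(or_leaves(s)), collapse = ","), character(1))
  subtrees <- subtrees[!duplicated(keys)]
  best <- NULL
  for (k in 0:kmax) {
    combos <- if (k == 0L) list(integer(0)) else
      asplit(utils::combn(length(subtrees), k), 2L)
    for (oi in seq_along(subtrees)) {
      for (ris in combos) {
        if (oi %in% ris) next
        blocks <- c(list(subtrees[[oi]]), subtrees[ris])
        bl_leaves <- lapply(blocks, or_leaves)
        if (!all(present %in% unique(unlist(bl_leaves)))) next
        claimed <- vector("list", length(blocks))
        ok <- TRUE
        for (i in seq_along(blocks)) {
          inner <- unlist(bl_leaves[vapply(seq_along(blocks), function(j) {
            j != i && !setequal(bl_leaves[[j]], bl_leaves[[i]]) &&
              all(bl_leaves[[j]] %in% bl_leaves[[i]])
          }, logical(1))])
          claimed[[i]] <- setdiff(intersect(bl_leaves[[i]], present), inner)
          if (length(claimed[[i]]) == 0L) { ok <- FALSE; break }
        }
        if (!ok) next
        if (anyDuplicated(vapply(bl_leaves, function(l) paste(sort(l), collapse = ","),
                                 character(1)))) next
        losses <- 0L
        btrees <- vector("list", length(blocks))
        for (i in seq_along(blocks)) {
          nested <- bl_leaves[vapply(seq_along(blocks), function(j) {
            j != i && !setequal(bl_leaves[[j]], bl_leaves[[i]]) &&
              all(bl_leaves[[j]] %in% bl_leaves[[i]])
          }, logical(1))]
          domain <- if (length(nested)) or_cut(blocks[[i]], nested) else blocks[[i]]
          if (is.null(domain)) { ok <- FALSE; break }
          losses <- losses + or_losses(domain, claimed[[i]])
          btrees[[i]] <- or_restrict(blocks[[i]], claimed[[i]])
        }
        if (!ok) next
        cost <- k + losses
        if (!is.null(best) && cost > best$cost) next
        # try every attachment order and position of the recipient blocks
        found <- FALSE
        if (k == 0L) {
          found <- identical(or_canon(btrees[[1L]]), target)
        } else {
          perms <- if (k == 1L) list(2L) else
            lapply(asplit(gtools_permutations(k), 1L), function(p) p + 1L)
          for (perm in perms) {
            trees_now <- list(btrees[[1L]])
            for (bi in perm) {
              nxt <- list()
              for (tn in trees_now) {
                nxt <- c(nxt, or_attach_everywhere(tn, btrees[[bi]]))
              }
              trees_now <- nxt
            }
            if (any(vapply(trees_now, function(tn) identical(or_canon(tn), target),
                           logical(1)))) { found <- TRUE; break }
          }
        }
        if (found && (is.null(best) || cost < best$cost ||
                      (cost == best$cost && k < best$transfers))) {
          best <- list(cost = cost, transfers = k, losses = losses)
        }
      }
    }
    if (!is.null(best) && best$cost <= k) break # deeper k cannot beat it
  }
  best
}

# tiny permutations helper (avoid extra deps)
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- gtools_permutations(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow = nrow(sub))))
  }
  unname(out)
}

## ---- shared fixtures ------------------------------------------------------

fx <- photoHGT::chloroflexi_fixtures()

rc6 <- fx$gene_sets[["phototrophy_rc6"]]
bch5 <- fx$gene_sets[["bch_synthesis5"]]

fixture_bin <- function(id) {
  b <- fx$bin_quality[fx$bin_quality$bin_id == id, , drop = FALSE]
  class(b) <- c("bin_quality", "data.frame")
  b
}

metagenome_bins <- function() {
  b <- fx$bin_quality[fx$bin_quality$bin_id %in% fx$metagenome_bins, , drop = FALSE]
  class(b) <- c("bin_quality", "data.frame")
  b
}

# write a BLAST outfmt-6 file; rows = list of character vectors
write_hits_file <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

hit_row <- function(marker = "pufL", contig = "c1", len = 260, evalue = 1e-30,
                    pident = 70, bitscore = 300, slen = NULL) {
  r <- c(marker, contig, pident, len, 10, 1, 1, len, 1, len, evalue, bitscore)
  if (!is.null(slen)) r <- c(r, slen)
  as.character(r)
}
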