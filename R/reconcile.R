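# Minimum-event reconciliation of a pathway gene tree against a rooted
# organismal tree.
#
# Event model. A scenario consists of a single origin on a species branch
# plus k transfers, each copying the gene lineage from a branch of the
# observed gene tree onto a recipient species branch; copies then descend
# vertically and may be lost. A transfer into a lineage that already carries
# the gene is xenologous replacement: the resident copy is overwritten and no
# separate loss is charged. Losses are counted as maximal subtrees that carry
# no surviving copy within each vertically inherited block. The fusion
# character evolves irreversibly on the gene tree itself (Dollo gains), so a
# fused gene stays fused through a transfer.
#
# Search. Every scenario is equivalent to a choice of origin branch plus a
# set of recipient branches: the present leaves are claimed by the innermost
# covering block, each block contributes its induced species topology, and
# validity is decided by peeling blocks off the observed gene tree (a block
# is removable when its claimed leaves form a gene-tree clade with matching
# internal topology). The search is exact: iterative deepening on the
# transfer count with a cost bound, feasible because pathway leaf subsets
# are small.

#' Event costs for the reconciliation search
#'
#' Unit costs by default; the origin is mandatory and free, matching the
#' convention that the initial acquisition is not tallied as a transfer.
#'
#' @param transfer_cost,loss_cost,fusion_cost Positive reals.
#' @return An object of class `event_costs`.
#' @export
event_costs <- function(transfer_cost = 1, loss_cost = 1, fusion_cost = 1) {
  for (v in c(transfer_cost, loss_cost, fusion_cost)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      ph_stop("input_error", "all event costs must be positive numbers")
    }
  }
  structure(list(transfer = transfer_cost, loss = loss_cost, fusion = fusion_cost),
            class = "event_costs")
}

#' Minimum-event transfer/loss reconciliation
#'
#' Finds all minimum-cost event scenarios (single origin, lateral transfers,
#' losses, irreversible fusion gains) under which the surviving gene copies'
#' branching order equals the observed gene tree. The search is exact within
#' `max_transfers`; scenarios are returned up to `scenario_cap`, sorted by
#' (transfers, losses, event list).
#'
#' @param species_tree Rooted `phylo` organismal tree.
#' @param gene_tree Rooted `phylo` gene tree; its leaves are the `present`
#'   set and must all appear in `species_tree`.
#' @param present Optional character vector of gene-bearing leaves; defaults
#'   to the gene-tree leaves and must equal them.
#' @param fusion_states Optional named 0/1 vector over gene-tree leaves for
#'   the fusion character (see [dollo_gains()]).
#' @param costs An [event_costs()] object.
#' @param max_transfers Bound on the transfer count explored (default 4).
#' @param scenario_cap Maximum number of co-optimal scenarios listed
#'   (default 25).
#' @return An object of class `hgt_reconciliation`: list with
#'   `min_cost`, `min_transfers`, `min_losses`, `min_fusions`,
#'   `fusion_gain_branches`, `scenarios` (each with `origin_branch`,
#'   `transfers` data frame, `losses`, counts and `total_cost`),
#'   `n_optimal_found`, `capped`.
#' @examples
#' s <- parse_newick("(((A,B),C),D);")
#' g <- parse_newick("(A,D);")
#' rec <- min_event_reconciliation(s, g)
#' rec$min_transfers # 1
#' @export
min_event_reconciliation <- function(species_tree, gene_tree, present = NULL,
                                     fusion_states = NULL,
                                     costs = event_costs(),
                                     max_transfers = 4L, scenario_cap = 25L) {
  stopifnot(inherits(species_tree, "phylo"), inherits(gene_tree, "phylo"),
            inherits(costs, "event_costs"))
  if (!is_count(max_transfers)) ph_stop("input_error", "max_transfers must be a count")
  gl <- gene_tree$tip.label
  if (is.null(present)) present <- gl
  if (!setequal(present, gl)) {
    ph_stop("input_error", "gene tree leaves must equal the present set")
  }
  missing <- setdiff(gl, species_tree$tip.label)
  if (length(missing)) {
    ph_stop("input_error", sprintf("gene leaf (leaves) missing from species tree: %s",
                                   paste(missing, collapse = ", ")))
  }
  if (length(gl) < 2L) ph_stop("input_error", "need at least 2 present leaves")

  S <- ph_rtree(species_tree)
  G <- ph_rtree(gene_tree, tip_index = S$tip_index)
  pmask <- ph_mask_of(S, gl)
  gclades <- unique(G$mask)

  fus <- if (is.null(fusion_states)) {
    list(count = 0L, gain_branches = character(0))
  } else {
    dollo_gains(gene_tree, fusion_states)
  }
  fus_cost <- fus$count * costs$fusion

  eligible <- which(bitwAnd(S$mask, pmask) != 0L)
  best <- Inf
  cands <- list() # each: list(cost, k, losses, scenarios = list)

  for (k in 0:max_transfers) {
    if (is.finite(best) && k * costs$transfer + fus_cost > best) break
    for (o in eligible) {
      others <- setdiff(eligible, o)
      if (k > length(others)) next
      sets <- if (k == 0L) {
        matrix(integer(0), nrow = 0L, ncol = 1L)
      } else {
        utils::combn(others, k)
      }
      # coverage filter: union of block leaf sets must contain all present
      if (k > 0L) {
        un <- rep(S$mask[o], ncol(sets))
        for (row in seq_len(k)) un <- bitwOr(un, S$mask[sets[row, ]])
        sets <- sets[, bitwAnd(pmask, un) == pmask, drop = FALSE]
      } else if (bitwAnd(pmask, S$mask[o]) != pmask) {
        next
      }
      ncomb <- if (k == 0L) 1L else ncol(sets)
      if (k > 0L && ncomb == 0L) next
      for (ci in seq_len(ncomb)) {
        blocks <- c(o, if (k > 0L) sets[, ci])
        ev <- ph_eval_blocks(S, blocks, pmask, gclades, costs, k, fus_cost, best)
        if (is.null(ev)) next
        if (ev$cost < best) {
          best <- ev$cost
          cands <- cands[vapply(cands, function(c) c$cost <= best, logical(1))]
        }
        cands[[length(cands) + 1L]] <- ev
      }
    }
  }

  cands <- cands[vapply(cands, function(c) c$cost <= best, logical(1))]
  if (!length(cands)) {
    ph_stop("bounded_search_error", sprintf(
      "no scenario found within %d transfers; raise max_transfers", max_transfers))
  }

  scenarios <- list()
  seen <- character(0)
  for (cand in cands) {
    for (sc in cand$scenarios) {
      if (sc$key %in% seen) next
      seen <- c(seen, sc$key)
      sc$n_fusions <- fus$count
      sc$fusion_gains <- fus$gain_branches
      sc$total_cost <- cand$cost
      scenarios[[length(scenarios) + 1L]] <- sc
    }
  }
  ord <- order(
    vapply(scenarios, function(s) s$n_transfers, integer(1)),
    vapply(scenarios, function(s) s$n_losses, integer(1)),
    vapply(scenarios, function(s) s$key, character(1))
  )
  scenarios <- scenarios[ord]
  n_found <- length(scenarios)
  capped <- n_found > scenario_cap
  if (capped) scenarios <- scenarios[seq_len(scenario_cap)]

  structure(list(
    min_cost = best,
    min_transfers = min(vapply(scenarios, function(s) s$n_transfers, integer(1))),
    min_losses = min(vapply(scenarios, function(s) s$n_losses, integer(1))),
    min_fusions = fus$count,
    fusion_gain_branches = fus$gain_branches,
    scenarios = scenarios,
    n_optimal_found = n_found,
    capped = capped,
    costs = costs,
    max_transfers = as.integer(max_transfers)
  ), class = "hgt_reconciliation")
}

# Evaluate one (origin, recipients) block choice: claims, losses, cost bound,
# then gene-tree validity by peeling. Returns NULL if invalid or beaten.
ph_eval_blocks <- function(S, blocks, pmask, gclades, costs, k, fus_cost, best) {
  nb <- length(blocks)
  bm <- S$mask[blocks]
  # innermost-claim rule
  claimed <- integer(nb)
  dead <- integer(nb)
  for (i in seq_len(nb)) {
    nested <- 0L
    for (j in seq_len(nb)) {
      if (j != i && bm[j] != bm[i] && ph_subset(bm[j], bm[i])) {
        nested <- bitwOr(nested, bm[j])
      }
    }
    dead[i] <- nested
    claimed[i] <- bitwAnd(bitwAnd(bm[i], pmask), bitwNot(nested))
    if (claimed[i] == 0L) return(NULL)
  }
  if (anyDuplicated(bm)) return(NULL)
  loss_info <- vector("list", nb)
  n_losses <- 0L
  for (i in seq_len(nb)) {
    loss_info[[i]] <- ph_count_losses(S, blocks[i], claimed[i], dead[i])
    n_losses <- n_losses + loss_info[[i]]$count
  }
  cost <- k * costs$transfer + n_losses * costs$loss + fus_cost
  if (cost > best) return(NULL)

  orders <- ph_peel_orders(S, blocks, claimed, gclades)
  if (!length(orders)) return(NULL)

  loss_nodes <- unlist(lapply(loss_info, function(l) l$nodes))
  loss_labels <- sort(vapply(loss_nodes, function(v) ph_branch_label(S, v), character(1)))
  scenarios <- lapply(orders, function(ord) {
    ph_scenario_from_order(S, blocks, claimed, gclades, ord, k, n_losses, loss_labels)
  })
  list(cost = cost, k = k, losses = n_losses, scenarios = scenarios)
}

# All valid peel orders (sequences of non-origin block indices; origin = 1
# must be the final remaining block). Each order is a vector of block
# indices in peel sequence (reverse attachment order).
ph_peel_orders <- function(S, blocks, claimed, gclades) {
  nb <- length(blocks)
  results <- list()
  recurse <- function(gc, remaining, order_so_far) {
    if (length(remaining) == 1L) {
      if (remaining != 1L) return()
      ind <- ph_induced_clades(S, blocks[1L], claimed[1L])
      if (setequal(gc, ind)) results[[length(results) + 1L]] <<- order_so_far
      return()
    }
    for (i in setdiff(remaining, 1L)) {
      b <- claimed[i]
      if (!(b %in% gc)) next
      sub <- gc[bitwAnd(gc, b) == gc]
      ind <- ph_induced_clades(S, blocks[i], claimed[i])
      if (!setequal(sub, ind)) next
      keep <- gc[bitwAnd(gc, b) != gc]
      gc2 <- unique(bitwAnd(keep, bitwNot(b)))
      gc2 <- gc2[gc2 != 0L]
      recurse(gc2, setdiff(remaining, i), c(order_so_far, i))
    }
  }
  recurse(gclades, seq_len(nb), integer(0))
  results
}

# Replay one peel order to derive donor branches and build the scenario
# record. Attachment order = origin, then reverse peel order.
ph_scenario_from_order <- function(S, blocks, claimed, gclades, ord, k,
                                   n_losses, loss_labels) {
  nb <- length(blocks)
  attach_rank <- integer(nb)
  attach_rank[1L] <- 1L
  if (length(ord)) attach_rank[rev(ord)] <- seq_along(ord) + 1L

  donors <- character(0)
  recips <- character(0)
  gc <- gclades
  for (i in ord) {
    b <- claimed[i]
    sup <- gc[bitwAnd(gc, b) == b & gc != b]
    parent <- sup[which.min(vapply(sup, ph_popcount, integer(1)))]
    sib <- bitwAnd(parent, bitwNot(b))
    # stem lineage of the sibling clade belongs to the earliest-attached block
    inter <- which(bitwAnd(claimed, sib) != 0L)
    donor_block <- inter[which.min(attach_rank[inter])]
    donor_mask <- bitwAnd(sib, claimed[donor_block])
    donor_node <- ph_mrca_node(S, donor_mask)
    donors <- c(donors, ph_branch_label(S, donor_node))
    recips <- c(recips, ph_branch_label(S, blocks[i]))
    keep <- gc[bitwAnd(gc, b) != gc]
    gc <- unique(bitwAnd(keep, bitwNot(b)))
    gc <- gc[gc != 0L]
  }
  # report transfers in attachment (chronological) order
  if (length(ord)) {
    donors <- rev(donors); recips <- rev(recips)
  }
  transfers <- data.frame(donor = donors, recipient = recips,
                          stringsAsFactors = FALSE)
  origin_label <- ph_branch_label(S, blocks[1L])
  key <- paste(origin_label,
               paste(sort(paste(transfers$donor, transfers$recipient, sep = " -> ")),
                     collapse = "; "),
               sep = " | ")
  list(
    origin_branch = origin_label,
    transfers = transfers,
    losses = loss_labels,
    n_transfers = as.integer(k),
    n_losses = as.integer(n_losses),
    key = key
  )
}

#' @export
print.hgt_reconciliation <- function(x, ...) {
  cat(sprintf(
    "<hgt_reconciliation> min cost %.3g: %d transfer(s), %d loss(es), %d fusion gain(s)\n",
    x$min_cost, x$min_transfers, x$min_losses, x$min_fusions))
  cat(sprintf("  %d co-optimal scenario(s)%s\n", x$n_optimal_found,
              if (x$capped) sprintf(" (showing %d)", length(x$scenarios)) else ""))
  invisible(x)
}

#' Render a reconciliation as a human-readable narrative
#'
#' Deterministic listing of each optimal scenario's events in chronological
#' order (origin, transfers, losses, fusion gains).
#'
#' @param rec An `hgt_reconciliation` object.
#' @param names Optional named character vector renaming leaves in branch
#'   labels (`c(old = "new")`).
#' @return Character vector of report lines (invisibly printable via `cat`).
#' @export
scenario_narrative <- function(rec, names = NULL) {
  stopifnot(inherits(rec, "hgt_reconciliation"))
  if (!length(rec$scenarios)) ph_stop("input_error", "empty scenario list")
  rename <- function(x) {
    if (is.null(names)) return(x)
    for (old in base::names(names)) x <- gsub(old, names[[old]], x, fixed = TRUE)
    x
  }
  out <- c(sprintf(
    "Minimum-event reconciliation: cost %.3g (%d transfer(s), %d loss(es), %d fusion gain(s))",
    rec$min_cost, rec$min_transfers, rec$min_losses, rec$min_fusions))
  for (i in seq_along(rec$scenarios)) {
    sc <- rec$scenarios[[i]]
    out <- c(out, sprintf("Scenario %d:", i),
             sprintf("  origin on %s", rename(sc$origin_branch)))
    if (nrow(sc$transfers) == 0L) {
      out <- c(out, "  no transfers")
    } else {
      for (j in seq_len(nrow(sc$transfers))) {
        out <- c(out, sprintf("  transfer from %s into %s",
                              rename(sc$transfers$donor[j]),
                              rename(sc$transfers$recipient[j])))
      }
    }
    if (length(sc$losses)) {
      out <- c(out, sprintf("  loss on %s", rename(sc$losses)))
    }
    if (sc$n_fusions > 0L) {
      out <- c(out, sprintf("  fusion gain on gene-tree %s", rename(sc$fusion_gains)))
    }
  }
  out
}
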