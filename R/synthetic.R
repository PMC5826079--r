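# Seeded generators producing inputs with the statistical structure the
# analysis assumes: uniform gene subsampling of a genome at a given
# completeness, contaminant admixture, Yule topologies, and gene-tree
# histories with planted lateral transfers.
#
# Every generator takes an explicit seed and restores the caller's RNG
# state; results are bit-reproducible for fixed (seed, parameters).

#' Simulate recovery of a genome bin by uniform gene subsampling
#'
#' Draws `n` of `T_genes` genes uniformly without replacement (the sampling
#' model behind [prob_absent()]) and appends `round(contamination * n)`
#' contaminant genes from a disjoint id space.
#'
#' @param T_genes True genome gene count.
#' @param n Number of genes recovered, `n <= T_genes`.
#' @param pathway A [gene_set()]; its members are embedded in the genome.
#' @param contamination Contaminant admixture rate (fraction of `n`).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Object of class `synthetic_bin`: list with `true_gene_set`,
#'   `sampled`, `pathway`, `contaminant_genes`, `n_pathway_recovered`,
#'   `seed`.
#' @examples
#' b <- simulate_bin_sampling(100, 40, gene_set("p", c("x1", "x2")), seed = 1)
#' b$n_pathway_recovered
#' @export
simulate_bin_sampling <- function(T_genes, n, pathway, contamination = 0,
                                  seed = NULL) {
  if (!is_count(T_genes) || !is_count(n)) {
    ph_stop("domain_error", "T_genes and n must be non-negative integers")
  }
  if (n > T_genes) ph_stop("domain_error", "n must not exceed T_genes")
  stopifnot(inherits(pathway, "gene_set"))
  if (pathway$size > T_genes) {
    ph_stop("domain_error", "pathway size must not exceed T_genes")
  }
  contamination <- normalize_fraction(contamination, "contamination")
  truth <- c(pathway$members,
             sprintf("g%05d", seq_len(T_genes - pathway$size)))
  with_seed(seed, {
    sampled <- if (n > 0L) truth[sample.int(T_genes, n)] else character(0)
    n_contam <- as.integer(round(contamination * n))
    contam <- if (n_contam > 0L) sprintf("foreign_%04d", seq_len(n_contam)) else character(0)
    structure(list(
      true_gene_set = truth,
      sampled = c(sampled, contam),
      pathway = pathway,
      contaminant_genes = contam,
      n_pathway_recovered = sum(pathway$members %in% sampled),
      seed = seed
    ), class = "synthetic_bin")
  })
}

#' Simulate a rooted Yule (pure-birth) topology
#'
#' Starting from a two-leaf tree, a uniformly chosen extant lineage splits
#' until `n_leaves` are present. Leaves are labeled `t1..tn` left to right.
#'
#' @param n_leaves Number of leaves, `>= 2`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A rooted `phylo` cladogram (no branch lengths).
#' @export
simulate_yule_tree <- function(n_leaves, seed = NULL) {
  if (!is_count(n_leaves) || n_leaves < 2) {
    ph_stop("domain_error", "n_leaves must be an integer >= 2")
  }
  with_seed(seed, {
    children <- list()          # by node id; absent entry = leaf
    next_id <- 4L
    children[["1"]] <- c(2L, 3L)
    tips <- c(2L, 3L)
    while (length(tips) < n_leaves) {
      i <- sample.int(length(tips), 1L)
      t <- tips[i]
      children[[as.character(t)]] <- c(next_id, next_id + 1L)
      tips <- c(tips[-i], next_id, next_id + 1L)
      next_id <- next_id + 2L
    }
    counter <- 0L
    nwk <- function(v) {
      kids <- children[[as.character(v)]]
      if (is.null(kids)) {
        counter <<- counter + 1L
        return(sprintf("t%d", counter))
      }
      paste0("(", paste(vapply(kids, nwk, character(1)), collapse = ","), ")")
    }
    parse_newick(paste0(nwk(1L), ";"))
  })
}

## -- nested-list tree surgery (internal) ------------------------------------
# A tree is either a leaf label (character) or a list of >= 2 child trees.

ph_phylo_to_list <- function(phy) {
  rt <- ph_rtree(phy)
  rec <- function(v) {
    kids <- rt$children[[v]]
    if (length(kids) == 0L) return(rt$tip_labels[v])
    lapply(kids, rec)
  }
  rec(rt$root)
}

ph_list_leaves <- function(tr) {
  if (is.character(tr)) return(tr)
  unlist(lapply(tr, ph_list_leaves))
}

ph_list_to_newick <- function(tr) {
  rec <- function(t) {
    if (is.character(t)) return(t)
    paste0("(", paste(vapply(t, rec, character(1)), collapse = ","), ")")
  }
  paste0(rec(tr), ";")
}

# Remove the subtree whose leaf set is exactly `leaves`; suppress the
# resulting unary node. Returns the remaining tree (or NULL if everything
# was removed).
ph_list_prune <- function(tr, leaves) {
  if (is.character(tr)) {
    if (setequal(tr, leaves)) return(NULL)
    return(tr)
  }
  if (setequal(ph_list_leaves(tr), leaves)) return(NULL)
  kept <- Filter(Negate(is.null), lapply(tr, ph_list_prune, leaves = leaves))
  if (length(kept) == 0L) return(NULL)
  if (length(kept) == 1L) return(kept[[1L]])
  kept
}

# Attach `graft` as sister to the subtree whose leaf set is exactly
# `at_leaves` (i.e. on the branch above that subtree).
ph_list_graft <- function(tr, at_leaves, graft) {
  if (setequal(ph_list_leaves(tr), at_leaves)) return(list(tr, graft))
  if (is.character(tr)) return(tr)
  lapply(tr, function(ch) ph_list_graft(ch, at_leaves, graft))
}

# Extract the subtree with leaf set exactly `leaves` (NULL if absent).
ph_list_subtree <- function(tr, leaves) {
  if (setequal(ph_list_leaves(tr), leaves)) return(tr)
  if (is.character(tr)) return(NULL)
  for (ch in tr) {
    hit <- ph_list_subtree(ch, leaves)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' Plant lateral transfers into a gene-tree history
#'
#' Starts from a congruent gene tree and applies `k` transfer events: each
#' event picks a donor and a recipient branch of the species tree (subtrees
#' disjoint; additionally non-adjacent and event regions pairwise disjoint
#' when `well_separated`) and moves the recipient's gene lineage so it
#' branches from the donor lineage — the signature a real transfer leaves in
#' the gene tree.
#'
#' @param species_tree Rooted `phylo` with at least `k + 3` leaves.
#' @param k Number of transfers to plant (`>= 0`).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param well_separated Reject adjacent/nested donor-recipient pairs and
#'   overlap between events (default TRUE), keeping events independently
#'   recoverable.
#' @return Object of class `synthetic_history`: list with `species_tree`,
#'   `gene_tree`, `true_events` (data frame of donor/recipient branch labels
#'   and leaf sets), `seed`, `well_separated`.
#' @examples
#' h <- plant_transfers(simulate_yule_tree(8, seed = 7), k = 1, seed = 11)
#' h$true_events
#' @export
plant_transfers <- function(species_tree, k, seed = NULL, well_separated = TRUE) {
  stopifnot(inherits(species_tree, "phylo"))
  if (!is_count(k)) ph_stop("domain_error", "k must be a non-negative integer")
  ntip <- length(species_tree$tip.label)
  if (ntip < k + 3) {
    ph_stop("domain_error", sprintf("species tree needs at least %d leaves", k + 3))
  }
  rt <- ph_rtree(species_tree)
  candidates <- setdiff(seq_len(rt$nnode), rt$root)
  with_seed(seed, {
    gene <- NULL
    # retry the whole event sequence: an unlucky first event can exhaust the
    # tree and make later well-separated events infeasible
    for (attempt in seq_len(50L)) {
      used <- 0L # leaf mask of regions already involved in an event
      events <- list()
      gene <- ph_phylo_to_list(species_tree)
      sequence_ok <- TRUE
      for (ev in seq_len(k)) {
        ok <- FALSE
        for (try in seq_len(200L)) {
          pair <- sample(candidates, 2L)
          d <- pair[1L]; r <- pair[2L]
          md <- rt$mask[d]; mr <- rt$mask[r]
          if (bitwAnd(md, mr) != 0L) next                 # nested/overlapping
          if (ph_popcount(bitwOr(md, mr)) >= ntip) next   # nothing left outside
          if (well_separated) {
            if (rt$parent[d] == rt$parent[r]) next        # sisters: no-op SPR
            if (bitwAnd(used, bitwOr(md, mr)) != 0L) next # overlap with prior event
          } else if (rt$parent[d] == rt$parent[r]) next
          d_leaves <- ph_mask_leaves(rt, md)
          r_leaves <- ph_mask_leaves(rt, mr)
          sub <- ph_list_subtree(gene, r_leaves)
          if (is.null(sub)) next # recipient clade already disrupted (overlap allowed)
          pruned <- ph_list_prune(gene, r_leaves)
          if (is.null(pruned) || is.character(pruned)) next
          if (is.null(ph_list_subtree(pruned, d_leaves))) next
          gene <- ph_list_graft(pruned, d_leaves, sub)
          used <- bitwOr(used, bitwOr(md, mr))
          events[[ev]] <- data.frame(
            donor = ph_branch_label(rt, d),
            recipient = ph_branch_label(rt, r),
            donor_leaves = paste(sort(d_leaves), collapse = ","),
            recipient_leaves = paste(sort(r_leaves), collapse = ","),
            stringsAsFactors = FALSE
          )
          ok <- TRUE
          break
        }
        if (!ok) { sequence_ok <- FALSE; break }
      }
      if (sequence_ok) break
    }
    if (!sequence_ok) {
      ph_stop("generation_error",
              "could not place a transfer satisfying the separation constraints")
    }
    structure(list(
      species_tree = species_tree,
      gene_tree = parse_newick(ph_list_to_newick(gene)),
      true_events = if (length(events)) do.call(rbind, events) else
        data.frame(donor = character(0), recipient = character(0),
                   donor_leaves = character(0), recipient_leaves = character(0)),
      seed = seed,
      well_separated = well_separated
    ), class = "synthetic_history")
  })
}
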