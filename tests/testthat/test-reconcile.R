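# Minimum-event reconciliation: toy cases, the Chloroflexi fixture, and
# equivalence with the naive enumeration oracle.

test_that("congruent trees need no events", {
  s <- parse_newick("((A,B),C);")
  rec <- min_event_reconciliation(s, s)
  expect_identical(rec$min_transfers, 0L)
  expect_identical(rec$min_losses, 0L)
  expect_equal(rec$min_cost, 0)
  expect_match(scenario_narrative(rec), "no transfers", all = FALSE)
  for (seed in 1:5) {
    t <- simulate_yule_tree(sample(4:12, 1), seed = seed)
    expect_identical(min_event_reconciliation(t, t)$min_transfers, 0L,
                     label = sprintf("identity seed %d", seed))
  }
})

test_that("spec toy cases reconcile as expected", {
  s <- parse_newick("(((A,B),C),D);")
  rec <- min_event_reconciliation(s, parse_newick("(A,D);"))
  expect_identical(rec$min_transfers, 1L)
  expect_equal(rec$min_cost, 1) # origin at A, transfer into D beats 2 losses
  # one xenologous replacement: a single transfer into D (overwriting the
  # resident copy, no loss charged) explains the regrafted gene tree
  s2 <- parse_newick("((A,B),(C,D));")
  g2 <- parse_newick("(((A,D),B),C);")
  rec2 <- min_event_reconciliation(s2, g2)
  expect_equal(rec2$min_cost, 1)
  expect_identical(rec2$min_transfers, 1L)
  expect_identical(rec2$min_losses, 0L)
})

test_that("fixture reconciliation: two transfers, one fusion, both encodings", {
  for (variant in c("rc_tree_between", "rc_tree_basal")) {
    rec <- min_event_reconciliation(fx$organismal_tree, fx[[variant]],
                                    present = fx$phototrophs,
                                    fusion_states = fx$fusion_states)
    expect_identical(rec$min_transfers, 2L, label = variant)
    expect_identical(rec$min_fusions, 1L, label = variant)
    expect_identical(rec$min_losses, 0L, label = variant)
    expect_equal(rec$min_cost, 3, label = variant)
    # donors sit in the Chloroflexia, as the narrative should say
    txt <- paste(scenario_narrative(rec), collapse = "\n")
    expect_match(txt, "transfer from .*Roseiflexus.* into CP2_42A")
    expect_match(txt, "into JP3_7")
  }
})

test_that("reconciliation cost is invariant under leaf relabeling", {
  s <- simulate_yule_tree(8, seed = 21)
  h <- plant_transfers(s, 2, seed = 22)
  rec <- min_event_reconciliation(h$species_tree, h$gene_tree, max_transfers = 3)
  perm <- stats::setNames(sprintf("Z%02d", 8:1), sprintf("t%d", 1:8))
  s2 <- h$species_tree; s2$tip.label <- unname(perm[s2$tip.label])
  g2 <- h$gene_tree; g2$tip.label <- unname(perm[g2$tip.label])
  rec2 <- min_event_reconciliation(s2, g2, max_transfers = 3)
  expect_equal(rec2$min_cost, rec$min_cost)
  expect_identical(rec2$min_transfers, rec$min_transfers)
  expect_identical(rec2$min_losses, rec$min_losses)
})

test_that("engine agrees with naive enumeration on small random cases", {
  set.seed(5)
  cases <- 0L
  for (i in 1:10) {
    n <- sample(5:6, 1)
    sp <- simulate_yule_tree(n, seed = 400 + i)
    h <- tryCatch(
      plant_transfers(sp, sample(0:2, 1), seed = 500 + i, well_separated = FALSE),
      photoHGT_generation_error = function(e) NULL)
    if (is.null(h)) next
    oracle <- oracle_reconcile(h$species_tree, h$gene_tree, kmax = 2L)
    eng <- tryCatch(
      min_event_reconciliation(h$species_tree, h$gene_tree, max_transfers = 2),
      photoHGT_bounded_search_error = function(e) NULL)
    if (is.null(oracle)) {
      expect_null(eng, label = sprintf("case %d: both out of bound", i))
    } else {
      expect_equal(eng$min_cost, oracle$cost, label = sprintf("case %d cost", i))
      expect_identical(eng$min_transfers, as.integer(oracle$transfers),
                       label = sprintf("case %d transfers", i))
      cases <- cases + 1L
    }
  }
  expect_gte(cases, 5L) # the comparison must actually have exercised cases
  # and one present-subset case against the oracle
  s <- parse_newick("(((A,B),(C,D)),(E,F));")
  g <- parse_newick("((A,(C,D)),F);")
  oracle <- oracle_reconcile(s, g, present = c("A", "C", "D", "F"), kmax = 2L)
  eng <- min_event_reconciliation(s, g, max_transfers = 2)
  expect_equal(eng$min_cost, oracle$cost)
  expect_identical(eng$min_transfers, as.integer(oracle$transfers))
})

test_that("adding a sister leaf to `present` never raises min_transfers", {
  # grow the present set by a leaf sitting sister to an existing present
  # leaf in both trees: the new leaf joins the same block
  set.seed(31)
  for (i in 1:6) {
    sp <- simulate_yule_tree(8, seed = 600 + i)
    h <- plant_transfers(sp, sample(1:2, 1), seed = 700 + i)
    g <- h$gene_tree
    # pick a cherry shared by both trees (guaranteed for unmoved leaves)
    base <- min_event_reconciliation(sp, g, max_transfers = 3)
    cherries <- photoHGT:::ph_rtree(g)
    # drop one leaf of a gene-tree cherry from both trees, reconcile, then
    # compare with the full reconciliation
    cherry_nodes <- which(vapply(seq_len(cherries$nnode), function(v) {
      k <- cherries$children[[v]]
      length(k) == 2 && all(k <= cherries$ntip)
    }, logical(1)))
    pair <- cherries$tip_labels[cherries$children[[cherry_nodes[1]]]]
    if (!is_monophyletic(sp, pair)) next # need sisters in both trees
    dropped <- setdiff(g$tip.label, pair[1])
    rec_small <- min_event_reconciliation(
      restrict_to_leaves(sp, dropped) , restrict_to_leaves(g, dropped),
      present = dropped, max_transfers = 3)
    expect_lte(base$min_transfers, rec_small$min_transfers,
               label = sprintf("case %d", i))
  }
})

test_that("bounded search and input validation fail loudly", {
  s <- parse_newick("((A,B),(C,D));")
  g <- parse_newick("(((A,D),B),C);")
  expect_error(min_event_reconciliation(s, g, max_transfers = 0),
               class = "photoHGT_bounded_search_error")
  expect_error(min_event_reconciliation(s, parse_newick("(A,E);")),
               class = "photoHGT_input_error")
  expect_error(min_event_reconciliation(s, g, present = c("A", "B")),
               class = "photoHGT_input_error")
  expect_error(event_costs(transfer_cost = 0), class = "photoHGT_input_error")
  expect_error(event_costs(loss_cost = -1), class = "photoHGT_input_error")
})

test_that("co-optimal scenarios are listed, capped and deterministically ordered", {
  # {A, D} present on a 4-leaf chain: origin at A with a transfer into D
  # ties with origin at D and a transfer into A
  s <- parse_newick("(((A,B),C),D);")
  g <- parse_newick("(A,D);")
  rec <- min_event_reconciliation(s, g)
  expect_gte(rec$n_optimal_found, 2L)
  keys <- vapply(rec$scenarios, function(x) x$key, character(1))
  expect_identical(keys, unique(keys))
  rec_b <- min_event_reconciliation(s, g)
  expect_identical(keys, vapply(rec_b$scenarios, function(x) x$key, character(1)))
  capped <- min_event_reconciliation(s, g, scenario_cap = 1L)
  expect_true(capped$capped)
  expect_length(capped$scenarios, 1L)
  # the headline counts ignore the cap (scenarios are sorted by transfers)
  expect_identical(capped$min_transfers, rec$min_transfers)
})

test_that("fusion states ride the gene tree through transfers", {
  # a transferred fused gene stays fused: states on the gene tree, one gain
  rec <- min_event_reconciliation(fx$organismal_tree, fx$rc_tree_between,
                                  present = fx$phototrophs,
                                  fusion_states = fx$fusion_states)
  expect_identical(rec$fusion_gain_branches,
                   "branch_to{CP2_42A,Kouleothrix,Roseiflexus}")
  # and the same set on the species tree would need two gains
  sp_states <- fx$fusion_states
  expect_identical(
    dollo_gains(restrict_to_leaves(fx$organismal_tree, fx$phototrophs), sp_states)$count,
    2L)
})
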