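---
title: "Pathway absence confidence and transfer parsimony in draft genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway absence confidence and transfer parsimony in draft genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoHGT)
```

photoHGT quantifies two sampling ambiguities of metagenome-assembled
genome (MAG) bins — is a pathway absent or unsampled; are recovered
pathway genes contaminants — and then asks how many horizontal-transfer,
loss, and gene-fusion events minimally reconcile a pathway gene tree with
an organismal tree. This vignette is the package's own account of the
models, the conventions chosen where the design was genuinely open, and
what the tests do and do not establish.

## 1. The hypergeometric absence model

A bin recovered `n` protein-coding sequences from a genome whose true gene
count is unknown. We estimate it as `T = round(n / completeness)`
(round-half-to-even; `T` is never allowed below `n`). If the `r` genes of
a pathway are a fixed subset of those `T` genes and bin assembly behaves
like uniform sampling of genes without replacement, the number of pathway
genes recovered is hypergeometric, and the probability of recovering none
is

$$f(0) = \binom{T-n}{r}\Big/\binom{T}{r}.$$

`prob_absent()` flags a bin *inconclusive* when `f(0)` exceeds a decision
threshold (default 0.05, the ">5%" convention; configurable).

**Assumptions.** Every gene is equally likely to be sampled: no length
weighting and no co-localization. For the phototrophy application this is
defensible — the marker genes sit on separate contigs and have near-average
length — but for operonic pathways on a single contig the model
understates the correlation between members, so `f(0)` is then
*optimistic* (too small). We deliberately do not model gene length or
linkage; that is out of scope.

**Numerical choices.** The pmf is evaluated in log space (`lchoose`), so
tails far below 1e−13 remain representable; an impossible configuration
(`r − x > T − n`) returns exactly 0. Rounding `T` versus using real-valued
generalized binomials is immaterial at the reported precision: for the
bundled bins the difference appears beyond the fourth significant digit.

**Input scales.** Completeness/contamination arrive either as fractions or
CheckM-style percentages; values in (1, 100] are auto-scaled to fractions
with a warning, values above 100 are rejected.

## 2. The false-assignment probability

With bin contamination `C` and pathway genes recovered on `k` distinct
contigs, the probability that all of them belong to the contaminant
fraction is `P = C^k`, treating contigs as independently mis-binned with
probability `C`. This is conservative: part of `C` reflects strain-level
heterogeneity, i.e. sequence from close relatives of the binned organism,
which would not produce spurious pathway calls. `prob_false_assignment()`
therefore also reports an adjusted value using
`C · (1 − strain_heterogeneity)`; both are printed, the raw value is the
headline number.

## 3. Marker calling and contaminant screening

`call_marker()` accepts a hit when it is near-full-length — alignment
span strictly greater than 90% of the *shortest* isolate reference — and
highly significant, e-value ≤ 1e−20. The e-value rule is implemented as a
maximum: a "more significant than 1e−20" cutoff. A variant measuring the
length rule on the hit ORF (subject) length instead of the alignment span
is available via `length_basis = "subject"`; the alignment-span reading is
the default and the one used everywhere else in the package. Hits for one
marker on several contigs union their support — expected here, since the
phototrophy genes largely reside on separate contigs.

`screen_contaminant_contigs()` removes support from contigs flagged as
compositional outliers; a call whose entire support is flagged becomes
`screened_out` rather than silently absent, so downstream tables preserve
the distinction. Screening is idempotent and calls with at least one clean
contig stay present.

## 4. The event model for reconciliation

A *scenario* is a single origin of the gene on a species-tree branch plus
`k` transfers; each transfer copies the gene lineage from a branch of the
**observed gene tree** onto a recipient species branch, after which the
copy descends vertically. Losses prune lineages. The minimum total cost
(defaults: transfer 1, loss 1, fusion 1, origin free) over scenarios whose
surviving copies' branching order equals the observed gene tree is found
exactly. The origin is mandatory and uncounted, matching the convention
that the initial acquisition is not a transfer.

Three conventions were genuinely open and are fixed as follows:

* **Xenologous replacement is one event.** A transfer into a lineage that
  already carries the gene overwrites the resident copy; no separate loss
  is charged. Without this convention a planted single transfer into an
  occupied lineage would cost 2 (transfer + loss) and tie with spurious
  two-transfer explanations; with it, simulated histories with `k` planted
  transfers and no losses are recovered at cost `k`.
* **Donors are observed gene lineages.** Transfers from extinct or
  unsampled gene lineages are not modeled. This matches how such scenarios
  are narrated (donors are named surviving lineages) and keeps the search
  space finite and exact. A consequence: a scenario whose origin block
  retains no surviving descendant is never proposed.
* **Temporal feasibility is not enforced.** The reasoning is purely
  topological; a strict mode rejecting time-inconsistent transfers would
  require node datings that the inputs do not carry.

The fusion character (here the pufL+pufM gene fusion) evolves on the
*gene tree*, not the species tree: once gained it is never reversed, and a
fused gene transferred stays fused. `dollo_gains()` counts the minimum
number of independent gains as the number of maximal derived-state
subtrees — with irreversibility and no reversal this is exact, and on the
bundled reaction-center tree the three fused lineages form one clade, so a
single fusion suffices even though they are scattered across the
organismal tree (two gains would be needed there).

**Search.** Any scenario is determined by its origin branch and recipient
branch set: present leaves are claimed by the innermost covering block,
each block contributes the species topology induced on its claimed leaves,
and block losses are counted as maximal surviving-copy-free subtrees.
Validity is decided by peeling blocks off the observed gene tree: a block
is removable when its claimed leaves form a gene-tree clade with matching
internal topology. The search deepens iteratively in the transfer count
with the best-known cost as bound (`max_transfers`, default 4, caps it; an
exhausted bound raises a classed error rather than returning a guess). All
co-optimal scenarios are listed up to a cap (default 25), sorted by
(transfers, losses, canonical event list). `min_transfers` is the minimum
transfer count among minimum-cost scenarios. Leaf sets are bitmask-encoded,
which limits the species tree to 30 leaves — far beyond the pathway
subsets this search is meant for.

An independent naive oracle (forward enumeration with explicit tree
grafting) is kept in the test suite and must agree with the engine on
random ≤6-leaf problems and on a 7-leaf restriction of the bundled case.

`min_vertical_losses()` quantifies the competing hypothesis: origin at the
most recent common ancestor of the present leaves, vertical descent, and
one loss per maximal gene-free subtree. For the bundled case this costs 7
losses against the 2-transfer scenario.

## 5. Synthetic data: what it emulates, what it does not

`simulate_bin_sampling()` draws `n` of `T` genes uniformly without
replacement — exactly the absence model's world — and appends
`round(C · n)` contaminant genes from a disjoint id space, so
false-assignment logic can be tested without ambiguity. It does *not*
emulate assembly fragmentation, coverage bias, or length-dependent
recovery; a green Monte-Carlo test establishes internal consistency of the
model and code, not that real binning is uniform.

`simulate_yule_tree()` grows pure-birth topologies (uniform lineage
splitting), the standard null for clade shapes; `plant_transfers()`
regrafts a recipient clade next to its donor — the signature a transfer
leaves in a gene tree — with `well_separated = TRUE` rejecting adjacent or
overlapping event regions so that planted events are independently
recoverable. Defaults for the recovery experiments are 20-leaf trees and
k ∈ {0, 1, 2}, the regime of the motivating analysis (two inferred
transfers among a handful of phototrophs). Recovery failures concentrate,
as expected, in histories where separation constraints cannot be satisfied;
these raise a classed generation error rather than returning a degenerate
history.

All generators take an explicit seed, use one local RNG scope, and restore
the caller's RNG state.

## 6. The bundled case study

The fixtures encode a published comparative analysis of phototrophy in the
Chloroflexi: Table-style bin statistics for ten hot-spring MAG bins and
one isolate, a marker presence/absence matrix, and text-derived cladogram
encodings of the organismal (RpoB) and Type 2 reaction-center (PufL+PufM)
topologies. Two points required a judgment call, recorded in
`inst/extdata/MANIFEST.md`: the reaction-center position of CP2_42A is
described two ways in the source text, so both encodings ship and every
asserted consequence (2 transfers, 1 fusion) holds for both; and JP3_7's
fusion state follows the marker matrix ("+ (unfused)") over a
contradictory prose sentence. One printed value of the source analysis
(a ~2e−13 absence probability for the bin JP3_13) is *not* reproducible
from the stated formula and inputs, which yield ~2.8e−9; the package
implements the formula as written, does not special-case that bin, and the
discrepancy is documented rather than fitted.

## 7. Known limitations

* No duplications: the event model is origin + transfer + loss + fusion;
  paralogous gene families are out of scope.
* ≤ 30 species-tree leaves in the event search (bitmask encoding); the
  exact search is exponential in `max_transfers` and intended for small
  pathway subsets, not genome-scale reconciliation.
* Transfers are undated and donors must be observed gene lineages.
* The absence model ignores gene length and linkage; the false-assignment
  model treats contigs as independent.
* Marker calling consumes precomputed homology hits; running the search
  itself, alignment curation, and tree inference are out of scope.
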