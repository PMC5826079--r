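# photoHGT

Statistical confidence and transfer parsimony for pathway presence/absence
in draft genomes.

## The problem

Metagenome-assembled genome (MAG) bins are incomplete and contaminated, so
"this bin has no photosynthesis genes" is ambiguous: the genes may be truly
absent from the organism, or merely unsampled; conversely, pathway genes
that *were* recovered may belong to the contaminant fraction. And once
presence/absence is settled, the evolutionary question remains: does the
distribution of the pathway across a phylum reflect vertical inheritance
with loss, or horizontal gene transfer (HGT)?

photoHGT is for comparative genomicists working with draft genomes who need
all three answers with numbers attached:

1. **Absence confidence.** For a bin that recovered `n` coding sequences of
   an estimated `T = round(n / completeness)` total, the probability that
   all `r` genes of a pathway were missed by chance under uniform sampling
   without replacement is hypergeometric:

   `f(x) = C(n, x) C(T − n, r − x) / C(T, r)`, evaluated at `x = 0`:
   `f(0) = C(T − n, r) / C(T, r)`.

   Bins with `f(0)` above a decision threshold (default 5%) are flagged
   inconclusive rather than called negative.

2. **False-assignment confidence.** If the bin's contamination fraction is
   `C` and the recovered pathway genes sit on `k` distinct contigs, the
   probability that *all* of them were mis-binned is `P = C^k` (with an
   optional strain-heterogeneity-adjusted variant).

3. **Minimum-event reconciliation.** Given a rooted organismal tree, a
   rooted pathway gene tree, and an irreversible gene-fusion character, an
   exact bounded search finds every minimum-cost scenario of one origin
   plus lateral transfers, losses, and Dollo fusion gains whose surviving
   gene lineages reproduce the observed gene tree — and compares it against
   the single-origin vertical-loss alternative.

Supporting modules call marker presence/absence from BLAST tabular hits
(full-length rule: alignment > 90% of the shortest isolate reference;
e-value ≤ 1e−20), screen calls on likely-contaminant contigs, provide tree
utilities (Robinson–Foulds distance, monophyly, leaf restriction), and
generate synthetic bins and planted-transfer gene-tree histories for
calibration. A Chloroflexi phototrophy case study ships as plain-text
fixtures (`inst/extdata/`, see its `MANIFEST.md`).

## Worked example

```r
library(photoHGT)
fx <- chloroflexi_fixtures()
bins <- fx$bin_quality[fx$bin_quality$bin_id %in% fx$metagenome_bins, ]
class(bins) <- c("bin_quality", "data.frame")

absence_report(bins, fx$gene_sets["phototrophy_rc6"])
#>     bin_id total_genes prob_zero_recovered flag_inconclusive
#> 1   CP1_1M        2796            3.69e-02             FALSE
#> ...
#> 6  JP1_191        3142            5.09e-01              TRUE
#> ...
#> 10   JP3_7        3538            4.69e-06             FALSE
```

Only JP1_191 (10.6% complete) is flagged: at ~51% miss probability its
lack of phototrophy genes is inconclusive, whereas every other bin's
absence calls are safe at the 5% level. The reverse check, that CP2_42A's
six recovered phototrophy genes (on six contigs, contamination 10.42%) are
all contaminants:

```r
cp <- bins[bins$bin_id == "CP2_42A", ]; class(cp) <- class(bins)
prob_false_assignment(cp, k_contigs = 6)
#>    bin_id k_contigs prob_all_contaminant prob_all_contaminant_adjusted
#> 1 CP2_42A         6         1.279989e-06                  4.454984e-07
```

Reconciling the reaction-center gene tree with the organismal tree, with
the pufL+pufM fusion as an irreversible character:

```r
rec <- min_event_reconciliation(fx$organismal_tree, fx$rc_tree_between,
                                present = fx$phototrophs,
                                fusion_states = fx$fusion_states)
cat(scenario_narrative(rec), sep = "\n")
#> Minimum-event reconciliation: cost 3 (2 transfer(s), 0 loss(es), 1 fusion gain(s))
#> Scenario 1:
#>   origin on branch_to{Chloroflexus,Kouleothrix,Roseiflexus}
#>   transfer from Roseiflexus into CP2_42A
#>   transfer from branch_to{Kouleothrix,Roseiflexus} into JP3_7
#>   fusion gain on gene-tree branch_to{CP2_42A,Kouleothrix,Roseiflexus}
```

Two transfers out of the classically phototrophic lineage plus one gene
fusion explain the data; the competing vertical-inheritance hypothesis
needs `min_vertical_losses(fx$organismal_tree, fx$phototrophs)$count` = 7
independent losses.

## Command line

```sh
exec/photohgt binprob   --bins inst/extdata/bin_quality.tsv \
                        --genesets inst/extdata/gene_sets.tsv --out out/
exec/photohgt reconcile --species inst/extdata/organismal_tree.nwk \
                        --gene inst/extdata/rc_tree_between.nwk \
                        --present inst/extdata/phototrophs.txt \
                        --fusion inst/extdata/fusion_states.tsv --out out/
exec/photohgt simulate  --mode history --leaves 20 --k 2 --seed 1 --out out/
```

## Notes

See `vignettes/phototrophy-absence-and-hgt.Rmd` for the model assumptions,
the event-cost conventions (xenologous replacement, free origin), the
synthetic-data generators' scope, and known limitations (≤ 30 leaves in
the event search; no duplications/paralogs; no transfer dating).
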