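# Bundled Chloroflexi phototrophy case study

Plain-text fixtures for the worked example: genome statistics and marker
presence/absence for ten hot-spring metagenome bins plus the isolate
*Kouleothrix aurantiaca*, and cladogram encodings of the published
organismal (RpoB) and Type 2 reaction-center (PufL+PufM) tree topologies.

## Files

- `bin_quality.tsv` — per-bin genome statistics (coding-sequence
  counts and CheckM-style completeness/contamination/strain-heterogeneity
  percentages).
- `marker_matrix.tsv` — presence/absence of organismal and metabolic
  markers; cell annotations (`+ (fused)`, `nirK`, ...) are kept verbatim.
- `gene_sets.tsv` — the two pathway gene sets used in the worked example:
  the six-gene reaction-center/bacteriochlorophyll set (`phototrophy_rc6`:
  pufL, pufM, pufC, bchX, bchY, bchZ) and the five bacteriochlorophyll
  synthesis genes not recovered in the phototrophic bins (`bch_synthesis5`:
  bchL, bchN, bchB, bchM, bchE).
- `organismal_tree.nwk` — organismal cladogram, rooted on Dehalococcoides
  (an encoding convention, not a data statement).
- `rc_tree_between.nwk` / `rc_tree_basal.nwk` — the two textual readings of
  CP2_42A's position in the reaction-center tree: branching between
  Kouleothrix and Roseiflexus (sister to Roseiflexus), or basal to the
  Roseiflexus+Kouleothrix clade. Downstream results (2 transfers, 1 fusion)
  are invariant to the choice.
- `fusion_states.tsv` — pufL+pufM fusion state per reaction-center leaf;
  JP3_7 is recorded unfused, following the marker matrix over a
  contradictory prose statement.
- `phototrophs.txt` — the reaction-center-bearing leaves (the `present` set
  for reconciliation).
- `synthetic_reference_lengths.tsv`, `synthetic_pufL_hits_CP2_42A.tsv` —
  synthetic (constructed, not observed) reference lengths and BLAST
  tabular hits used only to demonstrate the marker-calling interface.

## Encoding notes for the trees

Clades supported by the published topology descriptions:

- Chloroflexia: (Herpetosiphon, Kallotenue) basal pair; phototrophic
  Chloroflexales = (Chloroflexus, (Kouleothrix, Roseiflexus)) with
  Kouleothrix basal to Roseiflexus in both trees.
- A class-level clade sister to Anaerolineae containing the metagenome
  bins, with internal clade 1 = (JP3_13, CP1_1M, CP2_2F), clade 2
  containing (JP1_8, CP2_42A) as sisters, and clade 3 = (Roseilinea,
  JP3_7) branching with the new class.
- Reaction-center tree: JP3_7 sister to the Roseiflexus+Kouleothrix+CP2_42A
  clade; CP2_42A per the two variants above.

Arbitrary encoding choices (harmless to every computed quantity, all taxa
involved are non-phototrophic): the internal arrangement of clade 2 beyond
the (JP1_8, CP2_42A) pair, and grouping (CP2_20G, JP1_20). Roseilinea is
included in the organismal tree but excluded from the reaction-center
fixture: it is not a row of the marker matrix and its fusion state is not
consistently recorded. Leaf names are genus-level mnemonics; the marker
matrix row for the isolate uses `Kouleothrix_aurantiaca` while the trees
use `Kouleothrix`.
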