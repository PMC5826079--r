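Package: photoHGT
Title: Statistical Confidence and Transfer Parsimony for Phototrophy in
    Draft Genomes
Version: 0.1.0
Authors@R:
    person("photoHGT", "Maintainers", email = "photohgt@example.org",
           role = c("aut", "cre"))
Description: Inferential tools for asking whether a metabolic pathway is
    genuinely absent from an incomplete metagenome-assembled genome (MAG)
    bin or merely unsampled, whether recovered pathway genes could all be
    contaminants, and how many horizontal gene transfer, loss and
    gene-fusion events are minimally required to reconcile a pathway gene
    tree with an organismal tree. Includes a hypergeometric zero-recovery
    model for gene absence in bins of known completeness, a
    contamination-based false-assignment probability, marker
    presence/absence calling from BLAST tabular hits with contaminant
    contig screening, rooted-tree utilities (Robinson-Foulds distance,
    monophyly, leaf restriction), Dollo gain counting for irreversible
    fusion characters, an exact bounded search for minimum-event
    transfer/loss reconciliations, seeded generators for synthetic bins
    and planted-transfer gene-tree histories, and a command-line driver.
    Ships a worked Chloroflexi phototrophy case study as plain-text
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
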