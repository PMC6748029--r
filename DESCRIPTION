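Package: serumir
Title: Serum miRNA Profiling Linked to Innate-Immune Subgroups and
    Mitochondrial Respiration
Version: 0.1.0
Authors@R:
    person("serumir", "maintainers", email = "maintainers@serumir.dev",
           role = c("aut", "cre"))
Description: Tools for an integrated analysis of serum microRNA sequencing
    counts alongside monocyte cytokine production and extracellular-flux
    (Seahorse-style) oxygen consumption traces. Subjects are classified into
    innate-immune subgroups by comparing stimulated IL-1beta/IL-10 ratios
    against control-derived reference statistics; oxygen consumption traces
    are reduced to bioenergetic parameters (basal, ATP-linked and proton-leak
    respiration, maximal and reserve capacity); miRNA counts are filtered,
    CPM- and TMM-normalized and tested for differential expression with a
    conditioned negative-binomial exact test under a common dispersion with
    Benjamini-Hochberg adjustment; and stratified Spearman correlation screens
    relate miRNA levels to cytokine and respiration endpoints. A seeded
    synthetic-cohort generator with planted ground truth makes every pipeline
    stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
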