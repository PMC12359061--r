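Package: ClonalDivergence
Title: Clonal Evolution of Paired Baseline and Recurrent Tumours Under
    Divergent Immune Selection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing clonal evolution in paired baseline and
    recurrent tumour exomes profiled from formalin-fixed (FFPE) material.
    Implements FFPE-aware somatic variant filtering (artefact-signature and
    variant-allele-frequency thresholds), cancer cell fraction (CCF)
    estimation from purity and allele-specific copy number with multiplicity
    selection, clone clustering by a seeded EM binomial mixture with BIC
    model selection, a frequency-weighted clonality score and its
    between-timepoint deltas, private/public mutation classification with an
    unmatched-pair overlap null distribution, neoantigen binding-affinity
    tiers and delta-CCF immunoediting tests, catalogue-based immune-evasion
    loss-of-function flagging with Fisher and rank-sum comparisons, and
    promoter methylation summaries over upstream regulatory probes. A
    synthetic-cohort generator with known clonal truth, FFPE artefact
    injection and tunable immunoediting selection makes every stage testable
    without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
biocViews: SomaticMutation, CopyNumberVariation, Sequencing, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
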