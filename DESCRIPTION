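Package: broadH3K4
Title: Broad H3K4me3 Domain Classification and Integrative ChIP/RNA
    Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing broad H3K4me3 domains over genes from
    ChIP-seq peak calls and coverage tracks. Assigns peaks to genes,
    scores per-gene domain breadth, classifies genes into broad, medium
    and narrow groups by the quartile rule, builds RPM-normalised
    length-scaled TSS-to-TES metagene coverage profiles, performs
    median-of-ratios count normalisation with per-feature differential
    testing of expression and peak signal, and integrates the resulting
    reduced-H3K4me3 and reduced-expression gene sets with breadth-group
    composition. Ships a fully seeded synthetic-data generator (toy
    genome, peak sets, coverage, negative-binomial count matrices with
    planted effects) so the whole pipeline is testable without external
    data, plus a one-call pipeline driver with a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    knitr
biocViews: ChIPSeq, Epigenetics, DifferentialExpression, Coverage,
    GeneRegulation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
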