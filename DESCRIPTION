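Package: thsdyn
Title: Chromatin Accessibility Dynamics Across Plant Desiccation Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of a downstream
    ATAC-seq analysis pipeline for desiccation-stage time courses in
    resurrection plants: self-organizing-map classification of OJIP
    chlorophyll-fluorescence transients into stress stages, Tn5 insertion
    quality control (fragment-length periodicity, TSS enrichment, replicate
    correlation), local-lambda Poisson peak calling, replicate-reproducibility
    filtering into consensus transposase hypersensitive sites (THSs),
    cross-stage Venn partitioning and genomic-feature annotation,
    discriminative promoter motif enrichment with PWM matching, and
    integration with expression fold changes via a bipartite
    distance-threshold correlation network. Ships a synthetic-data generator
    with planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    IRanges,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
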