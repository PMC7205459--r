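Package: tnprof
Title: Conditional Fitness Profiling of Transposon Insertion Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates per-gene conditional fitness from transposon insertion
    sequencing (Tn-seq) read counts, builds gene-by-condition phenotypic
    fingerprints, classifies phenotype strength by fitness thresholds,
    clusters fingerprints hierarchically and ranks correlation neighbours
    for function prediction. Includes a multinomial simulator of dense
    transposon libraries under selection so every stage of the pipeline can
    be validated by parameter recovery on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
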