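Package: msconsensus
Title: Cross-Tissue Consensus Biomarkers for Progressive Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-dataset transcriptomic pipeline for isolating blood-detectable
    biomarkers of the transition from relapsing-remitting to secondary progressive
    multiple sclerosis. Implements a two-sample Rank Product differential expression
    test with permutation p-values and FDR control, a brain/blood cross-tissue
    consensus filter, interaction-network subcluster extraction, hypergeometric
    over-representation analysis with term-overlap fusion, and a three-layered
    disease-subtype specificity comparison. Ships a synthetic-study generator with
    planted ground truth so the whole pipeline is testable end to end without any
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
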