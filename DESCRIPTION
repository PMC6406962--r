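Package: deamfootprint
Title: Weight-Matrix Detection of AID/APOBEC Deaminase Footprints in
    Somatic Mutation Catalogues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds nucleotide weight matrices (sequence profiles) from sets
    of deaminase mutation contexts, scores mutated cytosines against their
    local DNA neighborhoods with a percent matching score, and tests for
    enrichment of AID/APOBEC mutable motifs with a dual t-test / Monte Carlo
    gate. Includes a two-component normal mixture estimator of the
    deaminase-attributable mutation fraction, four control experiments
    (shuffled contexts, composition-matched random matrices, negative and
    positive mutation sets), and a synthetic-data generator with planted
    motif fractions so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
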