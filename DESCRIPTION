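Package: fishprobes
Title: Genome-Wide Similarity Screening and Probe Design for Single-Copy
    and Locus-Specific Repetitive FISH Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Designs fluorescence in-situ hybridization (FISH) probes for a
    query locus by classifying every base of the query against the whole
    genome as unique, globally similar, or locally repetitive; tiles
    single-copy amplicons over long unique stretches; selects repetitive
    probe targets inside locally repetitive regions to maximise the
    cumulative length of their predicted binding sites; screens amplicons
    for forbidden restriction sites; and designs linker-extended PCR primer
    pairs for every probe template.  Includes a deterministic synthetic
    genome simulator with planted repeat structure and brute-force oracles
    for validating the classification and selection steps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    BiocGenerics,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
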