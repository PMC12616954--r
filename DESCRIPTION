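Package: ogmtopo
Title: Resolving Linked Interspersed Duplications with Optical Genome
    Mapping Spanning Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to disambiguate the alternative derivative-chromosome
    structures that are compatible with linked interspersed chromosomal
    duplications (DUP-NML-DUP and related chromoanasynthesis events).
    Enumerates candidate topologies from short-read breakpoint junctions
    and copy-number gains, derives the spanning-molecule label signatures
    that are diagnostic of each topology, simulates optical genome mapping
    (OGM) molecules with realistic label noise, classifies molecules
    against candidate label maps under an informative-molecule criterion,
    and quantifies the expected yield of spanning molecules as a function
    of duplication size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
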