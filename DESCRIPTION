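Package: cryptwebs
Title: Cryptic Species Delimitation and Quantitative Host-Parasitoid Food Webs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how cryptic species affect the structure of
    quantitative host-parasitoid food webs. Implements DNA-barcode species
    delimitation (Kimura two-parameter distances, barcode-gap recursive
    partitioning over a grid of prior intraspecific divergences, and the
    single-threshold generalized mixed Yule-coalescent model on ultrametric
    trees) together with consensus integration of methods against a
    morphological baseline; builds quantitative interaction matrices from
    rearing records under any crossing of morphological and molecular
    taxonomies; computes species-level specialization indices (resource range,
    paired difference index, species specificity index, Bluethgen's d' and the
    interaction service index) and network-level metrics (connectance, H2',
    generality, vulnerability, linkage density, compartments, NODF and
    nestedness temperature, specialization asymmetry, secondary-extinction
    robustness); assesses sampling completeness by Simpson-diversity (Hill q=2)
    rarefaction-extrapolation with sample coverage; and generates fully
    synthetic study inputs (species trees, marker alignments with cryptic
    structure, and overdispersed rearing records) so the whole pipeline runs
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
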