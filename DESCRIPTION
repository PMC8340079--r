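Package: glycoformr
Title: Multi-Level Glycoform Annotation for Heavily Glycosylated Protein
    Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates deconvoluted mass spectra of glycoprotein subunits
    and noncovalent protein complexes with ranked, probability-scored
    glycoform assignments. Starting from site-specific quantitative glycan
    libraries, a two-stage search decomposes residual masses into
    monosaccharide compositions and then enumerates library-constrained
    site assignments with hit scores. Annotations propagate upward from
    glycopeptide libraries to subunit glycoform libraries to annotation of
    a noncovalent dimer, and abundance-weighted glycosylation quality
    attributes (degree of sialylation, degree of core fucosylation)
    support batch comparison. A seeded synthetic-data module generates
    ground-truthed libraries and peak lists so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
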