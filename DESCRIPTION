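Package: mitomethr
Title: Genotype-Specific Mitochondrial DNA Methylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing cytosine methylation of small circular
    genomes, built around the mitochondrial bisulfite-sequencing workflow:
    CpG enumeration on circular mitochondrial genotypes, non-directional
    bisulfite read alignment and per-cytosine methylation calling,
    control-anchored "full potential" normalisation against M.SssI-treated
    and untreated long-PCR controls, per-site differential methylation
    contrasts, MeDIP 5mC/5hmC quantification and delta-delta-Ct expression
    analysis from qPCR Ct tables, and methylation-expression correlation.
    Includes a bisulfite read and qPCR simulator so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
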