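Package: tmeprofiler
Title: Tumor Microenvironment Profiling from Bulk Expression and Mutation Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for immunogenomic characterization of
    melanoma cohorts from bulk RNA-seq (TPM) and targeted-panel mutation
    tables: composite z-score immune signatures (interferon-gamma score,
    T cell-inflamed classification, T cell dysfunction, STING pathway),
    constrained least-squares immune-cell deconvolution, preranked GSEA and
    single-sample GSEA, tumor mutational burden, pathogenic mutation
    frequencies, HLA homozygosity, neoantigen affinity binning, and the
    nonparametric group-comparison statistics tying them together. Includes
    a synthetic three-group cohort generator with planted effects so every
    stage is testable without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
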