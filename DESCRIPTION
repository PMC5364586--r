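Package: cfMethMix
Title: Joint Inference of Circulating Tumor DNA Burden and Tissue of
    Origin from Plasma Cell-Free DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models a plasma cell-free DNA (cfDNA) bisulfite methylation
    profile as a mixture of a normal-plasma component and, optionally, one
    solid-tumor component.  Per-cluster methylation levels of each reference
    class are described by beta distributions fitted by the method of
    moments; the methylated cytosine count of a test sample is modeled as a
    binomial draw whose success probability follows the convolution of the
    two class beta densities.  Maximum likelihood over a grid of mixing
    proportions jointly estimates the circulating tumor DNA fraction and the
    tumor type, and a normalized likelihood-gain score calls cancer versus
    non-cancer.  The package also provides CpG-cluster feature construction
    from probe coordinates, methylation-range feature selection, a
    copy-number-aware read count simulator for plasma methylomes, a
    synthetic reference-pool generator, and an evaluation harness with
    confusion matrices, burden-bin error rates, and burden-recovery metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
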