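Package: clonesect
Title: Clonal Deconvolution and Coexpression Profiling of Serial Tumor Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiomic analysis of serially sectioned solid tumors.
    Simulates serial-section data with known clonal ground truth (phylogeny,
    per-section clone fractions, amplicon read counts, bulk and single-nucleus
    expression); reconstructs clonal architecture from variant allele
    frequencies via copy-number-aware cellular prevalence, exhaustive
    small-tree enumeration and constrained least squares; profiles clones
    transcriptionally with biweight-midcorrelation coexpression modules,
    eigengenes and kME; isolates tumor-specific coexpression by consensus
    subtraction against normal reference series; models gene expression on
    clonal abundance with bootstrapped lasso stability selection and a
    permutation FDR; validates purity-correlated markers in pseudobulk and
    single-nucleus data; and integrates purity correlations across cases with
    Fisher's z.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    glmnet,
    cluster,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
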