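Package: thermomark
Title: Multi-Omics Screening of Thermotolerance Biomarkers and Co-Expression Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for contrasting the temperature response of two
    plant genotypes (heat-tolerant vs heat-sensitive) from paired metabolome and
    transcriptome matrices. Implements PLS-DA with variable importance in
    projection (VIP) and permutation/cross-validation model checks, the
    VIP > 1 & p < 0.05 differential-metabolite rule, genotype-stratified
    random-forest classifiers of temperature with out-of-bag permutation
    importance, cross-genotype rank concordance and consistency
    categorization, a top-k biomarker screening cascade, weighted
    co-expression network analysis from first principles (soft threshold,
    unsigned topological overlap, static tree cut, module eigengenes, module
    merging, module-trait correlation), hub-gene ranking, hypergeometric
    over-representation analysis, and a synthetic multi-omics generator that
    plants recoverable markers, modules and module-trait correlations for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    mixOmics
Config/testthat/edition: 3
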