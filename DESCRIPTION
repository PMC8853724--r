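Package: metacourse
Title: Life-Course Metabolome-Cognition Association and Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of plasma metabolomics against cognitive
    outcomes with life-course covariate adjustment. Provides metabolite
    quality control (missingness filtering, k-nearest-neighbour imputation,
    log10 transform, standardization), multiple imputation of covariates by
    chained equations with Rubin's-rules pooling, sequential nested
    regression models with attenuation accounting, quantitative pathway
    scores, effective-number-of-tests Bonferroni correction, weighted signed
    correlation network construction (biweight midcorrelation, soft
    thresholding by scale-free fit, topological overlap, dynamic hybrid tree
    cutting, module eigenvalues, kME and hub detection), hypergeometric
    pathway overrepresentation, and a synthetic cohort generator with
    planted modules, confounders and effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
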