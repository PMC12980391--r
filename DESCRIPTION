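Package: acutephys
Title: Difference-in-Changes Mixed-Model Analysis of Acute-Exercise Blood Multi-Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for randomized group-by-timepoint blood
    multi-omics studies of acute exercise. Implements the
    difference-in-changes (delta-delta) cell-means linear mixed model with
    participant random intercepts and Satterthwaite degrees of freedom,
    count precision weights, stratified Benjamini-Hochberg adjustment,
    a moment-matched non-normal longitudinal simulator (Fleishman
    polynomials with Vale-Maurelli intermediate correlations) together with
    a type-I-error/power benchmark of six analytic strategies (paired t,
    OLS, weighted and unweighted random-intercept mixed models, MMRM with
    unstructured covariance, AR(1) GEE with sandwich covariance),
    metabolomics and RNA-seq preprocessing chains, competitive
    (correlation-adjusted mean-rank) and hypergeometric set enrichment,
    fuzzy c-means temporal clustering, and permutation-tuned sparse
    canonical correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    limma,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    lmerTest,
    lme4,
    nlme,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
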