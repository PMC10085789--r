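Package: hybridGP
Title: Genomic Prediction of Hybrid Performance in Tester-by-Line Factorials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative-genetic analysis of tester-by-line
    factorial hybrid trials bred under a cytoplasmic male-sterility system:
    marker quality control and positional thinning, F1 genotype construction
    from inbred parents, VanRaden additive genomic relationship matrices,
    a restricted maximum likelihood (AI-REML) engine for mixed models with
    identity, supplied, and Kronecker-product covariance structures,
    mid-parent and inbred-midparent heterosis, broad- and narrow-sense
    heritability, general and specific combining-ability variance
    decompositions, GBLUP hybrid genetic values, and cross-validation of
    prediction accuracy under training designs that share both parents (T2),
    only the female tester (T1F), or mask whole male lines (male GCA).
    A synthetic-data generator with known truths makes the whole pipeline
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
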