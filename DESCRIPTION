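Package: lmewscore
Title: Linear Mixed-Effects Harmonization of Multicenter Cortical Thickness
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Harmonization of regional cortical-thickness measurements pooled
    across imaging centers. Implements a per-region linear mixed-effects model
    with biological covariates (age, sex, education, intracranial volume) as
    fixed effects and center as a random intercept, fitted by restricted
    maximum likelihood with compound-symmetry closed forms, producing
    center-effect-free standardized w-scores for seen centers, unseen centers
    (marginal scoring) and incrementally registered centers (frozen-parameter
    BLUP updates). Includes two comparator harmonizers (protocol-specific
    w-scores from robust within-center regression, and location/scale ComBat
    with parametric empirical-Bayes shrinkage), a synthetic multicenter cohort
    generator with known ground truth, and evaluation protocols: PCA-LDA
    center-prediction and disease-classification experiments, paired
    intrasubject comparison, and leave-one-center-out scalability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
biocViews: BatchEffect, Preprocessing, Normalization, Regression, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cohort-class.R'
    'cohort-io.R'
    'combat.R'
    'lme.R'
    'utils.R'
    'evaluate.R'
    'lmewscore-package.R'
    'selfw.R'
    'serialize.R'
    'simulate.R'
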