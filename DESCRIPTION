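Package: visig
Title: Vascular-Invasion Gene-Expression Signature and Predictor for
    Stage I Lung Adenocarcinoma
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives a vascular-invasion (VI) co-expression signature from
    bulk RNA-seq of stage I lung adenocarcinoma graded on a three-level
    scale (LMP, NST, VI): negative binomial GLM likelihood-ratio testing
    with TMM normalization, Ward2 clustering of significant genes with
    consensus-based selection of the number of clusters, and
    cluster-proportional selection of a compact ridge binomial-logit
    predictor evaluated by nested cross-validation. Includes mean z-score
    and control-bin module scoring at sample and spot level, spatially
    weighted local correlation and distance binning around annotated
    invasion foci, multi-region intra- versus inter-tumor heterogeneity
    analysis with pre-ranked GSEA, a Bayesian Beta-posterior projection of
    positive and negative predictive values across prevalence, and seeded
    synthetic-data generators emulating the statistical structure of such
    cohorts for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
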