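Package: immunophen
Title: Immune Subtyping, Hot/Cold Phenotyping and ICB Response Prediction
    from Tumor Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for immunophenotyping tumor cohorts from bulk and
    single-cell expression. Derives early/late monocyte-to-macrophage
    (TAMM) differentiation signatures from single cells, estimates
    immune-cell fractions by constrained least-squares deconvolution,
    classifies tumors into immune subtypes with a two-step consensus
    clustering procedure, scores samples by single-sample gene-set
    enrichment (ssGSEA) including a four-chemokine immune hot/cold grade,
    screens hub genes by network centrality, estimates windowed relative
    copy number from expression, orders cells by diffusion-map pseudotime,
    and predicts immune-checkpoint-blockade response with a small
    feed-forward neural network. Ships a synthetic-data generator that
    emulates the statistical structure of the inputs so every stage is
    testable without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, survival, pracma, jsonlite
Suggests: testthat (>= 3.0.0), igraph, pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'immunophen-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'io.R'
    'synth.R'
    'preprocess.R'
    'deconv.R'
    'subtype.R'
    'score.R'
    'network.R'
    'cnv.R'
    'trajectory.R'
    'predict.R'
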