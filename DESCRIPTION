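Package: dxrank
Title: Phenotype- and Genotype-Driven Ranking of Candidate Genetic Diagnoses
Version: 0.1.0
Authors@R:
    person("dxrank", "developers", email = "dxrank@example.org", role = c("aut", "cre"))
Description: Ranks candidate genetic diagnoses (single variants or compound
    heterozygous pairs) in rare-disease probands by the predicted probability
    of being disease-causing. Combines four evidence levels: an ACMG/AMP
    criteria-based logistic pathogenicity score, Human Phenotype Ontology
    semantic similarity (Resnik information content with best-match-average
    set similarity and disease frequency weighting), family segregation
    matched against the expected mode of inheritance under complete
    penetrance, and variant call quality. Includes leave-one-proband-out
    cross-validation with top-K rank evaluation, ensemble-entropy
    decomposition of predictive uncertainty, border-based pointwise
    reliability scoring, and a fully synthetic trio-cohort generator for
    self-contained benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
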