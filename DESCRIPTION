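Package: metapgs
Title: Polygenic Score Construction, Meta-Score Combination, and Survival
    Evaluation for Coronary Artery Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building and evaluating genomic (polygenic) risk
    scores for coronary artery disease. Harmonizes per-variant weight files
    against genotype dosages and computes standardized additive scores;
    derives a genome-wide score from GWAS summary statistics by greedy LD
    thinning with a grid search tuned on a training cohort; combines several
    component scores into a meta-score with training-set mixing weights;
    derives CAD case status and conventional risk factors from coded
    hospital/death records (ICD-9, ICD-10, OPCS-4) and assessment fields;
    and evaluates scores with sex-stratified age-as-time-scale Cox models
    under delayed entry, Kaplan-Meier and Aalen-Johansen cumulative
    incidence, Harrell concordance, and ROC/precision-recall areas. A
    synthetic-data module generates LD-blocked genotypes, noisy summary
    statistics, survival cohorts with competing mortality, and coded record
    tables so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
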