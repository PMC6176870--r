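# metapgs

Polygenic score construction, meta-score combination, and survival
evaluation for coronary artery disease (CAD).

## The problem

Genome-wide association studies summarize CAD genetics as per-variant
effect sizes. A genomic risk score (GRS) turns those weights into a
per-person number, `GRS_i = Σ_j w_j x_ij`, where `x_ij` is the dosage
(expected count, 0–2) of the effect allele of variant `j` in person `i`.
A *meta-score* goes one step further: several component GRS — a targeted
array score, a sparse genome-wide-significant score, a dense LD-thinned
genome-wide score — are standardized and combined with mixing weights
learned on a small training cohort, and the combined score is evaluated
on an independent cohort with survival models on the age scale:

- per-SD hazard ratio from sex-stratified Cox regression with age as the
  time scale, delayed entry at assessment, censoring at 75;
- top-vs-bottom quintile hazard ratios;
- sex-stratified Harrell C-index;
- Kaplan-Meier and Aalen-Johansen (3-state: CAD, non-CAD death,
  censored) cumulative incidence;
- ROC and precision-recall areas (PR baseline = case prevalence).

The package implements this entire workflow — dosage/weight
harmonization (allele flips, strand complements, palindromic SNP
policies), variant QC (MAF, exact Hardy-Weinberg test, imputation info),
greedy LD thinning with grid-search tuning, meta-score fitting
(joint/univariate, logistic or Cox), electronic-record CAD phenotyping
(ICD-9 410–412; ICD-10 I21–I24, I25.2; OPCS-4 K40–K46, K49, K50.1, K75;
min(self-report, record) event ages), and the evaluation statistics —
plus a synthetic-data module that generates LD-blocked genotypes, noisy
GWAS summary statistics, survival cohorts with competing mortality, and
coded record tables, so everything is testable end to end without access
to any real cohort.

For whom: statistical geneticists and epidemiologists building or
evaluating polygenic scores for time-to-event outcomes, and anyone who
needs a fully synthetic, reproducible test bed for such pipelines.

## Worked example

```r
library(metapgs)

cfg   <- simConfig(n_samples = 2000, n_variants = 300, block_size = 10,
                   causal_fraction = 0.1, per_sd_log_hr = log(1.71),
                   gwas_n = 20000, baseline_hazard = 0.002, seed = 1)
study <- simulateStudy(cfg, n_training = 3000)

train <- study$genotypes[, study$training_ids]
valid <- study$genotypes[, study$validation_ids]

derived <- gridSearchDerive(study$sumstats, train, train,
                            study$training_cohort,
                            r2_grid = c(0.2, 0.5), p_grid = c(1e-4, 0.01, 1))
score_on <- function(def, g) computeRawScore(g, harmonizeWeights(def, g, "keep"))
fdr   <- ScoreDefinition("fdr", study$sumstats[study$sumstats$p_value < 1e-3, ])
dense <- ScoreDefinition("dense",
                         simulateSummaryStats(study$genotypes, study$truth,
                                              5000, seed = 41))
model <- fitMetaScore(list(genomewide = score_on(derived$best, train),
                           fdr = score_on(fdr, train),
                           dense = score_on(dense, train)),
                      study$training_cohort)
meta  <- applyMetaScore(list(genomewide = score_on(derived$best, valid),
                             fdr = score_on(fdr, valid),
                             dense = score_on(dense, valid)), model)

outcomes <- buildSurvivalOutcomes(study$validation_cohort, "all_cad")
sex <- study$validation_cohort$sex[match(outcomes$sample_id,
                                         study$validation_cohort$sample_id)]
res <- evaluateScore(meta, outcomes, strata = sex)
```

With seed 1 this run (it is what `scripts/acceptance.R --seed 1` prints)
gives:

```
meta-score: HR/SD 1.41 (1.27-1.57), Q5 vs Q1 HR 2.61, C 0.592, PR-AUC 0.250
```

Reading: each standard deviation of the meta-score multiplies the CAD
hazard by 1.41 in this synthetic validation cohort (the generating
per-SD hazard ratio is 1.71; the estimate is attenuated because the
score is built from noisy summary statistics, not the true effects);
the top score quintile carries 2.6 times the hazard of the bottom
quintile; the sex-stratified concordance is 0.592; and the
precision-recall area of 0.250 sits well above the case prevalence.

## Command line

A thin CLI wraps the same functions
(`system.file("exec", "metapgs", package = "metapgs")`):

```sh
metapgs simulate  --seed 1 --out-dir fixtures/
metapgs qc        --genotypes fixtures/genotypes.tsv --out qc.tsv
metapgs derive    --sumstats fixtures/sumstats.tsv --ld-ref ... --out-score best.score --out-grid grid.tsv
metapgs score     --score-file best.score --genotypes ... --out scores.tsv
metapgs combine   --components a.scores,b.scores --pheno train.tsv --out-model m --out-scores meta.tsv
metapgs phenotype --records records.tsv --assessment assessment.tsv --out pheno.tsv
metapgs evaluate-survival --scores meta.tsv --pheno cohort.tsv --out report.tsv
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch at the given seed — simulate a
mini-study, derive the genome-wide component by grid search on the
n = 3,000 training set, combine three components into a meta-score,
phenotype the validation cohort from its coded records, and evaluate the
meta-score with the survival and classification statistics above —
logging each stage's results, and writes the JSON report to `--out`.
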