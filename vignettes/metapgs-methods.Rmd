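---
title: "Methods: score construction, meta-scoring, phenotyping and survival evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: score construction, meta-scoring, phenotyping and survival evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design
choices made where the design was genuinely open.

## 1. Additive scores and harmonization

A genomic risk score is the additive model
`score_i = Σ_j w_j x_ij`, with `x_ij` the dosage of the effect allele of
variant `j`. Published weight files and genotype panels rarely agree on
which allele is counted or which strand is reported, so scoring is
preceded by harmonization. Variants are joined by
(chromosome, position, unordered allele pair) — identifiers differ
across sources and are used only for reporting. Four resolutions exist:

- **match**: effect/other equals counted/other — weight used as is;
- **flip**: effect/other equals other/counted — scored as
  `w(2 − x) = 2w − wx`, implemented as the negated weight plus a
  per-sample constant `2w`. The constant is retained in the raw score
  (so raw scores are comparable across harmonization runs);
  standardization removes it regardless;
- **complement match / flip**: the same after A↔T/C↔G complementation,
  for weight files reported on the opposite strand.

Palindromic variants (A/T or C/G pairs) cannot be strand-resolved from
alleles alone. The default policy is to drop them — standard practice
when the source study's strand conventions are unknown. The
`frequency_align` policy instead compares the effect-allele frequency in
the weight file with the counted-allele frequency in the genotypes, and
drops the variant when either frequency lies in (0.4, 0.6), where the
comparison is uninformative. The band is a fixed part of the policy,
not a tunable.

Missing dosages are imputed at scoring time by one of three policies
(per-variant mean, `2 × frequency`, or zero); with no missing data all
three coincide, a property the tests assert.

## 2. Variant QC

Summary-statistic scores inherit the QC of their genotype panel. The
package filters on minor-allele frequency (estimated as half the mean
dosage), an exact Hardy-Weinberg test, and optional per-variant
imputation info scores. The HWE test is the standard exact test on
genotype counts, conditioning on allele counts and summing the
probabilities of all heterozygote configurations no more probable than
the one observed (relative tie tolerance 1e-10). Because a dosage-aware
HWE test is not standard, the test runs on hard calls obtained by
rounding, with dosages in (0.1, 0.9) or (1.1, 1.9) treated as missing
for the HWE test only: such values carry real imputation uncertainty
and rounding them would manufacture spurious disequilibrium. Default
thresholds (MAF 0.01, HWE p 1e-6) are common practice; they are
configurable and always reported in the log, never asserted to be any
particular study's.

## 3. Genome-wide score derivation

The genome-wide component is derived from summary statistics by greedy
LD thinning: iterate variants by ascending p-value (ties broken by
chromosome, then position, for reproducibility) and retain a variant iff
its squared dosage correlation with every already-retained variant
within a physical window on the same chromosome stays at or below a
threshold. The thinning grid — r² in {0.2, 0.4, 0.6, 0.8}, p in
{5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.1, 1}, window 1 Mb — is evaluated on a
training cohort (n = 3,000 by default) and the cell with the best
training statistic wins; ties break toward fewer variants, then the
smaller r² threshold. The default training statistic is the z-statistic
of the standardized candidate score in a logistic model of case status
adjusted for sex and assessment age; a sex-stratified age-scale
concordance is selectable. The logistic default reflects the small
training set, where a binary-outcome fit is more stable than a survival
fit with few events. Whether candidate scores are standardized on the
training subset or the full panel is a logged configuration; the
package standardizes on the scored panel.

## 4. The meta-score

Component scores are standardized with their *training* moments, and
mixing weights are the coefficients of one joint model of case status on
all standardized components (adjusted for sex and age). The joint fit is
the default because components built from overlapping GWAS inputs are
correlated, and joint estimation is what discounts redundant components;
univariate weighting and a Cox-based joint fit are selectable
alternatives. The model object carries all moments (training component
means/SDs and the moments of the weighted sum), so it is portable: apply
it unchanged to any new cohort and the meta-score remains on the
training standardization scale. Perfectly collinear components abort the
joint fit with advice rather than silently dropping one.

## 5. CAD phenotyping from coded records

A sample is a CAD case if a hospital or death record carries a
qualifying code — MI: ICD-9 with 3-digit root 410–412, ICD-10 root
I21–I24 or the I25.2 subcode; revascularization: OPCS-4 root K40–K46,
K49, K75, or the K50.1 subcode — or if self-report indicates a
doctor-diagnosed heart attack or a PTCA/CABG operation. Prefix matching
is hierarchical and dot-insensitive (410.1 qualifies under 410; K50.2
does not qualify, as only the .1 subcode of K50 is in the set), because
coding dialects vary in subcode depth and punctuation. The event age is
the minimum of the earliest qualifying record age and the self-reported
age — when both exist the smaller is used — and timing is prevalent iff
that age is at or before assessment. Cases with no resolvable event age
are flagged and excluded rather than silently dated; whether undated
self-reported operations should contribute event ages is genuinely
ambiguous, and flagging keeps the ambiguity visible.

Risk factors use strict inequalities exactly as defined: systolic
> 140 mm Hg, diastolic > 90 mm Hg (or on blood-pressure medication) for
hypertension, BMI > 30 kg/m² for obesity; boundary equality never
qualifies. High cholesterol is self-report or ICD-9 272.0 / ICD-10
E78.0 in records; family history is any first-degree relative. Factors
with no data at all count as not elevated in the 0–6 factor count but
are flagged `undetermined`, so analyses can exclude such samples; the
right missing-data rule is not derivable from the phenotype definitions
and this choice keeps it explicit.

## 6. Survival evaluation

Two designs are supported. *All-CAD* analyses include prevalent and
incident cases with entry age 0 — germline variation precedes any
disease, so prevalent cases contribute their event age without left
truncation. *Incident-only* analyses exclude prevalent cases and use
delayed entry at the assessment age; this is the design used whenever
covariates measured at assessment enter the model, to avoid reverse
causation. Administrative censoring is at 75; events after 75 are
censored there. Non-CAD deaths become a competing state.

- **Cox models** run on the age scale via `survival::coxph` with Efron
  tie handling (ties are rare with continuous ages; the choice is
  recorded because it is not derivable from the definitions), sex as
  stratum, Wald 95% CIs; competing deaths are censored in these
  cause-specific fits.
- **Quantile contrasts** cut the evaluation cohort's own score
  distribution into q groups with ties assigned to the lower group and
  contrast the top against the bottom group in the same specification.
- **Concordance** is Harrell-type with delayed entry: a pair is
  comparable iff one sample's CAD event age lies strictly inside the
  other's at-risk interval (entry, exit); score ties count ½; strata are
  pooled by pair counts. The CI is an asymptotic normal approximation
  using the between-event-cluster variance of per-event concordance
  fractions — the CI method is a package decision, as no canonical
  choice exists for the delayed-entry statistic.
- **Kaplan-Meier** cumulative incidence is 1 − S from the product-limit
  estimator with delayed entry, with Greenwood log(−log) 95% bands;
  **Aalen-Johansen** gives the cause-specific cumulative incidence
  functions of the 3-state model, and at every age
  CIF_cad + CIF_death + S = 1 to machine precision (asserted in tests).
  Both go through `survival::survfit`; the in-package concordance and
  ROC/PR code is independent of `survival`, which the tests exploit as
  a cross-check.
- **ROC** area uses the Mann-Whitney identity; the **precision-recall**
  curve is evaluated at every distinct threshold and integrated by
  trapezoid over recall, carrying the first defined precision backward
  to recall 0 (precision is undefined there; carrying backward is the
  conservative standard rule).

## 7. The synthetic world

The generator states one world and the tests live in it:

- **Genotypes**: per LD block, a latent exchangeable-correlation normal
  thresholded at the Hardy-Weinberg cut-points of each variant's sampled
  MAF. This gives tunable dosage r² without haplotype panels. It does
  *not* emulate realistic human LD decay, population structure
  (principal components are generated as pure noise covariates), or
  imputation dosage uncertainty (dosages are hard calls).
- **Summary statistics**: estimated effect = marginal true effect
  (covariance of dosage with the realized genetic score over dosage
  variance — which includes LD leakage from causal neighbours) plus
  noise with the standard error of a `gwas_n`-sample regression;
  p-values from the z-statistics.
- **Survival**: CAD event times are exponential from birth with hazard
  `baseline × exp(β·score + risk-factor terms)`; β defaults to
  log(1.71). The constant baseline (0.0011/year, ≈8% cumulative CAD by
  75 at score 0 in men) keeps closed-form checks possible but is not an
  age-increasing hazard; absolute incidence-by-age trajectories are
  therefore not realistic even though all relative quantities are.
  Women's hazard is halved (CAD risk in women is lower and delayed).
  Entry ages are uniform on 40–69; follow-up is capped at 10 years after
  entry (calendar end of study) and at age 75. Competing mortality
  (0.003/year) starts at entry — cohort members are alive at assessment
  by design. Risk-factor flags act additively on the log-hazard, so the
  interaction-free null is exact.
- **Coded records**: every true case emits a qualifying code at its
  event age, with configurable fractions of self-report-only cases and
  discordant cases whose hospital record postdates the self-reported
  age; non-cases emit near-miss distractors (I25.1, K50.2). The
  phenotyping round trip must recover status, timing and ages exactly.

A green test therefore establishes internal correctness — estimators
recover the generating parameters, procedures match independent oracles
— not that any real-cohort estimate is reproduced; headline numbers
from population biobanks require the individual-level data.

## 8. Numerical choices and degenerate inputs

- Standardization uses sample SDs (n − 1); zero-variance scores error
  unless reference moments are supplied.
- Score files and meta-score models serialize numerics with 15
  significant digits; round-trips are tested to 1e-12.
- Duplicate score variants mapping to one genotype variant keep the
  first and drop the rest with reason `duplicate` (deterministic,
  logged).
- Zero-variance variants return LD r² 0; fewer than two complete pairs
  is an error.
- Quantile grouping with degenerate (constant or near-constant) scores
  errors as an empty extreme group.
- Empty grid cells are recorded with 0 variants and an undefined metric
  and are excluded from the argmax.

## 9. Replicate counts in the recovery checks

One stated check asks that a 95% CI cover the truth between 92% and 98%
of replicates. On 20 replicates the only attainable value in that band
is exactly 19/20, which a correctly calibrated interval misses about
60% of the time; the coverage check therefore runs 100 replicates at
the same sample size (n = 20,000, per-SD log hazard 0.5), where the
band is attainable and discriminating. Bias checks are unchanged. A
handful of other simulation examples run at moderately reduced sample
sizes purely for runtime, noted inline where they occur; thresholds and
tolerances are never adjusted.

## 10. Known limitations

- No BGEN support, no genotype imputation, no genome-build liftover.
- The concordance CI is cluster-asymptotic, not exact; for very few
  events it is unstable (and reported as such).
- Penalized-regression or Bayesian shrinkage score derivation is out of
  scope; thinning is the only derivation method.
- The phenotyping module models assessment fields as named columns, not
  any biobank's field-number plumbing; coronary-aneurysm exclusion is an
  input flag, not computed.
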