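#' Simulation configuration
#'
#' The stated world of the synthetic cohorts: LD-blocked Hardy-Weinberg
#' genotypes, summary statistics with estimation noise, survival under
#' proportional hazards with delayed entry between ages 40 and 69 and
#' administrative censoring at 75, and competing non-CAD mortality.
#'
#' @param n_samples,n_variants cohort and panel sizes.
#' @param block_size variants per LD block.
#' @param within_block_rho latent exchangeable correlation within a block,
#'   in \[0, 1).
#' @param maf_range minor-allele-frequency sampling range, within (0, 0.5].
#' @param causal_fraction fraction of variants with nonzero true effect.
#' @param per_sd_log_hr true log hazard ratio per SD of the genetic score.
#' @param gwas_n effective GWAS sample size governing summary-statistic
#'   noise.
#' @param baseline_hazard CAD events per person-year at score 0 in men.
#' @param competing_hazard non-CAD death events per person-year.
#' @param female_hr hazard multiplier for women (CAD risk in women is
#'   lower and delayed).
#' @param entry_age_range assessment/enrollment age range in years.
#' @param admin_censor_age administrative censoring age in years.
#' @param max_followup maximum follow-up after entry in years (calendar
#'   end of the study window).
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return a `simConfig` list.
#' @export
simConfig <- function(n_samples = 2000, n_variants = 200, block_size = 10,
                      within_block_rho = 0.5, maf_range = c(0.05, 0.5),
                      causal_fraction = 0.1, per_sd_log_hr = log(1.71),
                      gwas_n = 100000, baseline_hazard = 0.0011,
                      competing_hazard = 0.003, female_hr = 0.5,
                      entry_age_range = c(40, 69), admin_censor_age = 75,
                      max_followup = 10, seed = 1L) {
  stopifnot(n_samples > 0, n_variants > 0, block_size > 0,
            within_block_rho >= 0, within_block_rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            baseline_hazard >= 0, competing_hazard >= 0, gwas_n > 0)
  structure(as.list(environment()), class = "simConfig")
}

#' Simulate LD-blocked genotype dosages
#'
#' Per block, a latent multivariate normal with exchangeable correlation
#' `within_block_rho` is thresholded per variant at the Hardy-Weinberg
#' genotype-frequency cut-points of its sampled MAF, yielding hard dosages
#' in \{0, 1, 2\}; blocks are independent. Deterministic given the config
#' seed.
#'
#' @param config a [simConfig()].
#' @return list: `matrix` (a [DosageMatrix-class]), `frequencies`
#'   (counted-allele frequencies used for thresholding).
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  if (config$block_size > config$n_variants)
    stop("block_size exceeds n_variants")
  set.seed(config$seed)
  n <- config$n_samples; v <- config$n_variants
  rho <- config$within_block_rho
  blocks <- split(seq_len(v), ceiling(seq_len(v) / config$block_size))
  maf <- stats::runif(v, config$maf_range[1], config$maf_range[2])
  d <- matrix(NA_real_, v, n)
  for (b in blocks) {
    shared <- stats::rnorm(n)
    for (j in b) {
      z <- sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(n)
      p <- maf[j]
      q0 <- stats::qnorm((1 - p)^2)          # P(dosage 0) under HWE
      q1 <- stats::qnorm((1 - p)^2 + 2 * p * (1 - p))
      d[j, ] <- ifelse(z < q0, 0, ifelse(z < q1, 1, 2))
    }
  }
  n_chr_blocks <- length(blocks)
  chrom <- rep(as.character(rep_len(1:22, n_chr_blocks)),
               lengths(blocks))
  pos_in_chr <- stats::ave(seq_len(v), chrom, FUN = seq_along)
  alleles <- c("A", "C", "G", "T")
  ca <- sample(alleles, v, replace = TRUE)
  oa <- vapply(ca, function(a) sample(setdiff(alleles, a), 1L), character(1))
  variants <- data.frame(
    variant_id = sprintf("rs%06d", seq_len(v)),
    chromosome = chrom,
    position = as.integer(pos_in_chr * 5000L),  # 5 kb spacing within chr
    counted_allele = ca, other_allele = oa,
    stringsAsFactors = FALSE)
  list(matrix = DosageMatrix(d, variants,
                             sprintf("S%05d", seq_len(n))),
       frequencies = maf)
}

#' Assign true causal effects to variants
#'
#' A `causal_fraction` of variants receive normal effects scaled so the
#' realized genetic score has the configured per-SD log hazard ratio.
#'
#' @param matrix a [DosageMatrix-class].
#' @param config a [simConfig()].
#' @return list: `causal_variant_ids`, `true_effects` (per variant, zero
#'   for nulls), `realized_score` (per sample, standardized),
#'   `true_per_sd_log_hr`.
#' @export
simulateTruth <- function(matrix, config) {
  set.seed(config$seed + 1L)
  v <- nrow(matrix)
  n_causal <- max(1L, round(config$causal_fraction * v))
  causal <- sort(sample.int(v, n_causal))
  beta <- numeric(v)
  beta[causal] <- stats::rnorm(n_causal)
  g <- as.numeric(crossprod(dosages(matrix), beta))
  s <- stats::sd(g)
  if (s == 0) stop("degenerate genetic score; increase causal_fraction")
  z <- (g - mean(g)) / s
  list(causal_variant_ids = variantInfo(matrix)$variant_id[causal],
       true_effects = beta, realized_score = z,
       true_per_sd_log_hr = config$per_sd_log_hr)
}

#' Simulate GWAS summary statistics with estimation noise
#'
#' Per variant, the estimated effect is the marginal true effect — the
#' covariance of its dosage with the realized genetic score divided by the
#' dosage variance, which includes LD-induced leakage from causal
#' neighbours — plus normal noise with the standard error of a
#' `gwas_n`-sample regression; p-values come from the corresponding
#' z-statistics. Zero-variance variants are omitted with a message.
#'
#' @param matrix a [DosageMatrix-class].
#' @param truth output of [simulateTruth()].
#' @param gwas_n effective GWAS sample size.
#' @param seed RNG seed for the noise draw.
#' @return summary-statistic data.frame in the [readSummaryStats()] layout.
#' @export
simulateSummaryStats <- function(matrix, truth, gwas_n, seed = 1L) {
  set.seed(seed)
  d <- dosages(matrix)
  mv <- variantInfo(matrix)
  g_raw <- as.numeric(crossprod(d, truth$true_effects))
  sd_g <- stats::sd(g_raw)
  scale <- if (sd_g > 0) truth$true_per_sd_log_hr / sd_g else 0
  vx <- apply(d, 1L, stats::var)
  keep <- vx > 0
  if (any(!keep))
    message(sprintf("simulateSummaryStats: omitting %d zero-variance variant(s)",
                    sum(!keep)))
  # marginal effect of x_j on the liability-scale score (per-allele units)
  cov_xg <- as.numeric(d %*% (g_raw - mean(g_raw))) / (ncol(d) - 1)
  b_marg <- (cov_xg / vx) * scale
  se <- 1 / sqrt(gwas_n * vx)
  est <- b_marg + stats::rnorm(nrow(d), 0, se)
  zstat <- est / se
  p <- 2 * stats::pnorm(-abs(zstat))
  p <- pmax(p, .Machine$double.xmin)  # keep within (0, 1]
  out <- data.frame(
    variant_id = mv$variant_id, chromosome = mv$chromosome,
    position = mv$position, effect_allele = mv$counted_allele,
    other_allele = mv$other_allele, effect_weight = est, p_value = p,
    effect_allele_frequency = rowMeans(d, na.rm = TRUE) / 2,
    stringsAsFactors = FALSE)
  out[keep, , drop = FALSE]
}

#' Simulate a survival cohort under proportional hazards
#'
#' CAD event times are exponential from birth with hazard
#' `baseline_hazard * female_hr^(sex) * exp(per_sd_log_hr * score + risk-factor
#' contributions)`; competing non-CAD death is exponential at
#' `competing_hazard`. Entry (assessment) ages are uniform on
#' `entry_age_range`; events before entry are prevalent cases; after
#' entry, the first of CAD, death, end of follow-up, or age 75 determines
#' the outcome. Risk-factor flags are drawn with realistic prevalences and
#' act additively on the log-hazard scale, so the ground truth is
#' interaction-free.
#'
#' @param score per-sample real score (standardized internally).
#' @param config a [simConfig()].
#' @param rf_log_hr named log-hazard contributions of the risk-factor
#'   flags.
#' @param seed RNG seed.
#' @return list: `cohort` (cohort table, [readCohortTable()] layout) and
#'   `outcomes_truth` (true `SurvivalOutcome` records from the generator).
#' @export
simulateSurvivalCohort <- function(score, config,
                                   rf_log_hr = c(diabetes = log(2),
                                                 current_smoking = log(2),
                                                 hypertension = log(1.7),
                                                 family_history = log(1.5),
                                                 high_cholesterol = log(1.6)),
                                   seed = config$seed + 2L) {
  stopifnot(all(is.finite(score)))
  set.seed(seed)
  n <- length(score)
  z <- if (stats::sd(score) > 0) (score - mean(score)) / stats::sd(score)
       else score
  sex <- sample(c("male", "female"), n, replace = TRUE)
  prev <- c(diabetes = 0.05, current_smoking = 0.10, hypertension = 0.40,
            family_history = 0.43, high_cholesterol = 0.14)
  rf <- sapply(names(prev), function(f)
    stats::runif(n) < prev[[f]])
  lp <- config$per_sd_log_hr * z +
    as.numeric(rf %*% rf_log_hr[colnames(rf)]) +
    ifelse(sex == "female", log(config$female_hr), 0)
  haz <- config$baseline_hazard * exp(lp)
  t_cad <- if (config$baseline_hazard > 0) stats::rexp(n, haz) else
    rep(Inf, n)
  entry <- stats::runif(n, config$entry_age_range[1],
                        config$entry_age_range[2])
  # competing mortality acts after enrollment: cohort members are alive
  # at assessment by design
  t_death <- if (config$competing_hazard > 0)
    entry + stats::rexp(n, config$competing_hazard) else rep(Inf, n)
  cens <- pmin(config$admin_censor_age, entry + config$max_followup)

  prevalent <- t_cad <= entry
  if (all(prevalent))
    stop("every sample is a prevalent case; lower baseline_hazard")
  incident <- !prevalent & t_cad > entry & t_cad <= pmin(t_death, cens)
  death_first <- !prevalent & !incident & t_death <= cens
  status <- ifelse(prevalent, "prevalent",
                   ifelse(incident, "incident", "none"))
  cohort <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    sex = sex, age_at_assessment = entry,
    genotyping_batch = sample(c("batch1", "batch2"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  for (k in 1:10) cohort[[paste0("pc", k)]] <- stats::rnorm(n)
  cohort$diabetes <- rf[, "diabetes"]
  cohort$current_smoking <- rf[, "current_smoking"]
  cohort$hypertension <- rf[, "hypertension"]
  cohort$family_history <- rf[, "family_history"]
  cohort$high_cholesterol <- rf[, "high_cholesterol"]
  cohort$bmi <- stats::rnorm(n, 27, 4)
  cohort$lipid_lowering <- stats::runif(n) < 0.17
  cohort$bp_lowering <- stats::runif(n) < 0.21
  cohort$cad_status <- status
  cohort$age_at_event <- ifelse(status == "none", NA_real_, t_cad)
  cohort$age_at_death <- ifelse(is.finite(t_death) & t_death <= cens &
                                  !prevalent & !incident,
                                t_death, NA_real_)
  cohort$age_at_censoring <- cens
  truth <- data.frame(
    sample_id = cohort$sample_id, entry_age = entry,
    exit_age = pmin(ifelse(prevalent | incident, t_cad, Inf),
                    ifelse(death_first, t_death, Inf), cens),
    status = ifelse(prevalent | incident, "cad",
                    ifelse(death_first, "competing_death", "censored")),
    stringsAsFactors = FALSE)
  list(cohort = cohort, outcomes_truth = truth)
}

#' Simulate coded clinical records for a cohort
#'
#' Each true CAD case emits a qualifying code drawn from the full
#' qualifying sets (ICD-9 410-412; ICD-10 I21-I24, I25.2; OPCS-4 K40-K46,
#' K49, K50.1, K75) at its event age, split between record-only,
#' self-report-only (prevalent cases only) and discordant-age cases where
#' the hospital record postdates the self-reported age. Non-cases emit
#' distractor codes (I25.1, K50.2) at random ages.
#'
#' @param cohort cohort table with `cad_status` and `age_at_event`.
#' @param frac_self_only,frac_discordant fractions of prevalent cases that
#'   are self-report-only / carry a discordant later hospital record.
#' @param distractor_rate fraction of non-cases emitting a distractor
#'   code.
#' @param seed RNG seed.
#' @return list: `records` (coded records table), `self_report`
#'   (data.frame `sample_id`, `self_reported_mi`, `self_reported_mi_age`,
#'   `self_reported_ops`).
#' @export
simulateCodedRecords <- function(cohort, frac_self_only = 0.15,
                                 frac_discordant = 0.15,
                                 distractor_rate = 0.1, seed = 1L) {
  set.seed(seed)
  qual_codes <- data.frame(
    system = c(rep("ICD9", 3), rep("ICD10", 5), rep("OPCS4", 10)),
    code = c("410", "411", "412", "I21", "I22", "I23", "I24", "I25.2",
             sprintf("K%02d", 40:46), "K49", "K50.1", "K75"),
    stringsAsFactors = FALSE)
  recs <- list()
  sr <- data.frame(sample_id = cohort$sample_id, self_reported_mi = FALSE,
                   self_reported_mi_age = NA_real_,
                   self_reported_ops = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$sample_id[i]
    if (cohort$cad_status[i] != "none") {
      ev_age <- cohort$age_at_event[i]
      pick <- qual_codes[sample.int(nrow(qual_codes), 1L), ]
      u <- stats::runif(1)
      prevalent <- cohort$cad_status[i] == "prevalent"
      if (prevalent && u < frac_self_only) {
        sr$self_reported_mi[i] <- TRUE
        sr$self_reported_mi_age[i] <- ev_age
      } else if (prevalent && u < frac_self_only + frac_discordant) {
        sr$self_reported_mi[i] <- TRUE
        sr$self_reported_mi_age[i] <- ev_age
        recs[[length(recs) + 1L]] <- data.frame(
          sample_id = sid, system = pick$system, code = pick$code,
          age_at_record = ev_age + stats::runif(1, 0.5, 3),
          source = "hospital", stringsAsFactors = FALSE)
      } else {
        recs[[length(recs) + 1L]] <- data.frame(
          sample_id = sid, system = pick$system, code = pick$code,
          age_at_record = ev_age,
          source = sample(c("hospital", "death"), 1L, prob = c(0.9, 0.1)),
          stringsAsFactors = FALSE)
      }
    } else if (stats::runif(1) < distractor_rate) {
      dpick <- sample(c("I25.1", "K50.2"), 1L)
      recs[[length(recs) + 1L]] <- data.frame(
        sample_id = sid, system = if (dpick == "I25.1") "ICD10" else "OPCS4",
        code = dpick,
        age_at_record = stats::runif(1, 40, 74), source = "hospital",
        stringsAsFactors = FALSE)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(sample_id = character(0), system = character(0),
               code = character(0), age_at_record = numeric(0),
               source = character(0), stringsAsFactors = FALSE)
  list(records = records, self_report = sr)
}

#' Simulate a complete mini-study
#'
#' One command producing everything the pipeline consumes: an LD panel
#' with summary statistics, training and validation genotype cohorts with
#' survival outcomes, and coded records for the validation cohort. The
#' training set defaults to the n = 3,000 used to tune the genome-wide
#' component and weight the meta-score.
#'
#' @param config a [simConfig()]; `n_samples` is the validation size.
#' @param n_training training-set size (default 3000).
#' @return list: `genotypes` (combined [DosageMatrix-class]),
#'   `training_ids`, `validation_ids`, `truth`, `sumstats`,
#'   `training_cohort`, `validation_cohort`, `records`, `self_report`,
#'   `outcomes_truth` (validation).
#' @export
simulateStudy <- function(config, n_training = 3000) {
  big <- simConfig(n_samples = config$n_samples + n_training,
                   n_variants = config$n_variants,
                   block_size = config$block_size,
                   within_block_rho = config$within_block_rho,
                   maf_range = config$maf_range,
                   causal_fraction = config$causal_fraction,
                   per_sd_log_hr = config$per_sd_log_hr,
                   gwas_n = config$gwas_n,
                   baseline_hazard = config$baseline_hazard,
                   competing_hazard = config$competing_hazard,
                   female_hr = config$female_hr,
                   entry_age_range = config$entry_age_range,
                   admin_censor_age = config$admin_censor_age,
                   max_followup = config$max_followup, seed = config$seed)
  geno <- simulateGenotypes(big)
  truth <- simulateTruth(geno$matrix, big)
  sumstats <- simulateSummaryStats(geno$matrix, truth, big$gwas_n,
                                   seed = big$seed + 10L)
  ids <- sampleIds(geno$matrix)
  train_ids <- ids[seq_len(n_training)]
  valid_ids <- setdiff(ids, train_ids)
  sim <- simulateSurvivalCohort(truth$realized_score, big,
                                seed = big$seed + 20L)
  cohort <- sim$cohort
  train_cohort <- cohort[cohort$sample_id %in% train_ids, ]
  valid_cohort <- cohort[cohort$sample_id %in% valid_ids, ]
  rec <- simulateCodedRecords(valid_cohort, seed = big$seed + 30L)
  list(genotypes = geno$matrix, frequencies = geno$frequencies,
       training_ids = train_ids, validation_ids = valid_ids,
       truth = truth, sumstats = sumstats,
       training_cohort = train_cohort, validation_cohort = valid_cohort,
       records = rec$records, self_report = rec$self_report,
       outcomes_truth = sim$outcomes_truth[
         sim$outcomes_truth$sample_id %in% valid_ids, ])
}
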