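#' Build survival outcomes on the age time scale
#'
#' Converts a cohort table into (entry age, exit age, status) records for
#' age-as-time-scale analysis, censored administratively at 75 years.
#' `all_cad` analyses include prevalent and incident cases with entry age 0
#' (germline risk precedes any disease); `incident_only` analyses exclude
#' prevalent cases and use delayed entry at the assessment age, the design
#' used whenever conventional risk factors measured at assessment enter
#' the model (avoiding reverse causation). Non-CAD deaths before 75 become
#' `competing_death`; events after 75 are censored at 75.
#'
#' @param cohort cohort table ([readCohortTable()] layout).
#' @param analysis `"all_cad"` or `"incident_only"`.
#' @param censor_age administrative censoring age (default 75).
#' @return data.frame: `sample_id`, `entry_age`, `exit_age`, `status`
#'   (`cad` / `competing_death` / `censored`).
#' @export
buildSurvivalOutcomes <- function(cohort,
                                  analysis = c("all_cad", "incident_only"),
                                  censor_age = 75) {
  analysis <- match.arg(analysis)
  tab <- cohort
  if (analysis == "incident_only")
    tab <- tab[tab$cad_status != "prevalent", , drop = FALSE]
  entry <- if (analysis == "all_cad") rep(0, nrow(tab))
           else tab$age_at_assessment
  cens <- pmin(ifelse(is.na(tab$age_at_censoring), censor_age,
                      tab$age_at_censoring), censor_age)
  event <- tab$age_at_event
  death <- tab$age_at_death
  exit <- cens
  status <- rep("censored", nrow(tab))
  has_death <- !is.na(death) & death <= cens
  status[has_death] <- "competing_death"
  exit[has_death] <- death[has_death]
  is_event <- !is.na(event) & event <= censor_age &
    event <= ifelse(has_death, death, cens)
  status[is_event] <- "cad"
  exit[is_event] <- event[is_event]
  out <- data.frame(sample_id = tab$sample_id, entry_age = entry,
                    exit_age = exit, status = status,
                    stringsAsFactors = FALSE)
  bad <- out$exit_age <= out$entry_age
  if (any(bad)) {
    warning(sprintf("dropping %d sample(s) with exit <= entry", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

.cox_df <- function(score, outcomes, covariates, strata) {
  score <- .as_score_values(score, outcomes$sample_id)
  df <- data.frame(entry = outcomes$entry_age, exit = outcomes$exit_age,
                   event = outcomes$status == "cad", score = score)
  if (!is.null(strata)) df$sex_stratum <- strata
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == nrow(df))
    df <- cbind(df, covariates)
  }
  df
}

.as_score_values <- function(score, ids) {
  if (is(score, "ScoreVector")) {
    v <- standardizedScores(score)
    if (!all(ids %in% names(v))) stop("score does not cover all samples")
    return(as.numeric(v[ids]))
  }
  stopifnot(length(score) == length(ids))
  as.numeric(score)
}

.cox_fit <- function(df, main_terms) {
  main_cols <- unique(unlist(strsplit(main_terms, ":", fixed = TRUE)))
  extra <- setdiff(names(df),
                   c("entry", "exit", "event", "sex_stratum", main_cols))
  rhs <- c(main_terms, extra)
  if ("sex_stratum" %in% names(df))
    rhs <- c(rhs, "survival::strata(sex_stratum)")
  fml <- stats::as.formula(paste(
    "survival::Surv(entry, exit, event) ~", paste(rhs, collapse = " + ")))
  survival::coxph(fml, data = df, ties = "efron")
}

.wald_summary <- function(fit, term) {
  co <- summary(fit)$coefficients
  est <- co[term, "coef"]; se <- co[term, "se(coef)"]
  list(hr = exp(est), ci_lower = exp(est - 1.96 * se),
       ci_upper = exp(est + 1.96 * se), log_hr = est, se = se,
       p = co[term, "Pr(>|z|)"], n_events = fit$nevent)
}

#' Per-SD hazard ratio from a sex-stratified age-scale Cox model
#'
#' Proportional-hazards fit on the age time scale honoring delayed entry,
#' with sex as stratum, Efron tie handling, and Wald 95% CI; competing
#' deaths are treated as censoring in this cause-specific model.
#'
#' @param score standardized [ScoreVector-class] or numeric vector aligned
#'   with `outcomes`.
#' @param outcomes output of [buildSurvivalOutcomes()].
#' @param covariates optional data.frame of adjustment covariates
#'   (genotyping batch, principal components, risk factors), row-aligned
#'   with `outcomes`.
#' @param strata optional sex vector, row-aligned with `outcomes`.
#' @return list: `hr`, `ci_lower`, `ci_upper`, `log_hr`, `se`, `p`,
#'   `n_events`.
#' @export
fitPerSdHR <- function(score, outcomes, covariates = NULL, strata = NULL) {
  df <- .cox_df(score, outcomes, covariates, strata)
  if (stats::var(df$score) == 0) stop("score is constant")
  if (!is.null(strata)) {
    ev <- tapply(df$event, strata, sum)
    if (any(ev < 2)) stop("need >= 2 events per stratum")
  }
  fit <- .cox_fit(df, "score")
  .wald_summary(fit, "score")
}

#' Hazard ratio between extreme score quantile groups
#'
#' Assigns samples to `q` quantile groups of the evaluation cohort's own
#' score distribution (ties to the lower group) and contrasts the top
#' against the bottom group in the same Cox specification as
#' [fitPerSdHR()] (the "top 20% vs bottom 20%" style contrast when
#' `q = 5`).
#'
#' @inheritParams fitPerSdHR
#' @param q number of quantile groups (default 5).
#' @return list as in [fitPerSdHR()], plus `group` (the per-sample group
#'   index 1..q).
#' @export
quantileContrastHR <- function(score, outcomes, covariates = NULL,
                               strata = NULL, q = 5) {
  stopifnot(q >= 2)
  df <- .cox_df(score, outcomes, covariates, strata)
  brk <- unique(stats::quantile(df$score,
                                probs = seq(0, 1, length.out = q + 1)))
  if (length(brk) < 3) stop("empty extreme quantile group")
  grp <- cut(df$score, breaks = brk, include.lowest = TRUE,
             right = TRUE, labels = FALSE)
  if (max(grp) < q || min(grp) > 1 || !any(grp == 1) || !any(grp == max(grp)))
    stop("empty extreme quantile group")
  df$score <- NULL
  df$qgroup <- factor(grp)
  fit <- .cox_fit(df, "qgroup")
  res <- .wald_summary(fit, sprintf("qgroup%d", max(grp)))
  res$group <- grp
  res
}

#' Score-by-factor interaction in the Cox model
#'
#' Adds a product term between the score and a boolean or continuous
#' factor to the adjusted model and reports the interaction hazard ratio
#' with Wald CI and p-value.
#'
#' @inheritParams fitPerSdHR
#' @param factor logical or numeric vector, row-aligned with `outcomes`.
#' @return list: `hr`, `ci_lower`, `ci_upper`, `log_hr`, `se`, `p`.
#' @export
fitInteraction <- function(score, factor, outcomes, covariates = NULL,
                           strata = NULL) {
  if (length(unique(factor)) < 2L) stop("interaction factor is constant")
  df <- .cox_df(score, outcomes, covariates, strata)
  df$fct <- as.numeric(factor)
  fit <- .cox_fit(df, c("score", "fct", "score:fct"))
  .wald_summary(fit, "score:fct")
}

#' Sex-stratified Harrell concordance on the age scale
#'
#' A pair is comparable iff one sample has a CAD event at an age strictly
#' inside the other's at-risk interval (entry, exit); pairs are counted
#' within sex strata and pooled by pair counts. Concordant means the
#' event-bearing sample has the higher score; score ties count 0.5. The CI
#' is an asymptotic normal approximation using a between-event-cluster
#' variance of the per-event concordance fractions.
#'
#' @inheritParams fitPerSdHR
#' @param strata optional stratum vector (sex), row-aligned; NULL = one
#'   stratum.
#' @return list: `c_index`, `se`, `ci_lower`, `ci_upper`, `n_pairs`.
#' @export
concordanceIndex <- function(score, outcomes, strata = NULL) {
  s <- .as_score_values(score, outcomes$sample_id)
  if (is.null(strata)) strata <- rep("all", nrow(outcomes))
  conc_tot <- 0; pair_tot <- 0
  frac <- numeric(0); wt <- numeric(0)
  for (st in unique(strata)) {
    sel <- strata == st
    sc <- s[sel]
    entry <- outcomes$entry_age[sel]; exit <- outcomes$exit_age[sel]
    ev <- which(outcomes$status[sel] == "cad")
    for (i in ev) {
      at_risk <- which(entry < exit[i] & exit > exit[i])
      if (!length(at_risk)) next
      n_conc <- sum(sc[i] > sc[at_risk]) + 0.5 * sum(sc[i] == sc[at_risk])
      conc_tot <- conc_tot + n_conc
      pair_tot <- pair_tot + length(at_risk)
      frac <- c(frac, n_conc / length(at_risk))
      wt <- c(wt, length(at_risk))
    }
  }
  if (pair_tot == 0) stop("no comparable pairs")
  c_index <- conc_tot / pair_tot
  w <- wt / sum(wt)
  k <- length(frac)
  se <- if (k > 1)
    sqrt(sum(w^2 * (frac - c_index)^2) * k / (k - 1)) else NA_real_
  list(c_index = c_index, se = se,
       ci_lower = max(0, c_index - 1.96 * se),
       ci_upper = min(1, c_index + 1.96 * se), n_pairs = pair_tot)
}

#' Kaplan-Meier cumulative incidence with delayed entry
#'
#' Product-limit estimate on the age scale (risk set = entered and not yet
#' exited), reported as cumulative incidence 1 - S with pointwise 95%
#' bands from the Greenwood variance on the log(-log) scale.
#'
#' @param outcomes output of [buildSurvivalOutcomes()] for one group.
#' @return data.frame: `age`, `incidence`, `ci_lower`, `ci_upper`,
#'   `n_risk`.
#' @export
kmCurve <- function(outcomes) {
  stopifnot(nrow(outcomes) > 0)
  fit <- survival::survfit(
    survival::Surv(entry_age, exit_age, status == "cad") ~ 1,
    data = outcomes, conf.type = "log-log")
  data.frame(age = fit$time, incidence = 1 - fit$surv,
             ci_lower = 1 - ifelse(is.na(fit$upper), 1, fit$upper),
             ci_upper = 1 - ifelse(is.na(fit$lower), 1, fit$lower),
             n_risk = fit$n.risk)
}

#' Aalen-Johansen cause-specific cumulative incidence
#'
#' Three-state estimator (CAD, non-CAD death, censored) on the age scale
#' with delayed entry. At every age the two cumulative incidence functions
#' and the overall survival sum to 1.
#'
#' @param outcomes output of [buildSurvivalOutcomes()].
#' @return list of data.frames `cad` and `competing_death`, each with
#'   `age`, `incidence`, `ci_lower`, `ci_upper`, plus `survival`
#'   (data.frame `age`, `surv`).
#' @export
aalenJohansen <- function(outcomes) {
  stopifnot(nrow(outcomes) > 0)
  st <- factor(outcomes$status,
               levels = c("censored", "cad", "competing_death"))
  fit <- survival::survfit(
    survival::Surv(outcomes$entry_age, outcomes$exit_age, st) ~ 1)
  states <- fit$states
  get_cif <- function(state) {
    j <- match(state, states)
    data.frame(age = fit$time, incidence = fit$pstate[, j],
               ci_lower = fit$lower[, j], ci_upper = fit$upper[, j])
  }
  s0 <- match("(s0)", states)
  list(cad = get_cif("cad"),
       competing_death = get_cif("competing_death"),
       survival = data.frame(age = fit$time, surv = fit$pstate[, s0]))
}

#' ROC and precision-recall areas
#'
#' ROC area by the Mann-Whitney pair-counting identity (score ties count
#' 0.5); the precision-recall curve is evaluated at every distinct score
#' threshold, the undefined precision at recall 0 carries the first
#' defined precision backward, and its area is trapezoidal numerical
#' integration over recall. The PR baseline area equals the outcome
#' prevalence.
#'
#' @param score numeric predictions (higher = more case-like).
#' @param labels logical or 0/1 case labels.
#' @param reference optional second prediction vector (e.g. a reference
#'   model's linear predictor) evaluated the same way for comparison.
#' @return list: `roc_auc`, `pr_auc`, `pr_curve` (data.frame `recall`,
#'   `precision`), and when `reference` is given `reference_roc_auc`,
#'   `reference_pr_auc`.
#' @export
rocPrCurves <- function(score, labels, reference = NULL) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both classes must be present")
  one <- function(sc) {
    pos <- sc[labels]; neg <- sc[!labels]
    r <- rank(c(pos, neg))
    auc <- (sum(r[seq_along(pos)]) -
              length(pos) * (length(pos) + 1) / 2) /
      (length(pos) * length(neg))
    ord <- order(sc, decreasing = TRUE)
    lab <- labels[ord]
    sc_sorted <- sc[ord]
    last <- !duplicated(sc_sorted, fromLast = TRUE)  # threshold boundaries
    tp <- cumsum(lab)[last]
    n_pred <- seq_along(lab)[last]
    recall <- tp / sum(labels)
    precision <- tp / n_pred
    recall <- c(0, recall)
    precision <- c(precision[1L], precision)  # carry first value backward
    pr_auc <- sum(diff(recall) * (utils::head(precision, -1) +
                                    utils::tail(precision, -1)) / 2)
    list(auc = auc, pr_auc = pr_auc,
         curve = data.frame(recall = recall, precision = precision))
  }
  main <- one(as.numeric(score))
  out <- list(roc_auc = main$auc, pr_auc = main$pr_auc,
              pr_curve = main$curve)
  if (!is.null(reference)) {
    ref <- one(as.numeric(reference))
    out$reference_roc_auc <- ref$auc
    out$reference_pr_auc <- ref$pr_auc
  }
  out
}

#' Age at which a cumulative-incidence curve reaches a risk threshold
#'
#' @param curve data.frame with `age` and `incidence` (e.g. [kmCurve()]).
#' @param threshold risk fraction in (0, 1).
#' @return smallest curve age with incidence >= threshold, or NA when the
#'   threshold is never reached.
#' @export
ageAtCumulativeRisk <- function(curve, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  hit <- which(curve$incidence >= threshold)
  if (!length(hit)) return(NA_real_)
  curve$age[min(hit)]
}

#' One-call survival and classification evaluation of a score
#'
#' Bundles the per-SD hazard ratio, top-vs-bottom quantile contrast,
#' sex-stratified concordance, and ROC / precision-recall areas for one
#' standardized score.
#'
#' @inheritParams fitPerSdHR
#' @param q quantile groups for the extreme contrast (default 5).
#' @return list of the component results plus `n_cases`, `n_noncases`.
#' @export
evaluateScore <- function(score, outcomes, covariates = NULL,
                          strata = NULL, q = 5) {
  s <- .as_score_values(score, outcomes$sample_id)
  is_case <- outcomes$status == "cad"
  list(hr_per_sd = fitPerSdHR(s, outcomes, covariates, strata),
       quantile_contrast = quantileContrastHR(s, outcomes, covariates,
                                              strata, q = q),
       c_index = concordanceIndex(s, outcomes, strata),
       classification = rocPrCurves(s, is_case),
       n_cases = sum(is_case), n_noncases = sum(!is_case))
}
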