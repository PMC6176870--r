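test_that("survival outcomes implement the all-CAD / incident-only designs", {
  cohort <- data.frame(
    sample_id = c("prev", "inc", "late", "dead", "clean"),
    sex = "male", age_at_assessment = c(60, 60, 60, 60, 60),
    cad_status = c("prevalent", "incident", "incident", "none", "none"),
    age_at_event = c(54, 63, 77, NA, NA),
    age_at_death = c(NA, NA, NA, 70, NA),
    age_at_censoring = c(70, 70, 80, 70, 70),
    stringsAsFactors = FALSE)
  all_cad <- buildSurvivalOutcomes(cohort, "all_cad")
  expect_equal(all_cad$entry_age, rep(0, 5))
  expect_equal(all_cad$status[all_cad$sample_id == "prev"], "cad")
  expect_equal(all_cad$exit_age[all_cad$sample_id == "prev"], 54)
  expect_equal(all_cad$status[all_cad$sample_id == "dead"],
               "competing_death")
  expect_equal(all_cad$exit_age[all_cad$sample_id == "dead"], 70)
  # event at 77 is censored at 75
  expect_equal(all_cad$status[all_cad$sample_id == "late"], "censored")
  expect_equal(all_cad$exit_age[all_cad$sample_id == "late"], 75)

  inc <- buildSurvivalOutcomes(cohort, "incident_only")
  expect_false("prev" %in% inc$sample_id)
  expect_equal(inc$entry_age[inc$sample_id == "inc"], 60)
  expect_equal(inc$exit_age[inc$sample_id == "inc"], 63)
})

test_that("the Cox per-SD model recovers a null effect with nominal coverage", {
  # invariant grid's smallest setting: log-HR 0, n = 5,000, 100 replicates
  covered <- 0L; est <- numeric(100)
  for (r in 1:100) {
    w <- sim_simple_cohort(5000, beta = 0, seed = 700 + r)
    fit <- fitPerSdHR(w$score, w$outcomes, strata = w$sex)
    est[r] <- fit$log_hr
    if (fit$ci_lower <= 1 && fit$ci_upper >= 1) covered <- covered + 1L
  }
  expect_lt(abs(mean(est)), 0.02)
  expect_gte(covered, 93L)
  w <- sim_simple_cohort(200, beta = 0.3, seed = 1)
  expect_error(fitPerSdHR(rep(1, 200), w$outcomes), "constant")
})

test_that("quantile groups are assigned with ties to the lower group", {
  out <- data.frame(sample_id = sprintf("s%02d", 1:10), entry_age = 0,
                    exit_age = c(seq(50, 68, by = 2)),
                    status = rep(c("cad", "censored"), 5),
                    stringsAsFactors = FALSE)
  # degenerate 10-sample fit cannot converge; only the assignment matters
  res <- suppressWarnings(quantileContrastHR(1:10, out, q = 5))
  expect_equal(unname(res$group), rep(1:5, each = 2))
  expect_error(quantileContrastHR(rep(1, 10), out, q = 5), "empty extreme")
})

test_that("interaction fits flag degenerate factors and recover a known interaction", {
  w <- sim_simple_cohort(500, beta = 0.3, seed = 2)
  expect_error(fitInteraction(w$score, rep(1, 500), w$outcomes), "constant")
  # multiplicative interaction with a binary factor, scaled-down recovery
  est <- numeric(10)
  for (r in 1:10) {
    set.seed(800 + r)
    n <- 8000
    z <- rnorm(n)
    f <- runif(n) < 0.5
    haz <- 0.0015 * exp(0.25 * z + 0.2 * f + 0.3 * z * f)
    t_cad <- rexp(n, haz)
    exit <- pmin(t_cad, 75)
    out <- data.frame(sample_id = sprintf("s%05d", 1:n), entry_age = 0,
                      exit_age = exit,
                      status = ifelse(t_cad <= 75, "cad", "censored"),
                      stringsAsFactors = FALSE)
    est[r] <- fitInteraction(z, f, out)$log_hr
  }
  expect_lt(abs(mean(est) - 0.3), 0.07)
})

test_that("the concordance index matches brute-force pair counting with delayed entry", {
  set.seed(63)
  for (r in 1:20) {
    n <- 200
    entry <- runif(n, 40, 69)
    exit <- entry + rexp(n, 0.15)
    status <- ifelse(runif(n) < 0.5, "cad",
                     ifelse(runif(n) < 0.3, "competing_death", "censored"))
    score <- round(rnorm(n), 1)          # coarse scores force ties
    sex <- sample(c("male", "female"), n, replace = TRUE)
    out <- data.frame(sample_id = sprintf("s%04d", 1:n), entry_age = entry,
                      exit_age = exit, status = status,
                      stringsAsFactors = FALSE)
    got <- concordanceIndex(score, out, strata = sex)
    want <- oracle_concordance(score, entry, exit, status == "cad", sex)
    expect_equal(got$c_index, want$c, tolerance = 1e-12)
    expect_equal(got$n_pairs, want$pairs)
  }
  # perfect ranking: score = negative event age, all events, one stratum
  out <- data.frame(sample_id = c("a", "b", "c"), entry_age = 0,
                    exit_age = c(50, 60, 70), status = "cad",
                    stringsAsFactors = FALSE)
  expect_equal(concordanceIndex(-c(50, 60, 70), out)$c_index, 1)
  # random score hovers at 1/2
  w <- sim_simple_cohort(500, beta = 0, baseline = 0.004, seed = 64)
  ci <- concordanceIndex(rnorm(500), w$outcomes, strata = w$sex)
  expect_lt(abs(ci$c_index - 0.5), 0.05)
})

test_that("concordance agrees with survival::concordance as an independent cross-check", {
  w <- sim_simple_cohort(400, beta = 0.4, baseline = 0.003, seed = 65)
  got <- concordanceIndex(w$score, w$outcomes, strata = w$sex)
  cfit <- survival::concordance(
    survival::Surv(entry_age, exit_age, status == "cad") ~ score +
      survival::strata(sex),
    data = cbind(w$outcomes, score = w$score, sex = w$sex), reverse = TRUE)
  expect_equal(got$c_index, unname(cfit$concordance), tolerance = 1e-10)
})

test_that("Kaplan-Meier cumulative incidence matches the hand product-limit example", {
  out <- data.frame(sample_id = c("a", "b", "c"), entry_age = 0,
                    exit_age = c(1, 2, 3),
                    status = c("cad", "censored", "cad"),
                    stringsAsFactors = FALSE)
  km <- kmCurve(out)
  expect_equal(km$incidence[km$age == 1], 1 / 3)
  expect_equal(km$incidence[km$age == 3], 1)
  no_events <- data.frame(sample_id = c("a", "b"), entry_age = 0,
                          exit_age = c(5, 6), status = "censored",
                          stringsAsFactors = FALSE)
  expect_true(all(kmCurve(no_events)$incidence == 0))
  one_age <- data.frame(sample_id = c("a", "b"), entry_age = 0,
                        exit_age = 4, status = "cad",
                        stringsAsFactors = FALSE)
  expect_equal(kmCurve(one_age)$incidence[1], 1)
})

test_that("Aalen-Johansen matches hand-computed transitions and its identities", {
  out <- data.frame(
    sample_id = letters[1:6], entry_age = 0, exit_age = 1:6,
    status = c("cad", "competing_death", "cad", "censored",
               "competing_death", "censored"),
    stringsAsFactors = FALSE)
  aj <- aalenJohansen(out)
  last <- nrow(aj$cad)
  expect_equal(aj$cad$incidence[aj$cad$age == 1], 1 / 6)
  expect_equal(aj$cad$incidence[last], 1 / 3, tolerance = 1e-12)
  expect_equal(aj$competing_death$incidence[last], 5 / 12,
               tolerance = 1e-12)
  expect_equal(aj$survival$surv[last], 1 / 4, tolerance = 1e-12)
  total <- aj$cad$incidence + aj$competing_death$incidence +
    aj$survival$surv
  expect_equal(total, rep(1, length(total)), tolerance = 1e-12)

  # no competing events: CIF reduces to 1 - KM survival
  w <- sim_simple_cohort(300, beta = 0.2, baseline = 0.003, seed = 66)
  w$outcomes$status[w$outcomes$status == "competing_death"] <- "censored"
  aj2 <- aalenJohansen(w$outcomes)
  km2 <- kmCurve(w$outcomes)
  m <- match(km2$age, aj2$cad$age)
  expect_equal(aj2$cad$incidence[m], km2$incidence, tolerance = 1e-12)

  # no cad events: CIF identically zero
  w$outcomes$status[w$outcomes$status == "cad"] <- "censored"
  w$outcomes$status[1] <- "competing_death"
  aj3 <- aalenJohansen(w$outcomes)
  expect_true(all(aj3$cad$incidence == 0))
})

test_that("shifting entries to zero on truncation-free data changes nothing", {
  w <- sim_simple_cohort(300, beta = 0.4, baseline = 0.004, seed = 67)
  out <- w$outcomes
  out$entry_age <- min(out$exit_age) / 2  # everyone enters before the earliest exit
  out0 <- out; out0$entry_age <- 0
  f1 <- fitPerSdHR(w$score, out, strata = w$sex)
  f2 <- fitPerSdHR(w$score, out0, strata = w$sex)
  expect_equal(f1$log_hr, f2$log_hr, tolerance = 1e-12)
  c1 <- concordanceIndex(w$score, out, strata = w$sex)
  c2 <- concordanceIndex(w$score, out0, strata = w$sex)
  expect_equal(c1$c_index, c2$c_index, tolerance = 1e-12)
  expect_equal(kmCurve(out)$incidence, kmCurve(out0)$incidence,
               tolerance = 1e-12)
})

test_that("ROC and PR areas follow their pair-counting and integration rules", {
  res <- rocPrCurves(1:6, c(0, 0, 1, 0, 1, 1))
  expect_equal(res$roc_auc, 8 / 9)
  perf <- rocPrCurves(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  expect_equal(perf$roc_auc, 1)
  expect_equal(perf$pr_auc, 1)
  set.seed(68)
  lab <- runif(10000) < 0.05
  rnd <- rocPrCurves(rnorm(10000), lab)
  expect_lt(abs(rnd$pr_auc - mean(lab)), 0.02)
  # monotone-transform invariance of the ROC area
  sc <- rnorm(500); lb <- runif(500) < plogis(sc)
  expect_equal(rocPrCurves(sc, lb)$roc_auc,
               rocPrCurves(exp(3 * sc), lb)$roc_auc, tolerance = 1e-12)
  expect_error(rocPrCurves(1:5, rep(1, 5)), "both classes")
  # reference comparison mirrors score-vs-reference PR reporting
  both <- rocPrCurves(sc, lb, reference = rnorm(500))
  expect_true(both$pr_auc > both$reference_pr_auc)
})

test_that("age at cumulative risk is the first step reaching the threshold", {
  curve <- data.frame(age = c(50, 61), incidence = c(0.04, 0.11))
  expect_equal(ageAtCumulativeRisk(curve, 0.10), 61)
  expect_true(is.na(ageAtCumulativeRisk(
    data.frame(age = c(50, 61), incidence = c(0.04, 0.08)), 0.10)))
  expect_equal(ageAtCumulativeRisk(
    data.frame(age = c(50, 61), incidence = c(0.04, 0.10)), 0.10), 61)
})
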