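#' Fit a meta-score from component scores on a training cohort
#'
#' Standardizes each component with its training moments, estimates mixing
#' weights by regressing CAD case status (or age-scale survival) on all
#' standardized components, and records the training moments of the
#' weighted sum so the meta-score itself is standardized. The result is a
#' portable model: training moments travel with it, so it can be applied
#' unchanged to new cohorts.
#'
#' @param components named list of [ScoreVector-class]s over identical
#'   training samples.
#' @param training training cohort table ([readCohortTable()] layout); case
#'   status is `cad_status != "none"`.
#' @param fit_method `"joint_logistic"` (default): one logistic model of
#'   case status on all standardized components, adjusted for sex and
#'   assessment age; `"joint_cox"`: the analogous sex-stratified
#'   proportional-hazards fit on the age scale (all-CAD outcomes);
#'   `"univariate_logistic"`: each component's coefficient from its own
#'   adjusted logistic model.
#' @return A [MetaScoreModel-class].
#' @export
fitMetaScore <- function(components, training,
                         fit_method = c("joint_logistic", "joint_cox",
                                        "univariate_logistic")) {
  fit_method <- match.arg(fit_method)
  stopifnot(is.list(components), length(components) >= 1L,
            !is.null(names(components)), all(nzchar(names(components))))
  ids <- sampleIds(components[[1L]])
  for (sv in components)
    if (!identical(sort(sampleIds(sv)), sort(ids)))
      stop("all components must cover identical samples")
  if (!setequal(ids, training$sample_id))
    stop("component samples must match the training cohort")
  case <- training$cad_status[match(ids, training$sample_id)] != "none"
  if (!any(case) || all(case))
    stop("training cohort needs at least one case and one non-case")

  k <- length(components)
  means <- sds <- numeric(k)
  Z <- matrix(NA_real_, length(ids), k,
              dimnames = list(ids, names(components)))
  for (i in seq_len(k)) {
    raw <- rawScores(components[[i]])[ids]
    means[i] <- mean(raw)
    sds[i] <- stats::sd(raw)
    if (is.na(sds[i]) || sds[i] <= 0)
      stop(sprintf("component '%s' has zero variance", names(components)[i]))
    Z[, i] <- (raw - means[i]) / sds[i]
  }

  sex <- training$sex[match(ids, training$sample_id)]
  age <- training$age_at_assessment[match(ids, training$sample_id)]
  weights <- numeric(k)
  safe <- sprintf("comp_%d", seq_len(k))
  if (fit_method == "joint_logistic") {
    df <- data.frame(case = case, Z, sex = sex, age = age)
    names(df)[1L + seq_len(k)] <- safe
    fml <- stats::as.formula(paste(
      "case ~", paste(c(safe, "sex", "age"), collapse = " + ")))
    fit <- stats::glm(fml, data = df, family = stats::binomial())
    co <- stats::coef(fit)[safe]
    if (anyNA(co))
      stop("components are collinear under the joint fit; use ",
           "univariate_logistic or remove a component")
    weights <- as.numeric(co)
  } else if (fit_method == "joint_cox") {
    out <- buildSurvivalOutcomes(training, analysis = "all_cad")
    m <- match(out$sample_id, ids)
    df <- data.frame(Z[m, , drop = FALSE], sex = sex[m])
    names(df) <- c(safe, "sex")
    df$entry_age <- out$entry_age; df$exit_age <- out$exit_age
    df$status <- out$status
    fml <- stats::as.formula(paste(
      "survival::Surv(entry_age, exit_age, status == 'cad') ~",
      paste(c(safe, "survival::strata(sex)"), collapse = " + ")))
    fit <- survival::coxph(fml, data = df, ties = "efron")
    co <- stats::coef(fit)
    if (anyNA(co))
      stop("components are collinear under the joint fit; use ",
           "univariate_logistic or remove a component")
    weights <- as.numeric(co[safe])
  } else {
    for (i in seq_len(k)) {
      fit <- stats::glm(case ~ z + sex + age,
                        data = data.frame(case = case, z = Z[, i],
                                          sex = sex, age = age),
                        family = stats::binomial())
      weights[i] <- stats::coef(fit)["z"]
    }
  }

  meta_raw <- as.numeric(Z %*% weights)
  fm <- mean(meta_raw); fs <- stats::sd(meta_raw)
  if (is.na(fs) || fs <= 0)
    stop("meta-score has zero variance on the training set")
  new("MetaScoreModel", component_names = names(components),
      component_means = means, component_sds = sds,
      mixing_weights = weights, fit_method = fit_method,
      training_n = length(ids), final_mean = fm, final_sd = fs)
}

#' Apply a fitted meta-score model to component scores
#'
#' Per sample, the weighted sum of the model-standardized components,
#' standardized by the model's final training moments. Deterministic; the
#' components may cover any cohort.
#'
#' @param components named list of [ScoreVector-class]s; names must cover
#'   the model's component names, samples identical across components.
#' @param model a [MetaScoreModel-class].
#' @return A [ScoreVector-class] with both raw (the weighted sum) and
#'   standardized values.
#' @export
applyMetaScore <- function(components, model) {
  stopifnot(is(model, "MetaScoreModel"))
  missing_comp <- setdiff(model@component_names, names(components))
  if (length(missing_comp))
    stop("missing component score(s): ", paste(missing_comp, collapse = ", "))
  ids <- sampleIds(components[[model@component_names[1L]]])
  meta_raw <- numeric(length(ids))
  for (i in seq_along(model@component_names)) {
    nm <- model@component_names[i]
    sv <- components[[nm]]
    if (!identical(sort(sampleIds(sv)), sort(ids)))
      stop("components cover different sample sets")
    raw <- rawScores(sv)[ids]
    meta_raw <- meta_raw + model@mixing_weights[i] *
      (raw - model@component_means[i]) / model@component_sds[i]
  }
  sv <- .ScoreVector(ids, meta_raw,
                     n_variants_used = NA_integer_)
  standardizeScores(sv, reference = c(model@final_mean, model@final_sd))
}

#' Serialize / deserialize a meta-score model
#'
#' Human-readable key=value text with all moments and weights at 15
#' significant digits.
#'
#' @param model a [MetaScoreModel-class].
#' @param path file path.
#' @return `writeMetaScoreModel`: the path, invisibly;
#'   `readMetaScoreModel`: the model.
#' @export
writeMetaScoreModel <- function(model, path) {
  stopifnot(is(model, "MetaScoreModel"))
  num <- function(x) paste(sprintf("%.15g", x), collapse = ",")
  writeLines(c(
    sprintf("component_names=%s", paste(model@component_names, collapse = ",")),
    sprintf("component_means=%s", num(model@component_means)),
    sprintf("component_sds=%s", num(model@component_sds)),
    sprintf("mixing_weights=%s", num(model@mixing_weights)),
    sprintf("fit_method=%s", model@fit_method),
    sprintf("training_n=%d", model@training_n),
    sprintf("final_mean=%.15g", model@final_mean),
    sprintf("final_sd=%.15g", model@final_sd)), path)
  invisible(path)
}

#' @rdname writeMetaScoreModel
#' @export
readMetaScoreModel <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  nums <- function(key) as.numeric(strsplit(vals[[key]], ",")[[1L]])
  new("MetaScoreModel",
      component_names = strsplit(vals[["component_names"]], ",")[[1L]],
      component_means = nums("component_means"),
      component_sds = nums("component_sds"),
      mixing_weights = nums("mixing_weights"),
      fit_method = vals[["fit_method"]],
      training_n = as.integer(vals[["training_n"]]),
      final_mean = as.numeric(vals[["final_mean"]]),
      final_sd = as.numeric(vals[["final_sd"]]))
}
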