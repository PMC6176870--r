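#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of two variants' dosage vectors over
#' pairwise-complete samples; 0 when either variant has zero variance.
#'
#' @param matrix a [DosageMatrix-class].
#' @param i,j variant row indices.
#' @return r-squared in \[0, 1\].
#' @export
pairwiseR2 <- function(matrix, i, j) {
  d <- dosages(matrix)
  x <- d[i, ]; y <- d[j, ]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) stop("fewer than 2 pairwise-complete samples")
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  min(1, stats::cor(x, y)^2)
}

#' Greedy LD thinning of a variant list
#'
#' Iterates variants in ascending p-value order (ties broken by chromosome,
#' then position) and retains a variant iff its r-squared with every
#' already-retained variant within `window` base pairs on the same
#' chromosome is at most `r2_max` — the standard clumping/thinning rule
#' used to build sparse genome-wide scores from GWAS summary statistics.
#'
#' @param variants data.frame of variant records with `variant_id`,
#'   `chromosome`, `position`, `p_value` (all present).
#' @param ld_source a [DosageMatrix-class] containing every variant (LD
#'   reference panel).
#' @param r2_max retention threshold on pairwise r-squared.
#' @param window physical window in base pairs.
#' @return the retained subset of `variants`, in retention order.
#' @export
greedyThin <- function(variants, ld_source, r2_max, window = 1e6) {
  stopifnot(is(ld_source, "DosageMatrix"), window > 0, r2_max > 0)
  if (any(is.na(variants$p_value))) stop("p_values must be present")
  mv <- variantInfo(ld_source)
  idx <- match(variants$variant_id, mv$variant_id)
  if (anyNA(idx)) stop("variant(s) absent from the LD source")
  ord <- order(variants$p_value, variants$chromosome, variants$position)
  v <- variants[ord, , drop = FALSE]
  idx <- idx[ord]
  keep <- logical(nrow(v))
  d <- dosages(ld_source)
  for (k in seq_len(nrow(v))) {
    prior <- which(keep & v$chromosome == v$chromosome[k] &
                     abs(v$position - v$position[k]) <= window)
    ok <- TRUE
    for (p_ in prior) {
      if (pairwiseR2(ld_source, idx[k], idx[p_]) > r2_max) { ok <- FALSE; break }
    }
    keep[k] <- ok
  }
  out <- v[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive a genome-wide score by grid search over thinning parameters
#'
#' For each (r2, p) cell of the grid: filter summary statistics to
#' `p_value <= p`, greedily thin at `r2`, build a score weighted by the
#' estimated effect sizes, score the training samples, and compute the
#' training statistic. The cell maximizing the statistic wins (ties broken
#' toward fewer variants, then smaller r2). This mirrors deriving a
#' genome-wide polygenic score from GWAS summary statistics with the
#' thinning parameters tuned on a small training cohort.
#'
#' @param stats data.frame of summary-statistic variant records.
#' @param ld_source [DosageMatrix-class] LD reference panel.
#' @param training_matrix [DosageMatrix-class] of training genotypes.
#' @param training_cohort cohort table for the training samples (see
#'   [readCohortTable()]); case status is `cad_status != "none"`.
#' @param r2_grid,p_grid threshold grids.
#' @param window thinning window in base pairs.
#' @param training_metric `"per_sd_z"` (default): z-statistic of the
#'   standardized score in a logistic model of case status adjusted for sex
#'   and assessment age; `"c_index"`: sex-stratified concordance on the age
#'   scale.
#' @param score_name name for the derived [ScoreDefinition-class].
#' @return list with `best` (the winning ScoreDefinition, or NULL if every
#'   cell is empty) and `grid` (data.frame of every candidate:
#'   `r2_threshold`, `p_threshold`, `n_variants`, `training_statistic`,
#'   `standard_error`).
#' @export
gridSearchDerive <- function(stats, ld_source, training_matrix,
                             training_cohort,
                             r2_grid = c(0.2, 0.4, 0.6, 0.8),
                             p_grid = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.1, 1),
                             window = 1e6,
                             training_metric = c("per_sd_z", "c_index"),
                             score_name = "genomewide") {
  training_metric <- match.arg(training_metric)
  stopifnot(length(r2_grid) > 0, length(p_grid) > 0)
  case <- training_cohort$cad_status != "none"
  if (!any(case) || all(case))
    stop("training cohort needs at least one case and one non-case")

  grid <- expand.grid(r2_threshold = sort(r2_grid),
                      p_threshold = sort(p_grid))
  grid$n_variants <- 0L
  grid$training_statistic <- NA_real_
  grid$standard_error <- NA_real_
  best_def <- NULL; best_key <- NULL

  for (g in seq_len(nrow(grid))) {
    cand <- stats[!is.na(stats$p_value) &
                    stats$p_value <= grid$p_threshold[g], , drop = FALSE]
    if (!nrow(cand)) next
    thinned <- greedyThin(cand, ld_source, grid$r2_threshold[g], window)
    grid$n_variants[g] <- nrow(thinned)
    if (!nrow(thinned)) next
    def <- ScoreDefinition(score_name, thinned)
    hw <- harmonizeWeights(def, training_matrix, "keep")
    sv <- standardizeScores(computeRawScore(training_matrix, hw))
    z <- standardizedScores(sv)[training_cohort$sample_id]
    if (training_metric == "per_sd_z") {
      fit <- stats::glm(case ~ z + sex + age,
                        data = data.frame(case = case, z = z,
                                          sex = training_cohort$sex,
                                          age = training_cohort$age_at_assessment),
                        family = stats::binomial())
      co <- summary(fit)$coefficients
      grid$training_statistic[g] <- co["z", "z value"]
      grid$standard_error[g] <- co["z", "Std. Error"]
    } else {
      out <- buildSurvivalOutcomes(training_cohort, analysis = "all_cad")
      ci <- concordanceIndex(z[out$sample_id], out,
                             strata = training_cohort$sex[
                               match(out$sample_id,
                                     training_cohort$sample_id)])
      grid$training_statistic[g] <- ci$c_index
      grid$standard_error[g] <- ci$se
    }
    key <- c(-grid$training_statistic[g], grid$n_variants[g],
             grid$r2_threshold[g])
    if (is.null(best_key) || .lex_less(key, best_key)) {
      best_key <- key; best_def <- def
      attr(best_def, "r2_threshold") <- grid$r2_threshold[g]
      attr(best_def, "p_threshold") <- grid$p_threshold[g]
    }
  }
  list(best = best_def, grid = grid)
}

# lexicographic strictly-less comparison of equal-length numeric keys
.lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}
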