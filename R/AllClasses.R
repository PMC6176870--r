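#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.VALID_BASES <- c("A", "C", "G", "T")

.is_allele <- function(x) {
  nzchar(x) & !is.na(x) &
    vapply(strsplit(x, ""), function(b) all(b %in% .VALID_BASES), logical(1))
}

#' DosageMatrix: variant-by-sample additive allele dosages
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' assay `"dosage"` of per-sample expected counted-allele counts in
#' \eqn{[0, 2]} (NA marks a missing genotype), with per-variant metadata
#' (`variant_id`, `chromosome`, `position`, `counted_allele`,
#' `other_allele`) in `rowData`.
#'
#' The counted allele is the allele whose expected copy number the dosage
#' measures; harmonization against a score definition may count the other
#' allele by negating the weight and adding a per-sample constant.
#'
#' @aliases DosageMatrix-class
#' @exportClass DosageMatrix
setClass("DosageMatrix", contains = "SummarizedExperiment")

setValidity("DosageMatrix", function(object) {
  msg <- character(0)
  rd <- SummarizedExperiment::rowData(object)
  need <- c("variant_id", "chromosome", "position",
            "counted_allele", "other_allele")
  if (!all(need %in% colnames(rd)))
    return(paste("rowData must contain:", paste(need, collapse = ", ")))
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  if (any(d < 0 | d > 2, na.rm = TRUE))
    msg <- c(msg, "dosages must lie in [0, 2] (NA marks missing)")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (any(rd$position < 1L))
    msg <- c(msg, "positions are 1-based and must be >= 1")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a DosageMatrix
#'
#' @param dosages numeric matrix, variants in rows, samples in columns;
#'   values in `[0, 2]`, `NA` for missing.
#' @param variants data.frame with columns `variant_id`, `chromosome`,
#'   `position`, `counted_allele`, `other_allele` (one row per dosage row).
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the column names of `dosages`.
#' @return A [DosageMatrix-class] object.
#' @examples
#' dm <- DosageMatrix(
#'   matrix(c(0, 1, 2, 1), nrow = 2,
#'          dimnames = list(NULL, c("s1", "s2"))),
#'   data.frame(variant_id = c("v1", "v2"), chromosome = "1",
#'              position = c(100L, 200L), counted_allele = c("A", "C"),
#'              other_allele = c("G", "T")))
#' dosages(dm)
#' @export
DosageMatrix <- function(dosages, variants, sample_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids))
    stop("sample_ids are required (or set colnames on the dosage matrix)")
  if (nrow(variants) != nrow(dosages))
    stop("variant table and dosage matrix row counts differ")
  if (length(sample_ids) != ncol(dosages))
    stop("sample id count and dosage matrix column count differ")
  colnames(dosages) <- sample_ids
  rownames(dosages) <- variants$variant_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosages),
    rowData = S4Vectors::DataFrame(variants))
  new("DosageMatrix", se)
}

#' ScoreDefinition: a named set of per-variant score weights
#'
#' The computational form of a published genomic risk score: an ordered
#' collection of variants, each with an effect allele, other allele and a
#' per-effect-allele weight (log-hazard or log-odds units), optionally with
#' a p-value and an effect-allele frequency.
#'
#' @slot name single score name.
#' @slot variants [S4Vectors::DataFrame] with columns `variant_id`,
#'   `chromosome`, `position`, `effect_allele`, `other_allele`,
#'   `effect_weight`, `p_value`, `effect_allele_frequency` (the last two may
#'   be NA).
#' @aliases ScoreDefinition-class
#' @exportClass ScoreDefinition
setClass("ScoreDefinition",
         representation(name = "character", variants = "DataFrame"))

setValidity("ScoreDefinition", function(object) {
  v <- object@variants
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a single non-empty string")
  if (nrow(v) == 0L)
    return("a score definition must contain at least one variant")
  need <- c("variant_id", "chromosome", "position", "effect_allele",
            "other_allele", "effect_weight", "p_value",
            "effect_allele_frequency")
  if (!all(need %in% colnames(v)))
    return(paste("variant table must contain:", paste(need, collapse = ", ")))
  msg <- character(0)
  if (anyDuplicated(v$variant_id))
    msg <- c(msg, sprintf("duplicate variant_id: %s",
                          v$variant_id[duplicated(v$variant_id)][1L]))
  if (any(v$position < 1L))
    msg <- c(msg, "positions must be >= 1")
  if (any(v$effect_allele == v$other_allele))
    msg <- c(msg, "effect_allele must differ from other_allele")
  if (!all(.is_allele(v$effect_allele)) || !all(.is_allele(v$other_allele)))
    msg <- c(msg, "alleles must be non-empty A/C/G/T sequences")
  eaf <- v$effect_allele_frequency
  if (any(!is.na(eaf) & (eaf < 0 | eaf > 1)))
    msg <- c(msg, "effect_allele_frequency must lie in [0, 1]")
  p <- v$p_value
  if (any(!is.na(p) & (p <= 0 | p > 1)))
    msg <- c(msg, "p_value must lie in (0, 1]")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a ScoreDefinition
#'
#' @param name score name (e.g. `"FDR202"`).
#' @param variants data.frame with at least `variant_id`, `chromosome`,
#'   `position`, `effect_allele`, `other_allele`, `effect_weight`; optional
#'   `p_value` and `effect_allele_frequency` default to NA.
#' @return A [ScoreDefinition-class].
#' @export
ScoreDefinition <- function(name, variants) {
  variants <- as.data.frame(variants)
  if (is.null(variants$p_value)) variants$p_value <- NA_real_
  if (is.null(variants$effect_allele_frequency))
    variants$effect_allele_frequency <- NA_real_
  variants$position <- as.integer(variants$position)
  variants$chromosome <- as.character(variants$chromosome)
  new("ScoreDefinition", name = as.character(name),
      variants = S4Vectors::DataFrame(variants))
}

#' HarmonizedWeights: a score definition resolved against a DosageMatrix
#'
#' Maps each score variant either to a matrix variant (with a signed weight
#' and the action taken: direct match, allele flip, or the same after
#' strand complementation) or to a dropped record with a reason. Allele
#' flips are scored as weight negation plus a per-sample constant
#' \eqn{2w}, accumulated in `offset`, so that flipped scoring equals
#' counting the effect allele directly.
#'
#' @slot entries DataFrame: `matrix_index`, `weight`, `action`.
#' @slot offset single numeric, the accumulated per-sample constant.
#' @slot dropped DataFrame: `variant_id`, `reason`.
#' @slot n_score_variants number of variants in the source definition.
#' @aliases HarmonizedWeights-class
#' @exportClass HarmonizedWeights
setClass("HarmonizedWeights",
         representation(entries = "DataFrame", offset = "numeric",
                        dropped = "DataFrame", n_score_variants = "integer"))

setValidity("HarmonizedWeights", function(object) {
  e <- object@entries
  if (anyDuplicated(e$matrix_index))
    return("each matrix variant may be used at most once")
  if (nrow(e) + nrow(object@dropped) != object@n_score_variants)
    return("entries + dropped must account for every score variant")
  ok_act <- c("match", "flip", "complement_match", "complement_flip")
  if (nrow(e) && !all(e$action %in% ok_act))
    return("unknown harmonization action")
  ok_rsn <- c("not_found", "allele_mismatch", "ambiguous_palindrome",
              "duplicate")
  if (nrow(object@dropped) && !all(object@dropped$reason %in% ok_rsn))
    return("unknown drop reason")
  TRUE
})

#' ScoreVector: per-sample raw and standardized score values
#'
#' @slot sample_ids ordered sample identifiers.
#' @slot raw raw additive score per sample.
#' @slot standardized standardized score per sample (length 0 when not yet
#'   standardized).
#' @slot n_variants_used number of score variants contributing.
#' @slot standardization_mean,standardization_sd the moments used for
#'   standardization (NA before standardization).
#' @aliases ScoreVector-class
#' @exportClass ScoreVector
setClass("ScoreVector",
         representation(sample_ids = "character", raw = "numeric",
                        standardized = "numeric",
                        n_variants_used = "integer",
                        standardization_mean = "numeric",
                        standardization_sd = "numeric"))

setValidity("ScoreVector", function(object) {
  if (length(object@raw) != length(object@sample_ids))
    return("raw scores and sample ids differ in length")
  if (anyDuplicated(object@sample_ids))
    return("sample ids must be unique")
  if (length(object@standardized)) {
    if (length(object@standardized) != length(object@raw))
      return("standardized scores and raw scores differ in length")
    if (!is.na(object@standardization_sd) &&
        object@standardization_sd <= 0)
      return("standardization sd must be > 0")
    expect <- (object@raw - object@standardization_mean) /
      object@standardization_sd
    if (max(abs(object@standardized - expect), 0) > 1e-8)
      return("standardized != (raw - mean)/sd")
  }
  TRUE
})

.ScoreVector <- function(sample_ids, raw, standardized = numeric(0),
                         n_variants_used = NA_integer_,
                         mean = NA_real_, sd = NA_real_) {
  new("ScoreVector", sample_ids = as.character(sample_ids),
      raw = as.numeric(raw), standardized = as.numeric(standardized),
      n_variants_used = as.integer(n_variants_used),
      standardization_mean = as.numeric(mean),
      standardization_sd = as.numeric(sd))
}

#' MetaScoreModel: standardization moments plus mixing weights
#'
#' The portable form of a meta-score: per-component training means and SDs,
#' mixing weights for the standardized components, and the training moments
#' of the weighted sum used to standardize the final meta-score.
#'
#' @slot component_names,component_means,component_sds,mixing_weights
#'   parallel vectors over the components.
#' @slot fit_method one of `"joint_logistic"`, `"joint_cox"`,
#'   `"univariate_logistic"`.
#' @slot training_n training-set size.
#' @slot final_mean,final_sd moments of the weighted sum on the training
#'   samples.
#' @aliases MetaScoreModel-class
#' @exportClass MetaScoreModel
setClass("MetaScoreModel",
         representation(component_names = "character",
                        component_means = "numeric",
                        component_sds = "numeric",
                        mixing_weights = "numeric",
                        fit_method = "character",
                        training_n = "integer",
                        final_mean = "numeric", final_sd = "numeric"))

setValidity("MetaScoreModel", function(object) {
  k <- length(object@component_names)
  if (length(object@component_means) != k ||
      length(object@component_sds) != k ||
      length(object@mixing_weights) != k)
    return("component names, means, sds and weights must have equal length")
  if (any(object@component_sds <= 0)) return("component sds must be > 0")
  if (object@final_sd <= 0) return("final_sd must be > 0")
  if (!object@fit_method %in%
      c("joint_logistic", "joint_cox", "univariate_logistic"))
    return("unknown fit_method")
  TRUE
})
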