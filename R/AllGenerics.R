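#' @rdname DosageMatrix
#' @param x a package object.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname DosageMatrix
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname DosageMatrix
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname ScoreDefinition
#' @param x a package object.
#' @export
setGeneric("scoreName", function(x) standardGeneric("scoreName"))

#' @rdname ScoreDefinition
#' @export
setGeneric("scoreVariants", function(x) standardGeneric("scoreVariants"))

#' @rdname ScoreVector-class
#' @param x a package object.
#' @export
setGeneric("rawScores", function(x) standardGeneric("rawScores"))

#' @rdname ScoreVector-class
#' @export
setGeneric("standardizedScores",
           function(x) standardGeneric("standardizedScores"))

#' @describeIn DosageMatrix dosage assay (variants x samples, NA = missing).
#' @export
setMethod("dosages", "DosageMatrix", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @describeIn DosageMatrix per-variant metadata as a data.frame.
#' @export
setMethod("variantInfo", "DosageMatrix", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @describeIn DosageMatrix sample identifiers.
#' @export
setMethod("sampleIds", "DosageMatrix", function(x) colnames(x))

#' @describeIn ScoreDefinition the score's name.
#' @export
setMethod("scoreName", "ScoreDefinition", function(x) x@name)

#' @describeIn ScoreDefinition the variant/weight table as a data.frame.
#' @export
setMethod("scoreVariants", "ScoreDefinition", function(x)
  as.data.frame(x@variants))

#' @describeIn ScoreDefinition number of variants in the definition.
#' @export
setMethod("length", "ScoreDefinition", function(x) nrow(x@variants))

#' @describeIn ScoreVector-class raw per-sample scores, named by sample.
#' @export
setMethod("rawScores", "ScoreVector", function(x)
  stats::setNames(x@raw, x@sample_ids))

#' @describeIn ScoreVector-class standardized per-sample scores (error if the
#'   vector has not been standardized).
#' @export
setMethod("standardizedScores", "ScoreVector", function(x) {
  if (!length(x@standardized))
    stop("score vector has not been standardized; see standardizeScores()")
  stats::setNames(x@standardized, x@sample_ids)
})

#' @describeIn ScoreVector-class sample identifiers.
#' @export
setMethod("sampleIds", "ScoreVector", function(x) x@sample_ids)

#' @describeIn ScoreVector-class number of samples.
#' @export
setMethod("length", "ScoreVector", function(x) length(x@raw))

setMethod("show", "ScoreDefinition", function(object) {
  cat(sprintf("ScoreDefinition '%s': %d variants\n", object@name,
              nrow(object@variants)))
  w <- object@variants$effect_weight
  cat(sprintf("  weights: min %.4g, median %.4g, max %.4g\n",
              min(w), stats::median(w), max(w)))
})

setMethod("show", "ScoreVector", function(object) {
  cat(sprintf("ScoreVector: %d samples, %d variants used\n",
              length(object@raw), object@n_variants_used))
  if (length(object@standardized))
    cat(sprintf("  standardized with mean %.6g, sd %.6g\n",
                object@standardization_mean, object@standardization_sd))
  else cat("  raw only (not standardized)\n")
})

setMethod("show", "HarmonizedWeights", function(object) {
  cat(sprintf(
    "HarmonizedWeights: %d/%d score variants mapped, %d dropped\n",
    nrow(object@entries), object@n_score_variants, nrow(object@dropped)))
  if (nrow(object@entries))
    print(table(action = object@entries$action))
  if (nrow(object@dropped))
    print(table(reason = object@dropped$reason))
})

setMethod("show", "MetaScoreModel", function(object) {
  cat(sprintf("MetaScoreModel (%s, n_train = %d):\n", object@fit_method,
              object@training_n))
  for (i in seq_along(object@component_names))
    cat(sprintf("  %s: weight %.6g (mean %.6g, sd %.6g)\n",
                object@component_names[i], object@mixing_weights[i],
                object@component_means[i], object@component_sds[i]))
  cat(sprintf("  final: mean %.6g, sd %.6g\n", object@final_mean,
              object@final_sd))
})

#' @describeIn MetaScoreModel-class component mixing weights, named.
#' @export
setGeneric("mixingWeights", function(x) standardGeneric("mixingWeights"))

#' @rdname MetaScoreModel-class
#' @param x a `MetaScoreModel`.
#' @export
setMethod("mixingWeights", "MetaScoreModel", function(x)
  stats::setNames(x@mixing_weights, x@component_names))
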