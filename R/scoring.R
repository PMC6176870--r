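.revcomp <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""), function(b)
    paste(rev(b), collapse = ""), character(1))
}

.is_palindromic <- function(ea, oa) ea == .revcomp(oa)

#' Harmonize a score definition against a dosage matrix
#'
#' Resolves each score variant to a matrix variant by (chromosome,
#' position, unordered allele pair) — variant ids are used only for
#' reporting. A direct (effect, other) = (counted, other) match keeps the
#' weight; a swapped match negates the weight and accounts a per-sample
#' constant `2w` so the flipped scoring equals counting the effect allele;
#' matches found only after A<->T / C<->G strand complementation are
#' handled the same way with `complement_` actions. Palindromic variants
#' (A/T or C/G pairs), whose strand is unresolvable from alleles alone,
#' follow `palindrome_policy`.
#'
#' @param definition a [ScoreDefinition-class].
#' @param matrix a [DosageMatrix-class].
#' @param palindrome_policy `"drop"` (default): always drop;
#'   `"frequency_align"`: orient by comparing the score's effect-allele
#'   frequency with the matrix counted-allele frequency, dropping variants
#'   where either frequency lies in (0.4, 0.6); `"keep"`: treat as
#'   same-strand and match on alleles as given.
#' @return A [HarmonizedWeights-class].
#' @export
harmonizeWeights <- function(definition, matrix,
                             palindrome_policy = c("drop", "frequency_align",
                                                   "keep")) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(is(definition, "ScoreDefinition"), is(matrix, "DosageMatrix"))
  sv <- scoreVariants(definition)
  mv <- variantInfo(matrix)
  if (palindrome_policy == "frequency_align" &&
      all(is.na(sv$effect_allele_frequency)))
    stop("frequency_align requires effect_allele_frequency in the definition")
  mkey <- paste(mv$chromosome, mv$position, sep = ":")
  counted_af <- rowMeans(dosages(matrix), na.rm = TRUE) / 2

  used <- logical(nrow(mv))
  ent_idx <- integer(0); ent_w <- numeric(0); ent_act <- character(0)
  drop_id <- character(0); drop_rsn <- character(0)
  offset <- 0

  for (k in seq_len(nrow(sv))) {
    ea <- sv$effect_allele[k]; oa <- sv$other_allele[k]
    w <- sv$effect_weight[k]
    cand <- which(mkey == paste(sv$chromosome[k], sv$position[k], sep = ":"))
    drop <- function(reason) {
      drop_id <<- c(drop_id, sv$variant_id[k])
      drop_rsn <<- c(drop_rsn, reason)
    }
    if (!length(cand)) { drop("not_found"); next }

    pal <- .is_palindromic(ea, oa)
    hit <- NA_integer_; act <- NA_character_
    for (i in cand) {
      ca <- mv$counted_allele[i]; na_ <- mv$other_allele[i]
      if (ea == ca && oa == na_) { hit <- i; act <- "match"; break }
      if (ea == na_ && oa == ca) { hit <- i; act <- "flip"; break }
      if (!pal) { # complement only resolvable for non-palindromic pairs
        cea <- .revcomp(ea); coa <- .revcomp(oa)
        if (cea == ca && coa == na_) { hit <- i; act <- "complement_match"; break }
        if (cea == na_ && coa == ca) { hit <- i; act <- "complement_flip"; break }
      }
    }
    if (is.na(hit)) { drop("allele_mismatch"); next }

    if (pal) {
      if (palindrome_policy == "drop") { drop("ambiguous_palindrome"); next }
      if (palindrome_policy == "frequency_align") {
        eaf <- sv$effect_allele_frequency[k]
        caf <- counted_af[hit]
        if (is.na(eaf) || (eaf > 0.4 && eaf < 0.6) ||
            (caf > 0.4 && caf < 0.6)) {
          drop("ambiguous_palindrome"); next
        }
        # same strand if the frequencies agree on which allele is minor
        same_strand <- (eaf < 0.5) == (if (act == "match") caf < 0.5
                                       else caf > 0.5)
        if (!same_strand)
          act <- if (act == "match") "complement_flip" else "complement_match"
      }
      # policy "keep": use the allele match as-is
    }
    if (used[hit]) { drop("duplicate"); next }
    used[hit] <- TRUE
    if (act %in% c("flip", "complement_flip")) {
      ent_w <- c(ent_w, -w)
      offset <- offset + 2 * w
    } else ent_w <- c(ent_w, w)
    ent_idx <- c(ent_idx, hit); ent_act <- c(ent_act, act)
  }

  new("HarmonizedWeights",
      entries = S4Vectors::DataFrame(matrix_index = ent_idx,
                                     weight = ent_w, action = ent_act),
      offset = offset,
      dropped = S4Vectors::DataFrame(variant_id = drop_id,
                                     reason = drop_rsn),
      n_score_variants = nrow(sv))
}

#' Compute raw additive scores
#'
#' Per sample, the sum over harmonized entries of (signed weight x dosage)
#' plus the harmonization offset, so the result equals scoring the effect
#' allele directly regardless of which allele the matrix counts. Missing
#' dosages are imputed per `missing_policy`.
#'
#' @param matrix a [DosageMatrix-class].
#' @param weights a [HarmonizedWeights-class] from [harmonizeWeights()].
#' @param missing_policy `"mean_dosage"` (default): per-variant mean over
#'   non-missing samples; `"frequency_expected"`: twice the counted-allele
#'   frequency supplied in `frequencies`; `"zero"`: 0.
#' @param frequencies per-matrix-variant counted-allele frequencies,
#'   required for `"frequency_expected"`.
#' @return A [ScoreVector-class] (raw only).
#' @export
computeRawScore <- function(matrix, weights,
                            missing_policy = c("mean_dosage",
                                               "frequency_expected", "zero"),
                            frequencies = NULL) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(is(matrix, "DosageMatrix"), is(weights, "HarmonizedWeights"))
  e <- weights@entries
  d <- dosages(matrix)
  if (nrow(e) && (min(e$matrix_index) < 1L || max(e$matrix_index) > nrow(d)))
    stop("harmonized weights reference invalid matrix indices")
  sub <- d[e$matrix_index, , drop = FALSE]
  if (anyNA(sub)) {
    fill <- switch(missing_policy,
      mean_dosage = {
        m <- rowMeans(sub, na.rm = TRUE)
        m[is.nan(m)] <- 0
        m
      },
      frequency_expected = {
        if (is.null(frequencies))
          stop("frequency_expected requires per-variant frequencies")
        stopifnot(length(frequencies) == nrow(d))
        2 * frequencies[e$matrix_index]
      },
      zero = rep(0, nrow(sub)))
    na_at <- which(is.na(sub), arr.ind = TRUE)
    sub[na_at] <- fill[na_at[, 1L]]
  }
  raw <- as.numeric(crossprod(sub, e$weight)) + weights@offset
  .ScoreVector(sampleIds(matrix), raw, n_variants_used = nrow(e))
}

#' Standardize a score vector
#'
#' Populates the standardized field as (raw - mean)/sd, using supplied
#' reference moments when given, else the sample moments of the raw
#' scores (all scores are standardized to zero mean and unit variance in
#' the evaluation cohort by default).
#'
#' @param score a [ScoreVector-class].
#' @param reference optional `c(mean, sd)` reference moments.
#' @return the score with `standardized` populated.
#' @export
standardizeScores <- function(score, reference = NULL) {
  stopifnot(is(score, "ScoreVector"))
  if (is.null(reference)) {
    m <- mean(score@raw)
    s <- stats::sd(score@raw)
    if (is.na(s) || s <= 0)
      stop("raw scores have zero variance; supply reference moments")
  } else {
    stopifnot(length(reference) == 2L)
    m <- reference[1L]; s <- reference[2L]
    if (s <= 0) stop("reference sd must be > 0")
  }
  initialize(score, standardized = (score@raw - m) / s,
             standardization_mean = m, standardization_sd = s)
}
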