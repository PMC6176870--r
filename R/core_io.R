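#' Read GWAS summary statistics
#'
#' Reads a tab-delimited summary-statistics file into a variant table. Rows
#' violating the variant invariants (identical alleles, non-ACGT alleles,
#' position < 1, p-value outside (0, 1], allele frequency outside \[0, 1\],
#' unparseable numerics) are reported and dropped; the kept/dropped counts
#' are attached as attributes `n_kept` / `n_dropped`.
#'
#' @param path path to a tab-delimited file with a header line.
#' @param column_map named character vector mapping the canonical field
#'   names (`variant_id`, `chromosome`, `position`, `effect_allele`,
#'   `other_allele`, `effect_weight`, `p_value`,
#'   `effect_allele_frequency`) to the file's column names. `p_value` and
#'   `effect_allele_frequency` are optional; all others are mandatory.
#' @return data.frame with the canonical columns, one row per kept variant.
#' @export
readSummaryStats <- function(path, column_map = NULL) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE, comment.char = "#")
  canonical <- c("variant_id", "chromosome", "position", "effect_allele",
                 "other_allele", "effect_weight", "p_value",
                 "effect_allele_frequency")
  if (is.null(column_map))
    column_map <- stats::setNames(canonical, canonical)
  mandatory <- setdiff(canonical, c("p_value", "effect_allele_frequency"))
  for (f in mandatory) {
    if (is.na(column_map[f]) || !column_map[f] %in% names(raw))
      stop(sprintf("mandatory column '%s' (mapped to '%s') not in file",
                   f, column_map[f]))
  }
  out <- data.frame(
    variant_id = raw[[column_map["variant_id"]]],
    chromosome = raw[[column_map["chromosome"]]],
    position = suppressWarnings(
      as.integer(raw[[column_map["position"]]])),
    effect_allele = toupper(raw[[column_map["effect_allele"]]]),
    other_allele = toupper(raw[[column_map["other_allele"]]]),
    effect_weight = suppressWarnings(
      as.numeric(raw[[column_map["effect_weight"]]])),
    stringsAsFactors = FALSE)
  grab_opt <- function(f) {
    col <- column_map[f]
    if (!is.na(col) && col %in% names(raw))
      suppressWarnings(as.numeric(raw[[col]]))
    else rep(NA_real_, nrow(raw))
  }
  out$p_value <- grab_opt("p_value")
  out$effect_allele_frequency <- grab_opt("effect_allele_frequency")

  bad <- is.na(out$position) | out$position < 1L |
    is.na(out$effect_weight) |
    out$effect_allele == out$other_allele |
    !.is_allele(out$effect_allele) | !.is_allele(out$other_allele) |
    (!is.na(out$p_value) & (out$p_value <= 0 | out$p_value > 1)) |
    (!is.na(out$effect_allele_frequency) &
       (out$effect_allele_frequency < 0 | out$effect_allele_frequency > 1))
  if (any(bad))
    message(sprintf("readSummaryStats: dropped %d/%d rows failing variant invariants",
                    sum(bad), nrow(out)))
  kept <- out[!bad, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "n_kept") <- nrow(kept)
  attr(kept, "n_dropped") <- sum(bad)
  kept
}

#' Read and write score-definition files
#'
#' A score definition is stored as a tab-delimited table with a commented
#' header line `# score_name=<name>` followed by the columns `variant_id`,
#' `chromosome`, `position`, `effect_allele`, `other_allele`,
#' `effect_weight`, `p_value`, `effect_allele_frequency`. Weights are
#' serialized with 15 significant digits so write-then-read is the identity
#' to at least 12 significant digits.
#'
#' @param path file path.
#' @return `readScoreDefinition`: a [ScoreDefinition-class].
#' @export
readScoreDefinition <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  name <- sub("^#\\s*score_name=", "", first)
  if (identical(name, first))
    stop("score file must start with a '# score_name=<name>' header line")
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (anyDuplicated(tab$variant_id))
    stop(sprintf("duplicate variant_id in score file: %s",
                 tab$variant_id[duplicated(tab$variant_id)][1L]))
  ScoreDefinition(name, tab)
}

#' @rdname readScoreDefinition
#' @param def a [ScoreDefinition-class] to serialize.
#' @return `writeScoreDefinition`: the path, invisibly.
#' @export
writeScoreDefinition <- function(def, path) {
  stopifnot(is(def, "ScoreDefinition"))
  validObject(def)
  v <- scoreVariants(def)
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.15g", x))
  lines <- c(
    sprintf("# score_name=%s", scoreName(def)),
    paste(c("variant_id", "chromosome", "position", "effect_allele",
            "other_allele", "effect_weight", "p_value",
            "effect_allele_frequency"), collapse = "\t"),
    paste(v$variant_id, v$chromosome, v$position, v$effect_allele,
          v$other_allele, num(v$effect_weight), num(v$p_value),
          num(v$effect_allele_frequency), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Load genotype dosages from a VCF or a plain matrix file
#'
#' For VCF input the per-genotype dosage field `DS` is used when present,
#' otherwise dosages are hard-genotype alternate-allele counts from `GT`
#' (`./.` becomes missing); the counted allele is the ALT allele. Variants
#' with more than two alleles are skipped with a warning. For matrix input
#' the file is tab-delimited with columns `variant_id`, `chromosome`,
#' `position`, `counted_allele`, `other_allele` followed by one column per
#' sample; values must lie in \[0, 2\] (empty or `NA` = missing), and rows
#' with out-of-range values are rejected with a warning.
#'
#' @param source path to a `.vcf` file or a tab-delimited matrix file.
#' @param ids optional character vector: keep only these variant ids.
#' @return A [DosageMatrix-class].
#' @export
loadDosages <- function(source, ids = NULL) {
  stopifnot(file.exists(source))
  if (grepl("\\.vcf(\\.gz)?$", source)) .load_dosages_vcf(source, ids)
  else .load_dosages_matrix(source, ids)
}

.load_dosages_vcf <- function(source, ids) {
  vcf <- VariantAnnotation::readVcf(source)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt > 1L
  if (any(multi)) {
    warning(sprintf("skipping %d variant(s) with >2 alleles", sum(multi)))
    vcf <- vcf[!multi]
  }
  if (nrow(vcf) == 0L) stop("no parseable biallelic variants in VCF")
  geno <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(geno)) {
    d <- geno$DS
    mode(d) <- "numeric"
  } else if ("GT" %in% names(geno)) {
    gt <- geno$GT
    d <- matrix(NA_real_, nrow(gt), ncol(gt))
    alleles <- strsplit(gsub("\\|", "/", as.vector(gt)), "/")
    d[] <- vapply(alleles, function(a) {
      if (any(a == ".")) return(NA_real_)
      sum(a != "0")
    }, numeric(1))
  } else stop("VCF has neither DS nor GT genotype fields")
  rr <- SummarizedExperiment::rowRanges(vcf)
  variants <- data.frame(
    variant_id = names(vcf),
    chromosome = as.character(GenomicRanges::seqnames(rr)),
    position = GenomicRanges::start(rr),
    counted_allele = as.character(unlist(VariantAnnotation::alt(vcf))),
    other_allele = as.character(VariantAnnotation::ref(vcf)),
    stringsAsFactors = FALSE)
  dm <- DosageMatrix(d, variants, colnames(vcf))
  if (!is.null(ids)) dm <- dm[variants$variant_id %in% ids, ]
  if (nrow(dm) == 0L) stop("no variants left after id filtering")
  dm
}

.load_dosages_matrix <- function(source, ids) {
  tab <- utils::read.delim(source, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("variant_id", "chromosome", "position", "counted_allele",
                 "other_allele")
  if (!all(meta_cols %in% names(tab)))
    stop("matrix file must have columns: ", paste(meta_cols, collapse = ", "))
  sample_cols <- setdiff(names(tab), meta_cols)
  if (!length(sample_cols)) stop("matrix file has no sample columns")
  d <- as.matrix(tab[, sample_cols, drop = FALSE])
  mode(d) <- "numeric"
  bad <- apply(d, 1L, function(x) any(!is.na(x) & (x < 0 | x > 2)))
  if (any(bad)) {
    warning(sprintf("rejecting %d row(s) with dosages outside [0, 2]",
                    sum(bad)))
    tab <- tab[!bad, , drop = FALSE]
    d <- d[!bad, , drop = FALSE]
  }
  if (!is.null(ids)) {
    keep <- tab$variant_id %in% ids
    tab <- tab[keep, , drop = FALSE]
    d <- d[keep, , drop = FALSE]
  }
  if (nrow(d) == 0L) stop("no parseable variants in matrix file")
  DosageMatrix(d, tab[, meta_cols], sample_cols)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test for a biallelic variant from genotype counts,
#' summing the conditional probabilities (given allele counts) of all
#' heterozygote counts no more probable than the observed one.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hweExactTest <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0L) return(1)
  n_a <- 2L * n_hom_alt + n_het        # minor-allele bookkeeping below
  n_b <- 2L * n_hom_ref + n_het
  n_rare <- min(n_a, n_b)
  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  # log P(het = h | allele counts) up to a shared constant
  logp <- lgamma(n + 1) - lgamma((n_rare - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma((2 * n - n_rare - hets) / 2 + 1) +
    hets * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

#' Per-variant quality-control filtering
#'
#' Removes variants failing minor-allele-frequency, Hardy-Weinberg and
#' (optionally) imputation-quality thresholds, mirroring standard PLINK-style
#' summary-statistic QC. MAF is estimated from mean dosage; the exact HWE
#' test runs on hard calls obtained by rounding dosages, with dosages in
#' (0.1, 0.9) or (1.1, 1.9) treated as missing for the HWE test only.
#' Removal counts per criterion are reported with `message()`.
#'
#' @param matrix a [DosageMatrix-class].
#' @param maf_min minimum minor-allele frequency (default 0.01).
#' @param hwe_p_min minimum exact HWE p-value (default 1e-6).
#' @param info optional numeric vector of per-variant imputation info
#'   scores, parallel to the matrix rows.
#' @param info_min minimum info score; requires `info`.
#' @return the filtered [DosageMatrix-class].
#' @export
applyVariantQC <- function(matrix, maf_min = 0.01, hwe_p_min = 1e-6,
                           info = NULL, info_min = NULL) {
  stopifnot(is(matrix, "DosageMatrix"), nrow(matrix) > 0L)
  d <- dosages(matrix)
  af <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  fail_maf <- maf < maf_min

  hard <- d
  hard[(d > 0.1 & d < 0.9) | (d > 1.1 & d < 1.9)] <- NA
  hard <- round(hard)
  hwe_p <- vapply(seq_len(nrow(hard)), function(i) {
    g <- hard[i, ]
    hweExactTest(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                 sum(g == 2, na.rm = TRUE))
  }, numeric(1))
  fail_hwe <- hwe_p < hwe_p_min

  fail_info <- rep(FALSE, nrow(d))
  if (!is.null(info_min)) {
    if (is.null(info))
      stop("info_min given but no per-variant info scores supplied")
    stopifnot(length(info) == nrow(d))
    fail_info <- info < info_min
  }
  message(sprintf(
    "applyVariantQC: removing %d for MAF < %g, %d for HWE p < %g, %d for info%s",
    sum(fail_maf), maf_min, sum(fail_hwe & !fail_maf), hwe_p_min,
    sum(fail_info & !fail_maf & !fail_hwe),
    if (is.null(info_min)) " (not checked)" else sprintf(" < %g", info_min)))
  keep <- !(fail_maf | fail_hwe | fail_info)
  if (!any(keep)) stop("all variants removed by QC")
  matrix[keep, ]
}

#' Read a cohort table
#'
#' Tab-delimited, one row per sample. Required columns: `sample_id`, `sex`
#' (`male`/`female`), `age_at_assessment`, `genotyping_batch`,
#' `pc1`..`pc10`, the risk-factor flags `diabetes`, `current_smoking`,
#' `hypertension`, `family_history`, `high_cholesterol`, `bmi`, the
#' medication flags `lipid_lowering`, `bp_lowering`, and the outcome fields
#' `cad_status` (`none`/`prevalent`/`incident`), `age_at_event`,
#' `age_at_death`, `age_at_censoring` (empty = absent).
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
readCohortTable <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  validateCohortTable(tab)
}

#' Validate a cohort table against its invariants
#'
#' @param tab data.frame as described in [readCohortTable()].
#' @return the table, with logical/numeric columns coerced.
#' @export
validateCohortTable <- function(tab) {
  need <- c("sample_id", "sex", "age_at_assessment", "genotyping_batch",
            paste0("pc", 1:10), "diabetes", "current_smoking",
            "hypertension", "family_history", "high_cholesterol", "bmi",
            "lipid_lowering", "bp_lowering", "cad_status", "age_at_event",
            "age_at_death", "age_at_censoring")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("cohort table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id")
  if (!all(tab$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (!all(tab$cad_status %in% c("none", "prevalent", "incident")))
    stop("cad_status must be none/prevalent/incident")
  if (any(tab$age_at_assessment < 40 | tab$age_at_assessment > 69))
    stop("age_at_assessment must lie in [40, 69]")
  has_event <- !is.na(tab$age_at_event)
  if (!all(has_event == (tab$cad_status != "none")))
    stop("age_at_event must be present exactly for CAD cases")
  prev <- tab$cad_status == "prevalent"
  if (any(prev & tab$age_at_event > tab$age_at_assessment) ||
      any(tab$cad_status == "incident" &
            tab$age_at_event <= tab$age_at_assessment))
    stop("prevalent <=> age_at_event <= age_at_assessment violated")
  for (fl in c("diabetes", "current_smoking", "hypertension",
               "family_history", "high_cholesterol", "lipid_lowering",
               "bp_lowering"))
    tab[[fl]] <- as.logical(tab[[fl]])
  tab
}

#' Read coded clinical records
#'
#' Tab-delimited with columns `sample_id`, `system` (`ICD9`, `ICD10`,
#' `OPCS4`, `SELF_REPORT`), `code`, `age_at_record` (empty = absent),
#' `source` (`hospital`, `death`, `assessment`).
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
readCodedRecords <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(code = "character"))
  need <- c("sample_id", "system", "code", "age_at_record", "source")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("records table missing columns: ", paste(miss, collapse = ", "))
  if (!all(tab$system %in% c("ICD9", "ICD10", "OPCS4", "SELF_REPORT")))
    stop("unknown coding system in records")
  if (!all(tab$source %in% c("hospital", "death", "assessment")))
    stop("unknown record source")
  if (any(!nzchar(tab$code))) stop("empty code in records")
  if (any(!is.na(tab$age_at_record) & tab$age_at_record < 0))
    stop("age_at_record must be >= 0")
  tab
}
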