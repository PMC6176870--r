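.norm_code <- function(code) toupper(gsub("[. ]", "", code))

#' Does a clinical code qualify as a CAD event?
#'
#' CAD is fatal or nonfatal myocardial infarction, or coronary
#' revascularization (CABG/PTCA). MI: ICD-9 codes with 3-digit root
#' 410-412, ICD-10 roots I21-I24 or the I25.2 subcode. Revascularization:
#' OPCS-4 roots K40-K46, K49, K75, or the K50.1 subcode. Matching is on
#' hierarchical prefixes, with or without the dot (410.1 qualifies under
#' 410; K50.2 does not qualify because only K50.1 is listed).
#'
#' @param system one of `"ICD9"`, `"ICD10"`, `"OPCS4"`, `"SELF_REPORT"`
#'   (self-report codes never qualify here; self-report enters
#'   [classifyCAD()] through its explicit flags).
#' @param code code string.
#' @return `"MI"`, `"revascularization"`, or `"none"`.
#' @export
codeQualifiesCAD <- function(system, code) {
  if (length(system) > 1L || length(code) > 1L)
    return(mapply(codeQualifiesCAD, system, code, USE.NAMES = FALSE))
  nc <- .norm_code(code)
  switch(system,
    ICD9 = {
      root <- suppressWarnings(as.integer(substr(nc, 1L, 3L)))
      if (!is.na(root) && root >= 410L && root <= 412L) "MI" else "none"
    },
    ICD10 = {
      root <- substr(nc, 1L, 3L)
      if (root %in% c("I21", "I22", "I23", "I24")) "MI"
      else if (startsWith(nc, "I252")) "MI"
      else "none"
    },
    OPCS4 = {
      root <- substr(nc, 1L, 3L)
      if (root %in% c(sprintf("K%02d", 40:46), "K49", "K75"))
        "revascularization"
      else if (startsWith(nc, "K501")) "revascularization"
      else "none"
    },
    SELF_REPORT = "none",
    stop(sprintf("unknown coding system '%s'", system)))
}

#' Classify CAD status for one sample
#'
#' A sample is a CAD case iff any hospital/death record carries a
#' qualifying code or any self-report criterion holds (doctor-diagnosed
#' heart attack, or self-reported PTCA/CABG operation). The age at first
#' event is the minimum of the earliest qualifying record age and the
#' self-reported age — when both are available the smaller value is used.
#' Timing is prevalent iff that age is at or before the assessment age,
#' else incident.
#'
#' @param records data.frame of coded records for one sample
#'   ([readCodedRecords()] layout); hospital/death records must carry ages.
#' @param self_report list with `had_mi` (logical), `age` (self-reported
#'   event age or NA), `had_ops` (logical, self-reported
#'   PTCA/CABG/bypass).
#' @param age_at_assessment assessment age in years.
#' @return list: `is_cad_case`, `age_at_first_event` (NA for non-cases),
#'   `timing` (`"prevalent"`/`"incident"`/`"none"`), `qualifying_sources`
#'   (subset of `self_report`, `hospital`, `death`), `flagged` (TRUE when
#'   the sample is a case with no resolvable event age and must be
#'   excluded).
#' @export
classifyCAD <- function(records,
                        self_report = list(had_mi = FALSE, age = NA_real_,
                                           had_ops = FALSE),
                        age_at_assessment) {
  stopifnot(is.numeric(age_at_assessment), length(age_at_assessment) == 1L)
  qual_rec <- logical(0)
  rec_src <- character(0)
  rec_age <- numeric(0)
  if (!is.null(records) && nrow(records)) {
    hosp <- records$source %in% c("hospital", "death")
    q <- codeQualifiesCAD(records$system, records$code) != "none" & hosp
    if (any(q & is.na(records$age_at_record)))
      stop("hospital/death record without age")
    qual_rec <- q
    rec_src <- records$source[q]
    rec_age <- records$age_at_record[q]
  }
  self_case <- isTRUE(self_report$had_mi) || isTRUE(self_report$had_ops)
  is_case <- any(qual_rec) || self_case
  if (!is_case)
    return(list(is_cad_case = FALSE, age_at_first_event = NA_real_,
                timing = "none", qualifying_sources = character(0),
                flagged = FALSE))

  ages <- c(if (length(rec_age)) min(rec_age),
            if (self_case && !is.na(self_report$age)) self_report$age)
  if (!length(ages))
    return(list(is_cad_case = TRUE, age_at_first_event = NA_real_,
                timing = "none", qualifying_sources = "self_report",
                flagged = TRUE))
  age_first <- min(ages)
  sources <- unique(c(if (self_case) "self_report", rec_src))
  list(is_cad_case = TRUE, age_at_first_event = age_first,
       timing = if (age_first <= age_at_assessment) "prevalent"
                else "incident",
       qualifying_sources = sources, flagged = FALSE)
}

#' Hypertension flag from medication and blood pressure
#'
#' Expanded hypertension definition: on blood-pressure medication, or
#' systolic pressure strictly above 140 mm Hg, or diastolic strictly above
#' 90 mm Hg. Boundary equality does not qualify. All inputs missing gives
#' NA (undetermined, excluded from flag counting).
#'
#' @param on_bp_meds logical or NA.
#' @param sbp,dbp systolic / diastolic pressure in mm Hg, or NA.
#' @return logical or NA.
#' @export
deriveHypertension <- function(on_bp_meds, sbp = NA_real_, dbp = NA_real_) {
  if (is.na(on_bp_meds) && is.na(sbp) && is.na(dbp)) return(NA)
  isTRUE(on_bp_meds) | isTRUE(sbp > 140) | isTRUE(dbp > 90)
}

#' Conventional risk-factor profile for one sample
#'
#' Derives the six conventional risk factors: diagnosed diabetes, current
#' smoking, hypertension (expanded definition, [deriveHypertension()]),
#' family history of heart disease in any first-degree relative (father,
#' mother, sibling), high cholesterol (self-reported at assessment, or
#' ICD-9 272.0 / ICD-10 E78.0 in hospital/death records), and obesity
#' (BMI strictly above 30 kg/m^2). Undetermined factors (all inputs
#' missing) count as not elevated but are listed in `undetermined`.
#'
#' @param assessment list/one-row data.frame with `diabetes`,
#'   `current_smoking`, `self_reported_high_cholesterol`,
#'   `family_history_father`, `family_history_mother`,
#'   `family_history_sibling`, `bmi`, `on_bp_meds`, `sbp`, `dbp` (any may
#'   be NA).
#' @param records coded records for the sample (may be NULL).
#' @return list with the six logical flags, `n_elevated` (count of TRUE)
#'   and `undetermined` (character vector of factors with no data).
#' @export
deriveRiskFactors <- function(assessment, records = NULL) {
  g <- function(f) if (is.null(assessment[[f]])) NA else assessment[[f]]
  chol_rec <- FALSE
  if (!is.null(records) && nrow(records)) {
    nc <- .norm_code(records$code)
    chol_rec <- any((records$system == "ICD9" & startsWith(nc, "2720")) |
                      (records$system == "ICD10" & startsWith(nc, "E780")))
  }
  fam <- c(g("family_history_father"), g("family_history_mother"),
           g("family_history_sibling"))
  flags <- list(
    diabetes = g("diabetes"),
    current_smoking = g("current_smoking"),
    hypertension = deriveHypertension(g("on_bp_meds"), g("sbp"), g("dbp")),
    family_history = if (all(is.na(fam))) NA else any(fam, na.rm = TRUE),
    high_cholesterol = if (chol_rec) TRUE
      else g("self_reported_high_cholesterol"),
    obesity = if (is.na(g("bmi"))) NA else g("bmi") > 30)
  undetermined <- names(flags)[vapply(flags, is.na, logical(1))]
  counted <- vapply(flags, isTRUE, logical(1))
  c(lapply(flags, function(x) if (is.na(x)) FALSE else x),
    list(n_elevated = sum(counted), undetermined = undetermined))
}

#' Phenotype a whole cohort from coded records and assessment fields
#'
#' Applies [classifyCAD()] and [deriveRiskFactors()] per sample. Samples
#' that are cases with no resolvable event age are flagged and excluded
#' from the returned table (mirroring exclusion of participants without
#' event-date information), with their ids in `attr(, "excluded")`.
#'
#' @param records coded records table.
#' @param assessment data.frame with one row per sample: `sample_id`,
#'   `age_at_assessment`, the self-report fields `self_reported_mi`,
#'   `self_reported_mi_age`, `self_reported_ops`, and the risk-factor
#'   inputs of [deriveRiskFactors()].
#' @return data.frame with one row per retained sample: case status,
#'   event age, timing, qualifying sources, the six risk-factor flags and
#'   `n_elevated`.
#' @export
phenotypeCohort <- function(records, assessment) {
  res <- vector("list", nrow(assessment))
  excluded <- character(0)
  rec_split <- if (!is.null(records) && nrow(records))
    split(records, records$sample_id) else list()
  for (i in seq_len(nrow(assessment))) {
    a <- assessment[i, ]
    rec <- rec_split[[a$sample_id]]
    cls <- classifyCAD(rec,
                       list(had_mi = isTRUE(a$self_reported_mi),
                            age = if (is.null(a$self_reported_mi_age)) NA_real_
                                  else a$self_reported_mi_age,
                            had_ops = isTRUE(a$self_reported_ops)),
                       a$age_at_assessment)
    if (cls$flagged) { excluded <- c(excluded, a$sample_id); next }
    rf <- deriveRiskFactors(as.list(a), rec)
    res[[i]] <- data.frame(
      sample_id = a$sample_id, is_cad_case = cls$is_cad_case,
      age_at_first_event = cls$age_at_first_event, timing = cls$timing,
      qualifying_sources = paste(cls$qualifying_sources, collapse = ","),
      diabetes = rf$diabetes, current_smoking = rf$current_smoking,
      hypertension = rf$hypertension, family_history = rf$family_history,
      high_cholesterol = rf$high_cholesterol, obesity = rf$obesity,
      n_elevated = rf$n_elevated, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
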