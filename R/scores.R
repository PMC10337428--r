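# Trauma scoring: RTS coding/weighting and NISS from AIS severities.

#' Revised Trauma Score coefficients
#'
#' The fixed weights of the standard (weighted) Revised Trauma Score applied
#' to the coded Glasgow Coma Scale, systolic blood pressure, and respiratory
#' rate. The maximum attainable RTS is `sum(4 * rts_weights())` = 7.8408; the
#' smallest positive value reachable with a breathing-compatible code triple
#' (0, 1, 0) is 0.7326.
#'
#' @return Named numeric vector with elements `gcs`, `sbp`, `rr`.
#' @export
#' @examples
#' rts_weights()
#' sum(4 * rts_weights()) # 7.8408
rts_weights <- function() {
  c(gcs = 0.9368, sbp = 0.7326, rr = 0.2908)
}

#' Maximum attainable Revised Trauma Score
#'
#' @return `7.8408`, the weighted RTS for code triple (4, 4, 4).
#' @export
rts_max <- function() sum(4 * rts_weights())

code_gcs <- function(gcs) {
  ifelse(gcs >= 13, 4L, ifelse(gcs >= 9, 3L, ifelse(gcs >= 6, 2L,
    ifelse(gcs >= 4, 1L, 0L))))
}

code_sbp <- function(sbp) {
  ifelse(sbp > 89, 4L, ifelse(sbp >= 76, 3L, ifelse(sbp >= 50, 2L,
    ifelse(sbp >= 1, 1L, 0L))))
}

code_rr <- function(rr) {
  # 10-29 breaths/min is the physiological band (code 4); tachypnoea > 29
  # codes 3, hypopnoea codes 2 then 1, apnoea 0.
  ifelse(rr == 0, 0L, ifelse(rr >= 1 & rr <= 5, 1L, ifelse(rr <= 9, 2L,
    ifelse(rr <= 29, 4L, 3L))))
}

#' Code vital signs onto the 0-4 RTS scale
#'
#' Maps raw GCS, systolic blood pressure and respiratory rate onto the
#' standard Revised Trauma Score bands:
#' GCS 13-15 -> 4, 9-12 -> 3, 6-8 -> 2, 4-5 -> 1, 3 -> 0;
#' SBP (mmHg) > 89 -> 4, 76-89 -> 3, 50-75 -> 2, 1-49 -> 1, 0 -> 0;
#' RR (/min) 10-29 -> 4, > 29 -> 3, 6-9 -> 2, 1-5 -> 1, 0 -> 0.
#'
#' @param vitals Data frame with numeric columns `gcs` (3-15), `sbp`
#'   (mmHg, >= 0) and `rr` (breaths/min, >= 0). One row per patient.
#' @return Data frame with integer columns `gcs_code`, `sbp_code`, `rr_code`,
#'   each in 0-4.
#' @export
#' @examples
#' code_vitals(data.frame(gcs = 15, sbp = 85, rr = 35)) # codes 4, 3, 3
code_vitals <- function(vitals) {
  vitals <- as.data.frame(vitals)
  for (f in c("gcs", "sbp", "rr")) {
    if (is.null(vitals[[f]])) stop("vitals is missing required field '", f, "'")
    if (any(is.na(vitals[[f]]))) stop("field '", f, "' contains missing values")
  }
  if (any(vitals$gcs < 3 | vitals$gcs > 15))
    stop("field 'gcs' out of range: GCS must lie in 3-15")
  if (any(vitals$sbp < 0)) stop("field 'sbp' out of range: must be >= 0 mmHg")
  if (any(vitals$rr < 0)) stop("field 'rr' out of range: must be >= 0 /min")
  data.frame(
    gcs_code = code_gcs(vitals$gcs),
    sbp_code = code_sbp(vitals$sbp),
    rr_code = code_rr(vitals$rr)
  )
}

check_codes <- function(coding) {
  coding <- as.data.frame(coding)
  for (f in c("gcs_code", "sbp_code", "rr_code")) {
    v <- coding[[f]]
    if (is.null(v)) stop("coding is missing field '", f, "'")
    if (any(is.na(v)) || any(v != as.integer(v)) || any(v < 0 | v > 4))
      stop("field '", f, "' must contain integer codes in 0-4")
  }
  coding
}

#' Weighted Revised Trauma Score
#'
#' `RTS = 0.9368 * gcs_code + 0.7326 * sbp_code + 0.2908 * rr_code`.
#' Full floating-point precision is retained; round only for display
#' (printed values such as 6.8174 use 4 decimals).
#'
#' @param coding Data frame with integer columns `gcs_code`, `sbp_code`,
#'   `rr_code` (0-4 each), as returned by [code_vitals()].
#' @return Numeric vector of RTS values in \[0, 7.8408\].
#' @export
#' @examples
#' compute_rts(data.frame(gcs_code = 4, sbp_code = 3, rr_code = 3)) # 6.8174
compute_rts <- function(coding) {
  coding <- check_codes(coding)
  w <- rts_weights()
  as.numeric(w["gcs"] * coding$gcs_code + w["sbp"] * coding$sbp_code +
    w["rr"] * coding$rr_code)
}

#' Triage Revised Trauma Score (unweighted code sum)
#'
#' @inheritParams compute_rts
#' @return Integer vector of T-RTS values in 0-12.
#' @export
#' @examples
#' compute_t_rts(data.frame(gcs_code = 4, sbp_code = 3, rr_code = 3)) # 10
compute_t_rts <- function(coding) {
  coding <- check_codes(coding)
  as.integer(coding$gcs_code + coding$sbp_code + coding$rr_code)
}

#' New Injury Severity Score
#'
#' Sum of squares of the (up to) three highest AIS severities of a patient's
#' injuries, irrespective of body region. An AIS of 6 denotes an untreatable
#' injury and forces NISS = 75 by convention.
#'
#' @param ais Numeric vector of AIS severities (1-6) for one patient's 1-3
#'   injuries, or a list of such vectors for several patients.
#' @return Integer NISS in 1-75 (vector if `ais` is a list).
#' @export
#' @examples
#' compute_niss(c(4, 3, 2)) # 29
#' compute_niss(c(5, 5, 5)) # 75
compute_niss <- function(ais) {
  if (is.list(ais)) return(vapply(ais, compute_niss, integer(1)))
  ais <- ais[!is.na(ais)]
  if (length(ais) == 0) stop("at least one injury with a valid AIS is required")
  if (any(ais != as.integer(ais)) || any(ais < 1 | ais > 6))
    stop("AIS severities must be integers in 1-6")
  if (length(ais) > 3) stop("a patient carries at most 3 injuries")
  if (any(ais == 6)) return(75L)
  as.integer(sum(sort(ais, decreasing = TRUE)[seq_len(min(3, length(ais)))]^2))
}

vital_cols <- function() {
  c("gcs", "sbp", "rr", "hr", "spo2", "cap_refill_s", "walking",
    "radial_pulse_palpable", "obeys_commands",
    "breathing_after_airway_maneuver")
}

injury_cols <- function() {
  as.vector(t(outer(paste0("trauma_", 1:3), c("type", "location", "ais"),
    paste, sep = "_")))
}

ais_matrix <- function(patients) {
  cbind(patients$trauma_1_ais, patients$trauma_2_ais, patients$trauma_3_ais)
}

#' Validate a patient table
#'
#' Checks physiological ranges and the cross-field dependency rules of the
#' vital-sign record: SBP < 80 mmHg implies a non-palpable radial pulse,
#' GCS < 9 implies commands are not obeyed, and apnoea (RR = 0) implies the
#' patient cannot walk. Injuries, when present, must have AIS 1-6 and belong
#' to `catalog` if one is supplied.
#'
#' @param patients Data frame with columns `patient_id`, the vital-sign
#'   columns (`gcs`, `sbp`, `rr`, `cap_refill_s`, `walking`,
#'   `radial_pulse_palpable`, `obeys_commands`,
#'   `breathing_after_airway_maneuver`, optionally `hr`, `spo2`) and injury
#'   columns `trauma_<i>_type`, `trauma_<i>_location`, `trauma_<i>_ais` for
#'   i in 1-3 (slots beyond the first may be `NA`).
#' @param catalog Optional trauma catalog (see [default_trauma_catalog()]);
#'   when given, every (type, location) pair must be listed in it.
#' @return `patients`, invisibly, if valid; otherwise an error naming the
#'   offending field and patient.
#' @export
validate_patients <- function(patients, catalog = NULL) {
  patients <- as.data.frame(patients)
  if (is.null(patients$patient_id)) stop("missing 'patient_id' column")
  if (anyDuplicated(patients$patient_id))
    stop("patient_id values must be unique")
  code_vitals(patients) # range checks on gcs/sbp/rr
  if (any(patients$cap_refill_s < 0))
    stop("field 'cap_refill_s' out of range: must be >= 0 s")
  if (!is.null(patients$spo2) &&
      any(!is.na(patients$spo2) & (patients$spo2 < 0 | patients$spo2 > 100)))
    stop("field 'spo2' out of range: must be in 0-100 %")
  if (!is.null(patients$hr) && any(!is.na(patients$hr) & patients$hr < 0))
    stop("field 'hr' out of range: must be >= 0 /min")
  bad <- patients$sbp < 80 & patients$radial_pulse_palpable
  if (any(bad))
    stop("radial pulse cannot be palpable with SBP < 80 mmHg (patient ",
      patients$patient_id[which(bad)[1]], ")")
  bad <- patients$gcs < 9 & patients$obeys_commands
  if (any(bad))
    stop("commands cannot be obeyed with GCS < 9 (patient ",
      patients$patient_id[which(bad)[1]], ")")
  bad <- patients$rr == 0 & patients$walking
  if (any(bad))
    stop("an apnoeic patient cannot walk (patient ",
      patients$patient_id[which(bad)[1]], ")")
  ais <- ais_matrix(patients)
  if (is.null(ais) || ncol(ais) == 0 || all(is.na(ais)))
    stop("every patient needs at least one injury (trauma_1_* columns)")
  if (any(is.na(ais[, 1])))
    stop("every patient needs at least one injury (patient ",
      patients$patient_id[which(is.na(ais[, 1]))[1]], ")")
  ok <- is.na(ais) | (ais == round(ais) & ais >= 1 & ais <= 6)
  if (!all(ok)) stop("AIS severities must be integers in 1-6 (patient ",
    patients$patient_id[which(!apply(ok, 1, all))[1]], ")")
  if (!is.null(catalog)) {
    key <- paste(catalog$trauma_type, catalog$body_location)
    for (i in 1:3) {
      ty <- patients[[paste0("trauma_", i, "_type")]]
      lo <- patients[[paste0("trauma_", i, "_location")]]
      has <- !is.na(ty)
      bad <- has & !(paste(ty, lo) %in% key)
      if (any(bad))
        stop("injury (", ty[which(bad)[1]], ", ", lo[which(bad)[1]],
          ") is not in the active trauma catalog (patient ",
          patients$patient_id[which(bad)[1]], ")")
    }
  }
  invisible(patients)
}

#' Attach derived trauma scores to a patient table
#'
#' Computes NISS from the injury AIS columns and the weighted RTS and T-RTS
#' from the coded vitals, overwriting any existing `niss`, `rts`, `t_rts`
#' columns.
#'
#' @inheritParams validate_patients
#' @param validate Run [validate_patients()] first (default `TRUE`).
#' @return `patients` with `niss`, `rts` and `t_rts` columns appended.
#' @export
score_patients <- function(patients, catalog = NULL, validate = TRUE) {
  patients <- as.data.frame(patients)
  if (validate) validate_patients(patients, catalog)
  ais <- ais_matrix(patients)
  niss <- apply(ais, 1, function(a) compute_niss(a[!is.na(a)]))
  coding <- code_vitals(patients)
  patients$niss <- as.integer(niss)
  patients$rts <- compute_rts(coding)
  patients$t_rts <- compute_t_rts(coding)
  patients
}
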