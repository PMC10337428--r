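# Readers/writers for patient tables and reports (CSV and JSON).

patient_columns <- function() {
  c("patient_id", injury_cols(), vital_cols())
}

coerce_patient_types <- function(patients) {
  for (f in c("walking", "radial_pulse_palpable", "obeys_commands",
    "breathing_after_airway_maneuver"))
    if (!is.null(patients[[f]])) patients[[f]] <- as.logical(patients[[f]])
  for (f in c("gcs", "sbp", "rr", "hr", "spo2", "cap_refill_s",
    paste0("trauma_", 1:3, "_ais")))
    if (!is.null(patients[[f]])) patients[[f]] <- as.numeric(patients[[f]])
  patients
}

#' Read a patient table from CSV or JSON
#'
#' Reads, validates, and (re)scores a patient table. When the file already
#' carries `niss`, `rts` or `t_rts` columns, they are checked against the
#' values recomputed from the injuries and vitals; any inconsistency is a
#' validation error naming the patient.
#'
#' @param path File to read.
#' @param format `"csv"` or `"json"`; guessed from the file extension by
#'   default.
#' @param catalog Optional catalog to validate injuries against.
#' @return Scored patient data frame.
#' @export
read_patients <- function(path, format = c("auto", "csv", "json"),
                          catalog = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  patients <- if (format == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  for (f in names(patients)) # empty CSV cells are absent values
    if (is.character(patients[[f]])) patients[[f]][patients[[f]] == ""] <- NA

  missing_cols <- setdiff(setdiff(patient_columns(), c("hr", "spo2",
    paste0("trauma_", 2:3, "_type"), paste0("trauma_", 2:3, "_location"),
    paste0("trauma_", 2:3, "_ais"))), names(patients))
  if (length(missing_cols) > 0)
    stop("malformed patient table ", path, ": missing column(s) ",
      paste(missing_cols, collapse = ", "))
  for (i in 2:3) for (suf in c("type", "location", "ais")) {
    col <- paste0("trauma_", i, "_", suf)
    if (is.null(patients[[col]])) patients[[col]] <- NA
  }
  patients <- coerce_patient_types(patients)
  req <- c("gcs", "sbp", "rr", "cap_refill_s", "walking",
    "radial_pulse_palpable", "obeys_commands",
    "breathing_after_airway_maneuver")
  for (f in req) {
    bad <- which(is.na(patients[[f]]))
    if (length(bad) > 0)
      stop("malformed row ", bad[1] + 1L, " in ", path,
        ": missing or unparseable '", f, "'")
  }
  declared <- patients[intersect(c("niss", "rts", "t_rts"), names(patients))]
  patients$niss <- patients$rts <- patients$t_rts <- NULL
  patients <- score_patients(patients, catalog = catalog)
  for (f in names(declared)) {
    mism <- which(abs(as.numeric(declared[[f]]) - patients[[f]]) > 1e-4)
    if (length(mism) > 0)
      stop("declared ", f, " is inconsistent with vitals/injuries for ",
        "patient ", patients$patient_id[mism[1]])
  }
  patients
}

#' Write a patient table to CSV or JSON
#'
#' @param patients Patient data frame.
#' @param path Output file.
#' @param format `"csv"` or `"json"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    jsonlite::write_json(patients, path, dataframe = "rows", na = "null",
      digits = NA)
  } else {
    utils::write.csv(patients, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Write a scenario report
#'
#' CSV output holds the per-patient summary table; JSON output additionally
#' carries the sampled trajectories.
#'
#' @param report A [run_scenario()] result.
#' @param path Output file.
#' @param format `"csv"` or `"json"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    jsonlite::write_json(list(label = report$label, table = report$table,
      trajectories = report$trajectories), path, dataframe = "rows",
      na = "null", digits = NA)
  } else {
    utils::write.csv(report$table, path, row.names = FALSE)
  }
  invisible(path)
}
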