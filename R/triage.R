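# Comparator triage classifiers: START, T-RTS banding, and LIFE
# survival-time banding. Categories follow the classic colour scheme.

#' Triage category levels
#'
#' @return Character vector `c("green", "yellow", "red", "black")`: minimal,
#'   delayed, immediate, deceased/expectant.
#' @export
triage_levels <- function() c("green", "yellow", "red", "black")

as_category <- function(x) factor(x, levels = triage_levels())

#' LIFE triage category thresholds
#'
#' LIFE triage bins the continuous survival-time ranking back into the four
#' classic categories using ranges of the maximal survival time without
#' treatment. The defaults were calibrated against the default generator
#' (see the methods vignette) so that no patient with NISS > 25 can be
#' green, every yellow patient has NISS 10-25, and every green patient has
#' RTS > 7.5.
#'
#' @param black_max_min Survival times up to this bound (minutes) are black
#'   (default 30).
#' @param red_max_min Upper bound of the red band (default 7200 = 5 days).
#' @param yellow_max_min Upper bound of the yellow band (default 8500);
#'   anything longer is green.
#' @param t_horizon_min Model horizon the bounds must stay below.
#' @return A validated `life_thresholds` list.
#' @export
life_thresholds <- function(black_max_min = 30, red_max_min = 7200,
                            yellow_max_min = 8500, t_horizon_min = 10080) {
  if (!(black_max_min > 0 && black_max_min < red_max_min &&
        red_max_min < yellow_max_min && yellow_max_min < t_horizon_min))
    stop("thresholds must satisfy 0 < black < red < yellow < horizon")
  structure(list(black_max_min = black_max_min, red_max_min = red_max_min,
    yellow_max_min = yellow_max_min), class = "life_thresholds")
}

check_vitals_complete <- function(patients, fields) {
  for (f in fields) {
    if (is.null(patients[[f]]) || any(is.na(patients[[f]])))
      stop("triage requires complete vital field '", f, "'")
  }
}

#' START triage
#'
#' The Simple Triage And Rapid Treatment cascade, vitals-only: a walking
#' patient is green; otherwise a patient not breathing after an airway
#' maneuver is black; then respiratory rate > 30/min, capillary refill
#' > 2 s or a non-palpable radial pulse, or failure to obey commands each
#' give red; anyone left is yellow. START never looks at injury severity.
#'
#' @param patients Patient table with the vital-sign columns (see
#'   [validate_patients()]).
#' @return Factor of categories with levels [triage_levels()].
#' @export
start_triage <- function(patients) {
  patients <- as.data.frame(patients)
  check_vitals_complete(patients, c("walking",
    "breathing_after_airway_maneuver", "rr", "cap_refill_s",
    "radial_pulse_palpable", "obeys_commands"))
  out <- ifelse(patients$walking, "green",
    ifelse(!patients$breathing_after_airway_maneuver, "black",
      ifelse(patients$rr > 30 | patients$cap_refill_s > 2 |
          !patients$radial_pulse_palpable | !patients$obeys_commands,
        "red", "yellow")))
  as_category(out)
}

#' T-RTS triage
#'
#' Field triage on the unweighted code sum: a patient not breathing after
#' an airway maneuver is black; otherwise T-RTS 12 is green, 11 yellow,
#' 4-10 red, and 3 or below black.
#'
#' @inheritParams start_triage
#' @return Factor of categories with levels [triage_levels()].
#' @export
rts_triage <- function(patients) {
  patients <- as.data.frame(patients)
  check_vitals_complete(patients,
    c("breathing_after_airway_maneuver", "gcs", "sbp", "rr"))
  t_rts <- compute_t_rts(code_vitals(patients))
  out <- ifelse(!patients$breathing_after_airway_maneuver, "black",
    ifelse(t_rts == 12, "green", ifelse(t_rts == 11, "yellow",
      ifelse(t_rts >= 4, "red", "black"))))
  as_category(out)
}

#' LIFE triage
#'
#' Bins the survival time without treatment into categories: a patient not
#' breathing after an airway maneuver is black (keeping the black category
#' consistent with START and T-RTS triage); otherwise survival times up to
#' `black_max_min` are black, up to `red_max_min` red, up to
#' `yellow_max_min` yellow, and anything longer green.
#'
#' @param patients Scored patient table (`rts`, `niss`, vitals columns).
#' @param thresholds A [life_thresholds()] object.
#' @param params A [life_params()] object.
#' @return Factor of categories with levels [triage_levels()].
#' @export
life_triage <- function(patients, thresholds = life_thresholds(),
                        params = life_params()) {
  patients <- as.data.frame(patients)
  if (!inherits(thresholds, "life_thresholds"))
    stop("thresholds must be created with life_thresholds()")
  if (is.null(patients$rts) || is.null(patients$niss))
    stop("patients must be scored first (see score_patients())")
  s <- survival_time_without_treatment(patients$rts, patients$niss, params)
  out <- ifelse(s <= thresholds$black_max_min, "black",
    ifelse(s <= thresholds$red_max_min, "red",
      ifelse(s <= thresholds$yellow_max_min, "yellow", "green")))
  if (!is.null(patients$breathing_after_airway_maneuver))
    out[!patients$breathing_after_airway_maneuver] <- "black"
  as_category(out)
}

#' Apply several triage algorithms to a cohort
#'
#' @param patients Scored patient table.
#' @param algorithms Subset of `c("start", "rts", "life")`.
#' @param thresholds,params Passed to [life_triage()] / ranking.
#' @return Data frame with `patient_id`, one category column per requested
#'   algorithm, and (when `"life"` is requested) `survival_time_min` and
#'   `life_priority`.
#' @export
triage_all <- function(patients, algorithms = c("start", "rts", "life"),
                       thresholds = life_thresholds(),
                       params = life_params()) {
  patients <- as.data.frame(patients)
  known <- c("start", "rts", "life")
  if (length(algorithms) == 0)
    return(data.frame(patient_id = patients$patient_id)[0, , drop = FALSE])
  bad <- setdiff(algorithms, known)
  if (length(bad) > 0)
    stop("unknown algorithm(s) ", paste(bad, collapse = ", "),
      "; registered algorithms: ", paste(known, collapse = ", "))
  out <- data.frame(patient_id = patients$patient_id)
  if ("start" %in% algorithms) out$start <- start_triage(patients)
  if ("rts" %in% algorithms) out$rts <- rts_triage(patients)
  if ("life" %in% algorithms) {
    out$life <- life_triage(patients, thresholds, params)
    out$survival_time_min <-
      survival_time_without_treatment(patients$rts, patients$niss, params)
    rk <- rank_cohort(patients, params)
    out$life_priority <-
      rk$life_priority[match(out$patient_id, rk$patient_id)]
  }
  out
}
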