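# Mass-casualty scenario runner and the bundled 10-casualty demonstration.

#' Bundled 10-casualty demonstration scenario
#'
#' A reconstruction (not the original roster) of a multiple-vehicle
#' collision with ten casualties, built so that the qualitative relations
#' of interest all hold: START buckets the cohort into 2 red / 3 yellow /
#' 5 green; patient P02 walks despite a severe injury load (NISS 35,
#' RTS 6.8174) and is therefore START-green yet holds LIFE priority 2;
#' P06 and P07 share NISS 18 but differ in vital signs, so the ranking
#' separates them; P06 is START-red yet has lower urgency than P02.
#'
#' @return Scored 10-patient data frame.
#' @export
demo_scenario <- function() {
  inj <- function(t1, l1, a1, t2 = NA, l2 = NA, a2 = NA,
                  t3 = NA, l3 = NA, a3 = NA)
    list(t1, l1, a1, t2, l2, a2, t3, l3, a3)
  rows <- list(
    P01 = c(inj("traumatic_brain_injury", "head", 5, "crush", "chest", 4,
      "hemorrhage", "abdomen", 3),
      gcs = 6, sbp = 70, rr = 32, hr = 135, spo2 = 82, cap = 4.0,
      walk = FALSE, pulse = FALSE, obeys = FALSE, breath = TRUE),
    P02 = c(inj("spinal_cord_injury", "spine", 5, "blunt", "chest", 3,
      "laceration", "face", 1),
      gcs = 15, sbp = 85, rr = 35, hr = 110, spo2 = 93, cap = 1.8,
      walk = TRUE, pulse = TRUE, obeys = TRUE, breath = TRUE),
    P03 = c(inj("crush", "chest", 4, "hemorrhage", "abdomen", 3,
      "contusion", "back", 1),
      gcs = 13, sbp = 88, rr = 24, hr = 118, spo2 = 90, cap = 1.8,
      walk = FALSE, pulse = TRUE, obeys = TRUE, breath = TRUE),
    P04 = c(inj("fracture", "lower_extremity_left", 3, "fracture",
      "lower_extremity_right", 3, "dislocation", "upper_extremity_left", 1),
      gcs = 15, sbp = 105, rr = 18, hr = 95, spo2 = 97, cap = 1.2,
      walk = FALSE, pulse = TRUE, obeys = TRUE, breath = TRUE),
    P05 = c(inj("burn", "upper_extremity_left", 2, "burn", "face", 2,
      "contusion", "head", 2),
      gcs = 15, sbp = 115, rr = 16, hr = 90, spo2 = 97, cap = 1.0,
      walk = TRUE, pulse = TRUE, obeys = TRUE, breath = TRUE),
    P06 = c(inj("blunt", "chest", 3, "hemorrhage", "pelvis", 3),
      gcs = 14, sbp = 85, rr = 24, hr = 112, spo2 = 92, cap = 3.0,
      walk = FALSE, pulse = TRUE, obeys = TRUE, breath = TRUE),
    P07 = c(inj("penetrating", "chest", 3, "crush", "pelvis", 3),
      gcs = 15, sbp = 110, rr = 18, hr = 98, spo2 = 95, cap = 1.5,
      walk = FALSE, pulse = TRUE, obeys = TRUE, breath = TRUE),
    P08 = c(inj("laceration", "lower_extremity_left", 2, "dislocation",
      "lower_extremity_right", 2),
      gcs = 15, sbp = 120, rr = 14, hr = 85, spo2 = 98, cap = 1.2,
      walk = TRUE, pulse = TRUE, obeys = TRUE, breath = TRUE),
    P09 = c(inj("contusion", "head", 2),
      gcs = 15, sbp = 125, rr = 14, hr = 78, spo2 = 99, cap = 0.8,
      walk = TRUE, pulse = TRUE, obeys = TRUE, breath = TRUE),
    P10 = c(inj("penetrating", "lower_extremity_right", 2, "fracture",
      "spine", 3),
      gcs = 15, sbp = 118, rr = 16, hr = 88, spo2 = 97, cap = 1.0,
      walk = TRUE, pulse = TRUE, obeys = TRUE, breath = TRUE)
  )
  df <- do.call(rbind, lapply(names(rows), function(id) {
    r <- rows[[id]]
    data.frame(patient_id = id,
      trauma_1_type = r[[1]], trauma_1_location = r[[2]],
      trauma_1_ais = as.numeric(r[[3]]),
      trauma_2_type = as.character(r[[4]]),
      trauma_2_location = as.character(r[[5]]),
      trauma_2_ais = as.numeric(r[[6]]),
      trauma_3_type = as.character(r[[7]]),
      trauma_3_location = as.character(r[[8]]),
      trauma_3_ais = as.numeric(r[[9]]),
      gcs = r$gcs, sbp = r$sbp, rr = r$rr, hr = r$hr, spo2 = r$spo2,
      cap_refill_s = r$cap, walking = r$walk,
      radial_pulse_palpable = r$pulse, obeys_commands = r$obeys,
      breathing_after_airway_maneuver = r$breath)
  }))
  score_patients(df, catalog = default_trauma_catalog())
}

#' Run a mass-casualty scenario end to end
#'
#' Scores every patient, applies all three triage algorithms, ranks the
#' cohort by anticipated survival time, and samples each patient's LIFE
#' trajectory for plotting.
#'
#' @param patients Patient table (scored or not; ids must be unique).
#' @param params [life_params()].
#' @param thresholds [life_thresholds()].
#' @param t_grid Time grid (minutes) for the sampled trajectories.
#' @param label Free-text scenario label.
#' @return A `scenario_report` list: `label`; `table` with per-patient
#'   NISS, RTS, all three categories, survival time and LIFE priority
#'   (priorities are a permutation of 1..n); and `trajectories`, a data
#'   frame of `time_min` plus one LIFE-percentage column per patient.
#' @export
run_scenario <- function(patients, params = life_params(),
                         thresholds = life_thresholds(),
                         t_grid = seq(0, params$t_horizon_min, by = 30),
                         label = "scenario") {
  patients <- as.data.frame(patients)
  if (nrow(patients) < 1) stop("a scenario needs at least one patient")
  ok <- try(validate_patients(patients), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("unscorable patient table: ", attr(ok, "condition")$message)
  patients <- score_patients(patients, validate = FALSE)
  tri <- triage_all(patients, params = params, thresholds = thresholds)
  names(tri)[names(tri) == "rts"] <- "rts_triage"
  names(tri)[names(tri) == "start"] <- "start_triage"
  names(tri)[names(tri) == "life"] <- "life_triage"
  tab <- data.frame(patient_id = patients$patient_id,
    niss = patients$niss, rts = patients$rts, t_rts = patients$t_rts)
  tab <- merge(tab, tri, by = "patient_id", sort = FALSE)
  tab <- tab[order(tab$life_priority), ]
  rownames(tab) <- NULL
  traj <- vapply(seq_len(nrow(patients)), function(i)
    life_percentage(patients$rts[i], patients$niss[i], t_grid, params),
    numeric(length(t_grid)))
  traj <- as.data.frame(traj)
  names(traj) <- patients$patient_id
  traj <- cbind(time_min = t_grid, traj)
  structure(list(label = label, table = tab, trajectories = traj),
    class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("Scenario:", x$label, "(", nrow(x$table), "casualties )\n")
  tab <- x$table
  tab$rts <- sprintf("%.4f", tab$rts)
  tab$survival_time_min <- sprintf("%.0f", tab$survival_time_min)
  print(tab[, c("life_priority", "patient_id", "niss", "rts",
    "start_triage", "rts_triage", "life_triage", "survival_time_min")],
    row.names = FALSE)
  invisible(x)
}
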