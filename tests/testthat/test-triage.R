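test_that("START follows the decision cascade", {
  # a walking patient is green no matter how severe the injuries
  walk <- score_patients(base_patient(gcs = 15, sbp = 85, rr = 35,
    walking = TRUE, trauma_1_type = "spinal_cord_injury",
    trauma_1_location = "spine", trauma_1_ais = 5))
  expect_equal(walk$niss, 25L)
  expect_identical(as.character(start_triage(walk)), "green")
  # not breathing after the airway maneuver: black
  apnoea <- base_patient(gcs = 3, sbp = 60, rr = 0, walking = FALSE,
    radial_pulse_palpable = FALSE, obeys_commands = FALSE,
    breathing_after_airway_maneuver = FALSE)
  expect_identical(as.character(start_triage(apnoea)), "black")
  # red rules: tachypnoea, perfusion, mental status
  expect_identical(as.character(start_triage(base_patient(rr = 31,
    walking = FALSE))), "red")
  expect_identical(as.character(start_triage(base_patient(
    cap_refill_s = 2.5, walking = FALSE))), "red")
  expect_identical(as.character(start_triage(base_patient(sbp = 70,
    radial_pulse_palpable = FALSE, walking = FALSE))), "red")
  expect_identical(as.character(start_triage(base_patient(gcs = 10,
    obeys_commands = FALSE, walking = FALSE))), "red")
  # falls through every red rule: yellow
  expect_identical(as.character(start_triage(base_patient(rr = 16,
    cap_refill_s = 1.5, walking = FALSE))), "yellow")
  expect_error(start_triage(base_patient(walking = NA)), "walking")
})

test_that("T-RTS triage bands the code sum", {
  tri <- function(gcs, sbp, rr, breathing = TRUE)
    as.character(rts_triage(base_patient(gcs = gcs, sbp = sbp, rr = rr,
      walking = FALSE, obeys_commands = gcs >= 13,
      radial_pulse_palpable = sbp >= 80,
      breathing_after_airway_maneuver = breathing)))
  expect_identical(tri(15, 120, 16), "green")            # T-RTS 12
  expect_identical(tri(15, 85, 16), "yellow")            # T-RTS 11
  expect_identical(tri(15, 85, 35), "red")               # T-RTS 10
  expect_identical(tri(3, 60, 12), "red")                # T-RTS 0+2+4 = 6
  expect_identical(tri(3, 30, 0), "black")               # T-RTS 1
  expect_identical(tri(15, 120, 0, breathing = FALSE), "black")
})

test_that("LIFE triage bands the survival time and honours calibration", {
  thr <- life_thresholds()
  p <- life_params()
  dead <- score_patients(base_patient(gcs = 3, sbp = 0, rr = 0,
    walking = FALSE, radial_pulse_palpable = FALSE, obeys_commands = FALSE,
    breathing_after_airway_maneuver = FALSE))
  expect_equal(dead$rts, 0)
  expect_identical(as.character(life_triage(dead, thr, p)), "black")
  fine <- score_patients(base_patient(trauma_1_ais = 1)) # NISS 1, RTS max
  expect_identical(as.character(life_triage(fine, thr, p)), "green")
  stable_severe <- score_patients(base_patient(gcs = 15, sbp = 85, rr = 35,
    walking = TRUE, trauma_1_type = "spinal_cord_injury",
    trauma_1_location = "spine", trauma_1_ais = 5,
    trauma_2_type = "blunt", trauma_2_location = "chest", trauma_2_ais = 3,
    trauma_3_type = "laceration", trauma_3_location = "face",
    trauma_3_ais = 1))
  expect_equal(stable_severe$niss, 35L)
  expect_true(as.character(life_triage(stable_severe, thr, p)) %in%
    c("red", "yellow"))
  expect_error(life_triage(fine, thresholds = list(black_max_min = 1)),
    "life_thresholds")
  expect_error(life_thresholds(red_max_min = 10), "black < red")
})

test_that("triage_all partitions the cohort per algorithm", {
  d <- demo_scenario()
  tri <- triage_all(d)
  expect_identical(nrow(tri), 10L)
  for (a in c("start", "rts", "life"))
    expect_identical(sum(table(tri[[a]])), 10L)
  expect_setequal(tri$life_priority, 1:10)
  expect_identical(nrow(triage_all(d, character(0))), 0L)
  expect_error(triage_all(d, "salt"), "registered algorithms")
})

test_that("an RTS-0 cohort is black under all three algorithms", {
  dead <- do.call(rbind, lapply(1:3, function(i)
    base_patient(paste0("D", i), gcs = 3, sbp = 0, rr = 0, walking = FALSE,
      radial_pulse_palpable = FALSE, obeys_commands = FALSE,
      breathing_after_airway_maneuver = FALSE)))
  dead <- score_patients(dead)
  tri <- triage_all(dead)
  for (a in c("start", "rts", "life"))
    expect_true(all(tri[[a]] == "black"))
})

test_that("START ignores the NISS; LIFE triage does not", {
  pair <- rbind(
    base_patient("lo", walking = FALSE, trauma_1_ais = 1),
    base_patient("hi", walking = FALSE, trauma_1_type = "spinal_cord_injury",
      trauma_1_location = "spine", trauma_1_ais = 5,
      trauma_2_type = "crush", trauma_2_location = "chest",
      trauma_2_ais = 4))
  pair <- score_patients(pair)
  expect_identical(pair$rts[1], pair$rts[2]) # identical vitals
  tri <- triage_all(pair)
  expect_identical(as.character(tri$start[1]), as.character(tri$start[2]))
  expect_false(as.character(tri$life[1]) == as.character(tri$life[2]))
  expect_gt(tri$survival_time_min[1], tri$survival_time_min[2])
})

test_that("non-breathing patients are black under every algorithm (cohort)", {
  coh <- cached_default_cohort()
  tri <- triage_all(coh)
  nb <- !coh$breathing_after_airway_maneuver
  expect_gt(sum(nb), 0)
  for (a in c("start", "rts", "life"))
    expect_true(all(tri[[a]][nb] == "black"))
})
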