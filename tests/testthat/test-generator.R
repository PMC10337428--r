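test_that("enumeration yields all 1-3 subsets of allowed pairs", {
  toy <- data.frame(
    trauma_type = c("fracture", "burn", "contusion"),
    body_location = c("upper_extremity_left", "chest", "head"),
    ais = c(2, 3, 2))
  idx <- enumerate_injury_combinations(toy)
  expect_identical(nrow(idx), 7L) # C(3,1)+C(3,2)+C(3,3)
  one <- enumerate_injury_combinations(toy[1, , drop = FALSE])
  expect_identical(nrow(one), 1L)
  # no duplicated (type, location) pair within any patient
  expect_true(all(apply(idx, 1, function(i) !anyDuplicated(i[!is.na(i)]))))
  expect_error(enumerate_injury_combinations(toy[0, ]), "no allowed pairs")
})

test_that("the anatomical filter drops impossible combinations", {
  # three same-type injuries confined to two paired extremities
  expect_false(anatomical_filter(data.frame(
    trauma_type = "fracture",
    body_location = c("lower_extremity_left", "lower_extremity_right",
      "lower_extremity_left"))))
  # two injuries in one azygos region
  expect_false(anatomical_filter(data.frame(
    trauma_type = c("laceration", "penetrating"),
    body_location = c("abdomen", "abdomen"))))
  # no rule fires
  expect_true(anatomical_filter(data.frame(
    trauma_type = c("burn", "fracture", "contusion"),
    body_location = c("upper_extremity_left", "lower_extremity_right",
      "chest"))))
  # three same-type injuries across three distinct extremities survive
  expect_true(anatomical_filter(data.frame(
    trauma_type = "burn",
    body_location = c("upper_extremity_left", "upper_extremity_right",
      "lower_extremity_left"))))
  expect_error(anatomical_filter(data.frame(
    trauma_type = "burn", body_location = "tail")), "unknown body location")
})

test_that("vital draws honour the bands and dependency rules", {
  sets <- default_vital_sets()
  set.seed(99)
  niss <- sample(75, 400, replace = TRUE)
  v <- assign_vitals(niss, sets)
  band <- findInterval(niss, sets$niss_lo)
  for (f in c("gcs", "sbp", "rr", "hr", "spo2")) {
    expect_true(all(v[[f]] >= sets[[paste0(f, "_lo")]][band]))
    expect_true(all(v[[f]] <= sets[[paste0(f, "_hi")]][band]))
  }
  expect_true(all(v$radial_pulse_palpable == (v$sbp >= 80)))
  expect_true(all(v$breathing_after_airway_maneuver == (v$rr > 0)))
  expect_true(all(!v$obeys_commands[v$gcs < 13]))
  expect_true(all(!v$walking[v$rr == 0]))
  expect_true(all(v$cap_refill_s <= 10))
  expect_error(assign_vitals(10, sets[-2, ]), "uncovered|gap|NISS")
})

test_that("hypotension prolongs capillary refill at identical draws", {
  lo <- hi <- default_vital_sets()[3, ]
  lo$sbp_lo <- lo$sbp_hi <- 60
  hi$sbp_lo <- hi$sbp_hi <- 120
  lo$niss_lo <- hi$niss_lo <- 1; lo$niss_hi <- hi$niss_hi <- 75
  set.seed(5); v_lo <- assign_vitals(rep(20L, 50), lo)
  set.seed(5); v_hi <- assign_vitals(rep(20L, 50), hi)
  expect_true(all(v_lo$cap_refill_s > v_hi$cap_refill_s))
  expect_true(all(!v_lo$radial_pulse_palpable))
})

test_that("a lower-extremity injury of AIS >= 2 precludes walking", {
  sets <- default_vital_sets()
  set.seed(1)
  v <- assign_vitals(rep(5L, 200), sets, lower_ext_ais = 2)
  expect_true(all(!v$walking))
  set.seed(1)
  v1 <- assign_vitals(rep(5L, 200), sets, lower_ext_ais = 1)
  expect_gt(sum(v1$walking), 0)
})

test_that("cohort generation is seed-deterministic and unique", {
  toy <- default_trauma_catalog()[c(1, 5, 12, 20, 30, 40), ]
  c1 <- generate_cohort(toy, seed = 123)
  c2 <- generate_cohort(toy, seed = 123)
  expect_identical(c1, c2)
  expect_false(identical(c1, generate_cohort(toy, seed = 124)))
  expect_false(anyDuplicated(c1$patient_id) > 0)
  # byte-identical CSV round
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_patients(c1, f1); write_patients(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # subsetting is seeded too
  s1 <- generate_cohort(toy, seed = 9, max_patients = 10)
  s2 <- generate_cohort(toy, seed = 9, max_patients = 10)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 10L)
})

test_that("every emitted patient passes an independent validator sweep", {
  coh <- cached_default_cohort()
  set.seed(31)
  sub <- coh[sample(nrow(coh), 500), ]
  # anatomical rules re-applied independently
  for (i in seq_len(nrow(sub)))
    expect_true(independent_anatomy_ok(sub[i, ]))
  # scores consistent with raw fields
  resc <- score_patients(sub[, setdiff(names(sub),
    c("niss", "rts", "t_rts"))], catalog = default_trauma_catalog())
  expect_identical(resc$niss, sub$niss)
  expect_equal(resc$rts, sub$rts)
  # vitals invariants hold cohort-wide
  expect_silent(validate_patients(coh, catalog = default_trauma_catalog()))
  expect_true(all(coh$niss >= 1 & coh$niss <= 75))
  expect_true(all(coh$rts >= 0 & coh$rts <= rts_max() + 1e-9))
})

test_that("the default cohort NISS histogram is right-skewed with a mid-teens mode", {
  coh <- cached_default_cohort()
  tab <- table(coh$niss)
  mode_niss <- as.integer(names(tab)[which.max(tab)])
  expect_true(mode_niss >= 14 && mode_niss <= 20)
  expect_gt(mean(coh$niss), median(coh$niss)) # right skew
  expect_gt(nrow(coh), 10000)
})
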