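# Semisupervised cohort generator: enumerate realistic injury combinations,
# drop anatomically impossible ones, derive the NISS, then draw vitals from
# the NISS band with clinical dependency rules.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Enumerate all 1-3 injury combinations of a catalog
#'
#' All subsets of size 1-3 of the catalog's allowed (trauma type, body
#' location) pairs, in deterministic order (singletons, then pairs, then
#' triples, each in `utils::combn()` order), after applying the anatomical
#' filter (see [anatomical_filter()]). A (type, location) pair never repeats
#' within one patient.
#'
#' @param catalog Trauma catalog (see [default_trauma_catalog()]).
#' @return Integer matrix with 3 columns of row indices into `catalog`
#'   (`NA` for absent second/third injuries), one row per combination.
#' @export
enumerate_injury_combinations <- function(catalog = default_trauma_catalog()) {
  validate_catalog(catalog)
  p <- nrow(catalog)
  idx <- rbind(
    cbind(seq_len(p), NA_integer_, NA_integer_),
    if (p >= 2) cbind(t(utils::combn(p, 2)), NA_integer_),
    if (p >= 3) t(utils::combn(p, 3))
  )
  keep <- filter_combinations(idx, catalog)
  idx[keep, , drop = FALSE]
}

# Vectorised anatomical filter over an index matrix.
filter_combinations <- function(idx, catalog,
                                locations = body_locations()) {
  paired <- locations$body_location[locations$paired]
  azygos <- locations$body_location[!locations$paired]
  loc <- matrix(catalog$body_location[idx], ncol = 3)
  typ <- matrix(catalog$trauma_type[idx], ncol = 3)
  # (ii) >= 2 injuries in one azygos (unpaired) region
  az <- matrix(ifelse(loc %in% azygos, loc, NA), ncol = 3)
  dup_az <- (!is.na(az[, 1]) & !is.na(az[, 2]) & az[, 1] == az[, 2]) |
    (!is.na(az[, 1]) & !is.na(az[, 3]) & az[, 1] == az[, 3]) |
    (!is.na(az[, 2]) & !is.na(az[, 3]) & az[, 2] == az[, 3])
  # (i) same trauma type 3x confined to <= 2 paired-extremity locations
  full <- !is.na(idx[, 3])
  same_type <- full & typ[, 1] == typ[, 2] & typ[, 1] == typ[, 3]
  all_ext <- full & loc[, 1] %in% paired & loc[, 2] %in% paired &
    loc[, 3] %in% paired
  n_loc <- (loc[, 1] != loc[, 2]) + (loc[, 1] != loc[, 3] &
    loc[, 2] != loc[, 3]) + 1
  two_ext <- same_type & all_ext & n_loc <= 2
  !(dup_az | two_ext)
}

#' Anatomical plausibility filter for one injury list
#'
#' An injury list is dropped when (i) the same trauma type appears three
#' times across only two paired-extremity locations, or (ii) any unpaired
#' (azygos) body region carries two or more injuries.
#'
#' @param injuries Data frame with columns `trauma_type`, `body_location`
#'   (1-3 rows).
#' @param catalog Trauma catalog whose locations define the vocabulary.
#' @param locations Location table flagging paired regions.
#' @return `TRUE` to keep the combination, `FALSE` to drop it.
#' @export
#' @examples
#' anatomical_filter(data.frame(
#'   trauma_type = "laceration",
#'   body_location = c("abdomen", "abdomen"))) # FALSE: duplicated azygos
anatomical_filter <- function(injuries, catalog = default_trauma_catalog(),
                              locations = body_locations()) {
  injuries <- as.data.frame(injuries)
  if (nrow(injuries) < 1 || nrow(injuries) > 3)
    stop("an injury list holds 1-3 injuries")
  if (any(!injuries$body_location %in% locations$body_location))
    stop("unknown body location in injury list")
  paired <- locations$body_location[locations$paired]
  az <- injuries$body_location[!injuries$body_location %in% paired]
  if (anyDuplicated(az) > 0) return(FALSE)
  if (nrow(injuries) == 3 &&
      length(unique(injuries$trauma_type)) == 1 &&
      all(injuries$body_location %in% paired) &&
      length(unique(injuries$body_location)) <= 2) return(FALSE)
  TRUE
}

draw_int <- function(n, lo, hi) as.integer(lo + floor(stats::runif(n) * (hi - lo + 1)))

#' Draw vital signs for given NISS values
#'
#' Each vital is drawn uniformly from the range of the NISS band covering
#' the patient (GCS, SBP, RR, HR, SpO2 as integers; capillary refill to one
#' decimal), using the current RNG state. Dependency rules are then applied:
#' the radial pulse is palpable only with SBP >= 80 mmHg; hypotension
#' prolongs capillary refill by 1 s per 20 mmHg below 100 (capped at 10 s);
#' commands are obeyed only with GCS >= 13; breathing after an airway
#' maneuver requires RR > 0; and walking requires the band's Bernoulli draw
#' to succeed plus GCS >= 13, RR > 0 and no lower-extremity injury of
#' AIS >= 2.
#'
#' @param niss Integer vector of NISS values (1-75).
#' @param vital_sets Band table (see [default_vital_sets()]).
#' @param lower_ext_ais Per-patient maximum AIS over lower-extremity
#'   injuries (0 when none); recycled.
#' @return Data frame of vital-sign columns, one row per element of `niss`.
#' @export
assign_vitals <- function(niss, vital_sets = default_vital_sets(),
                          lower_ext_ais = 0) {
  vital_sets <- as.data.frame(validate_vital_sets(vital_sets))
  n <- length(niss)
  lower_ext_ais <- rep_len(lower_ext_ais, n)
  band <- rep(NA_integer_, n)
  for (b in seq_len(nrow(vital_sets)))
    band[niss >= vital_sets$niss_lo[b] & niss <= vital_sets$niss_hi[b]] <- b
  if (any(is.na(band)))
    stop("no vital parameter band covers NISS ", niss[which(is.na(band))[1]])
  bs <- vital_sets[band, ]
  gcs <- draw_int(n, bs$gcs_lo, bs$gcs_hi)
  sbp <- draw_int(n, bs$sbp_lo, bs$sbp_hi)
  rr <- draw_int(n, bs$rr_lo, bs$rr_hi)
  hr <- draw_int(n, bs$hr_lo, bs$hr_hi)
  spo2 <- draw_int(n, bs$spo2_lo, bs$spo2_hi)
  cap <- round(stats::runif(n, bs$cap_lo, bs$cap_hi), 1)
  walk_draw <- stats::runif(n) < bs$walk_p
  cap <- pmin(round(cap + pmax(0, (100 - sbp) / 20), 1), 10)
  data.frame(
    gcs = gcs, sbp = sbp, rr = rr, hr = hr, spo2 = spo2,
    cap_refill_s = cap,
    walking = walk_draw & gcs >= 13 & rr > 0 & lower_ext_ais < 2,
    radial_pulse_palpable = sbp >= 80,
    obeys_commands = gcs >= 13,
    breathing_after_airway_maneuver = rr > 0
  )
}

#' Generate the artificial trauma cohort
#'
#' Full pipeline: enumerate 1-3 injury combinations of the catalog, apply
#' the anatomical filter, compute the NISS, draw NISS-banded vitals with
#' the dependency rules, and score every patient (RTS, T-RTS). The output
#' is bit-for-bit reproducible from `seed`.
#'
#' @param catalog Trauma catalog (see [default_trauma_catalog()]).
#' @param vital_sets Vital band table (see [default_vital_sets()]).
#' @param seed Integer RNG seed fixing the whole cohort.
#' @param max_patients Optional cap: keep a seeded random subset of this
#'   size (useful for quick runs; `NULL` keeps the full enumeration).
#' @return Scored patient data frame (one row per unique patient) with
#'   `patient_id`, injury columns, vitals, `niss`, `rts`, `t_rts`.
#' @export
#' @examples
#' toy <- default_trauma_catalog()[c(1, 12, 30), ]
#' nrow(generate_cohort(toy, seed = 1)) # 7 = C(3,1) + C(3,2) + C(3,3)
generate_cohort <- function(catalog = default_trauma_catalog(),
                            vital_sets = default_vital_sets(),
                            seed = 1L, max_patients = NULL) {
  idx <- enumerate_injury_combinations(catalog)
  with_seed(seed, {
    if (!is.null(max_patients) && max_patients < nrow(idx))
      idx <- idx[sort(sample.int(nrow(idx), max_patients)), , drop = FALSE]
    n <- nrow(idx)
    patients <- data.frame(patient_id = sprintf("P%06d", seq_len(n)))
    for (i in 1:3) {
      patients[[paste0("trauma_", i, "_type")]] <- catalog$trauma_type[idx[, i]]
      patients[[paste0("trauma_", i, "_location")]] <-
        catalog$body_location[idx[, i]]
      patients[[paste0("trauma_", i, "_ais")]] <- catalog$ais[idx[, i]]
    }
    ais <- matrix(catalog$ais[idx], ncol = 3)
    ais2 <- ais^2
    ais2[is.na(ais2)] <- 0
    niss <- as.integer(ifelse(apply(ais, 1, function(a) any(a == 6, na.rm = TRUE)),
      75L, rowSums(ais2)))
    loc <- matrix(catalog$body_location[idx], ncol = 3)
    low <- matrix(loc %in% c("lower_extremity_left", "lower_extremity_right"),
      ncol = 3)
    le_ais <- ais
    le_ais[!low | is.na(le_ais)] <- 0
    vit <- assign_vitals(niss, vital_sets,
      lower_ext_ais = apply(le_ais, 1, max))
    patients <- cbind(patients, vit)
    score_patients(patients, catalog = catalog)
  })
}
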