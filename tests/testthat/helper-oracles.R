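# Independent oracles and shared fixtures. These re-derive expectations by
# routes separate from the package implementation (brute force, re-applied
# rules, hand formulas).

# All 125 RTS code triples.
all_code_triples <- function() {
  expand.grid(gcs_code = 0:4, sbp_code = 0:4, rr_code = 0:4)
}

# Brute-force k-medoids: exhaustive search over all medoid subsets.
brute_force_kmedoids <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  best <- Inf
  subsets <- utils::combn(n, k)
  for (j in seq_len(ncol(subsets))) {
    cost <- sum(apply(d[subsets[, j], , drop = FALSE], 2, min))
    if (cost < best) best <- cost
  }
  best
}

# Hand (loop-based) Gower for complete-data records, independent of the
# vectorised implementation.
hand_gower <- function(x, spec) {
  n <- nrow(x)
  rng <- sapply(spec$name, function(f)
    if (is.numeric(x[[f]])) diff(range(x[[f]])) else NA)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; den <- 0
    for (m in seq_len(nrow(spec))) {
      f <- spec$name[m]
      a <- x[[f]][i]; b <- x[[f]][j]
      if (is.na(a) || is.na(b)) next
      if (spec$type[m] == "numeric") {
        if (rng[[f]] == 0) next
        num <- num + abs(a - b) / rng[[f]]
      } else num <- num + (a != b)
      den <- den + 1
    }
    out[i, j] <- num / den
  }
  out
}

# Independent re-application of the anatomical rules to an emitted patient
# row (wide format), written from the rule text rather than shared code.
independent_anatomy_ok <- function(row) {
  locs <- unlist(row[paste0("trauma_", 1:3, "_location")], use.names = FALSE)
  typs <- unlist(row[paste0("trauma_", 1:3, "_type")], use.names = FALSE)
  keep <- !is.na(locs)
  locs <- locs[keep]; typs <- typs[keep]
  paired <- c("upper_extremity_left", "upper_extremity_right",
    "lower_extremity_left", "lower_extremity_right")
  az <- locs[!(locs %in% paired)]
  if (any(table(az) >= 2)) return(FALSE)
  if (length(typs) == 3 && length(unique(typs)) == 1 &&
      all(locs %in% paired) && length(unique(locs)) <= 2) return(FALSE)
  TRUE
}

# Cache the default cohort across test files (generation takes a few
# seconds and several files need it).
.cohort_cache <- new.env(parent = emptyenv())
cached_default_cohort <- function(seed = 20260910) {
  key <- as.character(seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(seed = seed)
  .cohort_cache[[key]]
}

# Two well-separated blobs in 2D with known labels, as a dissimilarity.
make_blobs <- function(n_per = 15, k = 2, sep = 10, seed = 7) {
  set.seed(seed)
  centers <- cbind(sep * seq_len(k), sep * seq_len(k))
  x <- do.call(rbind, lapply(seq_len(k), function(g)
    cbind(rnorm(n_per, centers[g, 1], 0.5), rnorm(n_per, centers[g, 2], 0.5))))
  list(x = x, d = as.matrix(stats::dist(x)),
    labels = rep(seq_len(k), each = n_per))
}

# A minimal valid one-patient table with overridable fields.
base_patient <- function(id = "X1", ...) {
  p <- data.frame(patient_id = id,
    trauma_1_type = "contusion", trauma_1_location = "head",
    trauma_1_ais = 2,
    trauma_2_type = NA, trauma_2_location = NA, trauma_2_ais = NA,
    trauma_3_type = NA, trauma_3_location = NA, trauma_3_ais = NA,
    gcs = 15, sbp = 120, rr = 16, hr = 80, spo2 = 98, cap_refill_s = 1,
    walking = TRUE, radial_pulse_palpable = TRUE, obeys_commands = TRUE,
    breathing_after_airway_maneuver = TRUE)
  over <- list(...)
  for (f in names(over)) p[[f]] <- over[[f]]
  p
}
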