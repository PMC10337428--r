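# Gower dissimilarity for mixed numeric/binary/categorical patient records.

#' Declare the scale type of each clustering feature
#'
#' @param name Character vector of feature (column) names.
#' @param type Matching vector of scale types: `"numeric"`, `"binary"` or
#'   `"categorical"`.
#' @return Data frame `name`, `type` usable as a feature spec.
#' @export
feature_spec <- function(name, type) {
  type <- match.arg(type, c("numeric", "binary", "categorical"),
    several.ok = TRUE)
  data.frame(name = name, type = rep_len(type, length(name)))
}

#' Default 27-feature clustering spec
#'
#' The clinical and algorithm-calculated features used for the mixed-data
#' cohort analysis: the six measured vitals and four binary assessments,
#' the per-location maximum AIS for all 13 body locations, the injury
#' count, NISS, weighted RTS, and the survival time without treatment.
#' Triage categories themselves are deliberately excluded to avoid
#' clustering on the very labels being compared.
#'
#' @return A 27-row feature spec (see [feature_spec()]).
#' @export
default_feature_spec <- function() {
  rbind(
    feature_spec(c("gcs", "sbp", "rr", "hr", "spo2", "cap_refill_s"),
      "numeric"),
    feature_spec(c("walking", "radial_pulse_palpable", "obeys_commands",
      "breathing_after_airway_maneuver"), "binary"),
    feature_spec(paste0("ais_", body_locations()$body_location), "numeric"),
    feature_spec(c("injury_count", "niss", "rts", "survival_time_min"),
      "numeric")
  )
}

#' Build the clustering feature table of a scored cohort
#'
#' @param patients Scored patient table (see [score_patients()]).
#' @param params [life_params()] used for the survival-time feature.
#' @return Data frame with the columns of [default_feature_spec()], row
#'   names set to `patient_id`.
#' @export
patient_features <- function(patients, params = life_params()) {
  patients <- as.data.frame(patients)
  out <- patients[, c("gcs", "sbp", "rr", "hr", "spo2", "cap_refill_s",
    "walking", "radial_pulse_palpable", "obeys_commands",
    "breathing_after_airway_maneuver")]
  ais <- ais_matrix(patients)
  for (loc in body_locations()$body_location) {
    hit <- sapply(1:3, function(i)
      !is.na(patients[[paste0("trauma_", i, "_location")]]) &
        patients[[paste0("trauma_", i, "_location")]] == loc)
    hit <- matrix(hit, ncol = 3)
    a <- ais
    a[!hit | is.na(a)] <- 0
    out[[paste0("ais_", loc)]] <- apply(a, 1, max)
  }
  out$injury_count <- rowSums(!is.na(ais))
  out$niss <- patients$niss
  out$rts <- patients$rts
  out$survival_time_min <-
    survival_time_without_treatment(patients$rts, patients$niss, params)
  rownames(out) <- patients$patient_id
  out
}

#' Gower dissimilarity matrix
#'
#' Pairwise Gower dissimilarity over mixed features: numeric features
#' contribute `|a - b| / range` (range taken over the supplied data),
#' binary and categorical features contribute 0 on a match and 1 otherwise.
#' The per-pair dissimilarity is the mean contribution over the features
#' observed in both records (missing values drop out and the weight is
#' renormalised). Numeric features with zero range carry no information
#' and are skipped.
#'
#' @param x Data frame of feature columns (e.g. [patient_features()]).
#' @param spec Feature spec (default [default_feature_spec()] restricted to
#'   the columns present in `x`).
#' @return Symmetric n x n matrix with zero diagonal and entries in
#'   \[0, 1\]; dimnames taken from `rownames(x)`.
#' @export
gower_matrix <- function(x, spec = NULL) {
  x <- as.data.frame(x)
  if (is.null(spec)) {
    spec <- default_feature_spec()
    spec <- spec[spec$name %in% names(x), , drop = FALSE]
    if (nrow(spec) == 0)
      stop("no feature spec given and no default feature found in x")
  }
  miss <- setdiff(spec$name, names(x))
  if (length(miss) > 0)
    stop("features missing from data: ", paste(miss, collapse = ", "))
  n <- nrow(x)
  acc <- matrix(0, n, n)
  wt <- matrix(0, n, n)
  for (j in seq_len(nrow(spec))) {
    v <- x[[spec$name[j]]]
    obs <- !is.na(v)
    if (!any(obs)) next
    w <- outer(obs, obs, "&")
    if (spec$type[j] == "numeric") {
      v <- as.numeric(v)
      rng <- diff(range(v, na.rm = TRUE))
      if (!is.finite(rng)) stop("non-finite range for feature ", spec$name[j])
      if (rng == 0) next # constant feature: no information
      vv <- v
      vv[!obs] <- 0
      d <- abs(outer(vv, vv, "-")) / rng
    } else {
      f <- as.integer(factor(v))
      f[!obs] <- 0L
      d <- outer(f, f, "!=") * 1
    }
    acc <- acc + d * w
    wt <- wt + w
  }
  if (any(wt[upper.tri(wt)] == 0) && n > 1)
    stop("some record pairs share no observed feature")
  diag(wt)[diag(wt) == 0] <- 1
  out <- acc / wt
  dimnames(out) <- list(rownames(x), rownames(x))
  out
}

#' Gower dissimilarity between two records
#'
#' Convenience scalar form of [gower_matrix()] for two records; numeric
#' ranges may be supplied explicitly (as precomputed over a cohort) via
#' `ranges`, a named vector.
#'
#' @param a,b Single-row data frames or named lists with the spec's
#'   features.
#' @param spec Feature spec (see [feature_spec()]).
#' @param ranges Named numeric vector of ranges for the numeric features;
#'   defaults to the range observed in `a` and `b`.
#' @return Dissimilarity in \[0, 1\].
#' @export
gower_pair <- function(a, b, spec, ranges = NULL) {
  num <- 0
  den <- 0
  for (j in seq_len(nrow(spec))) {
    f <- spec$name[j]
    va <- a[[f]]
    vb <- b[[f]]
    if (is.null(va) || is.null(vb) || is.na(va) || is.na(vb)) next
    if (spec$type[j] == "numeric") {
      rng <- if (!is.null(ranges) && f %in% names(ranges)) ranges[[f]]
        else abs(va - vb)
      if (rng == 0) next
      num <- num + abs(va - vb) / rng
    } else {
      num <- num + as.numeric(va != vb)
    }
    den <- den + 1
  }
  if (den == 0) stop("records share no observed feature")
  num / den
}
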