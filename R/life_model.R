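# LIFE-percentage time-course model: a Boltzmann sigmoid whose plateau is set
# by the RTS and whose decompensation midpoint and slope are set by the NISS.

#' Constants of the LIFE time-course model
#'
#' The expected LIFE percentage of an untreated casualty follows a modified
#' Boltzmann sigmoid
#' \deqn{L(t) = L_0 \, B(t) / B(0), \qquad B(t) = 1 / (1 + e^{(t - t_{50})/\tau}),}
#' with plateau \eqn{L_0 = 100 \cdot RTS / RTS_{max}}, decompensation midpoint
#' \eqn{t_{50} = t_{ref} (1 - NISS/75)(f + (1 - f) RTS / RTS_{max})} and slope
#' \eqn{\tau = \tau_{ref} (1 - NISS/75) + \tau_{min}}. Normalising by
#' \eqn{B(0)} pins \eqn{L(0) = L_0}, giving the three clinical phases:
#' a compensation plateau, a near-linear decompensation around \eqn{t_{50}},
#' and a prolonged asymptotic fatal tail.
#'
#' @param rts_max Maximum weighted RTS (7.8408).
#' @param niss_max Maximum NISS (75).
#' @param death_threshold_pct LIFE percentage at which the patient is counted
#'   dead (default 5; the sigmoid tail never reaches 0 exactly).
#' @param t_ref_min Minutes scaling the decompensation midpoint (default
#'   10080 = 7 days, so only near-perfect scores remain compensated at the
#'   model horizon).
#' @param tau_ref_min Minutes scaling the sigmoid slope (default 120).
#' @param tau_min_min Floor for the slope in minutes (default 10), so the
#'   NISS = 75 curve still has a finite decline.
#' @param rts_floor_frac Damping fraction in (0, 1) of the RTS influence on
#'   the midpoint (default 0.25): even an RTS of 0+ keeps a quarter of the
#'   NISS-determined compensation time.
#' @param t_horizon_min Minutes after which an untreated patient is declared
#'   stable (default 10080 = 7 days).
#' @return A `life_params` list of validated model constants.
#' @export
#' @examples
#' p <- life_params()
#' survival_time_without_treatment(6.8174, 35, p)
life_params <- function(rts_max = lifetriage::rts_max(), niss_max = 75L,
                        death_threshold_pct = 5, t_ref_min = 10080,
                        tau_ref_min = 120, tau_min_min = 10,
                        rts_floor_frac = 0.25, t_horizon_min = 10080) {
  p <- list(rts_max = rts_max, niss_max = as.integer(niss_max),
    death_threshold_pct = death_threshold_pct, t_ref_min = t_ref_min,
    tau_ref_min = tau_ref_min, tau_min_min = tau_min_min,
    rts_floor_frac = rts_floor_frac, t_horizon_min = t_horizon_min)
  if (any(vapply(p, length, 1L) != 1) || any(!vapply(p, is.numeric, TRUE)))
    stop("all model constants must be numeric scalars")
  if (t_ref_min <= 0 || tau_ref_min <= 0 || tau_min_min <= 0 ||
      t_horizon_min <= 0)
    stop("all time constants must be > 0")
  if (death_threshold_pct <= 0 || death_threshold_pct >= 100)
    stop("death_threshold_pct must lie in (0, 100)")
  if (rts_floor_frac <= 0 || rts_floor_frac >= 1)
    stop("rts_floor_frac must lie in (0, 1)")
  structure(p, class = "life_params")
}

check_rts_niss <- function(rts, niss, params) {
  if (any(is.na(rts)) || any(rts < 0 | rts > params$rts_max + 1e-9))
    stop("rts out of range [0, ", format(params$rts_max), "]")
  if (any(is.na(niss)) || any(niss < 1 | niss > params$niss_max))
    stop("niss out of range [1, ", params$niss_max, "]")
}

life_curve_params <- function(rts, niss, params) {
  f <- params$rts_floor_frac
  r <- rts / params$rts_max
  list(
    L0 = 100 * r,
    t50 = params$t_ref_min * (1 - niss / params$niss_max) * (f + (1 - f) * r),
    tau = params$tau_ref_min * (1 - niss / params$niss_max) + params$tau_min_min
  )
}

#' LIFE percentage at time t
#'
#' Evaluates the modified Boltzmann time course (see [life_params()]) at
#' `t_minutes` after assessment. Arguments are recycled, so either a single
#' patient over a grid of times or many patients at one time can be computed.
#'
#' @param rts Weighted RTS in \[0, 7.8408\].
#' @param niss NISS in 1-75.
#' @param t_minutes Time since assessment, minutes (>= 0).
#' @param params A [life_params()] object.
#' @return Numeric LIFE percentage in \[0, 100\]; `life_percentage(rts, ., 0, .)`
#'   equals `100 * rts / rts_max()`.
#' @export
life_percentage <- function(rts, niss, t_minutes, params = life_params()) {
  check_rts_niss(rts, niss, params)
  if (any(is.na(t_minutes)) || any(t_minutes < 0))
    stop("t_minutes must be >= 0")
  cp <- life_curve_params(rts, niss, params)
  b <- stats::plogis(-(t_minutes - cp$t50) / cp$tau)
  b0 <- stats::plogis(cp$t50 / cp$tau)
  cp$L0 * b / b0
}

#' Survival time without treatment
#'
#' Closed-form solution of `L(t) = death_threshold`: with
#' `B_t = threshold * B(0) / L0`, the crossing time is
#' `t50 + tau * log(1 / B_t - 1)`. A patient whose plateau already sits at or
#' below the threshold (`L0 <= threshold`, i.e. RTS near 0) gets survival
#' time 0; times beyond `t_horizon_min` are clamped to the horizon and mean
#' "stable without treatment at the model horizon".
#'
#' @inheritParams life_percentage
#' @return Survival time in minutes, in \[0, `t_horizon_min`\]. Vectorised
#'   over `rts` and `niss`.
#' @export
#' @examples
#' p <- life_params()
#' survival_time_without_treatment(0, 40, p)          # 0: dead at assessment
#' survival_time_without_treatment(rts_max(), 1, p)   # horizon: stable
survival_time_without_treatment <- function(rts, niss, params = life_params()) {
  check_rts_niss(rts, niss, params)
  n <- max(length(rts), length(niss))
  rts <- rep_len(rts, n)
  niss <- rep_len(niss, n)
  cp <- life_curve_params(rts, niss, params)
  thr <- params$death_threshold_pct
  s <- numeric(n)
  alive <- cp$L0 > thr
  if (any(alive)) {
    b0 <- stats::plogis(cp$t50[alive] / cp$tau[alive])
    bt <- thr * b0 / cp$L0[alive]
    s[alive] <- cp$t50[alive] + cp$tau[alive] * log(1 / bt - 1)
  }
  pmin(pmax(s, 0), params$t_horizon_min)
}

#' Sampled LIFE trajectory of one patient
#'
#' @inheritParams life_percentage
#' @param t_grid Strictly increasing time grid in minutes starting at 0.
#' @return A `life_trajectory` list: `time_grid`, `life_pct` (nonincreasing,
#'   `life_pct[1] = 100 * rts / rts_max()`), the decompensation midpoint
#'   `t50` (the marker for the transition out of the compensation phase),
#'   the slope `tau`, and `survival_time_min`.
#' @export
life_trajectory <- function(rts, niss, t_grid = seq(0, 10080, by = 10),
                            params = life_params()) {
  stopifnot(length(rts) == 1, length(niss) == 1)
  if (length(t_grid) < 1 || t_grid[1] != 0 ||
      (length(t_grid) > 1 && any(diff(t_grid) <= 0)))
    stop("t_grid must be strictly increasing and start at 0")
  cp <- life_curve_params(rts, niss, params)
  structure(list(
    time_grid = t_grid,
    life_pct = life_percentage(rts, niss, t_grid, params),
    t50 = cp$t50, tau = cp$tau,
    survival_time_min = survival_time_without_treatment(rts, niss, params),
    rts = rts, niss = niss
  ), class = "life_trajectory")
}

#' @export
print.life_trajectory <- function(x, ...) {
  cat(sprintf(
    "LIFE trajectory: RTS %.4f, NISS %d | t50 %.1f min, tau %.1f min, survival %.1f min\n",
    x$rts, as.integer(x$niss), x$t50, x$tau, x$survival_time_min))
  invisible(x)
}

#' Rank a scored cohort by anticipated survival time
#'
#' LIFE priority 1 is the patient with the shortest survival time without
#' treatment (treat first). Ties are broken deterministically by the
#' lexicographic order of `patient_id`.
#'
#' @param patients Scored patient table with `patient_id`, `rts`, `niss`
#'   columns (see [score_patients()]).
#' @param params A [life_params()] object.
#' @return Data frame `patient_id`, `survival_time_min`, `life_priority`
#'   (a permutation of 1..n), ordered by ascending survival time.
#' @export
rank_cohort <- function(patients, params = life_params()) {
  patients <- as.data.frame(patients)
  if (nrow(patients) == 0) stop("cannot rank an empty cohort")
  if (is.null(patients$rts) || is.null(patients$niss))
    stop("patients must be scored first (see score_patients())")
  s <- survival_time_without_treatment(patients$rts, patients$niss, params)
  ord <- order(s, as.character(patients$patient_id), method = "radix")
  out <- data.frame(
    patient_id = patients$patient_id[ord],
    survival_time_min = s[ord],
    life_priority = seq_along(ord)
  )
  rownames(out) <- NULL
  out
}
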