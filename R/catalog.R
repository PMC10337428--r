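# Default trauma-by-location catalog and NISS-banded vital parameter sets.
# Both are plain data frames and fully replaceable by user-supplied CSV
# tables with the same columns.

#' Body locations of the default catalog
#'
#' @return Data frame with `body_location` (13 labels) and logical `paired`
#'   (`TRUE` for the four extremities; the other nine are unpaired "azygos"
#'   regions that cannot plausibly carry more than one injury).
#' @export
body_locations <- function() {
  data.frame(
    body_location = c("head", "face", "neck", "chest", "abdomen", "pelvis",
      "spine", "back", "external", "upper_extremity_left",
      "upper_extremity_right", "lower_extremity_left",
      "lower_extremity_right"),
    paired = c(rep(FALSE, 9), rep(TRUE, 4))
  )
}

#' Default trauma catalog
#'
#' The 67 (trauma type, body location) pairs judged realistic, each with a
#' fixed AIS severity. 14 trauma types are crossed with 13 body locations;
#' only anatomically and clinically plausible pairs are retained. The AIS
#' assignments were chosen so that full enumeration of 1-3 injuries yields
#' a right-skewed NISS distribution with its mode in the mid-teens. This
#' table is a documented synthetic stand-in; supply your own catalog with
#' the same columns to replace it.
#'
#' @return Data frame with columns `trauma_type`, `body_location`, `ais`.
#' @export
default_trauma_catalog <- function() {
  p <- function(type, ...) {
    x <- c(...)
    data.frame(trauma_type = type, body_location = names(x),
      ais = as.integer(x), row.names = NULL)
  }
  ue <- c("upper_extremity_left", "upper_extremity_right")
  le <- c("lower_extremity_left", "lower_extremity_right")
  cat <- rbind(
    p("fracture", stats::setNames(c(2, 2, 3, 3, 3, 1, 3),
      c(ue, le, "pelvis", "face", "spine"))),
    p("dislocation", stats::setNames(c(1, 1, 2, 2), c(ue, le))),
    p("contusion", stats::setNames(c(2, 1, 1, 1, 1, 1, 1, 1),
      c("head", "chest", "abdomen", ue, le, "back"))),
    p("laceration", stats::setNames(c(1, 1, 1, 2, 2, 1, 2),
      c("face", ue, le, "external", "neck"))),
    p("penetrating", stats::setNames(c(3, 3, 4, 2, 2, 2, 2),
      c("chest", "abdomen", "neck", ue, le))),
    p("blunt", stats::setNames(c(3, 2, 1, 2),
      c("chest", "abdomen", "back", "pelvis"))),
    p("burn", stats::setNames(c(2, 2, 2, 2, 2, 2, 3),
      c("external", "face", ue, le, "chest"))),
    p("amputation", stats::setNames(c(3, 3, 3, 3), c(ue, le))),
    p("crush", stats::setNames(c(4, 3, 2, 2, 3),
      c("chest", "pelvis", le, "abdomen"))),
    p("traumatic_brain_injury", c(head = 5)),
    p("hemorrhage", stats::setNames(c(3, 3, 4, 2),
      c("abdomen", "pelvis", "neck", "external"))),
    p("blast", stats::setNames(c(3, 3, 3, 2),
      c("chest", "abdomen", "head", "external"))),
    p("spinal_cord_injury", stats::setNames(c(5, 5), c("spine", "neck"))),
    p("inhalation", stats::setNames(c(2, 1, 3), c("neck", "face", "chest")))
  )
  rownames(cat) <- NULL
  cat
}

#' Validate a trauma catalog
#'
#' @param catalog Data frame with `trauma_type`, `body_location`, `ais`.
#' @param locations Location table as from [body_locations()].
#' @return `catalog`, invisibly.
#' @export
validate_catalog <- function(catalog, locations = body_locations()) {
  catalog <- as.data.frame(catalog)
  need <- c("trauma_type", "body_location", "ais")
  if (!all(need %in% names(catalog)))
    stop("catalog needs columns ", paste(need, collapse = ", "))
  if (nrow(catalog) == 0) stop("catalog has no allowed pairs")
  bad <- !(catalog$body_location %in% locations$body_location)
  if (any(bad))
    stop("unknown body location '", catalog$body_location[which(bad)[1]], "'")
  if (any(catalog$ais != round(catalog$ais) | catalog$ais < 1 |
      catalog$ais > 6))
    stop("catalog AIS values must be integers in 1-6")
  if (anyDuplicated(paste(catalog$trauma_type, catalog$body_location)))
    stop("each (trauma_type, body_location) pair may appear only once")
  invisible(catalog)
}

#' Default NISS-banded vital parameter sets
#'
#' Seven bands partition NISS 1-75 without overlap. Within a band each vital
#' parameter is drawn uniformly from its \[low, high\] range; `walk_p` is the
#' Bernoulli probability that an otherwise ambulatory patient can walk.
#' The bands encode the clinical gradient the generator emulates: minor
#' injury severity comes with near-normal vitals, and vitals deteriorate
#' with the NISS (the NISS = 75 band is the unsurvivable convention:
#' GCS 3, no pressure, apnoea). A synthetic stand-in table, replaceable via
#' the same columns.
#'
#' @return Data frame with columns `niss_lo`, `niss_hi`, `gcs_lo`, `gcs_hi`,
#'   `sbp_lo`, `sbp_hi`, `rr_lo`, `rr_hi`, `hr_lo`, `hr_hi`, `spo2_lo`,
#'   `spo2_hi`, `cap_lo`, `cap_hi`, `walk_p`.
#' @export
default_vital_sets <- function() {
  cols <- c("niss_lo", "niss_hi", "gcs_lo", "gcs_hi", "sbp_lo", "sbp_hi",
    "rr_lo", "rr_hi", "hr_lo", "hr_hi", "spo2_lo", "spo2_hi",
    "cap_lo", "cap_hi", "walk_p")
  m <- rbind(
    c(1, 9, 14, 15, 110, 140, 12, 20, 60, 100, 96, 100, 0.5, 2.0, 0.95),
    c(10, 15, 13, 15, 100, 135, 12, 24, 70, 110, 94, 99, 0.8, 2.2, 0.75),
    c(16, 24, 12, 15, 90, 125, 14, 28, 80, 120, 90, 98, 1.0, 2.8, 0.45),
    c(25, 40, 9, 13, 76, 105, 20, 35, 95, 135, 84, 94, 1.5, 3.5, 0.15),
    c(41, 58, 6, 9, 50, 80, 24, 40, 110, 150, 74, 88, 3.0, 5.0, 0),
    c(59, 74, 3, 5, 40, 70, 0, 8, 120, 160, 50, 75, 5.0, 8.0, 0),
    c(75, 75, 3, 3, 0, 0, 0, 0, 0, 0, 0, 0, 10.0, 10.0, 0)
  )
  colnames(m) <- cols
  as.data.frame(m)
}

#' Validate a vital parameter set table
#'
#' Checks that the NISS bands partition 1-75 without gap or overlap and
#' that every range satisfies low <= high.
#'
#' @param vital_sets Data frame as from [default_vital_sets()].
#' @return `vital_sets` invisibly, ordered by `niss_lo`.
#' @export
validate_vital_sets <- function(vital_sets) {
  vital_sets <- as.data.frame(vital_sets)
  vital_sets <- vital_sets[order(vital_sets$niss_lo), , drop = FALSE]
  covered <- unlist(Map(seq, vital_sets$niss_lo, vital_sets$niss_hi))
  if (anyDuplicated(covered))
    stop("vital parameter bands overlap at NISS ",
      covered[which(duplicated(covered))[1]])
  gap <- setdiff(1:75, covered)
  if (length(gap) > 0)
    stop("vital parameter bands leave NISS ", gap[1], " uncovered")
  for (v in c("gcs", "sbp", "rr", "hr", "spo2", "cap")) {
    lo <- vital_sets[[paste0(v, "_lo")]]
    hi <- vital_sets[[paste0(v, "_hi")]]
    if (is.null(lo) || is.null(hi)) stop("missing range columns for '", v, "'")
    if (any(lo > hi)) stop("range low > high for '", v, "'")
  }
  if (any(vital_sets$walk_p < 0 | vital_sets$walk_p > 1))
    stop("walk_p must lie in [0, 1]")
  invisible(vital_sets)
}
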