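# Cohort-level analytics: 2D embedding, triage cross-tabulation, and the
# consensus comparison used to adjudicate heterogeneously triaged clusters.

#' 2D t-SNE embedding of a dissimilarity matrix
#'
#' Thin adapter around [Rtsne::Rtsne()] run on the precomputed (Gower)
#' dissimilarities. The contract is structural only: finite coordinates of
#' shape n x 2, identical for identical seeds. The geometric layout itself
#' is a visualisation aid, not an assertable quantity.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param perplexity t-SNE perplexity; must satisfy `perplexity < (n-1)/3`.
#' @param seed Integer seed fixing the embedding.
#' @param ... Further arguments passed to [Rtsne::Rtsne()].
#' @return n x 2 numeric matrix of embedding coordinates (rownames from `d`).
#' @export
embed_2d <- function(d, perplexity = 30, seed = 1L, ...) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  if (perplexity >= (n - 1) / 3)
    stop("perplexity too large: must be < (n - 1)/3 = ", (n - 1) / 3)
  y <- with_seed(seed, Rtsne::Rtsne(stats::as.dist(d), is_distance = TRUE,
    dims = 2, perplexity = perplexity, pca = FALSE, ...))$Y
  rownames(y) <- rownames(d)
  y
}

#' Default score bands for the triage cross-tabulation
#'
#' @return List with `niss_breaks` (1-10, 10-25, 25-40, 40-75; right-closed)
#'   and `rts_breaks` (<2.5, 2.5-5, 5-7.5, >7.5; left-closed).
#' @export
default_score_bands <- function() {
  list(
    niss_breaks = c(0, 10, 25, 40, 75),
    niss_labels = c("1-10", "10-25", "25-40", "40-75"),
    rts_breaks = c(0, 2.5, 5, 7.5, rts_max() + 1e-9),
    rts_labels = c("<2.5", "2.5-5", "5-7.5", ">7.5")
  )
}

#' Cross-tabulate triage categories against NISS and RTS bands
#'
#' Counts (and percentages of the cohort) per algorithm, category and
#' score band — the data behind the nested donut display of category
#' composition.
#'
#' @param patients Scored patient table (`niss`, `rts`).
#' @param triaged Output of [triage_all()] for the same patients.
#' @param score_bands Band definition, see [default_score_bands()].
#' @return Data frame `algorithm`, `category`, `band_type` (`"niss"` or
#'   `"rts"`), `band`, `n`, `pct`. For each (algorithm, band_type) the
#'   counts sum to the cohort size.
#' @export
triage_crosstab <- function(patients, triaged,
                            score_bands = default_score_bands()) {
  patients <- as.data.frame(patients)
  need <- c("niss_breaks", "niss_labels", "rts_breaks", "rts_labels")
  if (!all(need %in% names(score_bands)))
    stop("unknown band spec: needs ", paste(need, collapse = ", "))
  algos <- intersect(c("start", "rts", "life"), names(triaged))
  if (length(algos) == 0) stop("triaged table holds no algorithm columns")
  i <- match(triaged$patient_id, patients$patient_id)
  if (any(is.na(i))) stop("triaged ids not found in patient table")
  bands <- list(
    niss = cut(patients$niss[i], score_bands$niss_breaks,
      labels = score_bands$niss_labels, include.lowest = TRUE),
    rts = cut(patients$rts[i], score_bands$rts_breaks,
      labels = score_bands$rts_labels, right = FALSE, include.lowest = TRUE)
  )
  n_tot <- nrow(triaged)
  out <- do.call(rbind, lapply(algos, function(a) {
    do.call(rbind, lapply(names(bands), function(bt) {
      tab <- table(category = triaged[[a]], band = bands[[bt]])
      df <- as.data.frame(tab, stringsAsFactors = FALSE)
      data.frame(algorithm = a, category = df$category, band_type = bt,
        band = df$band, n = df$Freq, pct = 100 * df$Freq / n_tot)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Compare a cluster with the triage consensus subsets
#'
#' The consensus subsets are the patients all three algorithms (START,
#' T-RTS, LIFE) assign to the same category. For the focus cluster, the
#' means of NISS, RTS and survival time are compared with each consensus
#' subset; for every variable the nearest consensus label (smallest
#' absolute difference in means) is reported, plus the overall nearest
#' label by majority over the three variables (ties resolved toward the
#' more urgent category).
#'
#' @param patients Scored patient table.
#' @param triaged [triage_all()] result with `start`, `rts` and `life`
#'   columns (and `survival_time_min`).
#' @param assignments Cluster label per row of `patients`.
#' @param focus_cluster Cluster label to compare.
#' @param params [life_params()] for survival times if `triaged` lacks them.
#' @return List: `focus` (per-variable mean/sd of the focus cluster),
#'   `consensus` (per consensus category and variable: n, mean, sd),
#'   `nearest` (named character: nearest consensus label per variable),
#'   `overall` (single label).
#' @export
consensus_compare <- function(patients, triaged, assignments, focus_cluster,
                              params = life_params()) {
  patients <- as.data.frame(patients)
  if (!all(c("start", "rts", "life") %in% names(triaged)))
    stop("consensus comparison needs all three algorithm columns")
  if (length(assignments) != nrow(patients))
    stop("assignments must label every patient")
  i <- match(triaged$patient_id, patients$patient_id)
  surv <- if (!is.null(triaged$survival_time_min)) triaged$survival_time_min
    else survival_time_without_treatment(patients$rts[i], patients$niss[i],
      params)
  vars <- data.frame(niss = patients$niss[i], rts = patients$rts[i],
    survival_time_min = surv)
  agree <- as.character(triaged$start) == as.character(triaged$rts) &
    as.character(triaged$start) == as.character(triaged$life)
  focus <- assignments[match(triaged$patient_id, patients$patient_id)] ==
    focus_cluster
  if (!any(focus)) stop("focus cluster ", focus_cluster, " is empty")
  cats <- c("green", "yellow", "red")
  cons <- lapply(cats, function(cc) {
    sel <- agree & as.character(triaged$start) == cc & !focus
    if (!any(sel)) {
      warning("empty consensus subset '", cc, "' excluded")
      return(NULL)
    }
    data.frame(category = cc, variable = names(vars),
      n = sum(sel),
      mean = vapply(vars, function(v) mean(v[sel]), numeric(1)),
      sd = vapply(vars, function(v) stats::sd(v[sel]), numeric(1)),
      row.names = NULL)
  })
  cons <- do.call(rbind, cons)
  if (is.null(cons)) stop("no non-empty consensus subset available")
  focus_stats <- data.frame(variable = names(vars),
    n = sum(focus),
    mean = vapply(vars, function(v) mean(v[focus]), numeric(1)),
    sd = vapply(vars, function(v) stats::sd(v[focus]), numeric(1)),
    row.names = NULL)
  nearest <- vapply(names(vars), function(v) {
    sub <- cons[cons$variable == v, ]
    sub$category[which.min(abs(sub$mean -
      focus_stats$mean[focus_stats$variable == v]))]
  }, character(1))
  urgency <- c(green = 1, yellow = 2, red = 3)
  votes <- table(factor(nearest, levels = names(urgency)))
  top <- names(votes)[votes == max(votes)]
  overall <- top[which.max(urgency[top])]
  list(focus = focus_stats, consensus = cons, nearest = nearest,
    overall = overall)
}
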