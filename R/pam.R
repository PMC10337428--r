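# Partitioning around medoids (BUILD + SWAP) on a precomputed
# dissimilarity matrix, with deterministic lowest-index tie-breaking, and
# silhouette-based selection of the cluster count.

as_dist_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("d must be a square dissimilarity matrix")
  if (any(abs(d - t(d)) > 1e-8)) stop("d must be symmetric")
  if (any(diag(d) != 0)) stop("d must have a zero diagonal")
  d
}

pam_cost <- function(d, medoids) {
  sum(apply(d[medoids, , drop = FALSE], 2, min))
}

#' k-medoids clustering (PAM, BUILD + SWAP)
#'
#' Greedy BUILD initialisation (first medoid minimises the total
#' dissimilarity; each further medoid maximises the cost reduction),
#' followed by SWAP steps: while any single exchange of a medoid for a
#' non-medoid lowers the total cost, the best such exchange is applied.
#' All ties break on the lowest index, so the result is fully
#' deterministic; `seed` is accepted for interface symmetry with the
#' stochastic stages but is not consumed.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`) with zero diagonal.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Ignored (deterministic algorithm); present so callers can
#'   thread one seed through a whole pipeline.
#' @return List of class `pam_result`: `k`, `medoid_idx`, `medoid_ids`
#'   (dimnames of `d`, when present — medoids are actual cohort members),
#'   `assignments` (cluster label 1..k per point, nearest medoid),
#'   `total_cost` (sum of dissimilarities to the assigned medoids) and
#'   `silhouette` (mean silhouette width, `NA` for k = 1 or k = n).
#' @export
pam_cluster <- function(d, k, seed = NULL) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  if (k < 1 || k > n) stop("k must lie in 1..n (n = ", n, ")")
  # BUILD
  medoids <- unname(which.min(colSums(d)))
  while (length(medoids) < k) {
    near <- apply(d[medoids, , drop = FALSE], 2, min)
    gain <- vapply(seq_len(n), function(j) {
      if (j %in% medoids) return(-Inf)
      sum(pmax(near - d[, j], 0))
    }, numeric(1))
    medoids <- c(medoids, which.max(gain)) # which.max: lowest index on ties
  }
  # SWAP
  cost <- pam_cost(d, medoids)
  repeat {
    best <- cost
    best_swap <- NULL
    others <- setdiff(seq_len(n), medoids)
    for (mi in seq_along(medoids)) {
      for (h in others) {
        cand <- medoids
        cand[mi] <- h
        cc <- pam_cost(d, cand)
        if (cc < best - 1e-12) {
          best <- cc
          best_swap <- c(mi, h)
        }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1]] <- best_swap[2]
    cost <- best
  }
  medoids <- sort(unname(medoids))
  assignments <- unname(apply(d[medoids, , drop = FALSE], 2, which.min))
  sil <- if (k > 1 && k < n) mean_silhouette(d, assignments) else NA_real_
  structure(list(k = k, medoid_idx = medoids,
    medoid_ids = if (!is.null(rownames(d))) rownames(d)[medoids] else medoids,
    assignments = as.integer(assignments),
    total_cost = pam_cost(d, medoids), silhouette = sil),
    class = "pam_result")
}

#' @export
print.pam_result <- function(x, ...) {
  cat(sprintf("PAM clustering: k = %d, total cost %.4f, mean silhouette %s\n",
    x$k, x$total_cost,
    if (is.na(x$silhouette)) "NA" else sprintf("%.3f", x$silhouette)))
  cat("cluster sizes:", tabulate(x$assignments, x$k), "\n")
  invisible(x)
}

#' Mean silhouette width of a clustering
#'
#' For each point, `a` is its mean dissimilarity to its own cluster
#' (excluding itself) and `b` the smallest mean dissimilarity to any other
#' cluster; the silhouette is `(b - a) / max(a, b)`, defined as 0 for
#' singleton clusters. Values lie in \[-1, 1\].
#'
#' @inheritParams pam_cluster
#' @param assignments Integer cluster labels per point (>= 2 clusters).
#' @return Mean silhouette width.
#' @export
mean_silhouette <- function(d, assignments) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  cl <- as.integer(factor(assignments))
  k <- max(cl)
  if (k < 2) stop("silhouette needs at least 2 clusters")
  sizes <- tabulate(cl, k)
  # mean dissimilarity of each point to each cluster
  m <- sapply(seq_len(k), function(g) rowSums(d[, cl == g, drop = FALSE]))
  s <- numeric(n)
  for (i in seq_len(n)) {
    g <- cl[i]
    if (sizes[g] == 1) { s[i] <- 0; next }
    a <- m[i, g] / (sizes[g] - 1)
    b <- min(m[i, -g] / sizes[-g])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Choose the cluster count by mean silhouette width
#'
#' Runs [pam_cluster()] for every k in `k_range` and picks the k with the
#' largest mean silhouette width (ties go to the smaller k).
#'
#' @inheritParams pam_cluster
#' @param k_range Integer vector of candidate cluster counts, within
#'   \[2, n - 1\].
#' @return List: `k_star`, and `profile`, a data frame of `k` and
#'   `avg_silhouette`.
#' @export
silhouette_select_k <- function(d, k_range = 2:8, seed = NULL) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  if (any(k_range < 2 | k_range > n - 1))
    stop("k_range must lie within [2, n - 1] (n = ", n, ")")
  if (all(d == 0)) stop("degenerate dissimilarities: all distances are zero")
  k_range <- sort(unique(as.integer(k_range)))
  prof <- vapply(k_range, function(k) pam_cluster(d, k, seed)$silhouette,
    numeric(1))
  list(k_star = k_range[which.max(prof)],
    profile = data.frame(k = k_range, avg_silhouette = prof))
}
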