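#' Exact univariate k-means clustering with BIC model selection
#'
#' Clusters a numeric vector into contiguous groups of its sorted values.
#' For each candidate number of clusters `k` in `[k_min, min(k_max,
#' #distinct values)]` the globally optimal (minimum within-cluster sum of
#' squares) partition is found by dynamic programming — unlike Lloyd-style
#' k-means there is no dependence on initialization. The number of clusters
#' is then chosen by BIC under a Gaussian mixture with one component per
#' cluster (component weight `n_j / n`, mean and ML variance from the
#' cluster; a variance floor of `1e-12` guards single-point clusters). Ties
#' in BIC resolve toward the smaller `k`.
#'
#' @param values Numeric vector (length >= 1).
#' @param k_min,k_max Cluster-number bounds (defaults 1 and 4).
#' @return List of class `clustering_1d`: `assignments` (cluster index per
#'   input value, clusters numbered in ascending value order), `centers`
#'   (cluster means, ascending), `k_selected`, `within_ss`, `sizes`.
#' @export
ckmeans_1d <- function(values, k_min = 1L, k_max = 4L) {
  if (length(values) < 1) stop("empty input", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("values must be finite", call. = FALSE)
  }
  stopifnot(k_max >= k_min, k_min >= 1)
  n <- length(values)
  ord <- order(values)
  xs <- values[ord]
  n_distinct <- length(unique(xs))
  k_hi <- min(k_max, n_distinct)
  k_lo <- min(k_min, k_hi)
  dp <- ckmeans_dp(xs, k_hi)
  ks <- seq.int(k_lo, k_hi)
  bics <- vapply(ks, function(k) bic_1d(xs, dp$starts[[k]]), 0)
  k_sel <- ks[which.max(bics)]           # which.max takes the first maximum
  starts <- dp$starts[[k_sel]]
  bounds <- c(starts, n + 1L)
  assign_sorted <- rep.int(seq_len(k_sel), diff(bounds))
  assignments <- integer(n)
  assignments[ord] <- assign_sorted
  centers <- vapply(seq_len(k_sel), function(j) {
    mean(xs[bounds[j]:(bounds[j + 1L] - 1L)])
  }, 0)
  structure(list(assignments = assignments, centers = centers,
                 k_selected = as.integer(k_sel),
                 within_ss = dp$within_ss[k_sel],
                 sizes = diff(bounds)),
            class = "clustering_1d")
}

# BIC of the Gaussian-mixture reading of a contiguous partition of sorted xs.
# starts: 1-based start index of each cluster. Free parameters: k means,
# k variances, k-1 mixing weights.
bic_1d <- function(xs, starts) {
  n <- length(xs)
  k <- length(starts)
  bounds <- c(starts, n + 1L)
  ll <- 0
  for (j in seq_len(k)) {
    seg <- xs[bounds[j]:(bounds[j + 1L] - 1L)]
    nj <- length(seg)
    mu <- mean(seg)
    v <- max(sum((seg - mu)^2) / nj, 1e-12)
    ll <- ll + sum(log(nj / n) + stats::dnorm(seg, mu, sqrt(v), log = TRUE))
  }
  2 * ll - (3 * k - 1) * log(n)
}

#' @exportS3Method base::print
print.clustering_1d <- function(x, ...) {
  cat("clustering_1d: k =", x$k_selected,
      "| centers:", paste(signif(x$centers, 4), collapse = ", "),
      "| within-SS:", signif(x$within_ss, 6), "\n")
  invisible(x)
}

#' Zero the scores of the lowest-distance cluster
#'
#' Given per-cell scores, the distances they were derived from, and a
#' clustering of those distances, sets to zero the scores of all cells
#' assigned to the cluster with the smallest center — the cells the
#' clustering reads as lacking the receptor. If only one cluster was found
#' the scores pass through unchanged. The operation only ever zeroes values
#' (idempotent, never increases a score). With exactly tied minimum centers
#' the cluster containing the smallest sorted value is chosen.
#'
#' @param scores Numeric vector in `[0, 1]`.
#' @param distances Numeric vector the clustering was computed on (same
#'   length and cell order).
#' @param clustering A `clustering_1d` object from [ckmeans_1d()].
#' @return Thresholded copy of `scores`.
#' @export
threshold_scores <- function(scores, distances, clustering) {
  if (length(scores) != length(distances) ||
      length(scores) != length(clustering$assignments)) {
    stop("scores, distances and clustering must align by cell",
         call. = FALSE)
  }
  if (clustering$k_selected <= 1L) return(scores)
  low <- which.min(clustering$centers)   # first minimum on exact ties
  scores[clustering$assignments == low] <- 0
  scores
}
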