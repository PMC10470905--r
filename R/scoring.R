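#' Per-gene technical variances
#'
#' Unbiased sample variance of each listed gene column of the reconstructed
#' matrix, under the working assumption that the observed marginal variance
#' of a reconstructed gene is entirely technical.
#'
#' @param recon Cells-by-genes reconstructed matrix.
#' @param genes Character vector of gene ids (must be columns of `recon`).
#' @return Named numeric vector of variances (>= 0).
#' @export
technical_variance <- function(recon, genes) {
  recon <- validate_matrix(recon, "reconstructed matrix")
  missing <- setdiff(genes, colnames(recon))
  if (length(missing)) {
    stop("unknown gene id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- recon[, genes, drop = FALSE]
  mu <- colMeans(x)
  colSums(sweep(x, 2, mu)^2) / (nrow(x) - 1)
}

#' Squared modified Mahalanobis distances for one gene set
#'
#' Per cell, the non-centered sum of squared set-gene values scaled by
#' inverse effective variances, where each gene's technical variance is
#' divided by its set weight:
#' `d(c) = sum_j x(c, j)^2 / (tech_var_j / w_j)`. Dividing the variance by
#' the weight shrinks the effective variance of highly weighted genes, so
#' they contribute more to the distance. Zero technical variances are
#' floored at `1e-12` times the largest variance in the set; if every
#' variance in the set is zero the set cannot be scored and an error is
#' raised.
#'
#' @param set_values Cells-by-g matrix of the set genes' values.
#' @param tech_var Length-g vector of technical variances.
#' @param weights Length-g vector of positive gene weights.
#' @return Numeric vector of squared distances (one per cell, >= 0).
#' @export
modified_mahalanobis <- function(set_values, tech_var, weights) {
  set_values <- as_dense(set_values)
  g <- ncol(set_values)
  stopifnot(g >= 1, length(tech_var) == g, length(weights) == g)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  if (all(tech_var == 0)) {
    stop("all technical variances are zero for this set", call. = FALSE)
  }
  tv <- pmax(tech_var, 1e-12 * max(tech_var))
  eff <- tv / weights
  as.vector(set_values^2 %*% (1 / eff))
}

#' Independently permute each column of a matrix
#'
#' Shuffles the row labels of every column independently (preserving each
#' column's multiset of values), which breaks all between-gene correlation —
#' the null under which the gamma calibration is fitted.
#'
#' @param matrix Numeric matrix.
#' @param seed Integer seed; the permutation is deterministic given it.
#' @return Matrix of the same shape.
#' @export
permute_within_columns <- function(matrix, seed) {
  m <- as_dense(matrix)
  n <- nrow(m)
  withr::with_seed(as.integer(seed %% 2147483647), {
    for (j in seq_len(ncol(m))) m[, j] <- m[sample.int(n), j]
  })
  m
}

#' Gamma maximum-likelihood fit
#'
#' Fits shape and rate to the positive entries of `distances` by maximum
#' likelihood: Newton iteration on the profile equation
#' `log(shape) - digamma(shape) = log(mean(x)) - mean(log(x))` from a
#' method-of-moments start, tolerance 1e-9 on the shape update; the rate is
#' then `shape / mean(x)`. Fewer than two distinct positive values cannot
#' identify the two parameters and yield a degenerate result.
#'
#' @param distances Non-negative numeric vector; zeros are dropped before
#'   fitting.
#' @return List with `shape`, `rate`, `n_used`, and logical `degenerate`.
#' @export
fit_gamma_mle <- function(distances) {
  x <- distances[is.finite(distances) & distances > 0]
  if (length(unique(x)) < 2) {
    return(list(shape = NA_real_, rate = NA_real_,
                n_used = length(x), degenerate = TRUE))
  }
  mx <- mean(x)
  s <- log(mx) - mean(log(x))            # s > 0 by Jensen for non-constant x
  shape <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)  # standard start
  mom <- mx^2 / var(x)
  if (!is.finite(shape) || shape <= 0) shape <- max(mom, 1e-8)
  for (it in 1:200) {
    f <- log(shape) - digamma(shape) - s
    fp <- 1 / shape - trigamma(shape)
    step <- f / fp
    new <- shape - step
    if (new <= 0) new <- shape / 2
    done <- abs(new - shape) < 1e-9
    shape <- new
    if (done) break
  }
  list(shape = shape, rate = shape / mx, n_used = length(x),
       degenerate = FALSE)
}

#' Score one receptor's gene set on a reconstructed target matrix
#'
#' Computes the squared modified Mahalanobis distance of every cell to the
#' origin in the set's weighted gene space, calibrates a gamma distribution
#' on null distances, and returns the gamma CDF of each observed distance as
#' the per-cell score in `[0, 1]`. Null distances come from one
#' column-permuted copy of the set submatrix (`null_mode = "permutation"`,
#' breaking gene-gene correlation) or from the observed distances themselves
#' (`null_mode = "direct"`, cheaper). A cell with all set genes at zero has
#' distance 0 and score 0. If the calibration is degenerate (fewer than two
#' distinct positive null distances) the scores fall back to min-max scaled
#' distances with a warning.
#'
#' @param recon_target Cells-by-genes reconstructed target matrix.
#' @param gene_set Data frame with columns `gene`, `weight` (one receptor's
#'   set, as stored in a `receptor_gene_sets` object).
#' @param null_mode `"permutation"` (default) or `"direct"`.
#' @param seed Integer seed for the permutation.
#' @return List with `distances`, `scores`, `params` (see
#'   [fit_gamma_mle()]).
#' @export
score_receptor <- function(recon_target, gene_set,
                           null_mode = c("permutation", "direct"),
                           seed = 1L) {
  null_mode <- match.arg(null_mode)
  recon_target <- validate_matrix(recon_target, "reconstructed target")
  genes <- gene_set$gene
  weights <- gene_set$weight
  missing <- setdiff(genes, colnames(recon_target))
  if (length(missing)) {
    stop("gene(s) absent from target: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- recon_target[, genes, drop = FALSE]
  tv <- technical_variance(recon_target, genes)
  d <- modified_mahalanobis(x, tv, weights)
  d_null <- if (null_mode == "permutation") {
    modified_mahalanobis(permute_within_columns(x, seed), tv, weights)
  } else d
  params <- fit_gamma_mle(d_null)
  if (params$degenerate) {
    warning("degenerate gamma calibration; falling back to min-max scaled ",
            "distances", call. = FALSE)
    rng <- range(d)
    scores <- if (rng[2] > rng[1]) (d - rng[1]) / (rng[2] - rng[1])
              else rep(0, length(d))
  } else {
    scores <- pgamma(d, shape = params$shape, rate = params$rate)
  }
  names(scores) <- names(d) <- rownames(recon_target)
  list(distances = d, scores = scores, params = params)
}
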