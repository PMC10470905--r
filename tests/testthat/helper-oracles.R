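# Independent oracles and small fixture builders used across the suite.

# Random named cells-by-features matrix.
rand_matrix <- function(n_cells, n_feat, seed, fun = function(n) rnorm(n)) {
  withr::with_seed(seed, {
    m <- matrix(fun(n_cells * n_feat), n_cells, n_feat)
    dimnames(m) <- list(sprintf("c%03d", seq_len(n_cells)),
                        sprintf("g%03d", seq_len(n_feat)))
    m
  })
}

rand_counts <- function(n_cells, n_feat, seed, lambda = 3) {
  rand_matrix(n_cells, n_feat, seed,
              fun = function(n) as.double(rpois(n, lambda)))
}

# Exhaustive minimum within-SS over all partitions of sorted values into k
# contiguous blocks. Oracle for the clustering DP (n small).
exhaustive_ckmeans <- function(values, k) {
  xs <- sort(values)
  n <- length(xs)
  if (k == 1) {
    return(sum((xs - mean(xs))^2))
  }
  if (k >= n) return(0)
  best <- Inf
  cuts <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    ss <- 0
    for (i in seq_len(k)) {
      seg <- xs[(b[i] + 1):b[i + 1]]
      ss <- ss + sum((seg - mean(seg))^2)
    }
    best <- min(best, ss)
  }
  best
}

# Element-by-element loop oracle for the weighted squared distance.
loop_mahalanobis <- function(x, tech_var, weights) {
  out <- numeric(nrow(x))
  for (c in seq_len(nrow(x))) {
    acc <- 0
    for (j in seq_len(ncol(x))) {
      acc <- acc + x[c, j]^2 / (tech_var[j] / weights[j])
    }
    out[c] <- acc
  }
  out
}

# Independent gamma MLE: profile log-likelihood in the shape, maximized by
# golden-section search (stats::optimize), no Newton step shared with the
# implementation.
oracle_gamma_mle <- function(x) {
  x <- x[x > 0]
  prof <- function(shape) {
    rate <- shape / mean(x)
    sum(stats::dgamma(x, shape = shape, rate = rate, log = TRUE))
  }
  opt <- stats::optimize(prof, c(1e-3, 1e3), maximum = TRUE,
                         tol = 1e-10)
  list(shape = opt$maximum, rate = opt$maximum / mean(x))
}
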