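#' Log-normalize RNA counts
#'
#' Per-cell library-size normalization followed by a natural-log transform:
#' `value(c, g) = ln(1 + count(c, g) * scale_factor / total(c))`, the standard
#' scRNA-seq convention. Cells with zero total counts are rejected.
#'
#' @param counts Cells-by-genes non-negative count matrix with dimnames.
#' @param scale_factor Library-size scale (default `1e4`, i.e. counts per ten
#'   thousand).
#' @return Matrix of the same shape, attribute `normalization = "lognorm"`.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  counts <- validate_counts(counts)
  stopifnot(is.numeric(scale_factor), scale_factor > 0)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop("cells with zero total counts: ",
         paste(rownames(counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  out <- log1p(counts / totals * scale_factor)
  attr(out, "normalization") <- "lognorm"
  out
}

#' Centered log-ratio normalize ADT counts
#'
#' Along the chosen margin vector `x`, each entry becomes
#' `log1p(x_i) - mean_j(log1p(x_j))`; the `+1` pseudocount handles zeros and
#' the output is exactly centered along that margin. The compositional
#' reading of ADT data centers within each cell across antibodies
#' (`margin = "per_cell"`, the default); `"per_feature"` centers each
#' antibody across cells instead.
#'
#' @param counts Cells-by-antibodies non-negative count matrix.
#' @param margin `"per_cell"` or `"per_feature"`.
#' @return Matrix of the same shape (entries may be negative), attribute
#'   `normalization = "clr"`.
#' @export
clr_normalize <- function(counts, margin = c("per_cell", "per_feature")) {
  margin <- match.arg(margin)
  counts <- validate_counts(counts)
  l <- log1p(counts)
  out <- if (margin == "per_cell") l - rowMeans(l)
         else sweep(l, 2, colMeans(l), `-`)
  attr(out, "normalization") <- "clr"
  attr(out, "clr_margin") <- margin
  out
}

# Seeded randomized SVD of the (non-centered) matrix x, returning the top
# `rank` singular triplets. Oversampling and subspace (power) iterations
# follow the standard Halko-Martinsson-Tropp scheme; long-tailed single-cell
# spectra need the power iterations for accurate tail singular values.
randomized_svd <- function(x, rank, seed, n_oversample = 10L,
                           n_power = 10L) {
  m <- nrow(x); n <- ncol(x)
  stopifnot(rank >= 1, rank <= min(m, n))
  l <- min(rank + n_oversample, m, n)
  withr::with_seed(as.integer(seed %% 2147483647), {
    omega <- matrix(rnorm(n * l), n, l)
    q <- qr.Q(qr(x %*% omega))
    for (i in seq_len(n_power)) {
      z <- qr.Q(qr(crossprod(x, q)))
      q <- qr.Q(qr(x %*% z))
    }
    b <- crossprod(q, x)                  # l x n
    s <- svd(b)
    idx <- seq_len(rank)
    list(d = s$d[idx],
         u = (q %*% s$u)[, idx, drop = FALSE],
         v = s$v[, idx, drop = FALSE])
  })
}

#' Select a reconstruction rank from the singular-value spectrum
#'
#' Computes the top `max_rank` singular values of the non-centered matrix by
#' randomized SVD and converts them to component standard deviations
#' `s_i = sigma_i / sqrt(m - 1)` (the SDs of the non-centered sample
#' principal components). After smoothing the SD curve with a centered
#' moving average of width `smooth`, the selected rank is the smallest `k`
#' at which the consecutive decrease `s_k - s_{k+1}` first falls below
#' `threshold` times the total decrease `s_2 - s_max` — an explicit
#' rate-of-change elbow rule on the SD spectrum. The reference decrease is
#' measured from the second component because the first non-centered
#' component tracks overall library size and would otherwise dwarf the
#' structure-bearing part of the spectrum.
#'
#' @param normalized Cells-by-features normalized matrix (cells >= 2).
#' @param max_rank Largest rank considered (must be <= min dimension).
#' @param seed Integer seed for the randomized SVD.
#' @param threshold Elbow fraction of the total SD decrease (default 0.01).
#' @param smooth Moving-average window on the SD curve (default 3; 1 = none).
#' @return List with `candidate_sds`, `selected_rank`, `max_rank_considered`.
#' @export
select_rank <- function(normalized, max_rank = 100L, seed = 1L,
                        threshold = 0.01, smooth = 3L) {
  x <- validate_matrix(normalized, "normalized matrix")
  m <- nrow(x)
  if (m < 2) stop("need at least 2 cells for rank selection", call. = FALSE)
  if (max_rank < 1 || max_rank > min(dim(x))) {
    stop("max_rank must lie in [1, min(cells, features)]", call. = FALSE)
  }
  d <- randomized_svd(x, max_rank, seed)$d
  sds <- d / sqrt(m - 1)
  sm <- smooth_ma(sds, smooth)
  k <- if (max_rank == 1L) 1L else {
    drops <- sm[-length(sm)] - sm[-1]
    ref <- if (max_rank >= 3L) sds[2] else sds[1]   # unsmoothed: the MA
    total <- ref - sds[length(sds)]                 # window spans s_1
    if (total <= 1e-10 * sds[1]) 1L else {          # collapsed spectrum
      hit <- which(drops < threshold * total)
      if (length(hit)) hit[1] else max_rank
    }
  }
  list(candidate_sds = sds, selected_rank = as.integer(k),
       max_rank_considered = as.integer(max_rank))
}

# Centered moving average with shrinking windows at the ends.
smooth_ma <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L || length(x) < 3L) return(x)
  half <- width %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, 0)
}

#' Reduced-rank reconstruction
#'
#' Rank-`rank` truncated SVD reconstruction `U_k D_k V_k'` of the
#' non-centered input, computed with the seeded randomized SVD. Because the
#' downstream scoring assumes non-negative expression, negative
#' reconstructed entries are clamped to zero by default and the number of
#' clamped entries is recorded.
#'
#' @param normalized Cells-by-features normalized matrix.
#' @param rank Reconstruction rank in `[1, min(cells, features)]`.
#' @param seed Integer seed.
#' @param clamp Zero out negative reconstructed entries (default `TRUE`).
#' @return Matrix with attributes `rank_used` and `clamp_count`.
#' @export
rrr_reconstruct <- function(normalized, rank, seed = 1L, clamp = TRUE) {
  x <- validate_matrix(normalized, "normalized matrix")
  if (rank < 1 || rank > min(dim(x))) {
    stop("rank must lie in [1, min(cells, features)]", call. = FALSE)
  }
  s <- randomized_svd(x, rank, seed)
  recon <- s$u %*% (s$d * t(s$v))
  dimnames(recon) <- dimnames(x)
  clamp_count <- 0L
  if (clamp) {
    neg <- recon < 0
    clamp_count <- sum(neg)
    recon[neg] <- 0
  }
  attr(recon, "rank_used") <- as.integer(rank)
  attr(recon, "clamp_count") <- clamp_count
  recon
}
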