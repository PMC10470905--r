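test_that("technical variance is the unbiased per-gene sample variance", {
  m <- matrix(c(3, 3, 0, 2), 2, 2,
              dimnames = list(c("c1", "c2"), c("g1", "g2")))
  tv <- technical_variance(m, c("g1", "g2"))
  expect_equal(unname(tv), c(0, 2))
  # invariant to cell order
  expect_equal(technical_variance(m[2:1, ], c("g2", "g1")),
               tv[c("g2", "g1")])
  expect_error(technical_variance(m, "nope"), "unknown gene")
})

test_that("weighted distances follow the formula exactly", {
  x <- matrix(c(1, 2), 1, 2, dimnames = list("c1", c("g1", "g2")))
  expect_equal(modified_mahalanobis(x, c(1, 1), c(1, 1)), 5)
  # doubling one weight doubles that gene's contribution
  d1 <- modified_mahalanobis(x, c(1, 1), c(1, 1))
  d2 <- modified_mahalanobis(x, c(1, 1), c(1, 2))
  expect_equal(d2 - d1, 2^2 / 1 * (2 - 1))
  # loop oracle on random instances
  for (seed in 1:3) {
    xs <- rand_matrix(5, 3, seed, fun = function(n) abs(rnorm(n)))
    tv <- withr::with_seed(seed + 50, runif(3, 0.2, 2))
    w <- withr::with_seed(seed + 60, runif(3, 0.1, 1))
    expect_lt(max(abs(modified_mahalanobis(xs, tv, w) -
                        loop_mahalanobis(xs, tv, w))), 1e-12)
  }
  expect_error(modified_mahalanobis(x, c(0, 0), c(1, 1)), "zero")
})

test_that("column permutation preserves columns and is seed-deterministic", {
  m <- rand_matrix(20, 4, seed = 21)
  p1 <- permute_within_columns(m, seed = 5)
  p2 <- permute_within_columns(m, seed = 5)
  p3 <- permute_within_columns(m, seed = 6)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  expect_equal(colSums(p1), colSums(m))
  for (j in 1:4) expect_equal(unname(sort(p1[, j])),
                              unname(sort(m[, j])))
  one <- m[1, , drop = FALSE]
  expect_identical(permute_within_columns(one, 1), one)
})

test_that("gamma MLE recovers parameters and matches a profile oracle", {
  draws <- withr::with_seed(22, rgamma(50000, shape = 2, rate = 3))
  fit <- fit_gamma_mle(draws)
  expect_false(fit$degenerate)
  expect_gt(fit$shape, 1.94); expect_lt(fit$shape, 2.06)
  expect_gt(fit$rate, 2.9);  expect_lt(fit$rate, 3.1)
  # tiny sample against an independent profile-likelihood maximizer
  small <- fit_gamma_mle(c(1, 2, 3))
  orc <- oracle_gamma_mle(c(1, 2, 3))
  expect_equal(small$shape, orc$shape, tolerance = 1e-6)
  expect_equal(small$rate, orc$rate, tolerance = 1e-6)
  # degenerate cases signal instead of fitting
  expect_true(fit_gamma_mle(rep(2, 10))$degenerate)
  expect_true(fit_gamma_mle(c(0, 0, 0))$degenerate)
})

test_that("receptor scoring maps distances through the gamma CDF", {
  recon <- rand_matrix(300, 6, seed = 23, fun = function(n) abs(rnorm(n)))
  recon[4, ] <- 0                       # a cell with nothing expressed
  gs <- data.frame(gene = colnames(recon)[1:4],
                   weight = c(1, 0.8, 0.5, 0.3))
  recon[4, ] <- 0
  out <- score_receptor(recon, gs, seed = 2)
  expect_true(all(out$scores >= 0 & out$scores <= 1))
  expect_equal(unname(out$distances[4]), 0)
  expect_equal(unname(out$scores[4]), 0)
  # score order equals distance order
  expect_identical(order(out$scores), order(out$distances))
  # direct mode fits on the observed distances
  dir <- score_receptor(recon, gs, null_mode = "direct", seed = 2)
  expect_equal(dir$params$shape,
               fit_gamma_mle(dir$distances)$shape)
  expect_error(score_receptor(recon, data.frame(gene = "zz", weight = 1)),
               "absent")
})

test_that("weight rescaling scales distances and preserves score ranking", {
  recon <- rand_matrix(100, 5, seed = 24, fun = function(n) abs(rnorm(n)))
  gs <- data.frame(gene = colnames(recon)[1:3], weight = c(0.9, 0.5, 0.2))
  gs2 <- gs; gs2$weight <- gs$weight * 3
  a <- score_receptor(recon, gs, seed = 7)
  b <- score_receptor(recon, gs2, seed = 7)
  expect_equal(b$distances, a$distances * 3, tolerance = 1e-12)
  expect_identical(order(a$scores), order(b$scores))
})

test_that("degenerate calibration falls back to scaled distances", {
  recon <- matrix(1, 5, 3, dimnames = list(sprintf("c%d", 1:5),
                                           sprintf("g%d", 1:3)))
  recon[, 1] <- c(0, 0, 2, 2, 0)        # two-valued gene
  gs <- data.frame(gene = "g1", weight = 1)
  # the only positive distance value repeats: < 2 distinct -> degenerate
  expect_warning(out <- score_receptor(recon, gs, seed = 1), "degenerate")
  expect_true(all(out$scores >= 0 & out$scores <= 1))
})

test_that("null scores are near-uniform on independent columns", {
  # i.i.d. half-normal columns: the squared distance is then a scaled
  # chi-square, inside the gamma family, so the calibrated scores on null
  # data should be approximately Uniform(0, 1)
  x <- withr::with_seed(25, matrix(abs(rnorm(5000 * 10)), 5000, 10))
  dimnames(x) <- list(sprintf("c%04d", 1:5000), sprintf("g%02d", 1:10))
  gs <- data.frame(gene = colnames(x), weight = rep(1, 10))
  out <- score_receptor(x, gs, seed = 3)
  ks <- suppressWarnings(stats::ks.test(out$scores, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})
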