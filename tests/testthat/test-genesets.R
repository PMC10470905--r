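test_that("spearman_rho matches closed forms and the rank-Pearson oracle", {
  expect_equal(spearman_rho(1:3, c(2, 4, 6)), 1.0)
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1.0)
  expect_equal(spearman_rho(1:4, c(1, 3, 2, 4)), 0.8)
  expect_error(spearman_rho(1:3, 1:4), "equal length")
  expect_true(is.nan(spearman_rho(rep(1, 5), 1:5)))
  # against stats::cor(method = "spearman"), including ties
  withr::with_seed(9, {
    for (i in 1:1000) {
      x <- sample(1:8, 12, replace = TRUE)
      y <- sample(1:8, 12, replace = TRUE)
      if (length(unique(x)) < 2 || length(unique(y)) < 2) next
      expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                   tolerance = 1e-12)
    }
  })
})

test_that("correlation table is consistent and truncates to gene sets", {
  recon <- rand_matrix(50, 12, seed = 10, fun = function(n) abs(rnorm(n)))
  adt <- rand_matrix(50, 5, seed = 11)
  colnames(adt) <- sprintf("ADT%d", 1:5)
  tab <- correlation_table(recon, adt)
  expect_identical(dim(tab), c(12L, 5L))
  # per-entry agreement with the scalar implementation
  for (g in sample(colnames(recon), 4)) {
    for (r in colnames(adt)) {
      expect_equal(tab[g, r], spearman_rho(recon[, g], adt[, r]),
                   tolerance = 1e-12)
    }
  }
  # gene whose values are the ADT ranks correlates perfectly
  recon2 <- recon
  recon2[, 1] <- rank(adt[, 1])
  expect_equal(correlation_table(recon2, adt)[1, 1], 1.0)
  # build_gene_sets equals brute-force sort + positive truncation
  sets <- build_gene_sets(recon, adt, set_size = 4)
  for (r in colnames(adt)) {
    rho <- tab[, r]
    pos <- rho[is.finite(rho) & rho > 0]
    expected <- names(sort(pos, decreasing = TRUE))[seq_len(min(4,
                                                                length(pos)))]
    expect_identical(sets[[r]]$gene, expected)
    expect_equal(sets[[r]]$weight, unname(rho[expected]))
  }
})

test_that("monotone receptor-gene coupling is recovered as the top gene", {
  withr::with_seed(12, {
    n <- 200
    adt <- matrix(rnorm(n), n, 1,
                  dimnames = list(sprintf("c%03d", 1:n), "R1"))
    recon <- matrix(abs(rnorm(n * 30)), n, 30,
                    dimnames = list(rownames(adt),
                                    sprintf("g%02d", 1:30)))
    recon[, "g07"] <- exp(adt[, 1])        # strictly increasing in the ADT
  })
  sets <- build_gene_sets(recon, adt, set_size = 10)
  expect_identical(sets$R1$gene[1], "g07")
  expect_equal(sets$R1$weight[1], 1.0)
})

test_that("gene set invariants hold: ordering, positivity, permutation", {
  recon <- rand_matrix(40, 15, seed = 13, fun = function(n) abs(rnorm(n)))
  adt <- rand_matrix(40, 3, seed = 14)
  colnames(adt) <- c("Ra", "Rb", "Rc")
  sets <- build_gene_sets(recon, adt, set_size = 10)
  expect_identical(attr(sets, "set_size"), 10L)
  for (r in names(sets)) {
    d <- sets[[r]]
    expect_true(all(d$weight > 0))
    expect_true(all(diff(d$weight) <= 0))
    # every stored weight reproducible from the raw columns
    for (i in seq_len(nrow(d))) {
      expect_equal(d$weight[i], spearman_rho(recon[, d$gene[i]], adt[, r]),
                   tolerance = 1e-12)
    }
  }
  # permuting gene columns leaves the learned sets unchanged
  perm <- withr::with_seed(15, sample(ncol(recon)))
  sets_p <- build_gene_sets(recon[, perm], adt, set_size = 10)
  for (r in names(sets)) expect_equal(sets[[r]], sets_p[[r]])
})

test_that("a constant antibody yields an empty set with a warning", {
  recon <- rand_matrix(30, 8, seed = 16, fun = function(n) abs(rnorm(n)))
  adt <- rand_matrix(30, 2, seed = 17)
  colnames(adt) <- c("Rconst", "Rok")
  adt[, "Rconst"] <- 4
  expect_warning(sets <- build_gene_sets(recon, adt), "Rconst")
  expect_identical(nrow(sets$Rconst), 0L)
  expect_gt(nrow(sets$Rok), 0L)
})

test_that("cell id mismatches are rejected", {
  recon <- rand_matrix(10, 4, seed = 18)
  adt <- rand_matrix(10, 2, seed = 19)
  rownames(adt)[1] <- "zzz"
  expect_error(correlation_table(recon, adt), "identical cell ids")
})
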