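test_that("splits have requested sizes, are disjoint, and reproduce", {
  ids <- sprintf("cell%04d", 1:5000)
  plans <- make_splits(ids, n_repeats = 5, train_frac = 0.2, seed = 3)
  expect_identical(length(plans), 5L)
  for (p in plans) {
    expect_identical(length(p$train), 1000L)
    expect_identical(length(p$target), 4000L)
    expect_identical(length(intersect(p$train, p$target)), 0L)
  }
  again <- make_splits(ids, 5, 0.2, seed = 3)
  expect_identical(plans, again)
  expect_false(identical(plans, make_splits(ids, 5, 0.2, seed = 4)))
  expect_error(make_splits(ids, 5, 1.2, 1), "train_frac")
})

test_that("concordance is a per-receptor rank correlation against ADT", {
  withr::with_seed(40, {
    adt <- matrix(rnbinom(5000 * 2, mu = 30, size = 5), 5000, 2,
                  dimnames = list(sprintf("c%04d", 1:5000),
                                  c("R1", "R2")))
    est <- matrix(runif(5000 * 2), 5000, 2,
                  dimnames = dimnames(adt))
  })
  # a monotone transform of the ADT is perfectly concordant
  clr <- clr_normalize(adt)
  est[, "R1"] <- exp(clr[, "R1"])
  rho <- concordance(est, adt)
  expect_equal(unname(rho["R1"]), 1.0)
  # independent noise is near zero at this sample size
  expect_lt(abs(rho["R2"]), 0.05)
  # constant estimates are undefined
  est[, "R2"] <- 0.5
  expect_true(is.nan(concordance(est, adt)["R2"]))
  # invariance to strictly monotone transforms of the estimates
  est2 <- est
  est2[, "R1"] <- 3 * est[, "R1"] + 1
  expect_equal(concordance(est2, adt)["R1"], rho["R1"])
  # rename map routes estimate columns to ADT features
  est3 <- est[, "R1", drop = FALSE]
  colnames(est3) <- "CD_R1"
  expect_equal(unname(concordance(est3, adt,
                                  rename_map = c(CD_R1 = "R1"))), 1.0)
})

test_that("best-method shares recount wins and split ties", {
  tab <- data.frame(method = rep(c("a", "b"), each = 2),
                    receptor = rep(c("r1", "r2"), 2),
                    rho = c(0.9, 0.8, 0.1, 0.2))
  p <- best_method_proportions(tab)
  expect_equal(unname(p["a"]), 100)
  expect_equal(unname(p["b"]), 0)
  tab$rho <- c(0.9, 0.1, 0.1, 0.9)
  p2 <- best_method_proportions(tab)
  expect_equal(unname(p2), c(50, 50))
  # random table against a brute-force recount
  tab3 <- withr::with_seed(41, expand.grid(
    method = c("a", "b", "c"), receptor = sprintf("r%02d", 1:20),
    repeat_index = 1:3, stringsAsFactors = FALSE))
  tab3$rho <- withr::with_seed(42, runif(nrow(tab3), -1, 1))
  p3 <- best_method_proportions(tab3)
  expect_equal(sum(p3), 100)
  avg <- tapply(tab3$rho, list(tab3$receptor, tab3$method), mean)
  manual <- table(factor(colnames(avg)[apply(avg, 1, which.max)],
                         levels = c("a", "b", "c")))
  expect_equal(unname(p3), unname(as.vector(manual) / 20 * 100))
})

test_that("ties and undefined rows are handled in proportions", {
  tab <- data.frame(method = c("a", "b"), receptor = c("r1", "r1"),
                    rho = c(0.5, 0.5))
  p <- best_method_proportions(tab)
  expect_equal(unname(p), c(50, 50))
  tab2 <- rbind(tab, data.frame(method = c("a", "b"),
                                receptor = "r2", rho = NaN))
  expect_warning(p2 <- best_method_proportions(tab2), "excluded")
  expect_equal(sum(p2), 100)
})

test_that("sensitivity sweep runs the grid and is seed-deterministic", {
  sim <- simulate_joint(n_cells = 250, n_genes = 120, n_receptors = 3,
                        module_size = 5, rna_dropout = 0.5, seed = 5)
  cfg <- abundance_config(seed = 5)
  res <- sensitivity_sweep(sim$rna, sim$adt,
                           receptor_to_gene = sim$truth$receptor_to_gene,
                           set_sizes = c(5L, 10L), train_sizes = 100L,
                           n_repeats = 1L, config = cfg)
  expect_identical(sort(unique(res$set_size)), c(5L, 10L))
  expect_setequal(unique(res$method), c("gene_set", "rna"))
  # 2 set sizes x 3 receptors x 2 methods
  expect_identical(nrow(res), 12L)
  res2 <- sensitivity_sweep(sim$rna, sim$adt,
                            receptor_to_gene = sim$truth$receptor_to_gene,
                            set_sizes = c(5L, 10L), train_sizes = 100L,
                            n_repeats = 1L, config = cfg)
  expect_identical(res, res2)
})
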