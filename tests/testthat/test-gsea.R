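# hand-built bootstrap object: B is genes x replicates, point defaults to row means
fake_boot <- function(B_d, B_c = B_d, point_d = rowMeans(B_d),
                      point_c = rowMeans(B_c)) {
  structure(list(boot_d = B_d, boot_c = B_c, point_d = point_d,
                 point_c = point_c, gene_ids = rownames(B_d),
                 term = "treatment", n_boot = ncol(B_d), seed = 1L),
            class = "hurdle_boot")
}

test_that("Stouffer combination follows the weighted-Z formula", {
  expect_equal(stouffer_combine(1, 1), sqrt(2))
  expect_equal(stouffer_combine(1, -1), 0)
  expect_equal(stouffer_combine(1.96, 0), 1.96 / sqrt(2), tolerance = 1e-4)
  expect_equal(stouffer_combine(1.96, 0), 1.3859, tolerance = 1e-4)
  expect_equal(stouffer_combine(2, 1, weights = c(3, 1)),
               (3 * 2 + 1) / sqrt(10))
})

test_that("bootstrap replicates are a pure function of the seed", {
  sim <- toy_assay(40, 10, seed = 40)
  fit <- hurdle(~ treatment, sim$covariates, sim$assay)
  b1 <- bootstrap_coefs(fit, "treatment", n_boot = 5, seed = 7)
  b2 <- bootstrap_coefs(fit, "treatment", n_boot = 5, seed = 7)
  expect_identical(b1$boot_d, b2$boot_d)
  expect_identical(b1$boot_c, b2$boot_c)
  b3 <- bootstrap_coefs(fit, "treatment", n_boot = 5, seed = 8)
  expect_false(identical(b1$boot_c, b3$boot_c))
})

test_that("a constant gene has zero continuous coefficient variance across replicates", {
  sim <- toy_assay(30, 5, seed = 41)
  vals <- sim$assay$values
  vals[, 2] <- 4.2   # identical in every cell
  fit <- hurdle(~ treatment, sim$covariates, sc_assay(vals))
  bt <- bootstrap_coefs(fit, "treatment", n_boot = 6, seed = 3)
  expect_equal(unname(var(bt$boot_c[2, ])), 0)
  # detection is all-ones there: discrete replicates are flagged missing
  expect_true(all(is.na(bt$boot_d[2, ])))
})

test_that("identical coefficients across all genes give Z = 0", {
  B <- matrix(0.7, 10, 6, dimnames = list(sprintf("g%d", 1:10), NULL))
  B <- B + matrix(rep(rnorm(6, sd = 0.1), each = 10), 10, 6) # common shift only
  bt <- fake_boot(B)
  res <- set_z_test(bt, c("g1", "g2", "g3"), "continuous")
  expect_equal(res$theta_test, res$theta_null)
  expect_equal(res$z, 0)
})

test_that("the covariance-aware variance equals the variance of the set mean", {
  set.seed(42)
  B <- matrix(rnorm(5 * 30), 5, 30, dimnames = list(sprintf("g%d", 1:5), NULL))
  B[2, ] <- B[1, ] * 0.8 + rnorm(30, sd = 0.2)  # correlated pair
  Bfull <- rbind(B, matrix(rnorm(20 * 30), 20, 30,
                           dimnames = list(sprintf("h%d", 1:20), NULL)))
  bt <- fake_boot(Bfull)
  res <- set_z_test(bt, sprintf("g%d", 1:5), "discrete")
  expect_equal(res$var_test, var(colMeans(B)), tolerance = 1e-10)
})

test_that("Z is antisymmetric under swapping test and null sets", {
  set.seed(43)
  B <- matrix(rnorm(12 * 8), 12, 8, dimnames = list(sprintf("g%d", 1:12), NULL))
  bt <- fake_boot(B)
  set1 <- sprintf("g%d", 1:5)
  set2 <- sprintf("g%d", 6:12)
  z1 <- set_z_test(bt, set1, "continuous")$z
  z2 <- set_z_test(bt, set2, "continuous")$z
  expect_equal(z1, -z2)
})

test_that("run_gsea results are invariant to gene order within sets", {
  sim <- simulate_cells(sim_scenario(n_cells = 60, n_genes = 40,
                                     effect_frac = 0.25, effect_c = 1,
                                     seed = 44))
  fit <- hurdle(~ treatment, sim$covariates, sim$assay)
  bt <- bootstrap_coefs(fit, "treatment", n_boot = 8, seed = 5)
  sets <- list(a = paste0("gene", 1:10), b = paste0("gene", 25:35))
  sets_rev <- lapply(sets, rev)
  g1 <- run_gsea(bt, sets)
  g2 <- run_gsea(bt, sets_rev)
  expect_equal(g1$z, g2$z)
  # boundary partition: near-universe set still yields finite Z
  big <- list(huge = paste0("gene", 1:39))
  g3 <- run_gsea(bt, big, min_set_size = 5)
  expect_true(is.finite(g3$z))
})

test_that("an enriched set ranks first and a signal-free collection stays quiet", {
  sim <- simulate_cells(sim_scenario(n_cells = 100, n_genes = 120,
                                     effect_frac = 1 / 6, effect_c = 1,
                                     seed = 45))
  fit <- hurdle(~ treatment + cdr, sim$covariates, sim$assay)
  bt <- bootstrap_coefs(fit, "treatment", n_boot = 20, seed = 9)
  eff <- paste0("gene", sim$truth$effect_genes)
  set.seed(46)
  sets <- c(list(signal = eff),
            lapply(1:20, function(i) sample(paste0("gene", 21:120), 15)))
  names(sets) <- c("signal", sprintf("rand%02d", 1:20))
  g <- run_gsea(bt, sets)
  expect_equal(g$set[1], "signal")
  expect_lt(g$p_adj[1], 0.01)
})

test_that("degenerate bootstrap inputs are rejected", {
  B <- matrix(rnorm(10), 10, 1, dimnames = list(sprintf("g%d", 1:10), NULL))
  bt <- fake_boot(B)
  expect_error(set_z_test(bt, "g1", "discrete"), "replicates")
  sim <- toy_assay(20, 5, seed = 47)
  fit <- hurdle(~ treatment, sim$covariates, sim$assay)
  expect_error(bootstrap_coefs(fit, "treatment", n_boot = 1), "at least 2")
})
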