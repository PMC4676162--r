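# minimal hand-built fit object for formula-level checks of the fold-change
fake_fit <- function(beta_d, beta_c, X) {
  structure(list(beta_d = beta_d, beta_c = beta_c, design = X,
                 gene_ids = rownames(beta_d), covariates = NULL),
            class = "hurdle_fit")
}

test_that("component statistics sum with added degrees of freedom", {
  comb <- combine_tests(3, 1, 5, 1)
  expect_equal(comb$chisq, 8)
  expect_equal(comb$df, 2)
  expect_equal(comb$p, exp(-4), tolerance = 1e-12)
  expect_equal(combine_tests(0, 1, 0, 1)$p, 1)
  flagged <- combine_tests(0, 0, 0, 0)
  expect_equal(flagged$p, 1)
  expect_true(flagged$df_zero)
  # symmetric in the two components
  expect_equal(combine_tests(2.2, 1, 0.7, 2)$p, combine_tests(0.7, 2, 2.2, 1)$p)
  expect_error(combine_tests(-1, 1, 0, 1), "non-negative")
})

test_that("the sum of independent chi-square(1) draws is chi-square(2)", {
  set.seed(30)
  x <- rchisq(1e5, 1) + rchisq(1e5, 1)
  D <- suppressWarnings(ks.test(x, pchisq, df = 2))$statistic
  expect_lt(D, 0.01)
})

test_that("BH adjustment matches the step-up oracle exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(31)
  worst <- 0
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    worst <- max(worst, max(abs(bh_adjust(p) - bh_oracle(p))))
  }
  expect_lt(worst, 1e-12)
  expect_error(bh_adjust(c(0.1, 1.2)), "within")
  expect_error(bh_adjust(c(0.1, NA)), "finite")
})

test_that("the DE call requires both the FDR and the fold-change gate", {
  tab <- data.frame(p_adj = c(0.005, 0.005, 0.02),
                    logfc = c(1.0, 0.30, 2.0))
  out <- call_de(tab)
  expect_equal(out$is_de, c(TRUE, FALSE, FALSE))
  # thresholds are configurable
  out2 <- call_de(tab, fdr_cut = 0.05, logfc_cut = 0.1)
  expect_equal(out2$is_de, c(TRUE, TRUE, TRUE))
})

test_that("Wald statistics equal the explicit quadratic form", {
  set.seed(32)
  b <- c(0.4, -0.2)
  A <- matrix(rnorm(4), 2); V <- crossprod(A) + diag(2) * 0.1
  expect_equal(schurdle:::wald_quadform(b, V),
               drop(t(b) %*% solve(V) %*% b))
  expect_equal(schurdle:::wald_quadform(c(0, 0), V), 0)
})

test_that("fold-change limits behave as the unconditional-mean definition implies", {
  cov <- data.frame(treatment = rep(c("a", "b"), 5))
  X <- build_design(~ treatment, cov)
  bz <- matrix(0, 2, 2, dimnames = list(c("g1", "g2"), colnames(X)))
  # no effect anywhere -> 0
  f0 <- fake_fit(bz, bz, X)
  expect_equal(estimate_logfc(f0, "treatment")$logfc, c(0, 0))
  # detection certain in both arms, pure continuous shift delta -> delta
  bd <- bz; bd[, 1] <- 50
  bc <- bz; bc[, 1] <- 5; bc[, 2] <- c(1.5, -0.7)
  f1 <- fake_fit(bd, bc, X)
  lfc <- estimate_logfc(f1, "treatment")
  expect_equal(lfc$logfc, c(1.5, -0.7), tolerance = 1e-10)
  # components always sum to the total
  expect_equal(lfc$logfc_d + lfc$logfc_c, lfc$logfc)
})

test_that("fold-change matches a brute-force prediction contrast on fitted models", {
  sim <- simulate_cells(sim_scenario(n_cells = 120, n_genes = 20,
                                     effect_frac = 0.5, effect_d = 0.7,
                                     effect_c = 0.9, seed = 33))
  fit <- hurdle(~ treatment + cdr, sim$covariates, sim$assay)
  lfc <- estimate_logfc(fit, "treatment")
  X <- fit$design
  x0 <- colMeans(X); x1 <- x0
  x0["treatmentstim"] <- 0; x1["treatmentstim"] <- 1
  oracle <- predict(fit, newdata = rbind(x1), type = "unconditional") -
    predict(fit, newdata = rbind(x0), type = "unconditional")
  expect_equal(lfc$logfc, drop(oracle), ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("lrt and wald component tests broadly agree on strong effects", {
  sim <- simulate_cells(sim_scenario(n_cells = 200, n_genes = 30,
                                     effect_frac = 0.5, effect_c = 1.2,
                                     seed = 34))
  fit <- hurdle(~ treatment, sim$covariates, sim$assay)
  de_l <- de_test(fit, "treatment", method = "lrt")
  de_w <- de_test(fit, "treatment", method = "wald")
  expect_gt(cor(de_l$chisq, de_w$chisq), 0.95)
  expect_error(component_tests(fit, fit, "treatment"), "not nested")
})

test_that("null data give approximately uniform combined p-values", {
  sim <- simulate_cells(sim_scenario(n_cells = 150, n_genes = 150, seed = 35))
  fit <- hurdle(~ treatment, sim$covariates, sim$assay)
  de <- de_test(fit, "treatment")
  frac <- mean(de$p < 0.05)
  se <- sqrt(0.05 * 0.95 / 150)
  expect_lt(abs(frac - 0.05), 3 * se)
  expect_equal(sum(de$is_de), 0)
})

test_that("deviance fractions: orthogonal covariates explain nothing, decisive ones everything", {
  set.seed(36)
  sim <- simulate_cells(sim_scenario(n_cells = 500, n_genes = 40, seed = 37))
  cov <- sim$covariates
  cov$noise <- rnorm(nrow(cov))     # independent of everything
  fit <- hurdle(~ treatment + noise, cov, sim$assay)
  dd <- deviance_decomposition(fit, "noise")
  expect_lt(mean(dd$frac), 0.01)

  # covariate fully determining detection: discrete fraction near 1
  n <- 60
  xx <- rep(c(0, 1), each = n / 2)
  vals <- matrix(0, n, 2)
  vals[xx == 1, ] <- matrix(rnorm(n, 6, 0.5), n / 2, 2)
  a <- sc_assay(abs(vals))
  fit2 <- hurdle(~ xx, data.frame(xx = xx), a)
  dd2 <- deviance_decomposition(fit2, "xx")
  expect_true(all(dd2$frac_d > 0.9))
})

test_that("deviance fractions match a brute-force refit sequence", {
  sim <- simulate_cells(sim_scenario(n_cells = 80, n_genes = 10,
                                     cell_size_sd = 0.3, seed = 38))
  fit <- hurdle(~ treatment + cdr, sim$covariates, sim$assay)
  dd <- deviance_decomposition(fit, "cdr")
  # oracle: recompute from scratch with independent component fits
  X <- fit$design
  Xr <- X[, colnames(X) != "cdr"]
  X0 <- X[, 1, drop = FALSE]
  for (g in c(1, 4, 10)) {
    z <- sim$assay$detection[, g]; y <- sim$assay$values[, g]
    dev_d <- function(M) -2 * fit_discrete(z, M, fit$settings$prior)$loglik
    num_d <- max(dev_d(Xr) - dev_d(X), 0)
    den_d <- dev_d(X0)
    expect_equal(dd$frac_d[g], min(num_d / den_d, 1), tolerance = 1e-6)
  }
})
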