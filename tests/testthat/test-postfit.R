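test_that("binomial deviance residuals match the closed-form formula", {
  sim <- toy_assay(50, 10, seed = 50)
  fit <- hurdle(~ treatment + cdr, sim$covariates, sim$assay)
  r <- deviance_residuals(fit, standardize = FALSE)
  phat <- predict(fit, type = "detection")
  Z <- sim$assay$detection
  set.seed(51)
  idx <- cbind(sample(nrow(Z), 100, TRUE), sample(ncol(Z), 100, TRUE))
  for (k in 1:100) {
    i <- idx[k, 1]; g <- idx[k, 2]
    p <- phat[i, g]; z <- Z[i, g]
    oracle <- sign(z - p) * sqrt(-2 * (z * log(p) + (1 - z) * log(1 - p)))
    expect_equal(r$discrete[i, g], oracle, tolerance = 1e-10)
  }
})

test_that("continuous residuals are missing exactly where undetected and combine by averaging", {
  sim <- toy_assay(40, 8, seed = 52)
  fit <- hurdle(~ treatment, sim$covariates, sim$assay)
  r <- deviance_residuals(fit)
  miss <- is.na(r$continuous)
  expect_identical(unname(miss), unname(sim$assay$detection == 0))
  expect_equal(r$combined[miss], r$discrete[miss])
  both <- !miss
  expect_equal(r$combined[both],
               (r$discrete[both] + r$continuous[both]) / 2)
})

test_that("standardization divides by sqrt(1 - leverage) of the continuous fit", {
  sim <- toy_assay(30, 4, seed = 53)
  fit <- hurdle(~ treatment, sim$covariates, sim$assay)
  raw <- deviance_residuals(fit, standardize = FALSE)
  std <- deviance_residuals(fit, standardize = TRUE)
  g <- 1
  idx <- which(sim$assay$detection[, g] == 1)
  Xg <- fit$design[idx, ]
  h <- diag(Xg %*% solve(crossprod(Xg)) %*% t(Xg))
  expect_equal(std$continuous[idx, g], raw$continuous[idx, g] / sqrt(1 - h),
               tolerance = 1e-8)
})

test_that("component residuals have near-zero gene means under the model", {
  # the combined average carries a systematic offset (the continuous residual
  # exists only on expressed cells, so averaging halves the positive-side
  # discrete residual); the centering property belongs to the components.
  sim <- simulate_cells(sim_scenario(n_cells = 500, n_genes = 30,
                                     baseline_logit_sd = 0.3, seed = 54))
  fit <- hurdle(~ treatment, sim$covariates, sim$assay)
  r <- deviance_residuals(fit)
  n <- nrow(r$discrete)
  mu_d <- colMeans(r$discrete)
  se_d <- apply(r$discrete, 2, sd) / sqrt(n)
  expect_gt(mean(abs(mu_d) <= 3 * se_d), 0.9)
  mu_c <- colMeans(r$continuous, na.rm = TRUE)
  n_c <- colSums(!is.na(r$continuous))
  se_c <- apply(r$continuous, 2, sd, na.rm = TRUE) / sqrt(n_c)
  expect_gt(mean(abs(mu_c) <= 3 * se_c), 0.9)
})

test_that("cell scores subtract the nuisance-restricted prediction", {
  sim <- toy_assay(30, 6, seed = 55)
  fit <- hurdle(~ treatment + cdr, sim$covariates, sim$assay)
  s <- cell_scores(fit, nuisance_terms = "cdr")
  Xn <- fit$design[, c("(Intercept)", "cdr")]
  g <- 3
  zhat <- plogis(drop(Xn %*% fit$beta_d[g, c("(Intercept)", "cdr")]))
  yhat <- drop(Xn %*% fit$beta_c[g, c("(Intercept)", "cdr")])
  expect_equal(s[, g], sim$assay$values[, g] - zhat * yhat,
               ignore_attr = TRUE)
  # empty nuisance set: intercept-only prediction
  s0 <- cell_scores(fit, character())
  b0d <- fit$beta_d[g, 1]; b0c <- fit$beta_c[g, 1]
  expect_equal(s0[, g], sim$assay$values[, g] - plogis(b0d) * b0c,
               ignore_attr = TRUE)
  expect_error(cell_scores(fit, "nope"), "unknown nuisance")
})

test_that("treatment shifts survive in scores after nuisance correction", {
  sim <- simulate_cells(sim_scenario(n_cells = 1000, n_genes = 40,
                                     effect_frac = 1, effect_c = 1,
                                     baseline_logit_mean = 3,
                                     baseline_logit_sd = 0, seed = 56))
  fit <- hurdle(~ treatment + cdr, sim$covariates, sim$assay)
  s <- cell_scores(fit, nuisance_terms = "cdr")
  stim <- sim$covariates$treatment == "stim"
  gap <- colMeans(s[stim, ]) - colMeans(s[!stim, ])
  # detection is near-certain, so the unconditional shift is ~ the continuous effect
  expect_lt(abs(mean(gap) - 1), 0.1)
})

test_that("module scores are plain member means", {
  s <- matrix(1:12, 3, 4, dimnames = list(NULL, paste0("g", 1:4)))
  ms <- module_scores(s, list(single = "g2", pair = c("g1", "g3"),
                              dup = c("g4", "g4")))
  expect_equal(ms[, "single"], s[, "g2"], ignore_attr = TRUE)
  expect_equal(ms[, "pair"], (s[, "g1"] + s[, "g3"]) / 2, ignore_attr = TRUE)
  expect_equal(ms[, "dup"], s[, "g4"], ignore_attr = TRUE)
  expect_warning(module_scores(s, list(a = "g1", gone = "zz")), "dropped")
})

test_that("residual correlations: unit diagonal, flagged degenerate genes, grouped output", {
  set.seed(57)
  R <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, paste0("g", 1:5)))
  R[, 5] <- 0 # zero variance
  rc <- residual_correlation(R)
  mats <- attr(rc, "matrices")$all
  expect_equal(diag(mats), rep(1, 5), ignore_attr = TRUE)
  expect_true(all(is.na(rc$rho[rc$gene1 == "g5" | rc$gene2 == "g5"])))
  # independent genes stay near zero
  expect_lt(mean(abs(rc$rho), na.rm = TRUE), 0.1)
  grp <- rep(c("x", "y"), each = 100)
  rcg <- residual_correlation(R[, 1:3], group = grp)
  expect_equal(sort(unique(rcg$group)), c("x", "y"))
  expect_error(residual_correlation(R[1:4, 1:3], group = c("a", "a", "b", "b")),
               "at least 3 cells")
})

test_that("CDR adjustment reduces background residual correlation", {
  sim <- simulate_cells(sim_scenario(n_cells = 200, n_genes = 60,
                                     cell_size_sd = 0.4, seed = 58))
  f_cdr <- hurdle(~ treatment + cdr, sim$covariates, sim$assay)
  f_raw <- hurdle(~ treatment, sim$covariates, sim$assay)
  med <- function(f) {
    C <- attr(residual_correlation(deviance_residuals(f)), "matrices")$all
    median(abs(C[upper.tri(C)]), na.rm = TRUE)
  }
  expect_lt(med(f_cdr), med(f_raw))
})

test_that("residual PCA is deterministic, sign-fixed and matches an eigen oracle", {
  set.seed(59)
  # rank-1 structure
  R1 <- outer(rnorm(30), rnorm(6))
  p1 <- residual_pca(R1, k = 1)
  expect_gt(p1$var_explained[1], 0.999)
  # sign convention: largest-magnitude loading entry positive, runs identical
  R <- matrix(rnorm(10 * 6), 10, 6)
  pa <- residual_pca(R, k = 3)
  pb <- residual_pca(R, k = 3)
  expect_identical(pa, pb)
  for (j in 1:3) expect_gt(max(pa$loadings[, j]), 0)
  # eigen oracle on the centered covariance
  C <- cov(scale(R, center = TRUE, scale = FALSE)) * (9 / 10) * (10 / 9)
  ev <- eigen(cov(R), symmetric = TRUE)
  expect_equal(pa$sdev^2, ev$values[1:3] * (9 / 10) * (10 / 9),
               tolerance = 1e-8)
  expect_equal(abs(pa$loadings[, 1]), abs(ev$vectors[, 1]), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_warning(residual_pca(R1, k = 4), "rank")
})
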