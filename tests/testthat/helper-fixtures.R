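# Small fixtures shared across test files. Everything is generated in code.

# a tiny deterministic assay with a binary treatment covariate
toy_assay <- function(n = 40, G = 8, seed = 1) {
  sim <- simulate_cells(sim_scenario(n_cells = n, n_genes = G, seed = seed))
  sim
}

# independent step-up implementation of Benjamini-Hochberg used as an oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# penalized logistic objective in the scaled space used by fit_discrete
penalized_logit_objective <- function(X, z, prior) {
  is_int <- apply(X, 2L, function(col) all(col == col[1L]))
  sds <- apply(X, 2L, stats::sd)
  f <- ifelse(is_int | sds == 0, 1, 2 * sds)
  Xs <- sweep(X, 2L, f, "/")
  pr_df <- ifelse(is_int, prior$df_intercept, prior$df)
  pr_sc <- ifelse(is_int, prior$scale_intercept, prior$scale)
  list(
    f = f,
    value = function(bs) {
      eta <- drop(Xs %*% bs)
      ll <- sum(z * eta) -
        sum(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))))
      ll + sum(stats::dt(bs / pr_sc, df = pr_df, log = TRUE) - log(pr_sc))
    })
}
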