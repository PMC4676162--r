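#' Empirical-Bayes gamma prior on residual precisions
#'
#' Genes expressed in few cells carry little information about their residual
#' variance, but variances are broadly similar across genes. A gamma prior
#' \eqn{\tau_g^2 \sim Gamma(\alpha, \beta)} on the per-gene precision is
#' fitted by marginal maximum likelihood: given precision \eqn{\tau}, the
#' residual sum of squares of a gene with \eqn{d} residual degrees of freedom
#' satisfies \eqn{\tau \cdot SSR \sim \chi^2_d}, and conjugacy integrates
#' \eqn{\tau} out analytically, leaving a closed-form marginal in
#' \eqn{(\alpha, \beta)}. Optimization is quasi-Newton on the log scale with
#' moment-matched starts plus restarts.
#'
#' @param ssr per-gene residual sums of squares (NA for genes without a
#'   continuous fit).
#' @param df per-gene residual degrees of freedom.
#' @return List of class `shrinkage_prior`: `alpha`, `beta`, `common_precision
#'   = alpha/beta`, `pseudo_obs = 2*alpha`, `loglik`, `convergence`,
#'   `n_genes_used`.
#' @seealso [shrink_precisions()]
#' @export
fit_gamma_prior <- function(ssr, df) {
  ok <- which(is.finite(ssr) & is.finite(df) & df >= 1 & ssr > 0)
  if (length(ok) < 2L)
    stop("need at least 2 genes with residual df >= 1 to fit the precision prior")
  s <- ssr[ok]; d <- df[ok]

  nll <- function(par) {
    a <- exp(par[1L]); b <- exp(par[2L])
    -sum(marginal_loglik_gene(s, d, a, b))
  }

  # moment-matched start from the precision MLEs
  tau <- d / s
  m <- mean(tau); v <- stats::var(tau)
  if (!is.finite(v) || v <= 0) v <- m^2
  start <- log(c(m^2 / v, m / v))
  starts <- list(start, start + c(1, 1), start - c(1, 1))

  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::optim(pmin(pmax(st, -25), 25), nll, method = "L-BFGS-B",
                   lower = c(-30, -30), upper = c(30, 30),
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("precision-prior optimization failed")
  alpha <- exp(best$par[1L]); beta <- exp(best$par[2L])
  structure(list(alpha = alpha, beta = beta,
                 common_precision = alpha / beta, pseudo_obs = 2 * alpha,
                 loglik = -best$value, convergence = best$convergence,
                 n_genes_used = length(ok)),
            class = "shrinkage_prior")
}

# log marginal likelihood of one gene's SSR given df, after integrating the
# gamma-distributed precision out: tau*SSR ~ chisq_df, tau ~ Gamma(a, b).
# Written via log1p/lbeta so it stays accurate as alpha grows large (the
# equal-precision ridge), where the naive lgamma difference cancels
# catastrophically.
marginal_loglik_gene <- function(ssr, df, alpha, beta) {
  d <- df / 2
  (d - 1) * log(ssr) - d * log(2) -
    alpha * log1p(ssr / (2 * beta)) - d * log(beta + ssr / 2) -
    lbeta(alpha, d)
}

#' Shrink per-gene precisions toward the common precision
#'
#' Posterior-mean precision under the fitted gamma prior:
#' \eqn{(\alpha + d_g/2) / (\beta + SSR_g/2)}. This is the convex combination
#' \eqn{w \cdot \alpha/\beta + (1-w) \cdot d_g/SSR_g} with
#' \eqn{w = \beta/(\beta + SSR_g/2)}: the prior contributes \eqn{2\alpha}
#' pseudo-observations at precision \eqn{\beta/\alpha}, so genes expressed in
#' fewer cells are shrunk proportionally harder. Genes with no residual
#' degrees of freedom receive the common precision \eqn{\alpha/\beta} exactly,
#' which keeps genes expressed in very few cells testable.
#'
#' @inheritParams fit_gamma_prior
#' @param alpha,beta gamma prior shape and rate (both positive).
#' @return Per-gene shrunken precisions.
#' @examples
#' shrink_precisions(ssr = 2, df = 2, alpha = 2, beta = 1) # 1.5
#' @export
shrink_precisions <- function(ssr, df, alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  ssr <- as.numeric(ssr); df <- as.numeric(df)
  if (any(ssr < 0, na.rm = TRUE)) stop("negative residual sum of squares")
  out <- (alpha + df / 2) / (beta + ssr / 2)
  none <- !is.finite(ssr) | !is.finite(df) | df < 1
  out[none] <- alpha / beta
  out
}

#' @export
print.shrinkage_prior <- function(x, ...) {
  cat(sprintf("gamma precision prior: alpha %.4g, beta %.4g\n", x$alpha, x$beta))
  cat(sprintf("  common precision %.4g (variance %.4g), %.3g pseudo-observations\n",
              x$common_precision, 1 / x$common_precision, x$pseudo_obs))
  cat(sprintf("  marginal log-likelihood %.4g over %d genes\n",
              x$loglik, x$n_genes_used))
  invisible(x)
}
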