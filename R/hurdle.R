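#' Fit a two-part hurdle model to every gene of a single-cell assay
#'
#' For each gene g, detection is modeled by regularized logistic regression
#' \deqn{logit Pr(Z_{ig} = 1) = X_i \beta^D_g}
#' and, conditionally on detection, expression level by a Gaussian linear
#' model
#' \deqn{Y_{ig} \mid Z_{ig} = 1 \sim N(X_i \beta^C_g, \sigma^2_g),}
#' the two components fitted independently per gene with a shared design.
#' The reserved formula term `cdr` injects the cellular detection rate as a
#' covariate, the recommended adjustment for global cell-size/efficiency
#' effects. Per-gene residual precisions are shrunk toward a common value
#' under an empirical-Bayes gamma prior (see [fit_gamma_prior()]); the
#' continuous-component log-likelihoods, coefficient covariances and all
#' downstream tests use the shrunken variances.
#'
#' @param formula one-sided model formula over `covariates` (plus the
#'   reserved term `cdr`), e.g. `~ treatment + cdr`.
#' @param covariates data.frame of per-cell covariates, rows in assay cell
#'   order. May be NULL when the formula only uses `cdr`.
#' @param assay an [sc_assay].
#' @param prior [prior_control()] for the discrete component.
#' @param shrink logical; apply empirical-Bayes precision shrinkage
#'   (default TRUE).
#' @param variance denominator convention for the raw residual variance:
#'   `"unbiased"` (n - rank) or `"mle"` (n).
#' @param reference_levels optional named list of baseline levels for
#'   categorical covariates.
#' @return Object of class `hurdle_fit`. Per-gene results are stored as
#'   genes x p coefficient matrices `beta_d`, `beta_c`, vectors `loglik_d`,
#'   `loglik_c`, `sigma2` (raw), `sigma2_shrunk`, `ssr`, `df_resid`,
#'   `n_expressed`, flags `converged_d`, `degenerate_d`, `present_c`, plus
#'   p x p x genes covariance arrays `cov_d` and `cov_c` (the latter already
#'   scaled by the shrunken variance), the `design`, the `prior` object of
#'   the precision shrinkage, and the call settings.
#' @examples
#' sim <- simulate_cells(sim_scenario(n_cells = 60, n_genes = 20, seed = 1))
#' fit <- hurdle(~ treatment + cdr, sim$covariates, sim$assay)
#' fit
#' head(coef(fit, "continuous"))
#' @export
hurdle <- function(formula, covariates = NULL, assay,
                   prior = prior_control(), shrink = TRUE,
                   variance = c("unbiased", "mle"), reference_levels = NULL) {
  variance <- match.arg(variance)
  stopifnot(inherits(assay, "sc_assay"))
  if (is.null(covariates))
    covariates <- data.frame(row.names = seq_len(nrow(assay$values)))
  X <- build_design(formula, covariates, assay, reference_levels)
  if (nrow(X) != nrow(assay$values))
    stop("design rows must align with assay cells")
  fit <- hurdle_fit_matrix(assay$detection, assay$values, X,
                           prior = prior, shrink = shrink, variance = variance)
  fit$formula <- formula
  fit$assay <- assay
  fit$covariates <- covariates
  fit$reference_levels <- reference_levels
  fit
}

# Core per-gene loop over a detection matrix Z, value matrix Y and design X.
# Used directly by bootstrap refits and reduced-model refits.
hurdle_fit_matrix <- function(Z, Y, X, prior = prior_control(), shrink = TRUE,
                              variance = "unbiased") {
  G <- ncol(Z); p <- ncol(X)
  stopifnot(ncol(Y) == G, nrow(Z) == nrow(X), nrow(Y) == nrow(X))
  gene_ids <- colnames(Z)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%d", seq_len(G))
  cn <- colnames(X)

  beta_d <- matrix(NA_real_, G, p, dimnames = list(gene_ids, cn))
  beta_c <- beta_d
  cov_d <- array(NA_real_, c(p, p, G), dimnames = list(cn, cn, gene_ids))
  cov_c_un <- cov_d
  loglik_d <- numeric(G)
  ssr <- rep(NA_real_, G); df_resid <- integer(G)
  sigma2 <- rep(NA_real_, G); n_expressed <- integer(G); rank_c <- integer(G)
  converged_d <- logical(G); degenerate_d <- logical(G); present_c <- logical(G)

  for (g in seq_len(G)) {
    fd <- fit_discrete(Z[, g], X, prior = prior)
    beta_d[g, ] <- fd$beta
    cov_d[, , g] <- fd$cov
    loglik_d[g] <- fd$loglik
    converged_d[g] <- fd$converged
    degenerate_d[g] <- fd$degenerate
    fc <- fit_continuous(Y[, g], Z[, g], X, variance = variance)
    beta_c[g, ] <- fc$beta
    cov_c_un[, , g] <- fc$cov
    ssr[g] <- fc$ssr
    df_resid[g] <- fc$df_resid
    sigma2[g] <- fc$sigma2
    n_expressed[g] <- fc$n_expressed
    rank_c[g] <- fc$rank
    present_c[g] <- fc$present
  }

  sp <- NULL
  if (shrink && sum(is.finite(ssr) & df_resid >= 1 & ssr > 0) >= 2L) {
    sp <- fit_gamma_prior(ssr, df_resid)
    tau <- shrink_precisions(ssr, df_resid, sp$alpha, sp$beta)
    sigma2_shrunk <- 1 / tau
  } else {
    # fall back to the per-gene MLE variance when shrinkage is off
    sigma2_shrunk <- ifelse(present_c & n_expressed > 0 & is.finite(ssr) & ssr > 0,
                            ssr / pmax(n_expressed, 1L), sigma2)
  }

  # continuous log-likelihood with the (shrunken) variance plugged in
  loglik_c <- numeric(G)
  usable <- present_c & is.finite(sigma2_shrunk) & sigma2_shrunk > 0 &
    is.finite(ssr)
  loglik_c[usable] <- -n_expressed[usable] / 2 *
    log(2 * pi * sigma2_shrunk[usable]) -
    ssr[usable] / (2 * sigma2_shrunk[usable])

  cov_c <- cov_c_un
  for (g in seq_len(G))
    if (is.finite(sigma2_shrunk[g])) cov_c[, , g] <- cov_c_un[, , g] * sigma2_shrunk[g]

  structure(list(
    beta_d = beta_d, beta_c = beta_c, cov_d = cov_d, cov_c = cov_c,
    loglik_d = loglik_d, loglik_c = loglik_c,
    sigma2 = sigma2, sigma2_shrunk = sigma2_shrunk, ssr = ssr,
    df_resid = df_resid, n_expressed = n_expressed, rank_c = rank_c,
    converged_d = converged_d, degenerate_d = degenerate_d,
    present_c = present_c,
    prior = sp, design = X, gene_ids = gene_ids,
    settings = list(prior = prior, shrink = shrink, variance = variance)),
    class = "hurdle_fit")
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat(sprintf("hurdle_fit: %d genes, %d cells, design [%s]\n",
              length(x$gene_ids), nrow(x$design),
              paste(colnames(x$design), collapse = ", ")))
  cat(sprintf("  expressed cells per gene: median %d (range %d-%d)\n",
              as.integer(stats::median(x$n_expressed)), min(x$n_expressed),
              max(x$n_expressed)))
  if (!is.null(x$prior))
    cat(sprintf("  precision shrinkage: alpha %.3g, beta %.3g (common variance %.3g)\n",
                x$prior$alpha, x$prior$beta, x$prior$beta / x$prior$alpha))
  ndeg <- sum(x$degenerate_d)
  if (ndeg) cat(sprintf("  %d gene(s) detected in all or no cells (degenerate discrete fit)\n", ndeg))
  invisible(x)
}

#' @export
summary.hurdle_fit <- function(object, ...) {
  out <- list(
    n_genes = length(object$gene_ids),
    n_cells = nrow(object$design),
    terms = colnames(object$design),
    n_degenerate = sum(object$degenerate_d),
    n_unconverged = sum(!object$converged_d),
    n_continuous_absent = sum(!object$present_c),
    prior = object$prior,
    sigma2_shrunk = summary(object$sigma2_shrunk))
  class(out) <- "summary.hurdle_fit"
  out
}

#' @export
print.summary.hurdle_fit <- function(x, ...) {
  cat(sprintf("hurdle model over %d genes x %d cells\n", x$n_genes, x$n_cells))
  cat("  design terms:", paste(x$terms, collapse = ", "), "\n")
  cat(sprintf("  degenerate discrete fits: %d; unconverged: %d; no expressed cells: %d\n",
              x$n_degenerate, x$n_unconverged, x$n_continuous_absent))
  if (!is.null(x$prior)) print(x$prior)
  cat("  shrunken residual variance:\n")
  print(x$sigma2_shrunk)
  invisible(x)
}

#' Extract per-gene coefficients
#'
#' @param object a `hurdle_fit`.
#' @param component `"discrete"` (logit scale) or `"continuous"` (log2
#'   expression units).
#' @param ... ignored.
#' @return genes x terms coefficient matrix.
#' @export
coef.hurdle_fit <- function(object, component = c("discrete", "continuous"),
                            ...) {
  component <- match.arg(component)
  if (component == "discrete") object$beta_d else object$beta_c
}

#' @export
logLik.hurdle_fit <- function(object, ...) {
  val <- sum(object$loglik_d) + sum(object$loglik_c)
  attr(val, "df") <- length(object$gene_ids) * (2 * ncol(object$design) + 1)
  class(val) <- "logLik"
  val
}

#' Model predictions for every cell and gene
#'
#' @param object a `hurdle_fit`.
#' @param newdata optional design matrix (cells x p, same columns as the fit's
#'   design); defaults to the training design.
#' @param type `"detection"` for fitted detection probabilities
#'   \eqn{\hat z_{ig}}, `"conditional"` for the conditional positive mean
#'   \eqn{\hat y_{ig}}, `"unconditional"` for
#'   \eqn{\hat z_{ig} \hat y_{ig}}, the model's expected expression.
#' @param ... ignored.
#' @return cells x genes matrix.
#' @export
predict.hurdle_fit <- function(object, newdata = NULL,
                               type = c("unconditional", "detection",
                                        "conditional"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$design else as.matrix(newdata)
  stopifnot(ncol(X) == ncol(object$design))
  bd <- object$beta_d; bd[is.na(bd)] <- 0
  bc <- object$beta_c; bc[is.na(bc)] <- 0
  zhat <- stats::plogis(tcrossprod(X, bd))
  if (type == "detection") return(zhat)
  yhat <- tcrossprod(X, bc)
  if (type == "conditional") return(yhat)
  zhat * yhat
}

#' Simulate replicate data from a fitted hurdle model
#'
#' Draws detection indicators from the fitted detection probabilities and
#' positive values from the fitted conditional Gaussians (shrunken
#' variances), producing parametric-bootstrap replicates of the assay.
#'
#' @param object a `hurdle_fit`.
#' @param nsim number of replicate matrices.
#' @param seed optional integer seed.
#' @param ... ignored.
#' @return List of `nsim` cells x genes matrices.
#' @export
simulate.hurdle_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  zhat <- predict(object, type = "detection")
  yhat <- predict(object, type = "conditional")
  n <- nrow(zhat); G <- ncol(zhat)
  sdm <- matrix(sqrt(ifelse(is.finite(object$sigma2_shrunk),
                            object$sigma2_shrunk, 1)),
                n, G, byrow = TRUE)
  lapply(seq_len(nsim), function(k) {
    z <- matrix(stats::rbinom(n * G, 1L, zhat), n, G)
    y <- matrix(stats::rnorm(n * G, yhat, sdm), n, G)
    out <- ifelse(z == 1L, pmax(y, 1e-3), 0)
    dimnames(out) <- dimnames(zhat)
    out
  })
}
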