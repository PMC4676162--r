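#' Per-component chi-squared tests for a model term
#'
#' Compares a full and a nested reduced hurdle fit, per gene and per
#' component. Because the discrete and continuous components are
#' conditionally independent, each component yields a statistic with an
#' asymptotic chi-squared null; [combine_tests()] then sums them with added
#' degrees of freedom. Continuous likelihood ratios and Wald forms use the
#' shrunken variance estimates. Genes whose discrete fit is degenerate
#' (detected in all or no cells) contribute statistic 0 while their degrees
#' of freedom still count, a conservative convention.
#'
#' @param fit_full,fit_reduced `hurdle_fit` objects; the reduced design must
#'   equal the full design minus the tested term's columns.
#' @param term name of the tested term (a `term_labels` entry of the full
#'   design).
#' @param method `"lrt"` (likelihood ratio, default) or `"wald"`.
#' @param degenerate_df `"count"` (default, conservative) or `"drop"`: whether
#'   degenerate-component genes keep their degrees of freedom.
#' @return data.frame with per-gene `chisq_d`, `df_d`, `chisq_c`, `df_c`.
#' @export
component_tests <- function(fit_full, fit_reduced, term,
                            method = c("lrt", "wald"),
                            degenerate_df = c("count", "drop")) {
  method <- match.arg(method)
  degenerate_df <- match.arg(degenerate_df)
  X <- fit_full$design
  cols <- term_columns(X, term)
  keep <- setdiff(seq_len(ncol(X)), cols)
  if (!identical(colnames(X)[keep], colnames(fit_reduced$design)))
    stop("fit_reduced is not nested in fit_full by removal of term '", term, "'")
  G <- length(fit_full$gene_ids)
  if (G != length(fit_reduced$gene_ids))
    stop("fits cover different gene sets")
  q <- length(cols)

  if (method == "lrt") {
    chisq_d <- pmax(2 * (fit_full$loglik_d - fit_reduced$loglik_d), 0)
    chisq_c <- pmax(2 * (fit_full$loglik_c - fit_reduced$loglik_c), 0)
  } else {
    chisq_d <- chisq_c <- numeric(G)
    for (g in seq_len(G)) {
      chisq_d[g] <- wald_quadform(fit_full$beta_d[g, cols],
                                  fit_full$cov_d[cols, cols, g])
      chisq_c[g] <- wald_quadform(fit_full$beta_c[g, cols],
                                  fit_full$cov_c[cols, cols, g])
    }
  }
  chisq_d[fit_full$degenerate_d] <- 0
  chisq_c[!fit_full$present_c] <- 0
  df_d <- rep(q, G); df_c <- rep(q, G)
  if (degenerate_df == "drop") {
    df_d[fit_full$degenerate_d] <- 0L
    df_c[!fit_full$present_c] <- 0L
  }
  data.frame(gene = fit_full$gene_ids, chisq_d = chisq_d, df_d = df_d,
             chisq_c = chisq_c, df_c = df_c, row.names = NULL)
}

wald_quadform <- function(b, V) {
  b <- as.numeric(b); V <- as.matrix(V)
  if (any(!is.finite(b)) || any(!is.finite(V))) return(0)
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi)) return(0)
  max(drop(t(b) %*% Vi %*% b), 0)
}

#' Sum component chi-squared statistics
#'
#' The discrete and continuous statistics are independent under the model, so
#' their sum is asymptotically chi-squared with the component degrees of
#' freedom added; the p-value is the upper tail at the summed statistic.
#'
#' @param chisq_d,df_d,chisq_c,df_c per-gene component statistics and df
#'   (non-negative; recycled as vectors).
#' @return data.frame with `chisq`, `df`, `p` and a logical `df_zero` flag
#'   (genes with no testable degrees of freedom receive p = 1).
#' @examples
#' combine_tests(3, 1, 5, 1)$p # exp(-4)
#' @export
combine_tests <- function(chisq_d, df_d, chisq_c, df_c) {
  if (any(c(chisq_d, chisq_c) < 0, na.rm = TRUE) ||
      any(c(df_d, df_c) < 0, na.rm = TRUE))
    stop("component statistics and degrees of freedom must be non-negative")
  chisq <- chisq_d + chisq_c
  df <- df_d + df_c
  p <- ifelse(df > 0, stats::pchisq(chisq, df = df, lower.tail = FALSE), 1)
  data.frame(chisq = chisq, df = df, p = p, df_zero = df == 0)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across genes: p-values are
#' multiplied by m/rank and a cumulative minimum is taken from the largest
#' rank down, capped at 1.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and within [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Log2 fold-change from the fitted hurdle model
#'
#' The fold-change of a two-level term is defined on the unconditional mean
#' scale: the difference, between the two levels, of the model-predicted
#' expected expression \eqn{E[Y] = Pr(Z = 1) \cdot E[Y \mid Z = 1]}, holding
#' every other covariate (including the CDR) at its overall mean. The
#' discrete and continuous contributions are reported as exact partial
#' differences: with detection probabilities \eqn{p_0, p_1} and conditional
#' means \eqn{m_0, m_1} at the two levels,
#' `logfc_d = (p1 - p0)(m0 + m1)/2` and `logfc_c = (p0 + p1)(m1 - m0)/2`,
#' which sum to the total \eqn{p_1 m_1 - p_0 m_0}.
#'
#' @param fit a `hurdle_fit`.
#' @param term tested term name; must expand to a single design column
#'   (two-level factor or numeric) unless `contrast` names two factor levels.
#' @param contrast optional character vector of two levels `c(reference,
#'   comparison)` for multi-level factors; dummy-column names are matched as
#'   `paste0(term, level)`.
#' @return data.frame with per-gene `logfc`, `logfc_d`, `logfc_c`.
#' @export
estimate_logfc <- function(fit, term, contrast = NULL) {
  X <- fit$design
  cols <- term_columns(X, term)
  xbar <- colMeans(X)
  x0 <- x1 <- xbar
  if (is.null(contrast)) {
    if (length(cols) != 1L)
      stop("term '", term, "' spans ", length(cols),
           " design columns; supply `contrast` naming two levels")
    x0[cols] <- 0; x1[cols] <- 1
  } else {
    if (length(contrast) != 2L) stop("`contrast` must name exactly two levels")
    x0[cols] <- 0; x1[cols] <- 0
    for (k in 1:2) {
      nm <- paste0(term, contrast[k])
      hit <- match(nm, colnames(X))
      if (!is.na(hit)) {
        if (k == 1L) x0[hit] <- 1 else x1[hit] <- 1
      } else if (!contrast[k] %in% c("", "(reference)") &&
                 !level_is_reference(fit, term, contrast[k])) {
        stop("contrast level '", contrast[k], "' not found for term '", term, "'")
      }
    }
  }
  bd <- fit$beta_d; bd[is.na(bd)] <- 0
  bc <- fit$beta_c; bc[is.na(bc)] <- 0
  p0 <- stats::plogis(drop(bd %*% x0)); p1 <- stats::plogis(drop(bd %*% x1))
  m0 <- drop(bc %*% x0); m1 <- drop(bc %*% x1)
  logfc_d <- (p1 - p0) * (m0 + m1) / 2
  logfc_c <- (p0 + p1) * (m1 - m0) / 2
  data.frame(gene = fit$gene_ids, logfc = p1 * m1 - p0 * m0,
             logfc_d = logfc_d, logfc_c = logfc_c, row.names = NULL)
}

level_is_reference <- function(fit, term, level) {
  cv <- fit$covariates
  if (is.null(cv) || !term %in% names(cv)) return(FALSE)
  v <- cv[[term]]
  if (!is.factor(v)) v <- factor(v)
  identical(as.character(levels(v)[1L]), as.character(level))
}

#' Flag differentially expressed genes
#'
#' A gene is called differentially expressed when its FDR-adjusted p-value
#' falls below `fdr_cut` and the magnitude of its estimated log2 fold-change
#' exceeds `logfc_cut` (defaults: FDR 0.01 and fold-change 1.5).
#'
#' @param result data.frame with columns `p_adj` and `logfc`.
#' @param fdr_cut,logfc_cut thresholds.
#' @return `result` with a logical `is_de` column.
#' @export
call_de <- function(result, fdr_cut = 0.01, logfc_cut = log2(1.5)) {
  stopifnot(all(c("p_adj", "logfc") %in% names(result)))
  result$is_de <- result$p_adj < fdr_cut & abs(result$logfc) > logfc_cut
  result
}

#' Differential expression test for one model term
#'
#' End-to-end per-gene inference: refits the hurdle model without the tested
#' term, forms component likelihood-ratio (or Wald) statistics, sums them into
#' the combined chi-squared test, adjusts across genes by Benjamini-Hochberg,
#' estimates unconditional-mean log2 fold-changes and applies the DE call.
#'
#' @param fit a `hurdle_fit` produced by [hurdle()] (the assay is needed for
#'   the reduced refit).
#' @param term tested term name.
#' @param method `"lrt"` or `"wald"`.
#' @param contrast optional two levels for multi-level factors, see
#'   [estimate_logfc()].
#' @param fdr_cut,logfc_cut DE-call thresholds, see [call_de()].
#' @return data.frame of class `hurdle_de` with columns `gene`, `chisq_d`,
#'   `df_d`, `chisq_c`, `df_c`, `chisq`, `df`, `p`, `p_adj`, `logfc`,
#'   `logfc_d`, `logfc_c`, `is_de`; attributes record term, method and cuts.
#' @examples
#' sim <- simulate_cells(sim_scenario(n_cells = 80, n_genes = 30,
#'                                    effect_frac = 0.3, effect_c = 1, seed = 2))
#' fit <- hurdle(~ treatment + cdr, sim$covariates, sim$assay)
#' de <- de_test(fit, "treatment")
#' head(de)
#' @export
de_test <- function(fit, term, method = c("lrt", "wald"), contrast = NULL,
                    fdr_cut = 0.01, logfc_cut = log2(1.5)) {
  method <- match.arg(method)
  if (is.null(fit$assay))
    stop("`fit` must come from hurdle() so the reduced model can be refit")
  Xr <- drop_term(fit$design, term)
  fit_red <- hurdle_fit_matrix(fit$assay$detection, fit$assay$values, Xr,
                               prior = fit$settings$prior,
                               shrink = fit$settings$shrink,
                               variance = fit$settings$variance)
  comp <- component_tests(fit, fit_red, term, method = method)
  comb <- combine_tests(comp$chisq_d, comp$df_d, comp$chisq_c, comp$df_c)
  lfc <- estimate_logfc(fit, term, contrast = contrast)
  out <- data.frame(comp, chisq = comb$chisq, df = comb$df, p = comb$p,
                    p_adj = bh_adjust(comb$p),
                    logfc = lfc$logfc, logfc_d = lfc$logfc_d,
                    logfc_c = lfc$logfc_c)
  out <- call_de(out, fdr_cut = fdr_cut, logfc_cut = logfc_cut)
  attr(out, "term") <- term
  attr(out, "method") <- method
  attr(out, "fdr_cut") <- fdr_cut
  attr(out, "logfc_cut") <- logfc_cut
  class(out) <- c("hurdle_de", "data.frame")
  out
}

#' @export
print.hurdle_de <- function(x, n = 6L, ...) {
  cat(sprintf("differential expression, term '%s' (%s test): %d genes, %d DE at FDR %g & |log2 FC| > %.3g\n",
              attr(x, "term"), attr(x, "method"), nrow(x), sum(x$is_de),
              attr(x, "fdr_cut"), attr(x, "logfc_cut")))
  ord <- order(x$p)
  print.data.frame(utils::head(x[ord, ], n), digits = 4)
  invisible(x)
}

#' Analysis of deviance: variability attributable to a term
#'
#' Quantifies, per gene, the fraction of model deviance explained by a
#' covariate (typically the CDR) as
#' `(deviance(model without term) - deviance(full)) / deviance(null model)`,
#' computed per component and for the component sum. Discrete deviance is the
#' binomial deviance of the detection fit; continuous deviance is the
#' residual sum of squares over the model's shrunken variance. Fractions are
#' clamped to \[0, 1\]; genes with zero null deviance are flagged with
#' fraction 0.
#'
#' @param fit a `hurdle_fit` from [hurdle()].
#' @param term the term whose contribution is measured.
#' @return data.frame with per-gene `frac_d`, `frac_c`, `frac`,
#'   `null_zero` flag; attribute `"summary"` holds the mean and quantiles of
#'   the combined fraction across genes.
#' @export
deviance_decomposition <- function(fit, term) {
  if (is.null(fit$assay)) stop("`fit` must come from hurdle()")
  Z <- fit$assay$detection; Y <- fit$assay$values
  refit <- function(X) hurdle_fit_matrix(Z, Y, X,
                                         prior = fit$settings$prior,
                                         shrink = fit$settings$shrink,
                                         variance = fit$settings$variance)
  Xr <- drop_term(fit$design, term)
  X0 <- fit$design[, 1L, drop = FALSE]   # intercept only
  attr(X0, "assign") <- 0L
  attr(X0, "term_labels") <- character()
  fit_drop <- refit(Xr)
  fit_null <- refit(X0)

  dev_d <- function(f) -2 * f$loglik_d            # saturated binary ll = 0
  dev_c <- function(f) ifelse(f$present_c & is.finite(f$ssr) &
                                is.finite(f$sigma2_shrunk),
                              f$ssr / f$sigma2_shrunk, 0)
  frac <- function(full, drop, null) {
    num <- pmax(drop - full, 0)
    out <- ifelse(null > 1e-12, pmin(num / null, 1), 0)
    out
  }
  fd <- frac(dev_d(fit), dev_d(fit_drop), dev_d(fit_null))
  fc <- frac(dev_c(fit), dev_c(fit_drop), dev_c(fit_null))
  null_tot <- dev_d(fit_null) + dev_c(fit_null)
  ft <- frac(dev_d(fit) + dev_c(fit), dev_d(fit_drop) + dev_c(fit_drop),
             null_tot)
  out <- data.frame(gene = fit$gene_ids, frac_d = fd, frac_c = fc, frac = ft,
                    null_zero = null_tot <= 1e-12, row.names = NULL)
  attr(out, "summary") <- c(mean = mean(ft),
                            stats::quantile(ft, c(0.5, 0.9, 0.99)))
  attr(out, "term") <- term
  out
}
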