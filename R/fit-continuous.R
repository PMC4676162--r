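#' Fit the continuous (positive expression) component
#'
#' Ordinary least squares for the expression level of a gene over the cells in
#' which it is detected. Only rows with `z == 1` enter the fit; the residual
#' variance uses the unbiased denominator (residual degrees of freedom) by
#' default because downstream shrinkage is expressed in terms of residual df.
#' If the expressed-subset design is rank deficient, collinear columns are
#' dropped (coefficient `NA`) and reported.
#'
#' @param y numeric expression vector over all cells (entries for unexpressed
#'   cells are ignored).
#' @param z 0/1 detection vector.
#' @param X design matrix over all cells.
#' @param variance `"unbiased"` (default, denominator n - rank) or `"mle"`
#'   (denominator n).
#' @return List with `beta` (NA for dropped columns), `cov` (unscaled
#'   \eqn{(X'X)^{-1}} on the kept columns, embedded with NA), `sigma2`
#'   (residual variance, NA when undefined), `ssr` (residual sum of squares),
#'   `df_resid`, `n_expressed`, `rank`, `dropped` (names of dropped columns),
#'   `present` (FALSE when no cell expresses the gene).
#' @examples
#' y <- c(2, 4, 6); fit_continuous(y, rep(1, 3), matrix(1, 3, 1))
#' @export
fit_continuous <- function(y, z, X, variance = c("unbiased", "mle")) {
  variance <- match.arg(variance)
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(z) == nrow(X))
  idx <- which(z == 1)
  p <- ncol(X)
  cn <- colnames(X)
  empty <- list(beta = stats::setNames(rep(NA_real_, p), cn),
                cov = matrix(NA_real_, p, p, dimnames = list(cn, cn)),
                sigma2 = NA_real_, ssr = NA_real_, df_resid = 0L,
                n_expressed = 0L, rank = 0L, dropped = character(),
                present = FALSE)
  if (!length(idx)) return(empty)
  ys <- y[idx]
  if (any(!is.finite(ys))) stop("non-finite expression value among expressed cells")
  Xs <- X[idx, , drop = FALSE]

  qrX <- qr(Xs)
  r <- qrX$rank
  keep <- qrX$pivot[seq_len(r)]
  dropped <- if (r < p) cn[qrX$pivot[(r + 1L):p]] else character()
  Xk <- Xs[, keep, drop = FALSE]
  fit <- stats::lm.fit(Xk, ys)
  ssr <- sum(fit$residuals^2)
  n <- length(idx)
  df_resid <- max(n - r, 0L)
  sigma2 <- if (variance == "unbiased") {
    if (df_resid >= 1L) ssr / df_resid else NA_real_
  } else {
    if (df_resid >= 1L) ssr / n else NA_real_
  }

  beta <- stats::setNames(rep(NA_real_, p), cn)
  beta[keep] <- fit$coefficients
  XtXinv <- chol2inv(chol(crossprod(Xk)))
  cov <- matrix(NA_real_, p, p, dimnames = list(cn, cn))
  cov[keep, keep] <- XtXinv

  list(beta = beta, cov = cov, sigma2 = sigma2, ssr = ssr,
       df_resid = as.integer(df_resid), n_expressed = as.integer(n),
       rank = as.integer(r), dropped = dropped, present = TRUE)
}
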