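#' Standardized deviance residuals of the hurdle model
#'
#' Computes, per cell and gene, the signed square-root binomial deviance
#' residual of the detection indicator against its fitted probability and,
#' for expressed cells only, the Gaussian residual of the positive value
#' scaled by the shrunken variance. Both are standardized by
#' \eqn{\sqrt{1 - h}} using each component's own leverage (switchable). The
#' combined residual is the unweighted mean of the available components: the
#' continuous residual of an unexpressed cell is missing and omitted, so the
#' combined residual then equals the discrete residual alone.
#'
#' Fitted detection probabilities are clamped so that a single cell's
#' deviance contribution cannot exceed 75 (a probability floor of
#' \eqn{e^{-37.5}}); cells hitting the clamp are counted in the `clamped`
#' attribute.
#'
#' @param object a `hurdle_fit` from [hurdle()].
#' @param type which matrix to return from [residuals.hurdle_fit()].
#' @param standardize divide by \eqn{\sqrt{1 - leverage}} (default TRUE).
#' @return `deviance_residuals()` returns an object of class
#'   `hurdle_residuals`: a list of cells x genes matrices `discrete`,
#'   `continuous` (NA where undetected) and `combined`.
#' @export
deviance_residuals <- function(object, standardize = TRUE) {
  if (is.null(object$assay)) stop("`object` must come from hurdle()")
  X <- object$design
  Z <- object$assay$detection
  Y <- object$assay$values
  n <- nrow(X); G <- ncol(Z)

  phat <- predict(object, type = "detection")
  pmin_ <- exp(-37.5)
  clamped <- sum((phat < pmin_ & Z == 1) | (phat > 1 - pmin_ & Z == 0))
  ph <- pmin(pmax(phat, pmin_), 1 - pmin_)
  dev <- -2 * (Z * log(ph) + (1 - Z) * log1p(-ph))
  rd <- sign(Z - ph) * sqrt(pmax(dev, 0))

  rc <- matrix(NA_real_, n, G, dimnames = dimnames(Z))
  yhat <- predict(object, type = "conditional")
  for (g in seq_len(G)) {
    idx <- which(Z[, g] == 1)
    if (!length(idx)) next
    s2 <- object$sigma2_shrunk[g]
    if (!is.finite(s2) || s2 <= 0) next
    r <- (Y[idx, g] - yhat[idx, g]) / sqrt(s2)
    if (standardize) {
      keep <- which(!is.na(object$beta_c[g, ]))
      V <- object$cov_c[keep, keep, g, drop = FALSE][, , 1L] / s2
      Xk <- X[idx, keep, drop = FALSE]
      h <- pmin(pmax(rowSums((Xk %*% V) * Xk), 0), 1 - 1e-8)
      r <- r / sqrt(1 - h)
    }
    rc[idx, g] <- r
  }

  if (standardize) {
    w <- ph * (1 - ph)
    for (g in seq_len(G)) {
      V <- object$cov_d[, , g]
      if (any(!is.finite(V))) next
      h <- pmin(pmax(w[, g] * rowSums((X %*% V) * X), 0), 1 - 1e-8)
      rd[, g] <- rd[, g] / sqrt(1 - h)
    }
  }

  comb <- ifelse(is.na(rc), rd, (rd + rc) / 2)
  structure(list(discrete = rd, continuous = rc, combined = comb),
            class = "hurdle_residuals", clamped = clamped,
            standardized = standardize)
}

#' @rdname deviance_residuals
#' @param ... passed to `deviance_residuals()`.
#' @export
residuals.hurdle_fit <- function(object,
                                 type = c("combined", "discrete",
                                          "continuous"), ...) {
  type <- match.arg(type)
  deviance_residuals(object, ...)[[type]]
}

#' @export
print.hurdle_residuals <- function(x, ...) {
  cat(sprintf("hurdle residuals: %d cells x %d genes (%s)\n",
              nrow(x$combined), ncol(x$combined),
              if (isTRUE(attr(x, "standardized"))) "leverage-standardized"
              else "unstandardized"))
  invisible(x)
}

#' Nuisance-corrected single-cell gene scores
#'
#' The score of gene j in cell i is the observed expression minus the
#' prediction of the model restricted to nuisance terms,
#' \eqn{s_{ij} = y_{ij} - \tilde y_{ij}} with
#' \eqn{\tilde y_{ij} = \hat z_{ij} \hat y_{ij}}, where \eqn{\hat z} and
#' \eqn{\hat y} are the detection probability and conditional mean computed
#' from the intercept plus the nuisance-term columns of the fitted
#' coefficients. Subtracting the nuisance expectation (typically the CDR
#' effect) leaves the treatment signal plus cell-level heterogeneity.
#'
#' @param fit a `hurdle_fit` from [hurdle()].
#' @param nuisance_terms character vector of design terms treated as
#'   nuisance; the complement is the effect of interest. May be empty
#'   (intercept-only prediction) or all terms (full-model residual scores).
#' @return cells x genes matrix of scores.
#' @export
cell_scores <- function(fit, nuisance_terms = character()) {
  if (is.null(fit$assay)) stop("`fit` must come from hurdle()")
  X <- fit$design
  tl <- attr(X, "term_labels")
  bad <- setdiff(nuisance_terms, tl)
  if (length(bad))
    stop("unknown nuisance term(s): ", paste(bad, collapse = ", "))
  asg <- attr(X, "assign")
  keep <- asg == 0L | tl[pmax(asg, 1L)] %in% nuisance_terms & asg > 0L
  Xn <- X[, keep, drop = FALSE]
  bd <- fit$beta_d[, keep, drop = FALSE]; bd[is.na(bd)] <- 0
  bc <- fit$beta_c[, keep, drop = FALSE]; bc[is.na(bc)] <- 0
  zhat <- stats::plogis(tcrossprod(Xn, bd))
  yhat <- tcrossprod(Xn, bc)
  fit$assay$values - zhat * yhat
}

#' Per-cell module scores
#'
#' The module score of cell i is the plain average of that cell's gene scores
#' over the module's member genes (after de-duplication and intersection with
#' the scored universe). Modules with no member in the universe are dropped
#' with a warning.
#'
#' @param gene_scores cells x genes matrix from [cell_scores()].
#' @param collection `gene_sets` object or named list of gene-id vectors.
#' @return cells x modules matrix.
#' @export
module_scores <- function(gene_scores, collection) {
  sets <- if (inherits(collection, "gene_sets")) collection$sets
          else lapply(collection, unique)
  genes <- colnames(gene_scores)
  sets <- lapply(sets, function(s) intersect(unique(s), genes))
  empty <- vapply(sets, length, 1L) == 0L
  if (any(empty)) {
    warning("module(s) with no genes in the scored universe dropped: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  if (!length(sets)) stop("no modules left after intersection")
  out <- vapply(sets, function(s)
    rowMeans(gene_scores[, s, drop = FALSE]), numeric(nrow(gene_scores)))
  out <- matrix(out, nrow = nrow(gene_scores),
                dimnames = list(rownames(gene_scores), names(sets)))
  out
}

#' Gene-gene correlation of model residuals
#'
#' Pearson correlation of combined residuals across cells, per cell group,
#' with two-sided t-approximation p-values and Benjamini-Hochberg adjustment
#' across all tested pairs. Because the model has removed marginal covariate
#' effects (including the CDR when it is in the design), remaining
#' correlation reflects cell-level co-expression rather than global scaling.
#'
#' @param residuals a `hurdle_residuals` (its `combined` matrix is used) or a
#'   cells x genes matrix.
#' @param genes optional gene subset (ids or indices).
#' @param group optional per-cell grouping factor; each group needs >= 3
#'   cells.
#' @return Long-format data.frame `gene1`, `gene2`, `group`, `rho`, `p`,
#'   `p_adj`; the per-group correlation matrices are attached as attribute
#'   `"matrices"`. Pairs involving a zero-variance gene have `rho = NA`.
#' @export
residual_correlation <- function(residuals, genes = NULL, group = NULL) {
  R <- if (inherits(residuals, "hurdle_residuals")) residuals$combined
       else as.matrix(residuals)
  if (!is.null(genes)) R <- R[, genes, drop = FALSE]
  if (ncol(R) < 2L) stop("need at least two genes")
  if (is.null(group)) group <- factor(rep("all", nrow(R)))
  group <- as.factor(group)
  if (any(table(group) < 3L)) stop("each group needs at least 3 cells")

  mats <- list()
  rows <- list()
  gn <- colnames(R)
  if (is.null(gn)) gn <- sprintf("gene%d", seq_len(ncol(R)))
  for (lev in levels(group)) {
    Rg <- R[group == lev, , drop = FALSE]
    ncell <- nrow(Rg)
    sds <- apply(Rg, 2L, stats::sd)
    C <- suppressWarnings(stats::cor(Rg))
    C[sds == 0, ] <- NA; C[, sds == 0] <- NA
    diag(C) <- 1
    mats[[lev]] <- C
    ut <- which(upper.tri(C), arr.ind = TRUE)
    rho <- C[ut]
    tt <- abs(rho) * sqrt((ncell - 2) / pmax(1 - rho^2, 1e-12))
    p <- 2 * stats::pt(tt, df = ncell - 2, lower.tail = FALSE)
    rows[[lev]] <- data.frame(gene1 = gn[ut[, 1L]], gene2 = gn[ut[, 2L]],
                              group = lev, rho = rho, p = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- NA_real_
  okp <- is.finite(out$p)
  out$p_adj[okp] <- bh_adjust(out$p[okp])
  attr(out, "matrices") <- mats
  out
}

#' Principal components of model residuals
#'
#' Centered PCA of the combined residual matrix over a gene subset.
#' Component signs are fixed by making the largest-magnitude entry of each
#' loading vector positive, so repeated runs are identical.
#'
#' @param residuals `hurdle_residuals` or cells x genes matrix.
#' @param genes optional gene subset.
#' @param k number of components; truncated with a warning when it exceeds
#'   the matrix rank.
#' @return List with `scores` (cells x k), `loadings` (genes x k), `sdev`,
#'   `var_explained` (fraction per returned component).
#' @export
residual_pca <- function(residuals, genes = NULL, k = 2L) {
  R <- if (inherits(residuals, "hurdle_residuals")) residuals$combined
       else as.matrix(residuals)
  if (!is.null(genes)) R <- R[, genes, drop = FALSE]
  if (k > min(dim(R))) stop("k exceeds matrix dimensions")
  pc <- stats::prcomp(R, center = TRUE, scale. = FALSE)
  rank_ <- sum(pc$sdev > pc$sdev[1L] * 1e-10)
  if (k > rank_) {
    warning("k = ", k, " exceeds rank ", rank_, "; truncated")
    k <- rank_
  }
  L <- pc$rotation[, seq_len(k), drop = FALSE]
  S <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) { L[, j] <- -L[, j]; S[, j] <- -S[, j] }
  }
  list(scores = S, loadings = L, sdev = pc$sdev[seq_len(k)],
       var_explained = pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2))
}
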