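#' Gene set collection
#'
#' A named list of gene-id vectors (modules), optionally intersected with a
#' fitted gene universe. Members are de-duplicated; after intersection every
#' retained set must reach `min_set_size` and leave a non-empty complement
#' (the competitive null set).
#'
#' @param sets named list of character vectors of gene ids.
#' @param universe optional character vector of gene ids to intersect with.
#' @param min_set_size minimum post-intersection set size (default 5).
#' @return Object of class `gene_sets`.
#' @export
gene_set_collection <- function(sets, universe = NULL, min_set_size = 5L) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a named list of gene-id vectors")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (!is.null(universe)) {
    universe <- as.character(universe)
    sets <- lapply(sets, intersect, y = universe)
    small <- vapply(sets, length, 1L) < min_set_size
    if (any(small)) {
      warning(sum(small), " set(s) below min_set_size after intersection; dropped")
      sets <- sets[!small]
    }
    full <- vapply(sets, length, 1L) >= length(universe)
    if (any(full)) {
      warning(sum(full), " set(s) cover the whole universe (empty null set); dropped")
      sets <- sets[!full]
    }
    if (!length(sets)) stop("no usable gene sets after intersection with universe")
  }
  structure(list(sets = sets, universe = universe,
                 min_set_size = as.integer(min_set_size)),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  sz <- vapply(x$sets, length, 1L)
  cat(sprintf("gene_sets: %d sets (sizes %d-%d)%s\n", length(x$sets),
              min(sz), max(sz),
              if (is.null(x$universe)) "" else
                sprintf(", universe %d genes", length(x$universe))))
  invisible(x)
}

#' Bootstrap the sampling distribution of a term's coefficients
#'
#' Resamples cells with replacement — stratified within the levels of the
#' primary design factor so that group sizes are preserved — refits the full
#' hurdle model on each replicate and records the tested term's discrete and
#' continuous coefficients for every gene. A few tens of replicates suffice
#' to stabilize the variance-covariance estimates used by [run_gsea()].
#' Replicates where a gene's fit is degenerate (detection all 0/1, no
#' expressed cells, or a dropped coefficient) record a missing value.
#'
#' @param fit a `hurdle_fit` from [hurdle()].
#' @param term tested term; must expand to a single design column.
#' @param n_boot number of replicates (>= 2; default 50).
#' @param seed integer seed; the replicate stream is fully determined by it.
#' @param strata optional per-cell stratification factor; defaults to the
#'   tested term's covariate when it is categorical, otherwise a single
#'   stratum.
#' @return Object of class `hurdle_boot`: genes x replicates matrices
#'   `boot_d`, `boot_c`, point-estimate vectors `point_d`, `point_c`,
#'   `gene_ids`, `term`, `n_boot`, `seed`.
#' @export
bootstrap_coefs <- function(fit, term, n_boot = 50L, seed = 1L,
                            strata = NULL) {
  if (n_boot < 2L) stop("n_boot must be at least 2")
  if (is.null(fit$assay)) stop("`fit` must come from hurdle()")
  X <- fit$design
  col <- term_columns(X, term)
  if (length(col) != 1L)
    stop("bootstrap GSEA requires a single-column term (two-level factor or numeric)")
  Z <- fit$assay$detection; Y <- fit$assay$values
  n <- nrow(X); G <- length(fit$gene_ids)

  if (is.null(strata)) {
    cv <- fit$covariates
    strata <- if (!is.null(cv) && term %in% names(cv) &&
                  (is.factor(cv[[term]]) || is.character(cv[[term]])))
      as.factor(cv[[term]]) else factor(rep(1L, n))
  }
  strata <- as.factor(strata)
  if (any(table(strata) == 0L)) stop("empty stratum in bootstrap resampling")
  idx_by <- split(seq_len(n), strata)

  boot_d <- matrix(NA_real_, G, n_boot, dimnames = list(fit$gene_ids, NULL))
  boot_c <- boot_d
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(idx_by, function(ii) ii[sample.int(length(ii),
                                                            replace = TRUE)]),
                  use.names = FALSE)
    Xb <- X[idx, , drop = FALSE]
    attr(Xb, "assign") <- attr(X, "assign")
    attr(Xb, "term_labels") <- attr(X, "term_labels")
    fb <- hurdle_fit_matrix(Z[idx, , drop = FALSE], Y[idx, , drop = FALSE], Xb,
                            prior = fit$settings$prior,
                            shrink = fit$settings$shrink,
                            variance = fit$settings$variance)
    bd <- fb$beta_d[, col]; bd[fb$degenerate_d] <- NA_real_
    bc <- fb$beta_c[, col]; bc[!fb$present_c] <- NA_real_
    boot_d[, b] <- bd
    boot_c[, b] <- bc
  }
  pd <- fit$beta_d[, col]; pd[fit$degenerate_d] <- NA_real_
  pc <- fit$beta_c[, col]; pc[!fit$present_c] <- NA_real_
  structure(list(boot_d = boot_d, boot_c = boot_c,
                 point_d = pd, point_c = pc,
                 gene_ids = fit$gene_ids, term = term,
                 n_expressed = fit$n_expressed,
                 n_boot = as.integer(n_boot), seed = seed),
            class = "hurdle_boot")
}

# Pairwise-complete bootstrap covariance of a component's coefficients,
# projected to the PSD cone (eigenvalues floored at 0) so that every
# set-average variance, a quadratic form with an indicator vector, is
# non-negative. Pairs sharing fewer than `min_shared` non-missing replicates
# get covariance 0 and are flagged.
boot_covariance <- function(B, min_shared = 3L) {
  C <- stats::cov(t(B), use = "pairwise.complete.obs")
  shared <- tcrossprod(!is.na(B))
  sparse <- shared < min_shared
  diag(sparse) <- FALSE
  flagged_pairs <- sum(sparse) / 2
  C[sparse] <- 0
  C[!is.finite(C)] <- 0
  projected <- FALSE
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-10 * max(abs(ev$values), 1)) {
    vals <- pmax(ev$values, 0)
    C <- ev$vectors %*% (vals * t(ev$vectors))
    projected <- TRUE
  }
  dimnames(C) <- list(rownames(B), rownames(B))
  list(C = C, projected = projected, flagged_pairs = flagged_pairs)
}

# Genes usable for a component: finite point estimate and >= 2 replicates.
# The continuous component additionally requires `min_expressed` expressed
# cells: coefficients resting on a handful of cells have bootstrap variances
# too unstable to enter a set-level variance sum.
usable_genes <- function(point, B, n_expressed = NULL, min_expressed = 0L) {
  ok <- is.finite(point) & rowSums(!is.na(B)) >= 2L
  if (!is.null(n_expressed) && min_expressed > 0L)
    ok <- ok & n_expressed >= min_expressed
  ok
}

#' Competitive Z test for one gene set and component
#'
#' Compares the mean point-estimate coefficient over the test set,
#' \eqn{\hat\theta}, with the mean over the complement (null) set,
#' \eqn{\hat\theta_0}. The sampling variance of each mean is
#' \eqn{(1/m^2)[\sum_g Var(\hat\beta_g) + 2 \sum_{g<h} Cov(\hat\beta_g,
#' \hat\beta_h)]} with variances and covariances estimated from the bootstrap
#' replicates (pairwise-complete over non-missing replicates); the covariance
#' terms are what protects the test from inter-gene correlation, which
#' otherwise inflates false significance.
#'
#' @param boot a `hurdle_boot`.
#' @param members gene ids (or indices into the universe) of the test set.
#' @param component `"discrete"` or `"continuous"`.
#' @param use_covariance include the inter-gene covariance terms (default
#'   TRUE); `FALSE` gives the independence-assuming variant.
#' @param min_shared minimum shared non-missing replicates per gene pair.
#' @param min_expressed continuous-component genes need at least this many
#'   expressed cells to enter the universe (default 10); their bootstrap
#'   variances are otherwise too unstable.
#' @return List with `theta_test`, `theta_null`, `var_test`, `var_null`, `z`,
#'   `m_test`, `m_null`, `projected` flag.
#' @export
set_z_test <- function(boot, members, component = c("discrete", "continuous"),
                       use_covariance = TRUE, min_shared = 3L,
                       min_expressed = 10L) {
  component <- match.arg(component)
  B <- if (component == "discrete") boot$boot_d else boot$boot_c
  point <- if (component == "discrete") boot$point_d else boot$point_c
  ok <- usable_genes(point, B,
                     n_expressed = if (component == "continuous")
                       boot$n_expressed else NULL,
                     min_expressed = min_expressed)
  if (sum(rowSums(!is.na(B)) >= 2L) < 1L || ncol(B) < 2L)
    stop("fewer than 2 usable bootstrap replicates")
  if (is.numeric(members)) members <- boot$gene_ids[members]
  in_set <- boot$gene_ids %in% members & ok
  in_null <- !(boot$gene_ids %in% members) & ok
  if (!any(in_set) || !any(in_null))
    stop("test set and null set must both be non-empty after intersection")
  cv <- boot_covariance(B[ok, , drop = FALSE], min_shared = min_shared)
  core_z(point, which(in_set), which(in_null), cv, which(ok),
         use_covariance = use_covariance, n_boot = ncol(B))
}

# shared Z computation given a precomputed covariance over `ok` genes.
# The variance is estimated from n_boot replicates, so the naive ratio is
# t-distributed rather than normal; the denominator carries the
# variance-matching factor (B - 1)/(B - 3) that restores unit variance of Z
# under the null.
core_z <- function(point, set_idx, null_idx, cv, ok_idx, use_covariance,
                   n_boot) {
  pos <- match(set_idx, ok_idx); pos0 <- match(null_idx, ok_idx)
  m <- length(pos); m0 <- length(pos0)
  theta <- mean(point[set_idx]); theta0 <- mean(point[null_idx])
  C <- cv$C
  if (use_covariance) {
    vt <- sum(C[pos, pos]) / m^2
    vn <- sum(C[pos0, pos0]) / m0^2
  } else {
    vt <- sum(diag(C)[pos]) / m^2
    vn <- sum(diag(C)[pos0]) / m0^2
  }
  vt <- max(vt, 0); vn <- max(vn, 0)
  cB <- if (n_boot > 3) (n_boot - 1) / (n_boot - 3) else 1
  list(theta_test = theta, theta_null = theta0,
       var_test = vt, var_null = vn,
       z = (theta - theta0) / sqrt(cB * (vt + vn)),
       m_test = m, m_null = m0, projected = cv$projected)
}

#' Stouffer combination of component Z scores
#'
#' \eqn{Z = (w_d z_d + w_c z_c)/\sqrt{w_d^2 + w_c^2}}; with the default equal
#' weights this is \eqn{(z_d + z_c)/\sqrt 2}, which rewards consensus between
#' the detection and expression-level components and cancels discordant
#' signals.
#'
#' @param z_d,z_c component Z scores (vectors allowed).
#' @param weights length-2 positive weights, default `c(1, 1)`.
#' @return Combined Z.
#' @examples
#' stouffer_combine(1, 1)    # sqrt(2)
#' stouffer_combine(1, -1)   # 0
#' @export
stouffer_combine <- function(z_d, z_c, weights = c(1, 1)) {
  stopifnot(length(weights) == 2L, all(weights > 0))
  (weights[1L] * z_d + weights[2L] * z_c) / sqrt(sum(weights^2))
}

#' Competitive gene-set enrichment over the hurdle coefficients
#'
#' Runs the per-component Z test of [set_z_test()] for every set in a
#' collection, combines the discrete and continuous Z scores by Stouffer's
#' method, derives two-sided normal p-values and adjusts them across sets by
#' Benjamini-Hochberg. Sets are returned sorted by |combined Z|.
#'
#' @param boot a `hurdle_boot` from [bootstrap_coefs()].
#' @param collection a `gene_sets` (or named list of gene-id vectors).
#' @param use_covariance include inter-gene covariance terms (default TRUE).
#' @param min_set_size minimum set size after intersection with the usable
#'   universe.
#' @param min_shared,min_expressed see [set_z_test()].
#' @param one_sided if TRUE, upper-tail p-values instead of two-sided.
#' @return data.frame of class `hurdle_gsea`: `set`, `size`, `theta_d`,
#'   `theta0_d`, `theta_c`, `theta0_c`, `z_d`, `z_c`, `z`, `p`, `p_adj`.
#' @export
run_gsea <- function(boot, collection, use_covariance = TRUE,
                     min_set_size = 5L, min_shared = 3L, min_expressed = 10L,
                     one_sided = FALSE) {
  if (!inherits(collection, "gene_sets"))
    collection <- gene_set_collection(collection)
  ok_d <- usable_genes(boot$point_d, boot$boot_d)
  ok_c <- usable_genes(boot$point_c, boot$boot_c,
                       n_expressed = boot$n_expressed,
                       min_expressed = min_expressed)
  universe <- boot$gene_ids[ok_d | ok_c]
  collection <- gene_set_collection(collection$sets, universe = universe,
                                    min_set_size = min_set_size)
  cv_d <- boot_covariance(boot$boot_d[ok_d, , drop = FALSE], min_shared)
  cv_c <- boot_covariance(boot$boot_c[ok_c, , drop = FALSE], min_shared)
  idx_d <- which(ok_d); idx_c <- which(ok_c)

  one <- function(members) {
    in_set <- boot$gene_ids %in% members
    zd <- core_z(boot$point_d, intersect(which(in_set), idx_d),
                 intersect(which(!in_set), idx_d), cv_d, idx_d, use_covariance,
                 n_boot = boot$n_boot)
    zc <- core_z(boot$point_c, intersect(which(in_set), idx_c),
                 intersect(which(!in_set), idx_c), cv_c, idx_c, use_covariance,
                 n_boot = boot$n_boot)
    c(size = sum(in_set & (ok_d | ok_c)),
      theta_d = zd$theta_test, theta0_d = zd$theta_null,
      theta_c = zc$theta_test, theta0_c = zc$theta_null,
      z_d = zd$z, z_c = zc$z)
  }
  res <- t(vapply(collection$sets, one, numeric(7)))
  out <- data.frame(set = rownames(res), res, row.names = NULL)
  out$z <- stouffer_combine(out$z_d, out$z_c)
  out$p <- if (one_sided) stats::pnorm(out$z, lower.tail = FALSE)
           else 2 * stats::pnorm(-abs(out$z))
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(-abs(out$z)), ]
  rownames(out) <- NULL
  attr(out, "use_covariance") <- use_covariance
  attr(out, "term") <- boot$term
  class(out) <- c("hurdle_gsea", "data.frame")
  out
}

#' @export
print.hurdle_gsea <- function(x, n = 6L, ...) {
  cat(sprintf("competitive GSEA, term '%s'%s: %d sets, %d at FDR 0.05\n",
              attr(x, "term"),
              if (isTRUE(attr(x, "use_covariance"))) "" else " (independence variant)",
              nrow(x), sum(x$p_adj < 0.05)))
  print.data.frame(utils::head(x, n), digits = 4)
  invisible(x)
}
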