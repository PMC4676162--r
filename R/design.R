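#' Build a design matrix for the hurdle model
#'
#' Expands a one-sided formula over a per-cell covariate table into the
#' regression design shared by the discrete and continuous components. The
#' reserved term `cdr` refers to the assay's cellular detection rate and may
#' be used in the formula without appearing in `covariates`. Categorical
#' variables are dummy-coded against a reference level (first level
#' alphabetically unless overridden), so a two-level treatment coefficient is
#' the group difference.
#'
#' @param formula one-sided formula, e.g. `~ treatment + cdr`.
#' @param covariates data.frame with one row per cell, in assay cell order.
#' @param assay optional [sc_assay] supplying the `cdr` term; required when
#'   the formula mentions `cdr` and `covariates` has no such column.
#' @param reference_levels named list/character vector mapping categorical
#'   covariate names to their baseline level.
#' @return Numeric design matrix (cells x p) with an intercept first column,
#'   a `"assign"` attribute mapping columns to terms and a `"term_labels"`
#'   attribute. The matrix is checked to have full column rank.
#' @examples
#' cov <- data.frame(treatment = rep(c("ctrl", "stim"), each = 2))
#' build_design(~ treatment, cov)
#' @export
build_design <- function(formula, covariates, assay = NULL,
                         reference_levels = NULL) {
  stopifnot(inherits(formula, "formula"))
  if (length(formula) == 3L)
    stop("`formula` must be one-sided, e.g. ~ treatment + cdr")
  covariates <- as.data.frame(covariates)
  tl <- attr(stats::terms(formula), "term.labels")
  vars <- all.vars(formula)
  if ("cdr" %in% vars && !("cdr" %in% names(covariates))) {
    if (is.null(assay))
      stop("formula uses the reserved term `cdr` but no assay was supplied")
    if (nrow(covariates) && nrow(covariates) != length(assay$cdr))
      stop("covariate rows must match assay cells")
    if (!nrow(covariates)) covariates <- data.frame(row.names = seq_along(assay$cdr))
    covariates$cdr <- assay$cdr
  }
  unknown <- setdiff(vars, names(covariates))
  if (length(unknown))
    stop("unknown term(s) in formula: ", paste(unknown, collapse = ", "))
  if (!is.null(assay) && nrow(covariates) != nrow(assay$values))
    stop("covariate rows must match assay cells")

  for (v in names(covariates)) {
    if (is.character(covariates[[v]]) || is.logical(covariates[[v]]))
      covariates[[v]] <- factor(covariates[[v]])
    if (is.factor(covariates[[v]])) {
      lev <- sort(levels(droplevels(covariates[[v]])))
      if (!is.null(reference_levels) && v %in% names(reference_levels)) {
        ref <- as.character(reference_levels[[v]])
        if (!ref %in% lev)
          stop(sprintf("reference level '%s' not found in covariate '%s'", ref, v))
        lev <- c(ref, setdiff(lev, ref))
      }
      covariates[[v]] <- factor(covariates[[v]], levels = lev)
    }
  }

  X <- stats::model.matrix(formula, data = covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  attr(X, "term_labels") <- tl
  attr(X, "contrasts") <- NULL
  X
}

# Column indices of `term` within a design built by build_design()
term_columns <- function(X, term) {
  tl <- attr(X, "term_labels")
  asg <- attr(X, "assign")
  if (is.null(tl) || is.null(asg))
    stop("design matrix lacks term annotations; build it with build_design()")
  k <- match(term, tl)
  if (is.na(k)) stop(sprintf("term '%s' not in design (terms: %s)", term,
                             paste(tl, collapse = ", ")))
  which(asg == k)
}

# Design with the columns of `term` removed, annotations preserved.
drop_term <- function(X, term) {
  cols <- term_columns(X, term)
  asg <- attr(X, "assign")
  tl <- attr(X, "term_labels")
  Xr <- X[, -cols, drop = FALSE]
  k <- match(term, tl)
  asg <- asg[-cols]
  asg[asg > k] <- asg[asg > k] - 1L
  attr(Xr, "assign") <- asg
  attr(Xr, "term_labels") <- tl[-k]
  Xr
}
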