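#' Run the full analysis pipeline from a configuration
#'
#' Executes read -> threshold -> fit -> differential expression and,
#' optionally, gene-set enrichment, residuals and module scores, writing all
#' result tables plus a JSON run manifest to an output directory. All
#' randomness flows from the single configured seed, so re-running with an
#' identical configuration reproduces outputs bit for bit.
#'
#' Recognized configuration keys (flat list or YAML file): `matrix`
#' (expression file), `covariates` (covariate file), `transpose`, `threshold`
#' (default 0), `formula` (e.g. `"~ treatment + cdr"`), `term` (tested term),
#' `method` (`"lrt"`/`"wald"`), `fdr_cut`, `logfc_cut`, `gmt` (gene-set file;
#' enables GSEA), `n_boot`, `nuisance_terms` (enables module scores when
#' `gmt` is also given), `residuals` (logical), `seed`, `outdir`.
#'
#' @param config named list or path to a YAML file.
#' @return Invisibly, a list of the produced objects (`assay`, `fit`, `de`,
#'   optionally `gsea`, `residuals`, `scores`) plus `outdir`.
#' @export
pipeline_run <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  need <- function(key) {
    if (is.null(config[[key]])) stop("pipeline config is missing '", key, "'")
    config[[key]]
  }
  get_or <- function(key, default) if (is.null(config[[key]])) default else config[[key]]

  outdir <- get_or("outdir", ".")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(get_or("seed", 1L))

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    message(sprintf("[schurdle] stage %-10s done", name))
    res
  }

  assay <- stage("read", {
    m <- read_matrix(need("matrix"), transpose = isTRUE(config$transpose))
    sc_assay(m, threshold = as.numeric(get_or("threshold", 0)))
  })
  covs <- NULL
  if (!is.null(config$covariates)) {
    covs <- stage("covariates",
                  read_covariates(config$covariates, cell_ids = assay$cell_ids))
  }
  fml <- stats::as.formula(need("formula"))
  fit <- stage("fit", hurdle(fml, covs, assay,
                             shrink = !isTRUE(config$no_shrink)))
  term <- need("term")
  de <- stage("de", de_test(fit, term,
                            method = get_or("method", "lrt"),
                            fdr_cut = as.numeric(get_or("fdr_cut", 0.01)),
                            logfc_cut = as.numeric(get_or("logfc_cut",
                                                          log2(1.5)))))
  utils::write.table(as.data.frame(de), file.path(outdir, "de_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_coef_table(fit, file.path(outdir, "coefficients.tsv"))

  out <- list(assay = assay, fit = fit, de = de, outdir = outdir)

  if (!is.null(config$gmt)) {
    out$gsea <- stage("gsea", {
      coll <- read_gmt(config$gmt)
      bt <- bootstrap_coefs(fit, term,
                            n_boot = as.integer(get_or("n_boot", 50L)),
                            seed = seed)
      gs <- run_gsea(bt, coll)
      utils::write.table(as.data.frame(gs),
                         file.path(outdir, "gsea_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      gs
    })
  }
  if (isTRUE(config$residuals)) {
    out$residuals <- stage("residuals", {
      r <- deviance_residuals(fit)
      write_matrix(r$combined, file.path(outdir, "residuals_combined.tsv"))
      r
    })
  }
  if (!is.null(config$nuisance_terms)) {
    out$scores <- stage("scores", {
      s <- cell_scores(fit, nuisance_terms = config$nuisance_terms)
      write_matrix(s, file.path(outdir, "cell_scores.tsv"))
      if (!is.null(config$gmt)) {
        ms <- module_scores(s, read_gmt(config$gmt))
        write_matrix(ms, file.path(outdir, "module_scores.tsv"))
      }
      s
    })
  }

  inputs <- unlist(config[c("matrix", "covariates", "gmt")], use.names = FALSE)
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    command = "pipeline_run",
    config = config,
    inputs = as.list(stats::setNames(as.character(tools::md5sum(inputs)),
                                     basename(inputs))),
    seed = seed,
    package_version = as.character(utils::packageVersion("schurdle")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

# long-format coefficient table (gene, component, term, estimate, std_error)
write_coef_table <- function(fit, path) {
  p <- ncol(fit$design); G <- length(fit$gene_ids)
  se_d <- t(vapply(seq_len(G), function(g) sqrt(diag(fit$cov_d[, , g])),
                   numeric(p)))
  se_c <- t(vapply(seq_len(G), function(g) sqrt(diag(fit$cov_c[, , g])),
                   numeric(p)))
  long <- function(B, SE, comp) data.frame(
    gene = rep(fit$gene_ids, p),
    component = comp,
    term = rep(colnames(fit$design), each = G),
    estimate = as.vector(B),
    std_error = as.vector(SE))
  tab <- rbind(long(fit$beta_d, se_d, "discrete"),
               long(fit$beta_c, se_c, "continuous"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
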