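#' Define a simulation scenario for hurdle-structured single-cell data
#'
#' Encodes a generative version of the two-part model: per gene g and cell i,
#' detection is drawn as
#' \eqn{z_{ig} \sim Bern(logit^{-1}(a_g + d_g t_i + \lambda_D s_i))} and,
#' given detection, the level as
#' \eqn{y_{ig} \sim N(m_g + c_g t_i + \lambda_C s_i + h_g f_i, 1/\tau_g)}
#' with \eqn{\tau_g \sim Gamma(\alpha, \beta)}; \eqn{y_{ig} = 0} otherwise.
#' The latent per-cell size factor \eqn{s_i} enters both components, so the
#' realized CDR tracks it — the mechanism the CDR covariate is meant to
#' absorb. `confound_rho` correlates \eqn{s_i} with treatment to emulate
#' treatment-CDR confounding, and `corr_loading_sd` switches on a shared
#' latent factor \eqn{f_i} with per-gene loadings \eqn{h_g \sim N(0,
#' corr\_loading\_sd^2)} that induces gene-gene correlation without any
#' set-level treatment signal.
#'
#' Baseline defaults (`a_g ~ N(0, 1.5)` on the logit scale, `m_g ~ N(6, 2)`
#' in log2 units, precisions from Gamma(4, 2)) produce realistic bimodal
#' log2(TPM+1)-like matrices with median detection near one half.
#'
#' @param n_cells,n_genes matrix dimensions (balanced two-arm treatment by
#'   default).
#' @param effect_frac fraction of genes carrying a treatment effect.
#' @param effect_d,effect_c treatment effect sizes on the logit (discrete)
#'   and log2 (continuous) scales for affected genes.
#' @param baseline_logit_mean,baseline_logit_sd distribution of per-gene
#'   baseline detection logits \eqn{a_g}.
#' @param baseline_mu_mean,baseline_mu_sd distribution of per-gene baseline
#'   levels \eqn{m_g}.
#' @param sigma_alpha,sigma_beta gamma shape/rate of the per-gene precisions.
#' @param cell_size_sd standard deviation of the latent cell size factor
#'   \eqn{s_i} (0 disables it).
#' @param size_loading_d,size_loading_c loadings of \eqn{s_i} on the two
#'   components (default 1 each).
#' @param confound_rho correlation in \[-1, 1\] between treatment and the
#'   size factor.
#' @param corr_loading_mean,corr_loading_sd mean and sd of the per-gene
#'   loadings \eqn{h_g} on the latent correlation factor(s); both 0 disables
#'   the mechanism.
#' @param corr_detection_scale multiplier applied to the latent-factor term
#'   on the detection logit scale (0, the default, confines the factor to the
#'   continuous component; 1 loads both components equally).
#' @param corr_block_size 0 (default) for a single factor shared by all
#'   genes; a positive integer partitions genes into consecutive blocks of
#'   this size, each block driven by its own independent factor — the
#'   module-structured correlation regime relevant to competitive
#'   enrichment testing.
#' @param seed integer seed; generation is a pure function of the scenario.
#' @return List of class `sim_scenario`.
#' @export
sim_scenario <- function(n_cells = 200L, n_genes = 300L,
                         effect_frac = 0, effect_d = 0, effect_c = 0,
                         baseline_logit_mean = 0, baseline_logit_sd = 1.5,
                         baseline_mu_mean = 6, baseline_mu_sd = 2,
                         sigma_alpha = 4, sigma_beta = 2,
                         cell_size_sd = 0, size_loading_d = 1,
                         size_loading_c = 1,
                         confound_rho = 0, corr_loading_mean = 0,
                         corr_loading_sd = 0, corr_detection_scale = 0,
                         corr_block_size = 0L,
                         seed = 1L) {
  stopifnot(n_cells >= 1, n_genes >= 1,
            effect_frac >= 0, effect_frac <= 1,
            baseline_logit_sd >= 0, baseline_mu_sd >= 0,
            sigma_alpha > 0, sigma_beta > 0,
            cell_size_sd >= 0, corr_loading_sd >= 0, corr_block_size >= 0,
            confound_rho >= -1, confound_rho <= 1)
  structure(as.list(environment()), class = "sim_scenario")
}

#' Simulate an assay, covariates and truth record from a scenario
#'
#' @param scenario a [sim_scenario()].
#' @return List with `assay` (an [sc_assay], threshold 0), `covariates`
#'   (data.frame with `cell_id` and a two-level `treatment` factor) and
#'   `truth` (per-gene parameters `a`, `d`, `m`, `c`, `tau`, loadings `h`,
#'   the `effect_genes` indices, per-cell `size` and `latent_factor`, and the
#'   scenario itself). Positive draws are floored at 0.001 so values remain
#'   non-negative.
#' @examples
#' sim <- simulate_cells(sim_scenario(n_cells = 50, n_genes = 20, seed = 3))
#' sim$assay
#' @export
simulate_cells <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  n <- sc$n_cells; G <- sc$n_genes

  treat <- rep_len(c(0L, 1L), n)
  ts <- (treat - mean(treat)) / stats::sd(treat)
  eps <- stats::rnorm(n)
  size <- sc$cell_size_sd *
    (sc$confound_rho * ts + sqrt(1 - sc$confound_rho^2) * eps)

  a <- stats::rnorm(G, sc$baseline_logit_mean, sc$baseline_logit_sd)
  m <- stats::rnorm(G, sc$baseline_mu_mean, sc$baseline_mu_sd)
  tau <- stats::rgamma(G, shape = sc$sigma_alpha, rate = sc$sigma_beta)
  n_eff <- round(sc$effect_frac * G)
  effect_genes <- if (n_eff > 0) seq_len(n_eff) else integer()
  d <- numeric(G); d[effect_genes] <- sc$effect_d
  cc <- numeric(G); cc[effect_genes] <- sc$effect_c

  use_corr <- sc$corr_loading_sd > 0 || sc$corr_loading_mean != 0
  block <- if (sc$corr_block_size > 0)
    ((seq_len(G) - 1L) %/% sc$corr_block_size) + 1L else rep(1L, G)
  nb <- max(block)
  f <- matrix(stats::rnorm(n * nb), n, nb)
  h <- if (use_corr) stats::rnorm(G, sc$corr_loading_mean, sc$corr_loading_sd)
       else numeric(G)
  corr_term <- if (use_corr) f[, block, drop = FALSE] *
    matrix(h, n, G, byrow = TRUE) else matrix(0, n, G)

  eta_d <- outer(sc$size_loading_d * size, a, "+") +
    outer(treat, d) + sc$corr_detection_scale * corr_term # n x G
  pz <- stats::plogis(eta_d)
  z <- matrix(stats::rbinom(n * G, 1L, pz), n, G)
  mu <- outer(sc$size_loading_c * size, m, "+") + outer(treat, cc) +
    corr_term
  sdm <- matrix(1 / sqrt(tau), n, G, byrow = TRUE)
  y <- matrix(stats::rnorm(n * G, mu, sdm), n, G)
  vals <- ifelse(z == 1L, pmax(y, 1e-3), 0)
  dimnames(vals) <- list(sprintf("cell%d", seq_len(n)),
                         sprintf("gene%d", seq_len(G)))

  assay <- sc_assay(vals, threshold = 0)
  covariates <- data.frame(
    cell_id = rownames(vals),
    treatment = factor(ifelse(treat == 1L, "stim", "ctrl"),
                       levels = c("ctrl", "stim")))
  truth <- list(a = a, d = d, m = m, c = cc, tau = tau, h = h,
                effect_genes = effect_genes, size = size, latent_factor = f,
                corr_block = block, treat = treat, scenario = sc)
  list(assay = assay, covariates = covariates, truth = truth)
}

#' Random balanced null relabeling of cells
#'
#' Replaces the treatment label by a random two-group split with group sizes
#' differing by at most one. Used by calibration suites: on such splits a
#' well-calibrated test should call no genes differentially expressed.
#'
#' @param covariates per-cell covariate data.frame (or an integer cell
#'   count).
#' @param seed integer seed.
#' @param name name of the new grouping column (default `"split"`).
#' @return The covariate data.frame with the new balanced factor column.
#' @export
null_split <- function(covariates, seed = 1L, name = "split") {
  if (is.numeric(covariates) && length(covariates) == 1L)
    covariates <- data.frame(row.names = seq_len(covariates))
  n <- nrow(covariates)
  if (n < 2L) stop("need at least 2 cells to split")
  set.seed(seed)
  half <- sample.int(n, size = floor(n / 2))
  g <- factor(ifelse(seq_len(n) %in% half, "A", "B"), levels = c("A", "B"))
  covariates[[name]] <- g
  covariates
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("sim_scenario: %d cells x %d genes, seed %d\n",
              x$n_cells, x$n_genes, x$seed))
  cat(sprintf("  effects: frac %.2f, discrete %.2f, continuous %.2f\n",
              x$effect_frac, x$effect_d, x$effect_c))
  cat(sprintf("  size factor sd %.2f (confound rho %.2f), latent-corr loading sd %.2f\n",
              x$cell_size_sd, x$confound_rho, x$corr_loading_sd))
  invisible(x)
}
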