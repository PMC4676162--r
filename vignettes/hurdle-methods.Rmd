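---
title: "Two-part hurdle models for single-cell expression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-part hurdle models for single-cell expression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schurdle)
```

## The model

Single-cell RNA-seq expression on the log2(TPM+1) scale is bimodal: in any
given cell a gene is either undetected (value 0) or expressed at a roughly
Gaussian positive level. schurdle models the two facets per gene g with a
pair of conditionally independent regressions sharing one design matrix X:

$$\mathrm{logit}\,\Pr(Z_{ig} = 1) = X_i \beta^D_g, \qquad
  Y_{ig} \mid Z_{ig} = 1 \sim \mathrm{N}(X_i \beta^C_g,\ \sigma^2_g),$$

where $Z_{ig} = \mathbf{1}[Y_{ig} > \text{threshold}]$ is the detection
indicator. The detection threshold defaults to 0 (any positive value counts
as expressed); `suggest_threshold()` offers a kernel-density trough heuristic
for data with background noise near zero, but results are typically
insensitive to the choice, which is why 0 is the default.

### The cellular detection rate

Cells differ in size, mRNA content and capture efficiency, and these global
factors move the expression of most genes at once. The cellular detection
rate
$$CDR_i = \frac{1}{N}\sum_{g=1}^{N} z_{ig}$$
is a cheap, control-gene-free proxy for them. Including `cdr` as a covariate
in both components (formula term `cdr`, filled from the assay) absorbs this
global variation so that the treatment coefficient reads as the change in
expression at fixed CDR. The simulator demonstrates the two consequences the
package's tests rely on: under treatment–cell-size confounding the CDR
covariate restores type-I error control, and after CDR adjustment the
background gene–gene correlation of residuals drops.

### Regularization of the detection fit

Genes expressed in few cells routinely produce separated logistic
regressions. The discrete component therefore maximizes the Bernoulli
likelihood plus independent Student-t log-priors: df 1 (Cauchy) and scale
2.5 on coefficients of predictors standardized to sd 0.5, df 1 and scale 10
on the intercept. These are the conventional weakly-informative defaults;
they are surfaced in `prior_control()` rather than hard-coded, and
`prior_control(enabled = FALSE)` gives the plain MLE. Optimization is
Newton with step-halving, with the t prior handled through its normal
scale-mixture representation (an EM-style update of an effective ridge
precision each iteration); the fixed point is the exact penalized posterior
mode, which the tests verify against brute-force numerical maximization.
Convergence is declared at a relative penalized-log-likelihood change of
1e-8 within 100 iterations; non-convergence is recorded, never raised.

### Empirical-Bayes variance shrinkage

The amount of information about $\sigma^2_g$ varies with how many cells
express gene g. Precisions $\tau_g = 1/\sigma^2_g$ receive a
$\mathrm{Gamma}(\alpha, \beta)$ prior whose parameters are fitted by
marginal maximum likelihood: given $\tau$, the residual sum of squares
$SSR_g$ with $d_g$ residual degrees of freedom satisfies
$\tau \cdot SSR_g \sim \chi^2_{d_g}$, and conjugacy yields a closed-form
marginal once $\tau$ is integrated out. The log-marginal is evaluated via
`log1p` and `lbeta` because the naive `lgamma` difference cancels
catastrophically along the large-$\alpha$ ridge (the equal-precision limit),
and is maximized by box-constrained quasi-Newton on $(\log\alpha,
\log\beta)$ from a moment-matched start with two shifted restarts.

The per-gene summary is the posterior mean
$$\tilde\tau_g = \frac{\alpha + d_g/2}{\beta + SSR_g/2},$$
the unique point summary consistent with the interpretation of the prior as
$2\alpha$ pseudo-observations of precision $\beta/\alpha$: it is a convex
combination of the gene's MLE $d_g/SSR_g$ and the common precision
$\alpha/\beta$, with genes expressed in fewer cells shrunk proportionally
harder. Genes with no residual degrees of freedom receive the common
precision exactly, so genes expressed in only a handful of cells remain
testable instead of being dropped. Downstream, the continuous-component
log-likelihoods and coefficient covariances are rescaled by the shrunken
variance (the rescaling of `cov_c` is this package's choice; it makes Wald
and likelihood-ratio tests consistent with each other).

## Differential expression testing

Because the two components are conditionally independent, component test
statistics with asymptotic $\chi^2$ nulls add, with their degrees of freedom
added. The default is the likelihood ratio (Wald is available for speed);
the continuous likelihood uses the shrunken variances. Degenerate discrete
fits (genes detected in all or no cells) contribute statistic 0 while their
df still count — a conservative convention, switchable via
`degenerate_df = "drop"`. P-values come from the upper $\chi^2$ tail,
Benjamini–Hochberg adjustment runs across genes only, and a gene is called
differentially expressed when the adjusted p-value is below 0.01 *and* the
log2 fold-change magnitude exceeds $\log_2 1.5$ (both configurable).

The fold-change needs a definition because the model is two-part: schurdle
uses the difference of model-predicted unconditional means
$E[Y] = \Pr(Z=1)\,E[Y \mid Z=1]$ between the two contrast levels, all other
covariates (including CDR) held at their overall means. The reported
discrete/continuous contributions, $(p_1-p_0)(m_0+m_1)/2$ and
$(p_0+p_1)(m_1-m_0)/2$, sum exactly to the total. A conditional-positive-mean
definition was the alternative; the unconditional mean was chosen because it
is the quantity a pseudobulk comparison estimates and it composes both model
components.

`deviance_decomposition()` attributes variability to a covariate as
(deviance without the term − full deviance) / null-model deviance, summed
over components, with binomial deviance for detection and
$SSR/\tilde\sigma^2$ for the continuous part; fractions are clamped to
[0, 1] and genes with zero null deviance are flagged with fraction 0.

## Competitive gene-set enrichment

For a tested single-column term, `set_z_test()` compares the mean
coefficient over a gene set, $\hat\theta$, with the mean over its complement,
$\hat\theta_0$, standardized by
$\sqrt{\widehat{Var}(\hat\theta) + \widehat{Var}(\hat\theta_0)}$ where each
variance is $(1/m^2)[\sum_g Var(\hat\beta_g) + 2\sum_{g<h}
Cov(\hat\beta_g, \hat\beta_h)]$. Variances *and covariances* are estimated
by a cell-level bootstrap, stratified within the levels of the primary
factor so group sizes are preserved (of the plausible resampling schemes,
stratification is the one that respects the design);
a few tens of replicates suffice. The covariance terms are the point:
co-regulated genes have correlated coefficient estimates, and ignoring the
correlation understates the variance of a set average, inflating false
positives. Discrete and continuous Z scores are combined by Stouffer's
equal-weight rule $(z_d + z_c)/\sqrt2$, which favors consensus between the
components; set coefficients are averaged without centering (both choices
were open; equal weights and no centering are the simplest defensible
reading and are documented here rather than asserted as canonical).

Three numerical details matter for calibration and are part of the
estimator's definition:

* With $B$ bootstrap replicates the naive ratio is t-like, not normal; the
  denominator carries the variance-matching factor $(B-1)/(B-3)$ so the
  null Z has unit variance.
* Continuous-component coefficients resting on fewer than `min_expressed`
  (default 10) expressed cells are excluded from the continuous universe:
  the cell-resampling bootstrap underestimates their variance badly (by up
  to ~40% below 10 cells in our measurements), and a single such gene can
  dominate a set-average variance.
* Pairwise-complete covariances (degenerate replicates are recorded as
  missing) can leave the matrix slightly indefinite; it is projected onto
  the PSD cone (eigenvalues floored at 0) and flagged, which guarantees
  non-negative set variances since these are quadratic forms with indicator
  vectors. Pairs sharing fewer than 3 replicates get covariance 0.

One structural point the tests document: a single global latent factor with
equal loadings on all genes cancels exactly in the competitive difference
$\hat\theta - \hat\theta_0$ and inflates nothing; and with mean-zero random
loadings, random sets have zero average pairwise covariance, so again no
inflation appears. The regime where the covariance terms earn their keep is
*module-structured* correlation — tested sets whose members share a factor.
The correlation-control experiments therefore simulate blocks of genes
sharing a latent factor and test the blocks as sets, pooling over replicate
data sets because rejection rates estimated from one data set's overlapping
sets are themselves noisy.

## Residuals and module scores

`deviance_residuals()` returns, per cell and gene, the signed square-root
binomial deviance residual of detection and, on expressed cells only, the
Gaussian residual scaled by the shrunken variance; both standardized by
$\sqrt{1-h}$ with each component's own leverage (the "standardized" in the
method description is not further specified; leverage standardization is
the regression-standard reading, and `standardize = FALSE` gives the plain
version). The combined residual is the unweighted mean of available
components; the continuous residual of an unexpressed cell is missing and
omitted, so the combined residual then equals the discrete one.
Precision-weighted averaging was deliberately rejected to stay with the
plain averaging rule. Note one consequence verified numerically: because
averaging halves only the expressed-branch discrete residual, combined
residuals carry a systematic negative offset (roughly −0.2 to −0.3 at 50%
detection) even under the true model; the per-component residuals center
at 0, and co-expression analyses are unaffected because the offset is a
per-gene constant. Fitted detection probabilities are clamped so a single
deviance contribution cannot exceed 75, and clamped cells are counted.

Per-cell scores subtract the nuisance-restricted model prediction:
$s_{ij} = y_{ij} - \hat z_{ij}\hat y_{ij}$, with $\hat z$ and $\hat y$
computed from the intercept plus nuisance-term columns only (typically
`cdr`). Module scores are plain member means of $s_{ij}$.
`residual_correlation()` reports Pearson correlations per cell group with
t-approximation p-values BH-adjusted across pairs; `residual_pca()` fixes
component signs by making each loading vector's largest entry positive so
repeated runs are identical.

## The simulator

`sim_scenario()`/`simulate_cells()` generate data from the model itself:
per-gene baseline detection logits $a_g \sim \mathrm{N}(0, 1.5)$, baseline
levels $m_g \sim \mathrm{N}(6, 2)$ in log2 units, precisions
$\tau_g \sim \mathrm{Gamma}(4, 2)$ — values chosen once to produce
realistically bimodal log2(TPM+1)-like matrices with median detection near
one half and positive levels around 6 ± 1. A latent per-cell size factor
(sd `cell_size_sd`) loads on both components with loading 1 by default —
the simplest mechanism consistent with the cell-volume interpretation of
the CDR — and can be correlated with treatment (`confound_rho`) to emulate
confounding. An optional latent factor (global or in gene blocks) induces
gene–gene correlation without any set-level treatment signal. Positive
draws are floored at 0.001 to keep values non-negative.

What passing tests on this simulator do **not** show: the generator is the
model, so the tests certify calibration, recovery and the CDR mechanism
under correct specification. Real data add skewed positive distributions,
zero inflation beyond the logistic law, batch structure and count noise at
low expression; the thresholding option and the robustness of rank-based
downstream use mitigate but do not remove this gap.

## Problem sizes and numerical defaults

The shipped test-suite and acceptance experiments use sizes a laptop
handles comfortably while keeping Monte-Carlo error small: 300 genes × 200
cells × 100 splits for null calibration, 200 genes × 500 cells for
recovery, 10⁴ replicate genes for the null distribution of the combined
statistic, 30 bootstrap replicates and 1000 random sets (over 4 replicate
data sets) for enrichment calibration, and 8 replicate data sets of 120
gene modules for correlation control. Other defaults worth knowing:
logistic convergence tolerance 1e-8 (max 100 iterations); gamma-prior
optimization bounds $|\log\alpha|, |\log\beta| \le 30$; minimum set size 5;
minimum shared bootstrap replicates per covariance pair 3; DE thresholds
FDR 0.01 and fold-change 1.5.

## Known limitations

* Random-effects extensions (repeated measures, multiple donors) are out of
  scope; the design matrix is fixed-effects only.
* The discrete component's dispersion is not moderated across genes; only
  the continuous variance is shrunk.
* The bootstrap GSEA requires a single-column tested term; multi-level
  contrasts must be recoded.
* The adaptive background-threshold rule is a density-trough heuristic, not
  a calibrated estimator; it is labeled as such and defaults are threshold
  0.
* Combined residuals carry the averaging offset described above; analyses
  that need zero-mean residuals should use the component residuals.
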