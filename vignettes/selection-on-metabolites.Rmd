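---
title: "Inferring stabilizing selection on metabolite levels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring stabilizing selection on metabolite levels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metselect)
```

# The scientific problem

Metabolite concentrations are classic quantitative traits: heritable,
polygenic, and plausibly held near an optimum by stabilizing selection.
Under stabilizing selection, alleles with large effects on a trait are
selected against and kept at low frequency, which couples a variant's
effect size to its minor allele frequency (MAF). `metselect` implements a
pipeline that quantifies this coupling from GWAS summary statistics,
relates it to causal importance (Mendelian randomization) and to
cross-species evolutionary conservation (Brownian-motion rates on a
phylogeny), and tests hypotheses about it while accounting for the genetic
correlation between metabolites. Everything runs on synthetic data with
known ground truth, so each estimator's statistical behaviour is
verifiable end to end.

# The selection-strength model

The expected squared per-allele effect of variant $j$ follows

$$E[b_j^2 \mid f_j, \omega_j] = \frac{h^2}{M}\,\omega_j\,
  [2f_j(1-f_j)]^{\alpha},$$

where $f_j$ is the MAF, $\omega_j$ a SNP weight (by default inversely
proportional to the LD score $\ell_j = \sum_l r^2_{jl}$), $h^2$ the trait
heritability, $M$ the number of causal variants, and $\alpha$ the
selection-strength exponent. $\alpha = 0$ corresponds to the neutral
architecture; $\alpha = -1$ means every variant contributes the same
expected heritability regardless of frequency, the signature of strong
stabilizing selection; $\alpha < -1$ would make rare variants carry more
heritability than common ones.

Marginal association statistics inherit LD inflation: the expected
chi-square of variant $j$ is

$$e_j = 1 + n \sum_{l \in \mathrm{block}(j)} r^2_{jl}\, E[h^2_l],$$

with $E[h^2_j] = h^2\,\omega_j H_j^{\alpha+1} / \sum_l \omega_l
H_l^{\alpha+1}$ and $H_j = 2f_j(1-f_j)$ (`expected_per_snp_h2()`,
`expected_chisq()`).

## Likelihood and profiling

Marginally over Gaussian effect draws, the z statistic of variant $j$ is
normal with variance $e_j$, so $S_j = z_j^2$ is a scaled chi-square with
one degree of freedom. `model_loglik()` uses the corresponding
quasi-log-likelihood with per-variant regression weights
$\kappa_j = \omega_j$, which down-weight variants in strong LD (their
statistics are largely redundant). Statistics below $10^{-8}$ are floored
there before the $\log S_j$ term — a measure-zero event in continuous
data, guarded against anyway.

`profile_alpha()` follows the profile-likelihood recipe: fix $\alpha$,
maximize over $h^2 \in [0,1]$ by bounded golden-section search (tolerance
$10^{-6}$, boundary values checked explicitly), repeat over a grid of 31
values from $-1$ to $0.5$ in steps of $0.05$, fit a quadratic to the
profiled points, and read off the estimate (vertex) and variance (inverse
negative Hessian, $1/(-2a)$). If the vertex lands within one grid step of
a boundary, the range is extended once per side, to $[-2, 1]$ on the left
or $[-1, 4]$ on the right, and the fit repeated.

Two numerical choices matter here:

* **Local quadratic window.** The quadratic approximation to a likelihood
  surface is local. On information-rich data the profile is sharply
  peaked and asymmetric across the full grid, and a least-squares
  quadratic through *all* points drags the vertex toward the shallow
  tail (a bias of about $+0.08$ at a true $\alpha$ of $-0.5$ with 20{,}000
  independent SNPs and $n = 50{,}000$). The fit therefore uses the
  contiguous run of grid points within a log-likelihood drop of 3 of the
  peak (at least 5 points). On flat, noisy profiles the window covers the
  whole grid, recovering the all-points fit.
* **Stability flag.** Instead of visual inspection, a fit is declared
  stable when the quadratic is concave ($a < -10^{-6}$), describes the
  windowed profile well ($R^2 \ge 0.95$), and the vertex lies inside the
  final range. Thresholds are arguments.

`wald_selection_test()` converts a stable fit into a two-sided normal
test of $\alpha = 0$ with nominal (0.05) and Bonferroni ($0.05/n$) flags.

# The synthetic-data generator

`simulate_panel()` draws MAFs uniformly on a range (default
$[0.01, 0.5]$) and builds LD blocks of near-equal size with exchangeable
within-block correlation; a length-2 range draws each block's correlation
uniformly, making LD scores vary across blocks as LD-score regression
requires. SNP weights are $1/\ell_j$ or unit (`weights = "unit"`).
`simulate_effects_alpha()` draws causal effects with variance
$c\,\omega_j H_j^\alpha$, with $c$ chosen so the expected total
heritability equals the requested $h^2$ exactly.
`simulate_sumstats()` draws per-block z vectors from
$N(\sqrt{n}\,R\beta^*, R)$ on the standardized scale
($\beta^*_j = b_j\sqrt{H_j}$), so LD both spreads signal and correlates
noise; this is the exact generative twin of the fitted expectation, which
is what makes unbiasedness and coverage testable.

## The selection-coupled (Eyre-Walker-style) architecture

To test the model against data *not* generated under it, the package
couples effects and frequencies through a latent selection coefficient
$S_j \sim \Gamma(\text{shape}, \text{scale})$:
$|b_j| = \delta S_j^{\tau}(1+\epsilon_j)$ and heterozygosity
$H_j = 0.5\,(1 + S_j/s_0)^{-\kappa}$ with coupling strength $\kappa$.
Deep in the power-law regime ($S_j \gg s_0$), $b_j^2 \propto
H_j^{-2\tau/\kappa}$. The shipped preset `ew_strong_selection_spec()`
sets $2\tau = \kappa$ with $s_0 = 0.01$, so squared effects scale exactly
as $H^{-1}$: the strong-selection limit in which every variant carries
equal expected heritability and the fitted $\alpha$ approaches $-1$.
Decoupled settings ($\tau = 0$ or $\kappa = 0$) leave effects independent
of frequency, and the fitted $\alpha$ sits near 0. The literature invokes
this model without fixing a parametrization; the one above was chosen
because its strong limit is the only quantitatively testable statement,
and it is documented as such.

# Mendelian randomization

`harmonize()` joins exposure and outcome records by variant, flips
outcome effects coded on the other allele, drops strand-ambiguous
palindromic variants (A/T, C/G) and irreconcilable allele pairs, and is
involutive. `ivw_estimate()` is the fixed-effect inverse-variance-weighted
estimator with first-order weights,

$$\hat\theta = \frac{\sum_i \beta_{Xi}\beta_{Yi}/se^2_{Yi}}
                  {\sum_i \beta_{Xi}^2/se^2_{Yi}},\qquad
  SE = \Big(\sum_i \beta_{Xi}^2/se^2_{Yi}\Big)^{-1/2},$$

which with one instrument is the Wald ratio. First-order weights ignore
exposure-side noise, so a regression-dilution bias of order
$se_X^2/\mathrm{Var}(\beta_X)$ is inherent; calibration studies in the
test suite therefore use strong instruments
(`exposure_h2_per_instr = 5e-3` at $n = 10^5$, instrument F
around 500), while the generator default remains weaker.
`filter_large_effects()` flags estimates above 0.5 in absolute value
(strict inequality) — the sample-overlap guard for exposure and outcome
measuring nearly the same quantity — and `importance_scores()` sums the
surviving absolute effects per metabolite.

# Conservation scores

For each metabolite and organ, `conservation_scores()` prunes the species
tree to the measured species (at least 3), log-transforms the relative
concentrations (they live on a ratio scale; `log_transform = FALSE`
switches this off), and fits the Brownian-motion rate by generalized
least squares on the tip covariance $C$ (shared root-to-tip branch
length, `phylo_covariance()`):

$$\hat\mu = \frac{1'C^{-1}x}{1'C^{-1}1},\qquad
  \hat\sigma^2 = \frac{(x-\hat\mu 1)'C^{-1}(x-\hat\mu 1)}{n-1}.$$

The $n-1$ denominator (restricted-likelihood style) is unbiased under the
model; with maximum likelihood's $n$ the recovery oracle would show a
systematic $-1/n$ bias. The conservation score is $1/\hat\sigma^2$.
`aggregate_conservation()` imputes a metabolite's missing organ scores by
its median across measured organs, ranks scores within each organ
(average ranks on ties), and takes the median rank across organs;
metabolites measured in at most one organ are excluded (`min_organs`
exposes the threshold, and `organs_subset` supports leave-one-organ-out
robustness checks). Because the aggregate is rank-based, it is invariant
to any strictly monotone transform of the per-organ scores.

# Genetic correlations between metabolites

`cross_trait_ldsc()` regresses $z_{1j} z_{2j}$ on the LD score; the slope
times $M/\sqrt{n_1 n_2}$ estimates the genetic covariance, with the
intercept absorbing confounding and sample overlap, and a delete-one-block
jackknife over LD blocks for the standard error. Note the model
assumption: LD-score regression posits (near-)constant per-SNP
heritability. Under the inverse-LD-weights architecture per-SNP
heritability is proportional to $1/\ell_j$ and the slope signal vanishes
— recovery studies (and the pipeline's generative design) therefore use
the equal-weights architecture, under which the regression is well-posed
for any $\alpha$.

The matrix pipeline follows the estimation order: estimate all pairs
(`gencov_matrix()`), zero off-diagonal entries that are not nominally
significant ($P > 0.05$, strict; `sparsify()`), restore positive
semidefiniteness by precision-weighted bending (`weighted_bending()`),
and normalize to a correlation matrix (`cov_to_corr()`). Bending floors
negative eigenvalues, reconstructs, and blends the adjustment back
elementwise with weights proportional to the estimate variances (step 0.5
per iteration): precisely estimated entries move least and the diagonal —
treated as precisely known — is held fixed. Positive semidefinite input
passes through untouched, making the operation idempotent; the
mean-absolute-change diagnostic is reported. Rescaling by a small
diagonal can magnify a just-tolerated negative eigenvalue, so the
normalization projects any residual negative eigenvalue to zero and
restores the unit diagonal.

# Correlation-adjusted inference

With $\Sigma$ the metabolite correlation matrix, three tests account for
correlated estimates:

* `adjusted_slope()` fits $y = r x + \epsilon$, $\epsilon \sim N(0,
  \sigma^2\Sigma)$ on standardized quantities. The ordinary
  through-origin estimator $\hat r = y'x/x'x$ stays unbiased; only its
  variance changes, to $\sigma^2\, x'\Sigma x/(x'x)^2$ with $\hat\sigma^2
  = RSS/(n-1)$. This deliberately avoids likelihood maximization, which
  the near-zero eigenvalues of sparsified-and-bent $\Sigma$ matrices make
  numerically fragile. Coverage simulations call it with `scale = FALSE`
  on data generated directly from the standardized model, isolating the
  variance formula under test; the default standardizing path is checked
  against ordinary least squares at $\Sigma = I$.
* `modified_cochran_q()` tests heterogeneity of class means. Under the
  null $\hat\alpha \sim N(\cdot, \Omega)$ with $\Omega =
  \mathrm{diag}(SE)\,\Sigma\,\mathrm{diag}(SE)$; class means
  $\hat\alpha_i = v(i)'\hat\alpha$ have covariance $W_{ij} =
  v(i)'\Omega v(j)$. The statistic is the quadratic form of the centered
  class means in the *pseudoinverse* of their covariance
  ($Q = d'[DWD']^{+}d$, $D$ the centering matrix): a quadratic form in
  $W$ itself cannot be chi-square distributed with $K-1$ degrees of
  freedom, so the inverse is taken to be implied, and the choice is
  validated by simulation (null size 0.04–0.06 at $K = 8$ under
  correlated $\Sigma$; QQ agreement with $\chi^2_{K-1}$ at $\Sigma = I$).
  The overall mean defaults to the unweighted mean of class means, with
  the all-metabolite mean as an option.
* `class_vs_rest()` contrasts one class against its complement with
  weights $1/n_i$ and $-1/n_{-i}$ and null variance $w'\Omega w$; the
  statistics for a class and its complement are equal and opposite.

# The pipeline and its synthetic study design

`validate_config()` reads a flat `key = value` file (defaults: grid
$-1$ to $0.5$ by $0.05$; overlap filter 0.5; zeroing threshold 0.05;
FDR 5%); unknown keys warn, missing or malformed required values error.
`run_pipeline()` executes `simulate → alpha → gencorr → mr → conserve →
stats` with per-stage seeds derived from one global seed, writes
tab-separated outputs readable by the package's own readers, and a JSON
report. Stages demand their upstream artifacts by name.

The simulated study links the generative quantities the way the
scientific hypotheses expect: each metabolite's Brownian rate is
$\exp(c_0 + c_1 \alpha_m)$ with $c_1 > 0$, so metabolites under stronger
stabilizing selection (more negative $\alpha$) evolve more slowly and
score as more conserved — the fitted $\alpha$-versus-conservation slope
is negative when the estimators work; likewise causal effects on traits
grow as $\alpha$ decreases, so importance scores correlate negatively
with $\alpha$. Default problem sizes (6{,}000 SNPs in 750 blocks, 12
metabolites at $n = 50{,}000$, 26 species, 4 organs) are chosen so a full
run takes seconds while every stage still has enough information to
behave like its asymptotic self; the test suite uses 20{,}000 SNPs where
estimator calibration is the question.

```{r example, eval = FALSE}
panel <- simulate_panel(5000, 5000, seed = 1, weights = "unit")
b <- simulate_effects_alpha(panel, architecture_spec(
  h2 = 0.5, alpha = -0.5, n_samples = 5e4, seed = 2))
stats <- simulate_sumstats(panel, b, n = 5e4, seed = 3)
fit <- profile_alpha(stats, panel)
glance(fit)
autoplot(fit)
```

# What passing tests do and do not show

The generator emulates block-wise LD with exchangeable correlation,
Gaussian effect sizes, complete variant overlap between traits, and no
confounding inflation (the model assumes intercept-free expectation
$e_j \ge 1$). Real GWAS data have banded LD, non-Gaussian effect tails,
partial variant overlap, population stratification, and assay artifacts;
passing calibration here shows the estimators are correct *under the
model*, not that the model captures every feature of real data. In
particular the likelihood weights $\kappa_j = \omega_j$ are one
defensible choice among several, the exact SNP-weight optimization of
LDAK is intentionally out of scope (inverse LD score matches the stated
proportionality), and confounding-inflation modeling is assumed handled
upstream.

# Known limitations

* $\hat\alpha$ below $-1$ is representable (the extended range reaches
  $-2$) but, as the strong-selection analysis shows, cannot be produced
  by the selection-coupled generator; such estimates flag model
  misspecification rather than stronger selection.
* The bending iteration can fail on matrices whose fixed diagonal is
  inconsistent with any PSD completion (it errors with diagnostics after
  1{,}000 iterations); nonpositive diagonal estimates must be removed
  first, as the pipeline's gencorr stage does.
* Jackknife standard errors require at least two LD blocks; with one
  block the variance is reported as `NA`.
* The IVW estimator implements no pleiotropy-robust variants
  (MR-Egger, weighted median are out of scope).
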