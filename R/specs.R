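#' Genetic architecture under the alpha model
#'
#' Describes a trait whose causal effect-size variance follows
#' \eqn{E[b_j^2] = c \,\omega_j [2 f_j (1-f_j)]^\alpha}: `alpha` is the
#' selection-strength exponent (negative under stabilizing selection, 0 for
#' the neutral GCTA-style architecture), `h2` the total SNP heritability,
#' `prop_causal` the fraction of variants carrying a nonzero effect and
#' `n_samples` the GWAS sample size used when summary statistics are drawn.
#'
#' @param h2 Heritability in `[0, 1]`.
#' @param alpha Selection-strength exponent.
#' @param prop_causal Fraction of causal variants in `(0, 1]`.
#' @param n_samples GWAS sample size.
#' @param seed Optional integer seed used when effects are drawn.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(h2 = 0.5, alpha = 0, prop_causal = 1,
                              n_samples = 50000, seed = NULL) {
  assert_that(h2 >= 0 && h2 <= 1, "h2 must lie in [0, 1]")
  assert_that(prop_causal > 0 && prop_causal <= 1,
              "prop_causal must lie in (0, 1]")
  assert_that(n_samples >= 1, "n_samples must be positive")
  structure(list(h2 = h2, alpha = alpha, prop_causal = prop_causal,
                 n_samples = as.integer(n_samples), seed = seed),
            class = "architecture_spec")
}

#' Selection-coupled architecture (Eyre-Walker style)
#'
#' Couples effect sizes and allele frequencies through a latent selection
#' coefficient \eqn{S_j \sim \mathrm{Gamma}(shape, scale)}:
#' \eqn{|b_j| = \delta S_j^\tau (1 + \epsilon_j)} with
#' \eqn{\epsilon_j \sim N(0, noise\_sd^2)}, and heterozygosity decreasing with
#' selection as \eqn{2f_j(1-f_j) = 0.5\,(1 + S_j/s_0)^{-maf\_coupling}}.
#' Deep in the power-law regime (\eqn{S_j \gg s_0}) the squared effect scales
#' as heterozygosity to the power \eqn{-2\tau/maf\_coupling}; with
#' \eqn{2\tau = maf\_coupling} every variant contributes the same expected
#' heritability, the strong-selection limit in which the fitted alpha
#' approaches -1. See [ew_strong_selection_spec()] for that preset.
#'
#' @param tau Nonnegative coupling exponent of effect size on `S`.
#' @param s_shape,s_scale Gamma parameters of the selection coefficient.
#' @param effect_scale Effect-size scale `delta` (> 0).
#' @param noise_sd SD of the multiplicative effect-size noise (>= 0).
#' @param maf_coupling Nonnegative exponent governing how fast heterozygosity
#'   decreases with `S`; 0 leaves MAF untouched.
#' @param s_ref Reference selection coefficient `s0` (> 0) setting where the
#'   frequency coupling enters its power-law regime.
#' @param seed Optional integer seed.
#' @return An object of class `eyre_walker_spec`.
#' @export
eyre_walker_spec <- function(tau = 0.5, s_shape = 4, s_scale = 25,
                             effect_scale = 1, noise_sd = 0,
                             maf_coupling = 1, s_ref = 1, seed = NULL) {
  assert_that(tau >= 0, "tau must be nonnegative")
  assert_that(s_shape > 0 && s_scale > 0, "gamma parameters must be positive")
  assert_that(effect_scale > 0, "effect_scale must be positive")
  assert_that(noise_sd >= 0, "noise_sd must be nonnegative")
  assert_that(maf_coupling >= 0, "maf_coupling must be nonnegative")
  assert_that(s_ref > 0, "s_ref must be positive")
  structure(list(tau = tau, s_shape = s_shape, s_scale = s_scale,
                 effect_scale = effect_scale, noise_sd = noise_sd,
                 maf_coupling = maf_coupling, s_ref = s_ref, seed = seed),
            class = "eyre_walker_spec")
}

#' Strong-selection preset of the coupled architecture
#'
#' `2 tau = maf_coupling` with a small reference coefficient, so generated
#' squared effects scale as the inverse of heterozygosity and every variant
#' contributes equal expected heritability: fitted alpha approaches -1.
#'
#' @inheritParams eyre_walker_spec
#' @export
ew_strong_selection_spec <- function(seed = NULL) {
  eyre_walker_spec(tau = 0.5, s_shape = 4, s_scale = 25, effect_scale = 1,
                   noise_sd = 0, maf_coupling = 1, s_ref = 0.01, seed = seed)
}

#' Specification of a correlated metabolite trait set
#'
#' @param genetic_corr Metabolite-by-metabolite genetic correlation matrix
#'   (symmetric, unit diagonal, positive semidefinite).
#' @param per_metabolite_arch List of [architecture_spec()], one per
#'   metabolite.
#' @param names Optional metabolite names (default `met01`, ...).
#' @return An object of class `metabolite_panel_spec`.
#' @export
metabolite_panel_spec <- function(genetic_corr, per_metabolite_arch,
                                  names = NULL) {
  genetic_corr <- as.matrix(genetic_corr)
  k <- nrow(genetic_corr)
  assert_that(length(per_metabolite_arch) == k,
              "one architecture_spec needed per metabolite")
  assert_that(max(abs(genetic_corr - t(genetic_corr))) < 1e-10,
              "genetic_corr must be symmetric")
  assert_that(max(abs(diag(genetic_corr) - 1)) < 1e-10,
              "genetic_corr must have unit diagonal")
  assert_that(is_psd(genetic_corr),
              "genetic_corr must be positive semidefinite")
  names <- names %||% sprintf("met%02d", seq_len(k))
  assert_that(length(names) == k && !anyDuplicated(names),
              "metabolite names must be unique, one per metabolite")
  structure(list(n_metabolites = k, genetic_corr = genetic_corr,
                 per_metabolite_arch = per_metabolite_arch,
                 names = names),
            class = "metabolite_panel_spec")
}
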