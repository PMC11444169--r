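#' Draw per-allele causal effects under the alpha model
#'
#' A causal subset of `round(prop_causal * n_snps)` variants is chosen
#' uniformly; each causal variant j receives
#' \eqn{b_j \sim N(0,\; c\,\omega_j [2 f_j (1-f_j)]^\alpha)}, with the
#' constant c set so the expected total heritability
#' \eqn{\sum_j E[b_j^2]\, 2 f_j (1-f_j)} equals `spec$h2` exactly.
#' Non-causal effects are exactly zero; `h2 = 0` yields an all-zero vector.
#'
#' @param panel A [snp_panel()].
#' @param spec An [architecture_spec()].
#' @return Numeric vector of per-allele effects, one per panel variant,
#'   named by variant id.
#' @export
simulate_effects_alpha <- function(panel, spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  local_seed(spec$seed)
  n <- nrow(panel)
  b <- setNames(numeric(n), panel$variant_id)
  if (spec$h2 == 0) return(b)

  m <- max(1L, round(spec$prop_causal * n))
  causal <- sample.int(n, m)
  het <- heterozygosity(panel$maf[causal])
  w <- panel$snp_weight[causal]
  per_snp_h2 <- w * het^(spec$alpha + 1)
  c0 <- spec$h2 / sum(per_snp_h2)
  b[causal] <- rnorm(m, 0, sqrt(c0 * w * het^spec$alpha))
  b
}

#' Draw per-allele effects under the selection-coupled architecture
#'
#' Implements the generative process of [eyre_walker_spec()]: latent
#' selection coefficients \eqn{S_j}, effect magnitudes
#' \eqn{\delta S_j^\tau (1+\epsilon_j)} with random sign, and re-drawn MAFs
#' whose heterozygosity decreases with \eqn{S_j}. Returns the modified panel
#' together with the effects, because the frequency coupling replaces the
#' panel MAFs.
#'
#' @param panel A [snp_panel()].
#' @param spec An [eyre_walker_spec()].
#' @return List with elements `panel` (MAFs re-drawn when
#'   `maf_coupling > 0`), `effects` (named per-allele effect vector) and
#'   `s` (latent selection coefficients).
#' @export
simulate_effects_eyre_walker <- function(panel, spec) {
  stopifnot(inherits(spec, "eyre_walker_spec"))
  local_seed(spec$seed)
  n <- nrow(panel)
  s <- rgamma(n, shape = spec$s_shape, scale = spec$s_scale)
  eps <- if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else numeric(n)
  magnitude <- spec$effect_scale * s^spec$tau * (1 + eps)
  b <- sample(c(-1, 1), n, replace = TRUE) * magnitude

  if (spec$maf_coupling > 0) {
    het <- 0.5 * (1 + s / spec$s_ref)^(-spec$maf_coupling)
    panel$maf <- maf_from_het(het)
  }
  list(panel = panel,
       effects = setNames(b, panel$variant_id),
       s = s)
}

#' Rescale an effect vector to a target heritability
#'
#' Multiplies effects by a constant so the realized heritability
#' \eqn{\sum_j b_j^2\, 2 f_j(1-f_j)} equals `h2`.
#'
#' @param panel A [snp_panel()].
#' @param effects Per-allele effect vector aligned with the panel.
#' @param h2 Target heritability.
#' @return Rescaled effect vector.
#' @export
scale_effects_to_h2 <- function(panel, effects, h2) {
  realized <- sum(effects^2 * heterozygosity(panel$maf))
  assert_that(realized > 0, "cannot rescale an all-zero effect vector")
  effects * sqrt(h2 / realized)
}

#' Realized heritability of an effect vector
#'
#' @inheritParams scale_effects_to_h2
#' @return `sum(b^2 * 2f(1-f))` on the per-allele scale.
#' @export
realized_h2 <- function(panel, effects) {
  sum(effects^2 * heterozygosity(panel$maf))
}
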