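#' Harmonize exposure and outcome association records
#'
#' Joins the two sources on `variant_id`, flips the sign of the outcome
#' effect when its effect allele is the exposure's other allele, drops
#' strand-ambiguous palindromic variants (A/T and C/G pairs) and drops
#' variants whose allele pairs cannot be reconciled, reporting the counts.
#' Harmonization is involutive: applying it to already-harmonized records
#' changes nothing.
#'
#' @param exposure_records,outcome_records Tibbles with columns
#'   `variant_id`, `beta`, `se`, `effect_allele`, `other_allele`.
#' @return An instrument-set tibble: `variant_id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, `effect_allele`,
#'   `other_allele` (exposure coding).
#' @export
harmonize <- function(exposure_records, outcome_records) {
  need <- c("variant_id", "beta", "se", "effect_allele", "other_allele")
  assert_that(all(need %in% names(exposure_records)) &&
                all(need %in% names(outcome_records)),
              "records need variant_id, beta, se, effect_allele, other_allele")
  joined <- dplyr::inner_join(
    dplyr::rename(exposure_records, beta_exposure = "beta",
                  se_exposure = "se"),
    dplyr::rename(outcome_records, beta_outcome = "beta",
                  se_outcome = "se",
                  effect_allele_out = "effect_allele",
                  other_allele_out = "other_allele"),
    by = "variant_id")
  assert_that(nrow(joined) > 0, "no shared variants between the two sources")

  pal <- c("A/T", "T/A", "C/G", "G/C")
  joined <- dplyr::mutate(
    joined,
    palindromic = paste(.data$effect_allele, .data$other_allele,
                        sep = "/") %in% pal,
    same = .data$effect_allele == .data$effect_allele_out &
      .data$other_allele == .data$other_allele_out,
    swapped = .data$effect_allele == .data$other_allele_out &
      .data$other_allele == .data$effect_allele_out
  )
  n_pal <- sum(joined$palindromic)
  n_mismatch <- sum(!joined$palindromic & !joined$same & !joined$swapped)
  if (n_pal > 0)
    inform(sprintf("harmonize: dropped %d palindromic variant(s)", n_pal))
  if (n_mismatch > 0)
    inform(sprintf("harmonize: dropped %d variant(s) with mismatched alleles",
                   n_mismatch))

  out <- joined |>
    dplyr::filter(!.data$palindromic, .data$same | .data$swapped) |>
    dplyr::mutate(beta_outcome = ifelse(.data$swapped, -.data$beta_outcome,
                                        .data$beta_outcome)) |>
    dplyr::select("variant_id", "beta_exposure", "se_exposure",
                  "beta_outcome", "se_outcome", "effect_allele",
                  "other_allele")
  assert_that(nrow(out) > 0, "no variants survive harmonization")
  out
}

#' Inverse-variance-weighted causal estimate
#'
#' Fixed-effect IVW with first-order weights:
#' \deqn{\hat\theta = \frac{\sum_i \beta_{Xi}\beta_{Yi}/se^2_{Yi}}
#'                         {\sum_i \beta_{Xi}^2/se^2_{Yi}},\qquad
#'       SE = \Big(\sum_i \beta_{Xi}^2/se^2_{Yi}\Big)^{-1/2},}
#' with a two-sided normal P value. With a single instrument this is the
#' Wald ratio with `SE = se_Y / |beta_X|`.
#'
#' @param instruments An instrument-set tibble from [harmonize()] or
#'   [simulate_mr_dataset()].
#' @return One-row tibble: `theta_hat`, `se`, `p`, `n_instruments`.
#' @export
ivw_estimate <- function(instruments) {
  need <- c("beta_exposure", "beta_outcome", "se_outcome")
  assert_that(all(need %in% names(instruments)),
              "instrument set needs beta_exposure, beta_outcome, se_outcome")
  assert_that(nrow(instruments) >= 1, "need at least one instrument")
  assert_that(all(instruments$se_outcome > 0),
              "outcome standard errors must be positive")
  assert_that(any(instruments$beta_exposure != 0),
              "all instrument-exposure effects are zero")
  w <- 1 / instruments$se_outcome^2
  denom <- sum(instruments$beta_exposure^2 * w)
  theta <- sum(instruments$beta_exposure * instruments$beta_outcome * w) /
    denom
  se <- 1 / sqrt(denom)
  tibble::tibble(theta_hat = theta, se = se,
                 p = 2 * pnorm(-abs(theta / se)),
                 n_instruments = nrow(instruments))
}

#' Flag implausibly large causal effects (sample-overlap filter)
#'
#' Causal estimates larger than `threshold` in absolute value typically
#' indicate that exposure and outcome measure (nearly) the same quantity in
#' overlapping samples; they are flagged and excluded from downstream
#' correlation and importance computations. The comparison is strict, so an
#' estimate exactly at the threshold is retained.
#'
#' @param estimates Tibble of causal estimates with a `theta_hat` column
#'   (typically also `metabolite` and `trait`).
#' @param threshold Absolute-effect cutoff (default 0.5).
#' @return The input with a logical `filtered_overlap` column.
#' @export
filter_large_effects <- function(estimates, threshold = 0.5) {
  out <- dplyr::mutate(estimates,
                       filtered_overlap = abs(.data$theta_hat) > threshold)
  n_rm <- sum(out$filtered_overlap, na.rm = TRUE)
  if (n_rm > 0)
    inform(sprintf(
      "filter_large_effects: flagged %d estimate(s) with |theta| > %g",
      n_rm, threshold))
  out
}

#' Per-metabolite importance scores
#'
#' The total absolute causal effect of each metabolite across all traits,
#' skipping cells removed by the overlap filter or missing.
#'
#' @param estimates Tibble with columns `metabolite`, `theta_hat` and
#'   (after [filter_large_effects()]) `filtered_overlap`.
#' @return Tibble with `metabolite`, `importance`, `n_traits_used`.
#' @export
importance_scores <- function(estimates) {
  if (!"filtered_overlap" %in% names(estimates))
    estimates$filtered_overlap <- FALSE
  out <- estimates |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(
      importance = sum(abs(.data$theta_hat[!.data$filtered_overlap]),
                       na.rm = TRUE),
      n_traits_used = sum(!.data$filtered_overlap & !is.na(.data$theta_hat)),
      .groups = "drop")
  empty <- out$metabolite[out$n_traits_used == 0]
  if (length(empty) > 0)
    warn(sprintf(
      "importance_scores: no usable estimates for %s (score 0)",
      paste(empty, collapse = ", ")))
  out
}
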