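#' Tidy a profile-likelihood selection fit
#'
#' @param x An `alpha_fit` object.
#' @param ... Unused.
#' @return One-row tibble with the estimate, its standard error, Wald P,
#'   heritability at the optimum and the stability flag.
#' @export
tidy.alpha_fit <- function(x, ...) {
  tibble::tibble(term = "alpha", estimate = x$alpha_hat,
                 std.error = x$se_alpha, p.value = x$p_value,
                 h2 = x$h2_at_hat, stable = x$stable)
}

#' @rdname tidy.alpha_fit
#' @export
glance.alpha_fit <- function(x, ...) {
  tibble::tibble(alpha_hat = x$alpha_hat, se_alpha = x$se_alpha,
                 h2 = x$h2_at_hat, p.value = x$p_value,
                 r.squared = x$r_squared, stable = x$stable,
                 range_lo = x$range_used[1], range_hi = x$range_used[2],
                 n_grid = nrow(x$profile))
}

#' Tidy a modified Cochran's Q heterogeneity result
#'
#' @param x A `het_q` object.
#' @param ... Unused.
#' @return `tidy()` returns per-class means with their null standard
#'   errors; `glance()` the Q statistic, degrees of freedom and P value.
#' @export
tidy.het_q <- function(x, ...) {
  dplyr::mutate(x$class_means, se = sqrt(diag(x$W)),
                deviation = .data$mean - x$overall_mean)
}

#' @rdname tidy.het_q
#' @export
glance.het_q <- function(x, ...) {
  tibble::tibble(Q = x$Q, df = x$df, p.value = x$p,
                 overall_mean = x$overall_mean)
}

#' Tidy an adjusted-slope result
#'
#' @param x An `adjusted_slope` object.
#' @param ... Unused.
#' @export
tidy.adjusted_slope <- function(x, ...) {
  tibble::tibble(term = "slope", estimate = x$r_hat, std.error = x$se,
                 p.value = x$p)
}

#' @rdname tidy.adjusted_slope
#' @export
glance.adjusted_slope <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("r_hat", "se", "sigma2", "p", "n",
                                 "degenerate")])
}
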