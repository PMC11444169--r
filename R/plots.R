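#' Plot a profile likelihood with its fitted quadratic
#'
#' Points are the profiled log-likelihood values; the curve is the quadratic
#' whose vertex and curvature give the estimate and its variance; the
#' vertical line marks the estimate.
#'
#' @param object An `alpha_fit` object.
#' @param ... Unused.
#' @return A `ggplot`.
#' @export
autoplot.alpha_fit <- function(object, ...) {
  qc <- object$quad_coeffs
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(x = .data$alpha, y = .data$loglik)) +
    ggplot2::geom_point() +
    ggplot2::geom_function(
      fun = function(a) qc["a"] * a^2 + qc["b"] * a + qc["c"],
      colour = "steelblue") +
    ggplot2::labs(x = expression(alpha), y = "profile log-likelihood")
  if (!is.na(object$alpha_hat)) {
    p <- p + ggplot2::geom_vline(xintercept = object$alpha_hat,
                                 linetype = "dashed")
  }
  p
}

#' Scatter of selection estimates against a second metabolite quantity
#'
#' Draws per-metabolite selection estimates (with +/- 1 SE bars when
#' available) against e.g. conservation ranks or importance scores, with an
#' ordinary least-squares guide line.
#'
#' @param data Tibble with columns `x`, `alpha_hat` and optionally `se`.
#' @param xlab Label for the x axis.
#' @return A `ggplot`.
#' @export
plot_selection_scatter <- function(data, xlab = "conservation rank") {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$x,
                                          y = .data$alpha_hat)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = xlab, y = expression(hat(alpha)))
  if ("se" %in% names(data)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$alpha_hat - .data$se,
                   ymax = .data$alpha_hat + .data$se),
      width = 0, alpha = 0.4)
  }
  p
}

#' Class-level selection estimates with null standard errors
#'
#' @param het A `het_q` object.
#' @return A `ggplot` of class means with +/- 1.96 SE intervals and the
#'   overall mean as a dashed line.
#' @export
plot_class_heterogeneity <- function(het) {
  stopifnot(inherits(het, "het_q"))
  df <- tidy(het)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - 1.96 * .data$se,
                   ymax = .data$mean + 1.96 * .data$se),
      width = 0.2) +
    ggplot2::geom_hline(yintercept = het$overall_mean,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(bar(hat(alpha))[class])) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
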