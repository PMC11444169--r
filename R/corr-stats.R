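#' Random-effect slope with correlated residuals
#'
#' Fits \eqn{y = r\,x + \epsilon} with \eqn{\epsilon \sim N(0,
#' \sigma^2 \Sigma)} on standardized (zero-mean, unit-variance) quantities.
#' The ordinary through-origin estimator \eqn{\hat r = (y'x)/(x'x)} remains
#' unbiased under residual correlation; only its variance changes, to
#' \eqn{Var(\hat r) = \sigma^2 (x'\Sigma x)/(x'x)^2}. This avoids the
#' numerically fragile likelihood maximization that near-singular
#' correlation matrices provoke. \eqn{\hat\sigma^2} is the residual sum of
#' squares over n-1.
#'
#' @param y,x Numeric vectors of equal length (e.g. selection estimates vs
#'   conservation ranks across metabolites).
#' @param sigma A [correlation_context()] or correlation matrix matching the
#'   vectors.
#' @param scale Standardize `y` and `x` first (the default, matching the
#'   intended use on incommensurate quantities); set `FALSE` when inputs
#'   are already on the model scale.
#' @return One-row tibble of class `adjusted_slope`: `r_hat`, `se`,
#'   `sigma2`, `p`, `n`, `degenerate`.
#' @export
adjusted_slope <- function(y, x, sigma, scale = TRUE) {
  assert_that(length(y) == length(x), "y and x lengths differ")
  n <- length(y)
  smat <- as_sigma_matrix(sigma, n)
  assert_that(sd(x) > 0 && sd(y) > 0, "zero-variance input")
  if (scale) {
    y <- as.vector(base::scale(y))
    x <- as.vector(base::scale(x))
  }
  xtx <- sum(x^2)
  r_hat <- sum(y * x) / xtx
  rss <- sum((y - r_hat * x)^2)
  sigma2 <- rss / (n - 1)
  se <- sqrt(sigma2 * drop(x %*% smat %*% x)) / xtx
  degenerate <- sigma2 < 1e-12
  p <- if (degenerate) 0 else 2 * pnorm(-abs(r_hat / se))
  out <- tibble::tibble(r_hat = r_hat, se = se, sigma2 = sigma2, p = p,
                        n = n, degenerate = degenerate)
  class(out) <- c("adjusted_slope", class(out))
  out
}

# Omega = diag(se) %*% Sigma %*% diag(se): covariance of the estimates under
# the null, combining per-estimate precision with cross-trait correlation.
omega_matrix <- function(se, sigma) {
  smat <- as_sigma_matrix(sigma, length(se))
  assert_that(all(se > 0), "standard errors must be positive")
  smat * outer(se, se)
}

# Class-membership averaging matrix V (K x n): row i is v(i), 1/n_i on
# members of class i and 0 elsewhere.
class_indicator <- function(classes) {
  classes <- as.factor(classes)
  lev <- levels(classes)
  v <- vapply(lev, function(l) (classes == l) / sum(classes == l),
              numeric(length(classes)))
  t(v)
}

#' Modified Cochran's Q for heterogeneity of correlated estimates
#'
#' Tests whether mean selection strength differs across metabolite classes
#' when the per-metabolite estimates are correlated. Under the null
#' \eqn{\hat\alpha \sim N(\cdot, \Omega)} with
#' \eqn{\Omega = diag(SE)\,\Sigma\,diag(SE)}; class means are
#' \eqn{\hat\alpha_i = v(i)'\hat\alpha} with joint covariance
#' \eqn{W_{ij} = v(i)' \Omega\, v(j)}. With d the vector of class means
#' minus their overall mean, \eqn{Q = d'\,[DWD']^{+}\,d} (D the centering
#' matrix, pseudoinverse because centering removes one rank), referred to a
#' chi-square with K-1 degrees of freedom.
#'
#' @param alpha_hat Per-metabolite estimates.
#' @param se Their standard errors.
#' @param sigma A [correlation_context()] or correlation matrix.
#' @param classes Class label per metabolite (>= 2 classes, all nonempty).
#' @param overall_mean `"classes"` (default) averages the class means;
#'   `"metabolites"` averages over all metabolites instead.
#' @return An object of class `het_q`: class means, `Q`, `df`, `p`, and the
#'   `W` and `Omega` matrices.
#' @export
modified_cochran_q <- function(alpha_hat, se, sigma, classes,
                               overall_mean = c("classes", "metabolites")) {
  overall_mean <- match.arg(overall_mean)
  n <- length(alpha_hat)
  assert_that(length(se) == n && length(classes) == n,
              "alpha_hat, se and classes lengths differ")
  v <- class_indicator(classes)
  k <- nrow(v)
  assert_that(k >= 2, "heterogeneity testing needs >= 2 classes")

  omega <- omega_matrix(se, sigma)
  m <- drop(v %*% alpha_hat)
  w <- v %*% omega %*% t(v)
  abar <- if (overall_mean == "classes") mean(m) else mean(alpha_hat)
  d <- m - abar

  centering <- diag(k) - 1 / k
  cov_d <- centering %*% w %*% t(centering)
  q <- drop(d %*% MASS::ginv(cov_d) %*% d)
  df <- k - 1L
  structure(list(
    class_means = tibble::tibble(class = rownames(v) %||% levels(as.factor(classes)),
                                 mean = m,
                                 n = as.integer(table(as.factor(classes)))),
    overall_mean = abar, omega = omega, W = w,
    Q = q, df = df, p = pchisq(q, df, lower.tail = FALSE)
  ), class = "het_q")
}

#' @export
print.het_q <- function(x, ...) {
  cat(sprintf("Modified Cochran's Q = %.4f, df = %d, P = %.3g\n",
              x$Q, x$df, x$p))
  print(x$class_means)
  invisible(x)
}

#' Class-versus-rest contrast on correlated estimates
#'
#' Compares the mean estimate in one class with the mean outside it:
#' contrast weights are \eqn{1/n_i} inside the class and \eqn{-1/n_{-i}}
#' outside, \eqn{t = w'\hat\alpha} with null variance \eqn{w'\Omega w},
#' and a two-sided normal P value.
#'
#' @inheritParams modified_cochran_q
#' @param target_class The class to contrast against the rest.
#' @return One-row tibble: `class`, `t`, `var_t`, `z`, `p`, `n_class`,
#'   `n_rest`.
#' @export
class_vs_rest <- function(alpha_hat, se, sigma, classes, target_class) {
  n <- length(alpha_hat)
  assert_that(length(se) == n && length(classes) == n,
              "alpha_hat, se and classes lengths differ")
  inside <- classes == target_class
  n_in <- sum(inside); n_out <- sum(!inside)
  assert_that(n_in > 0, sprintf("class %s is empty", target_class))
  assert_that(n_out > 0, "class covers all metabolites: nothing to compare")

  w <- ifelse(inside, 1 / n_in, -1 / n_out)
  omega <- omega_matrix(se, sigma)
  t_stat <- sum(w * alpha_hat)
  var_t <- drop(w %*% omega %*% w)
  z <- t_stat / sqrt(var_t)
  tibble::tibble(class = as.character(target_class), t = t_stat,
                 var_t = var_t, z = z, p = 2 * pnorm(-abs(z)),
                 n_class = n_in, n_rest = n_out)
}
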