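#' MAF/LD-dependent heritability model
#'
#' Under the alpha model the expected squared per-allele effect of variant j
#' is proportional to \eqn{\omega_j [2 f_j (1-f_j)]^\alpha}: `alpha = 0`
#' gives the neutral architecture in which rarer alleles have equal expected
#' per-standardized-SNP effects, while `alpha = -1` makes every variant's
#' expected heritability contribution independent of its frequency — the
#' signature of strong stabilizing selection. Optionally the heritability is
#' stratified over annotation categories, each category contributing a term
#' of the same functional form.
#'
#' @param h2 Total SNP heritability in `[0, 1]`.
#' @param alpha Selection-strength exponent.
#' @param stratum_h2 Optional named vector of per-annotation heritability
#'   contributions (names match annotation columns of the panel); must sum
#'   to `h2`.
#' @return An object of class `heritability_model`.
#' @export
heritability_model <- function(h2, alpha, stratum_h2 = NULL) {
  assert_that(h2 >= 0 && h2 <= 1, "h2 must lie in [0, 1]")
  if (!is.null(stratum_h2)) {
    assert_that(!is.null(names(stratum_h2)),
                "stratum_h2 must be named by annotation category")
    assert_that(all(stratum_h2 >= 0), "stratum contributions must be >= 0")
    assert_that(abs(sum(stratum_h2) - h2) < 1e-8,
                "stratum contributions must sum to h2")
  }
  structure(list(h2 = h2, alpha = alpha, stratum_h2 = stratum_h2),
            class = "heritability_model")
}

#' Expected per-SNP heritability under the alpha model
#'
#' \eqn{E[h^2_j] = h^2 \omega_j H_j^{\alpha+1} / \sum_l \omega_l
#' H_l^{\alpha+1}} with \eqn{H_j = 2 f_j (1-f_j)}; the vector sums to `h2`
#' exactly. With annotation strata, a sum of per-category terms of the same
#' form weighted by the annotation values.
#'
#' @param panel A [snp_panel()].
#' @param model A [heritability_model()].
#' @return Named numeric vector of expected per-variant heritability.
#' @export
expected_per_snp_h2 <- function(panel, model) {
  stopifnot(inherits(model, "heritability_model"))
  u <- panel$snp_weight * heterozygosity(panel$maf)^(model$alpha + 1)
  if (is.null(model$stratum_h2)) {
    out <- if (model$h2 == 0) numeric(nrow(panel)) else model$h2 * u / sum(u)
    return(setNames(out, panel$variant_id))
  }
  ann <- panel_annotations(panel)
  assert_that(!is.null(ann) && all(names(model$stratum_h2) %in% colnames(ann)),
              "panel annotations missing for the model's strata")
  out <- numeric(nrow(panel))
  for (k in names(model$stratum_h2)) {
    uk <- ann[, k] * u
    denom <- sum(uk)
    if (model$stratum_h2[[k]] > 0) {
      assert_that(denom > 0,
                  sprintf("annotation %s puts no weight on any variant", k))
      out <- out + model$stratum_h2[[k]] * uk / denom
    }
  }
  setNames(out, panel$variant_id)
}

#' Expected marginal chi-square statistics
#'
#' LD dilution spreads each variant's heritability onto its neighbours:
#' \eqn{e_j = 1 + n_j \sum_{l \in block(j)} r_{jl}^2\, E[h^2_l]}, so
#' `e_j >= 1` always, with equality under the null model.
#'
#' @inheritParams expected_per_snp_h2
#' @param n GWAS sample size, scalar or per-variant (panel order).
#' @return Named numeric vector of expected chi-square values.
#' @export
expected_chisq <- function(panel, model, n) {
  eh2 <- expected_per_snp_h2(panel, model)
  n <- rep_len(n, nrow(panel))
  e <- 1 + n * ld_diluted(panel, eh2)
  setNames(e, panel$variant_id)
}

# Per-variant sum over the block of r^2 times a per-variant quantity.
# Singleton blocks contribute x unchanged; multi-variant blocks a dense
# r^2 mat-vec. The block split is memoised on the panel.
ld_diluted <- function(panel, x) {
  info <- block_index(panel)
  out <- numeric(nrow(panel))
  if (length(info$single) > 0) out[info$single] <- x[info$single]
  for (k in seq_along(info$multi_idx)) {
    i <- info$multi_idx[[k]]
    out[i] <- drop(info$multi_r2[[k]] %*% x[i])
  }
  out
}

block_index <- function(panel) {
  cache <- attr(panel, "cache")
  if (is.environment(cache) && !is.null(cache$block_index))
    return(cache$block_index)
  blocks <- ld_blocks(panel)
  idx <- split(seq_len(nrow(panel)), panel$block_id)
  sizes <- lengths(idx)
  multi <- which(sizes > 1L)
  pos <- match(names(idx)[multi], names(blocks))
  info <- list(
    single = unlist(idx[sizes == 1L], use.names = FALSE),
    multi_idx = unname(idx[multi]),
    multi_r2 = lapply(seq_along(multi),
                      function(k) blocks[[pos[k]]]^2))
  if (is.environment(cache)) cache$block_index <- info
  info
}

# Align summary statistics to a panel; errors if panel variants are missing.
align_stats <- function(stats, panel) {
  pos <- match(panel$variant_id, stats$variant_id)
  assert_that(!anyNA(pos),
              "summary statistics missing variants present in the panel")
  stats[pos, , drop = FALSE]
}

#' Quasi-log-likelihood of summary statistics under the alpha model
#'
#' Each marginal statistic is treated as a scaled chi-square with one degree
#' of freedom and expectation `e_j` from [expected_chisq()]:
#' \deqn{\ell = \sum_j \kappa_j\left[-\tfrac12\log(2\pi)
#'   - \tfrac12\log S_j - \tfrac12\log e_j - S_j/(2 e_j)\right],}
#' with regression weights \eqn{\kappa_j = \omega_j} down-weighting variants
#' in strong LD (which contribute largely redundant information).
#' Statistics below `1e-8` are floored there before the log term.
#'
#' @param stats A `sumstats` tibble (needs `variant_id`, `chisq`, `n`).
#' @inheritParams expected_per_snp_h2
#' @return Scalar log-likelihood.
#' @export
model_loglik <- function(stats, panel, model) {
  stats <- align_stats(stats, panel)
  e <- expected_chisq(panel, model, stats$n)
  s <- pmax(stats$chisq, 1e-8)
  kappa <- panel$snp_weight
  sum(kappa * (-0.5 * log(2 * pi) - 0.5 * log(s) - 0.5 * log(e) -
                 s / (2 * e)))
}

# Contiguous run of grid indices around the profile maximum whose
# log-likelihood lies within `drop` of the peak, padded outward to at
# least `min_points` points.
peak_window <- function(ll, drop, min_points) {
  imax <- which.max(ll)
  ok <- ll >= max(ll) - drop
  lo <- imax; hi <- imax
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  while (hi < length(ll) && ok[hi + 1]) hi <- hi + 1
  while (hi - lo + 1 < min(min_points, length(ll))) {
    grow_lo <- lo > 1 && (hi == length(ll) ||
                            ll[lo - 1] >= ll[hi + 1])
    if (grow_lo) lo <- lo - 1 else hi <- hi + 1
  }
  lo:hi
}

# Pieces of the profile likelihood that are fixed given alpha: with
# e_j = 1 + h2 * t_j, the 1-D likelihood in h2 is cheap to evaluate.
profile_pieces <- function(stats, panel, alpha) {
  stats <- align_stats(stats, panel)
  u <- panel$snp_weight * heterozygosity(panel$maf)^(alpha + 1)
  share <- u / sum(u)
  t_j <- stats$n * ld_diluted(panel, share)
  s <- pmax(stats$chisq, 1e-8)
  kappa <- panel$snp_weight
  const <- sum(kappa * (-0.5 * log(2 * pi) - 0.5 * log(s)))
  list(t_j = t_j, s = s, kappa = kappa, const = const)
}

profile_loglik_h2 <- function(h2, pieces) {
  e <- 1 + h2 * pieces$t_j
  pieces$const +
    sum(pieces$kappa * (-0.5 * log(e) - pieces$s / (2 * e)))
}

#' Maximize the likelihood over heritability at fixed alpha
#'
#' Bounded 1-D maximization of [model_loglik()] over \eqn{h^2 \in [0, 1]}
#' (golden-section search, tolerance `1e-6` on h2), with the boundary values
#' checked explicitly so that e.g. fully null statistics return exactly 0.
#'
#' @inheritParams model_loglik
#' @param alpha Fixed selection-strength exponent.
#' @return List with `h2_hat`, `loglik_max` and a `converged` flag.
#' @export
fit_h2_given_alpha <- function(stats, panel, alpha) {
  pieces <- profile_pieces(stats, panel, alpha)
  opt <- optimize(profile_loglik_h2, interval = c(0, 1), pieces = pieces,
                  maximum = TRUE, tol = 1e-6)
  cand_h2 <- c(opt$maximum, 0, 1)
  cand_ll <- c(opt$objective,
               profile_loglik_h2(0, pieces),
               profile_loglik_h2(1, pieces))
  best <- which.max(cand_ll)
  list(h2_hat = cand_h2[best], loglik_max = cand_ll[best], converged = TRUE)
}

#' Vertex and curvature of a quadratic fitted to a likelihood profile
#'
#' Least-squares fit of \eqn{q(\alpha) = a\alpha^2 + b\alpha + c} to the
#' profiled log-likelihood points; the maximum-likelihood estimate is the
#' vertex \eqn{\hat\alpha = -b/(2a)} and its variance the inverse negative
#' Hessian \eqn{1/(-2a)}.
#'
#' @param grid Strictly increasing alpha values.
#' @param loglik Profile log-likelihood at each grid point.
#' @return List with `alpha_hat`, `se`, coefficients `a`, `b`, `c`, and the
#'   quadratic fit's `r_squared`. When the fit is convex (`a >= 0`) the
#'   estimate and standard error are `NA`.
#' @export
quadratic_mle <- function(grid, loglik) {
  assert_that(length(grid) == length(loglik) && length(grid) >= 3,
              "need at least 3 grid points")
  assert_that(all(diff(grid) > 0), "grid must be strictly increasing")
  fit <- lm(loglik ~ grid + I(grid^2))
  cf <- coef(fit)
  a <- unname(cf[3]); b <- unname(cf[2]); cc <- unname(cf[1])
  tss <- sum((loglik - mean(loglik))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 1
  if (!is.finite(a) || a >= 0) {
    return(list(alpha_hat = NA_real_, se = NA_real_, a = a, b = b, c = cc,
                r_squared = r2))
  }
  list(alpha_hat = -b / (2 * a), se = sqrt(1 / (-2 * a)),
       a = a, b = b, c = cc, r_squared = r2)
}

#' Profile-likelihood estimation of the selection-strength parameter
#'
#' For each alpha on a grid (31 points from -1 to 0.5 by default) the
#' likelihood is maximized over heritability; a quadratic is fitted to the
#' profiled points and its vertex and curvature give the estimate and its
#' variance. If the vertex lands within one grid step of a range boundary
#' the grid is extended, once per side, to `[-2, 1]` (left) or `[-1, 4]`
#' (right) and the fit repeated. The fit is flagged stable when the
#' quadratic is concave (`a < -1e-6`), describes the profile well
#' (`R^2 >= 0.95`) and the vertex lies inside the final range.
#'
#' @inheritParams model_loglik
#' @param grid_lo,grid_hi,step Grid bounds and spacing.
#' @param r2_min,curvature_max Stability thresholds (quadratic fit R^2 and
#'   upper bound on the leading coefficient).
#' @param loglik_window The quadratic is fitted to the contiguous run of
#'   grid points whose profile log-likelihood lies within this drop of the
#'   maximum (at least `min_points` points): the quadratic approximation
#'   to a likelihood surface is local, and on information-rich data a fit
#'   across the whole grid is dominated by the asymmetric tails and biases
#'   the vertex. On flat, noisy profiles the window covers the whole grid
#'   and this reduces to fitting all points.
#' @param min_points Minimum number of points in the fitting window.
#' @return An object of class `alpha_fit`; see [tidy.alpha_fit()].
#' @export
profile_alpha <- function(stats, panel, grid_lo = -1, grid_hi = 0.5,
                          step = 0.05, r2_min = 0.95,
                          curvature_max = -1e-6, loglik_window = 3,
                          min_points = 5) {
  assert_that(grid_lo < grid_hi, "grid_lo must be below grid_hi")
  assert_that(step > 0, "step must be positive")

  cache <- new.env(parent = emptyenv())
  point <- function(a) {
    key <- sprintf("%.10f", a)
    got <- cache[[key]]
    if (is.null(got)) {
      got <- fit_h2_given_alpha(stats, panel, a)
      cache[[key]] <- got
    }
    got
  }

  lo <- grid_lo; hi <- grid_hi
  extended_left <- FALSE; extended_right <- FALSE
  repeat {
    grid <- seq(lo, hi, by = step)
    pts <- lapply(grid, point)
    ll <- vapply(pts, `[[`, numeric(1), "loglik_max")
    win <- peak_window(ll, loglik_window, min_points)
    qf <- quadratic_mle(grid[win], ll[win])
    ah <- qf$alpha_hat
    if (!is.na(ah) && ah <= lo + step && !extended_left) {
      lo <- -2; hi <- max(hi, 1); extended_left <- TRUE
    } else if (!is.na(ah) && ah >= hi - step && !extended_right) {
      lo <- min(lo, -1); hi <- 4; extended_right <- TRUE
    } else {
      break
    }
  }

  stable <- !is.na(ah) && qf$a < curvature_max &&
    qf$r_squared >= r2_min && ah >= lo && ah <= hi
  h2_at_hat <- if (!is.na(ah)) fit_h2_given_alpha(stats, panel, ah)$h2_hat
               else NA_real_
  p_value <- if (!is.na(ah)) 2 * pnorm(-abs(ah / qf$se)) else NA_real_

  structure(list(
    profile = tibble::tibble(
      alpha = grid, loglik = ll,
      h2_hat = vapply(pts, `[[`, numeric(1), "h2_hat"),
      in_window = seq_along(grid) %in% win),
    quad_coeffs = c(a = qf$a, b = qf$b, c = qf$c),
    alpha_hat = ah,
    se_alpha = qf$se,
    h2_at_hat = h2_at_hat,
    range_used = c(lo, hi),
    r_squared = qf$r_squared,
    stable = stable,
    extended = c(left = extended_left, right = extended_right),
    p_value = p_value
  ), class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat("Profile-likelihood selection-strength fit\n")
  cat(sprintf("  alpha_hat = %.4f (SE %.4f), h2 = %.4f, P = %.3g\n",
              x$alpha_hat, x$se_alpha, x$h2_at_hat, x$p_value))
  cat(sprintf("  range [%g, %g], quadratic R^2 = %.4f, %s\n",
              x$range_used[1], x$range_used[2], x$r_squared,
              if (x$stable) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Wald test of the selection-strength estimate
#'
#' Two-sided normal test of `alpha_hat = 0` with nominal (0.05) and
#' Bonferroni (`0.05 / n_tests`) significance flags; the default `n_tests`
#' matches a panel of 97 traits tested jointly.
#'
#' @param fit A stable [profile_alpha()] fit.
#' @param n_tests Number of tests in the family for the Bonferroni flag.
#' @return One-row tibble with `z`, `p`, `significant_nominal`,
#'   `significant_bonferroni`.
#' @export
wald_selection_test <- function(fit, n_tests = 97) {
  stopifnot(inherits(fit, "alpha_fit"))
  assert_that(isTRUE(fit$stable),
              "Wald test requires a stable profile-likelihood fit")
  z <- fit$alpha_hat / fit$se_alpha
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(
    z = z, p = p,
    significant_nominal = p < 0.05,
    significant_bonferroni = p < 0.05 / n_tests
  )
}

#' Fit the alpha model to every metabolite in a set
#'
#' @param stats_list Named list of `sumstats` tibbles.
#' @inheritParams profile_alpha
#' @return Tibble report with one row per metabolite (`metabolite`,
#'   `alpha_hat`, `se`, `p`, `h2`, `stable`, `range_lo`, `range_hi`) and the
#'   fits as an attribute `fits`.
#' @export
fit_alpha_report <- function(stats_list, panel, grid_lo = -1,
                             grid_hi = 0.5, step = 0.05) {
  fits <- lapply(stats_list, profile_alpha, panel = panel,
                 grid_lo = grid_lo, grid_hi = grid_hi, step = step)
  report <- purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(metabolite = nm, alpha_hat = f$alpha_hat,
                   se = f$se_alpha, p = f$p_value, h2 = f$h2_at_hat,
                   stable = f$stable, range_lo = f$range_used[1],
                   range_hi = f$range_used[2])
  })
  attr(report, "fits") <- fits
  report
}
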