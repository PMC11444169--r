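#' Cross-trait LD-score regression
#'
#' Regresses the per-variant z-score product on the LD score: under
#' polygenic architectures
#' \eqn{E[z_{1j} z_{2j}] = \sqrt{n_1 n_2}\,\rho_g\, \ell_j / M +
#' intercept}, so the slope times \eqn{M/\sqrt{n_1 n_2}} estimates the
#' genetic covariance (M = panel size; the intercept absorbs confounding
#' and sample overlap). With `stats2 = stats1` this is the univariate
#' LD-score heritability estimate. The regression is weighted by the SNP
#' weights; the standard error comes from a delete-one-block jackknife over
#' LD blocks.
#'
#' @param stats1,stats2 `sumstats` tibbles sharing >= 200 variants with the
#'   panel.
#' @param panel A [snp_panel()].
#' @return One-row tibble: `cov_g`, `se`, `var_of_est`, `p`, `intercept`,
#'   `n_snps_used`, `n_blocks`.
#' @export
cross_trait_ldsc <- function(stats1, stats2, panel) {
  s1 <- align_stats(stats1, panel)
  s2 <- align_stats(stats2, panel)
  assert_that(nrow(panel) >= 200,
              "cross-trait LD-score regression needs >= 200 shared variants")
  ell <- panel$ld_score
  assert_that(var(ell) > 0 || length(unique(ell)) > 1,
              "all LD scores equal: regression design is collinear")

  y <- s1$z * s2$z
  w <- panel$snp_weight
  m_panel <- nrow(panel)
  scale_f <- m_panel / sqrt(mean(s1$n) * mean(s2$n))

  # Weighted simple regression via per-block partial sums, so the
  # delete-one-block jackknife is O(blocks).
  blk <- panel$block_id
  sums <- function(v) tapply(v, blk, sum)
  bw <- sums(w); bwx <- sums(w * ell); bwy <- sums(w * y)
  bwxx <- sums(w * ell^2); bwxy <- sums(w * ell * y)
  slope_from <- function(sw, swx, swy, swxx, swxy) {
    denom <- swxx - swx^2 / sw
    if (denom <= 0) return(NA_real_)
    (swxy - swx * swy / sw) / denom
  }
  tw <- sum(bw); twx <- sum(bwx); twy <- sum(bwy)
  twxx <- sum(bwxx); twxy <- sum(bwxy)
  slope <- slope_from(tw, twx, twy, twxx, twxy)
  assert_that(is.finite(slope),
              "all LD scores equal: regression design is collinear")
  intercept <- (twy - slope * twx) / tw
  cov_g <- slope * scale_f

  n_blocks <- length(bw)
  if (n_blocks >= 2) {
    jack <- vapply(seq_len(n_blocks), function(b) {
      slope_from(tw - bw[b], twx - bwx[b], twy - bwy[b],
                 twxx - bwxx[b], twxy - bwxy[b]) * scale_f
    }, numeric(1))
    jbar <- mean(jack)
    var_est <- (n_blocks - 1) / n_blocks * sum((jack - jbar)^2)
  } else {
    var_est <- NA_real_
  }
  se <- sqrt(var_est)
  tibble::tibble(
    cov_g = cov_g, se = se, var_of_est = var_est,
    p = if (is.na(se) || se == 0) NA_real_ else 2 * pnorm(-abs(cov_g / se)),
    intercept = intercept, n_snps_used = m_panel, n_blocks = n_blocks)
}

#' Pairwise genetic covariance matrix of a metabolite set
#'
#' Runs [cross_trait_ldsc()] on every pair (and each trait against itself
#' for the diagonal heritability estimates).
#'
#' @param stats_list Named list of `sumstats` tibbles.
#' @param panel A [snp_panel()].
#' @return An object of class `gencov`: list with matrices `cov`,
#'   `var_of_est`, `p` and logical flag matrices `zeroed`, plus `bent`
#'   bookkeeping added by [weighted_bending()].
#' @export
gencov_matrix <- function(stats_list, panel) {
  k <- length(stats_list)
  nm <- names(stats_list) %||% sprintf("trait%02d", seq_len(k))
  cov <- var_of_est <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in i:k) {
      est <- cross_trait_ldsc(stats_list[[i]], stats_list[[j]], panel)
      cov[i, j] <- cov[j, i] <- est$cov_g
      var_of_est[i, j] <- var_of_est[j, i] <- est$var_of_est
      p[i, j] <- p[j, i] <- est$p
    }
  }
  structure(list(cov = cov, var_of_est = var_of_est, p = p,
                 zeroed = matrix(FALSE, k, k, dimnames = list(nm, nm)),
                 bent = FALSE, mean_abs_change = 0),
            class = "gencov")
}

#' Zero non-significant covariance entries
#'
#' Off-diagonal entries whose estimates are not even nominally significant
#' (`p > p_threshold`, strict) are set to zero and flagged; the diagonal is
#' untouched and symmetry is preserved.
#'
#' @param covmat A `gencov` object.
#' @param p_threshold Significance cutoff (default 0.05).
#' @return The sparsified `gencov` object.
#' @export
sparsify <- function(covmat, p_threshold = 0.05) {
  stopifnot(inherits(covmat, "gencov"))
  drop_mask <- covmat$p > p_threshold
  drop_mask[is.na(drop_mask)] <- FALSE
  diag(drop_mask) <- FALSE
  covmat$cov[drop_mask] <- 0
  covmat$zeroed <- covmat$zeroed | drop_mask
  covmat
}

#' Precision-weighted bending to positive semidefiniteness
#'
#' While the smallest eigenvalue is below `-tol`, negative eigenvalues are
#' floored at a small positive value, the matrix is reconstructed, and the
#' implied adjustment is blended back elementwise with weights proportional
#' to the estimate variances: imprecise entries absorb most of the change,
#' precisely estimated entries move least, and the diagonal (treated as
#' precisely known) is held fixed. Positive semidefinite input is returned
#' unchanged, making the operation idempotent.
#'
#' @param covmat A `gencov` object (or plain symmetric matrix, in which case
#'   equal weights are used).
#' @param tol Eigenvalue tolerance defining "positive semidefinite".
#' @param step Blending step per iteration in `(0, 1]`.
#' @param max_iter Iteration cap; exceeded -> error with diagnostics.
#' @return The bent object, with `bent` flag and `mean_abs_change`
#'   diagnostic (average absolute change over matrix entries).
#' @export
weighted_bending <- function(covmat, tol = 1e-8, step = 0.5,
                             max_iter = 1000) {
  plain <- !inherits(covmat, "gencov")
  a0 <- if (plain) as.matrix(covmat) else covmat$cov
  vmat <- if (plain) matrix(1, nrow(a0), ncol(a0)) else covmat$var_of_est
  assert_that(max(abs(a0 - t(a0))) < 1e-10, "matrix must be symmetric")

  wts <- vmat
  wts[!is.finite(wts) | wts <= 0] <- max(vmat[is.finite(vmat) & vmat > 0], 1)
  diag(wts) <- 0                      # diagonal held fixed
  off_max <- max(wts[row(wts) != col(wts)], 0)
  if (off_max > 0) wts <- wts / off_max

  a <- a0
  iter <- 0L
  while (min_eigenvalue(a) < -tol) {
    iter <- iter + 1L
    if (iter > max_iter) {
      abort(sprintf(
        "weighted_bending: no convergence in %d iterations (min eigenvalue %.3g)",
        max_iter, min_eigenvalue(a)))
    }
    eig <- eigen((a + t(a)) / 2, symmetric = TRUE)
    floor_val <- max(max(eig$values) * 1e-8, 1e-12)
    lam <- pmax(eig$values, floor_val)
    target <- eig$vectors %*% (lam * t(eig$vectors))
    a <- a + step * wts * (target - a)
    a <- (a + t(a)) / 2
  }

  mean_abs_change <- mean(abs(a - a0))
  if (plain) {
    attr(a, "mean_abs_change") <- mean_abs_change
    return(a)
  }
  covmat$cov <- a
  covmat$bent <- iter > 0
  covmat$mean_abs_change <- mean_abs_change
  covmat
}

#' Convert a genetic covariance matrix to a correlation context
#'
#' \eqn{\Sigma_{ij} = cov_{ij}/\sqrt{cov_{ii}\,cov_{jj}}}; requires a
#' strictly positive diagonal. Positive semidefiniteness is preserved.
#'
#' @param covmat A `gencov` object or plain covariance matrix.
#' @return An object of class `correlation_context`: list with `sigma` (the
#'   correlation matrix) and `min_eigenvalue`.
#' @export
cov_to_corr <- function(covmat) {
  a <- if (inherits(covmat, "gencov")) covmat$cov else as.matrix(covmat)
  d <- diag(a)
  assert_that(all(d > 0), "diagonal must be strictly positive")
  s <- 1 / sqrt(d)
  sigma <- a * outer(s, s)
  diag(sigma) <- 1
  sigma <- (sigma + t(sigma)) / 2
  # rescaling by a small diagonal can magnify a just-tolerated negative
  # eigenvalue; project it away and restore the unit diagonal
  if (min_eigenvalue(sigma) < -1e-8) {
    eig <- eigen(sigma, symmetric = TRUE)
    sigma <- eig$vectors %*% (pmax(eig$values, 0) * t(eig$vectors))
    d2 <- 1 / sqrt(diag(sigma))
    sigma <- sigma * outer(d2, d2)
    diag(sigma) <- 1
    sigma <- (sigma + t(sigma)) / 2
    dimnames(sigma) <- dimnames(a)
  }
  correlation_context(sigma)
}

#' @rdname cov_to_corr
#' @param sigma A symmetric unit-diagonal correlation matrix with minimum
#'   eigenvalue `>= -1e-8`.
#' @export
correlation_context <- function(sigma) {
  sigma <- as.matrix(sigma)
  assert_that(max(abs(sigma - t(sigma))) < 1e-8,
              "correlation matrix must be symmetric")
  assert_that(max(abs(diag(sigma) - 1)) < 1e-8,
              "correlation matrix must have unit diagonal")
  me <- min_eigenvalue(sigma)
  assert_that(me >= -1e-8,
              "correlation matrix is not positive semidefinite")
  structure(list(sigma = sigma, min_eigenvalue = me),
            class = "correlation_context")
}

# Accept either a correlation_context or a bare matrix.
as_sigma_matrix <- function(sigma, n = NULL) {
  m <- if (inherits(sigma, "correlation_context")) sigma$sigma
       else as.matrix(sigma)
  if (!is.null(n)) assert_that(nrow(m) == n, "Sigma dimension mismatch")
  m
}
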