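# Internal helpers shared across modules.

# Scoped RNG: functions that accept `seed` restore the caller's RNG state.
local_seed <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    withr::local_seed(as.integer(seed), .local_envir = envir)
  }
  invisible(NULL)
}

# Heterozygosity 2f(1-f) from minor allele frequency.
heterozygosity <- function(maf) 2 * maf * (1 - maf)

# MAF recovering a given heterozygosity H in (0, 0.5].
maf_from_het <- function(het) {
  stopifnot(all(het > 0), all(het <= 0.5 + 1e-12))
  het <- pmin(het, 0.5)
  (1 - sqrt(1 - 2 * het)) / 2
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

# Symmetric PSD check up to a tolerance on the minimum eigenvalue.
min_eigenvalue <- function(m) {
  min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

is_psd <- function(m, tol = 1e-8) min_eigenvalue(m) >= -tol

# One multivariate normal draw with covariance `sigma` (mean 0), via the
# upper Cholesky factor; `chol_sigma` may be precomputed.
rmvnorm1 <- function(sigma = NULL, chol_sigma = NULL) {
  if (is.null(chol_sigma)) chol_sigma <- chol(sigma)
  drop(crossprod(chol_sigma, rnorm(ncol(chol_sigma))))
}

`%||%` <- rlang::`%||%`
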