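# LD-score regression models per-SNP heritability as constant across
# variants, so the recovery study generates under that architecture
# (unit weights, alpha = -1 on the standardized scale).
sim_pair <- function(rho, h2 = 0.5, n_snps = 3000, n = 5e4, seed = 1,
                     alpha = -1) {
  panel <- simulate_panel(n_snps, 300, within_block_corr = c(0, 0.8),
                          seed = seed, weights = "unit")
  spec <- metabolite_panel_spec(
    exchangeable_corr(2, rho),
    list(architecture_spec(h2 = h2, alpha = alpha, n_samples = n),
         architecture_spec(h2 = h2, alpha = alpha, n_samples = n)))
  set <- simulate_metabolite_set(spec, panel, seed = seed + 1)
  list(panel = panel, stats = set$sumstats)
}

test_that("self-covariance equals the univariate heritability estimate", {
  d <- sim_pair(0.5, seed = 3)
  self <- cross_trait_ldsc(d$stats[[1]], d$stats[[1]], d$panel)
  # univariate LD-score regression on z^2 has the same slope scaling
  expect_lt(abs(self$cov_g - 0.5), 0.2)
  # rough unbiasedness of the heritability estimate over replicates
  ests <- vapply(1:10, function(s) {
    d <- sim_pair(0.5, seed = 100 + s)
    cross_trait_ldsc(d$stats[[1]], d$stats[[1]], d$panel)$cov_g
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.5), 3 * sd(ests) / sqrt(10) + 0.05)
})

test_that("cross-trait regression recovers the generative genetic covariance", {
  ests <- vapply(1:10, function(s) {
    d <- sim_pair(0.5, seed = 200 + s)
    cross_trait_ldsc(d$stats[[1]], d$stats[[2]], d$panel)$cov_g
  }, numeric(1))
  # genetic covariance = rho * sqrt(h2_1 h2_2) = 0.25
  expect_lt(abs(mean(ests) - 0.25), 3 * sd(ests) / sqrt(10) + 0.03)

  # independent traits: estimates near zero
  ests0 <- vapply(1:10, function(s) {
    d <- sim_pair(0, seed = 300 + s)
    cross_trait_ldsc(d$stats[[1]], d$stats[[2]], d$panel)$cov_g
  }, numeric(1))
  expect_lt(abs(mean(ests0)), 3 * sd(ests0) / sqrt(10) + 0.02)
})

test_that("collinear LD scores are rejected", {
  p <- tiny_panel(250)   # all LD scores exactly 1
  ss <- simulate_sumstats(p, rep(0, nrow(p)), 1e4, seed = 1)
  expect_error(cross_trait_ldsc(ss, ss, p), "collinear")
})

test_that("sparsification zeroes only non-significant off-diagonals, symmetrically", {
  k <- 3
  nm <- c("a", "b", "c")
  gc <- structure(list(
    cov = matrix(c(1, 0.3, 0.2, 0.3, 1, 0.1, 0.2, 0.1, 1), k, k,
                 dimnames = list(nm, nm)),
    var_of_est = matrix(0.01, k, k, dimnames = list(nm, nm)),
    p = matrix(c(0, 0.2, 0.049, 0.2, 0, 0.051, 0.049, 0.051, 0), k, k,
               dimnames = list(nm, nm)),
    zeroed = matrix(FALSE, k, k), bent = FALSE, mean_abs_change = 0),
    class = "gencov")
  sp <- sparsify(gc)
  expect_equal(sp$cov["a", "b"], 0)        # p = 0.2 > 0.05
  expect_equal(sp$cov["b", "a"], 0)        # symmetric partner
  expect_equal(sp$cov["a", "c"], 0.2)      # p = 0.049 retained (strict)
  expect_equal(sp$cov["b", "c"], 0)        # p = 0.051 zeroed
  expect_equal(unname(diag(sp$cov)), rep(1, k))  # diagonal untouched
})

test_that("bending restores positive semidefiniteness, preserves the diagonal, and is idempotent", {
  # PSD input: unchanged
  psd <- exchangeable_corr(4, 0.3)
  expect_lt(max(abs(weighted_bending(psd) - psd)), 1e-12)

  # indefinite 2x2 from the hand example
  m <- matrix(c(1, 0.9, 0.9, 0.5), 2, 2)
  bent <- weighted_bending(m)
  expect_gte(min(eigen(bent, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
  expect_equal(unname(diag(bent)), c(1, 0.5), tolerance = 1e-10)

  # idempotent beyond tolerance
  expect_lt(max(abs(weighted_bending(bent) - bent)), 1e-10)

  # constructed non-PSD matrices from 3x3 to 10x10
  withr::with_seed(5, {
    for (k in 3:10) {
      a <- exchangeable_corr(k, 0.2)
      a[1, 2] <- a[2, 1] <- 0.99
      a[1, 3] <- a[3, 1] <- -0.99
      a[2, 3] <- a[3, 2] <- 0.99
      if (min(eigen(a, only.values = TRUE)$values) >= -1e-8) next
      b <- weighted_bending(a)
      expect_gte(min(eigen(b, symmetric = TRUE,
                           only.values = TRUE)$values), -1e-8)
      expect_equal(diag(b), diag(a), tolerance = 1e-10)
    }
  })
})

test_that("imprecise entries absorb more of the bending adjustment", {
  nm <- c("a", "b", "c")
  base <- matrix(c(1, 0.95, -0.95, 0.95, 1, 0.95, -0.95, 0.95, 1), 3, 3,
                 dimnames = list(nm, nm))
  make_gc <- function(var_ab) {
    v <- matrix(1, 3, 3, dimnames = list(nm, nm))
    v["a", "b"] <- v["b", "a"] <- var_ab
    structure(list(cov = base, var_of_est = v,
                   p = matrix(0, 3, 3, dimnames = list(nm, nm)),
                   zeroed = matrix(FALSE, 3, 3), bent = FALSE,
                   mean_abs_change = 0), class = "gencov")
  }
  low_var <- weighted_bending(make_gc(0.01))
  high_var <- weighted_bending(make_gc(100))
  move_low <- abs(low_var$cov["a", "b"] - base["a", "b"])
  move_high <- abs(high_var$cov["a", "b"] - base["a", "b"])
  expect_gt(move_high, move_low)
})

test_that("covariance-to-correlation normalization is exact and scale-free", {
  m <- matrix(c(4, 1, 1, 1), 2, 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  ctx <- cov_to_corr(m)
  expect_equal(unname(ctx$sigma), matrix(c(1, 0.5, 0.5, 1), 2, 2))

  # diagonal covariance: identity correlation
  d <- diag(c(2, 3, 4)); dimnames(d) <- list(letters[1:3], letters[1:3])
  expect_equal(unname(cov_to_corr(d)$sigma), diag(3))

  # scaling one trait's covariances leaves the correlation unchanged
  s <- diag(c(5, 1)); scaled <- s %*% m %*% s
  dimnames(scaled) <- dimnames(m)
  expect_equal(cov_to_corr(scaled)$sigma, cov_to_corr(m)$sigma,
               tolerance = 1e-12)

  bad <- m; bad[1, 1] <- -1
  expect_error(cov_to_corr(bad), "positive")
})

test_that("the full estimate-sparsify-bend-normalize chain yields a valid Sigma", {
  d3 <- local({
    panel <- simulate_panel(1200, 120, within_block_corr = c(0, 0.8),
                            seed = 71)
    spec <- metabolite_panel_spec(
      exchangeable_corr(3, 0.4),
      replicate(3, architecture_spec(h2 = 0.5, alpha = -0.25,
                                     n_samples = 5e4), simplify = FALSE))
    list(panel = panel,
         stats = simulate_metabolite_set(spec, panel, seed = 72)$sumstats)
  })
  gc <- gencov_matrix(d3$stats, d3$panel)
  ctx <- cov_to_corr(weighted_bending(sparsify(gc)))
  expect_equal(unname(diag(ctx$sigma)), rep(1, 3))
  expect_equal(ctx$sigma, t(ctx$sigma))
  expect_gte(ctx$min_eigenvalue, -1e-8)
})
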