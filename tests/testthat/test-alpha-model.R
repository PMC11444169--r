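test_that("expected per-SNP heritability is correctly normalized and MAF-weighted", {
  # alpha = -1: flat per-SNP heritability regardless of MAF
  p <- panel_from_maf(c(0.05, 0.2, 0.35, 0.5))
  m <- heritability_model(h2 = 0.8, alpha = -1)
  expect_equal(unname(expected_per_snp_h2(p, m)), rep(0.2, 4))

  # alpha = 0, two SNPs at f = 0.5 and 0.1: shares 0.5/0.68 and 0.18/0.68
  p2 <- panel_from_maf(c(0.5, 0.1))
  m2 <- heritability_model(h2 = 1, alpha = 0)
  expect_equal(unname(expected_per_snp_h2(p2, m2)),
               c(0.5, 0.18) / 0.68, tolerance = 1e-12)

  # sums to h2 exactly for arbitrary models
  p3 <- simulate_panel(200, 40, within_block_corr = 0.3, seed = 5)
  for (a in c(-1.5, -0.3, 0.7)) {
    expect_equal(sum(expected_per_snp_h2(
      p3, heritability_model(0.37, a))), 0.37, tolerance = 1e-12)
  }
})

test_that("annotation strata contribute additively and sum to h2", {
  maf <- c(0.1, 0.2, 0.3, 0.4)
  ann <- cbind(coding = c(1, 1, 0, 0), rest = c(0, 0, 1, 1))
  rownames(ann) <- sprintf("v%03d", 1:4)
  p <- snp_panel(tibble::tibble(variant_id = rownames(ann), maf = maf,
                                block_id = 1:4), annotations = ann)
  m <- heritability_model(h2 = 0.6, alpha = -1,
                          stratum_h2 = c(coding = 0.4, rest = 0.2))
  eh <- expected_per_snp_h2(p, m)
  expect_equal(sum(eh), 0.6, tolerance = 1e-12)
  # alpha = -1 flattens within stratum: 0.4 split over 2, 0.2 over 2
  expect_equal(unname(eh), c(0.2, 0.2, 0.1, 0.1))
  expect_error(heritability_model(0.6, 0, c(coding = 0.1, rest = 0.1)),
               "sum to h2")
})

test_that("expected chi-square includes LD dilution and is bounded below by 1", {
  p <- panel_from_maf(c(0.25, 0.25))
  expect_equal(unname(expected_chisq(p, heritability_model(0, 0), 1e5)),
               c(1, 1))

  # single SNP with E[h2_j] = 1e-4 at n = 10,000: e = 2
  p1 <- panel_from_maf(0.3)
  m1 <- heritability_model(h2 = 1e-4, alpha = 0)
  expect_equal(unname(expected_chisq(p1, m1, 1e4)), 2)

  # a null SNP in perfect LD with it sees the same expectation
  ids <- c("a", "b")
  r <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(ids, ids))
  p2 <- snp_panel(tibble::tibble(variant_id = ids, maf = c(0.3, 0.3),
                                 block_id = c(1, 1)),
                  blocks = list(`1` = r))
  e2 <- expected_chisq(p2, heritability_model(1e-4, 0), 1e4)
  expect_equal(unname(e2[1]), unname(e2[2]))
  expect_equal(unname(e2[1]), 2)

  p3 <- simulate_panel(300, 60, within_block_corr = 0.6, seed = 9)
  for (a in c(-1.2, 0, 0.5)) {
    expect_true(all(expected_chisq(
      p3, heritability_model(0.9, a), 5e4) >= 1))
  }
})

test_that("model log-likelihood matches its closed form and responds to fit", {
  m <- 7
  p <- panel_from_maf(rep(0.25, m))
  stats <- tibble::tibble(variant_id = p$variant_id, chisq = rep(1, m),
                          n = rep(1e4, m))
  ll <- model_loglik(stats, p, heritability_model(0, 0))
  expect_equal(ll, m * (-0.5 * log(2 * pi) - 0.5), tolerance = 1e-12)

  # inflated statistics prefer inflated expectations
  stats2 <- tibble::tibble(variant_id = p$variant_id, chisq = rep(25, m),
                           n = rep(1e5, m))
  ll_null <- model_loglik(stats2, p, heritability_model(0, 0))
  ll_fit <- model_loglik(stats2, p, heritability_model(0.5, 0))
  expect_gt(ll_fit, ll_null)
})

test_that("heritability profiling finds the boundary and the generative value", {
  p <- tiny_panel(400, seed = 3)
  # statistics all below 1: no inflation to explain, h2_hat exactly 0
  stats <- tibble::tibble(variant_id = p$variant_id,
                          chisq = runif(nrow(p), 0, 1), n = 1e4)
  fit0 <- fit_h2_given_alpha(stats, p, alpha = 0)
  expect_identical(fit0$h2_hat, 0)
  expect_gte(fit0$loglik_max, model_loglik(
    stats, p, heritability_model(0, 0)) - 1e-9)

  # recovery: data at h2 = 0.3, alpha = -0.25
  p2 <- simulate_panel(20000, 20000, seed = 71)
  b <- simulate_effects_alpha(p2, architecture_spec(
    h2 = 0.3, alpha = -0.25, n_samples = 5e4, seed = 72))
  ss <- simulate_sumstats(p2, b, 5e4, seed = 73)
  fit <- fit_h2_given_alpha(ss, p2, alpha = -0.25)
  expect_lt(abs(fit$h2_hat - 0.3), 0.05)
})

test_that("quadratic vertex and curvature match the closed form", {
  # exact concave quadratic: -(alpha + 0.5)^2 has vertex -0.5, SE sqrt(0.5)
  g <- seq(-1, 0.5, by = 0.05)
  qf <- quadratic_mle(g, -(g + 0.5)^2)
  expect_equal(qf$alpha_hat, -0.5, tolerance = 1e-10)
  expect_equal(qf$se, sqrt(0.5), tolerance = 1e-10)

  # generic quadratics, randomized coefficients
  withr::with_seed(10, {
    for (r in 1:20) {
      a <- -runif(1, 0.1, 50); b <- rnorm(1, 0, 5); cc <- rnorm(1)
      ll <- a * g^2 + b * g + cc
      qf <- quadratic_mle(g, ll)
      expect_equal(qf$alpha_hat, -b / (2 * a), tolerance = 1e-10)
      expect_equal(qf$se, sqrt(1 / (-2 * a)), tolerance = 1e-10)
    }
  })

  # convex input yields a withheld estimate
  expect_true(is.na(quadratic_mle(g, (g - 0.2)^2)$alpha_hat))
})

test_that("profile grid defaults to 31 points from -1 to 0.5", {
  p <- tiny_panel(250, seed = 6)
  ss <- simulate_sumstats(p, rep(0, nrow(p)), 1e3, seed = 7)
  fit <- profile_alpha(ss, p)
  full_grid <- fit$profile$alpha
  expect_length(full_grid, 31)
  expect_equal(full_grid[1], -1)
  expect_equal(full_grid[31], 0.5)
  expect_equal(unique(round(diff(full_grid), 10)), 0.05)
})

test_that("standard errors shrink with sample size (monotone information)", {
  p <- simulate_panel(8000, 8000, seed = 81)
  se_at <- function(n) {
    b <- simulate_effects_alpha(p, architecture_spec(
      h2 = 0.5, alpha = -0.25, n_samples = n, seed = 82))
    ss <- simulate_sumstats(p, b, n, seed = 83)
    profile_alpha(ss, p)$se_alpha
  }
  expect_lt(se_at(1e5), se_at(1e4))
})

test_that("Wald selection test matches the normal reference", {
  fit <- structure(list(alpha_hat = -1.37, se_alpha = 0.5, stable = TRUE),
                   class = "alpha_fit")
  res <- wald_selection_test(fit, n_tests = 97)
  expect_equal(res$z, -2.74)
  expect_equal(res$p, 2 * pnorm(-2.74), tolerance = 1e-12)
  expect_true(res$significant_nominal)
  expect_false(res$significant_bonferroni)  # 0.0061 > 0.05/97

  fit0 <- structure(list(alpha_hat = 0, se_alpha = 0.3, stable = TRUE),
                    class = "alpha_fit")
  res0 <- wald_selection_test(fit0)
  expect_equal(res0$p, 1)
  expect_false(res0$significant_nominal)

  # with a single test the two flags coincide
  res1 <- wald_selection_test(fit, n_tests = 1)
  expect_identical(res1$significant_nominal, res1$significant_bonferroni)

  unstable <- structure(list(alpha_hat = 1, se_alpha = 1, stable = FALSE),
                        class = "alpha_fit")
  expect_error(wald_selection_test(unstable), "stable")
})

test_that("range extension follows the boundary rules", {
  # data generated beyond the right boundary of the default grid
  p <- simulate_panel(10000, 10000, seed = 91)
  b <- simulate_effects_alpha(p, architecture_spec(
    h2 = 0.5, alpha = 1, n_samples = 5e4, seed = 92))
  ss <- simulate_sumstats(p, b, 5e4, seed = 93)
  fit <- profile_alpha(ss, p)
  expect_true(fit$extended["right"])
  expect_equal(fit$range_used, c(-1, 4))
  expect_lt(abs(fit$alpha_hat - 1), 0.3)

  # strong-selection data trip the left extension
  b2 <- simulate_effects_alpha(p, architecture_spec(
    h2 = 0.5, alpha = -1.3, n_samples = 5e4, seed = 94))
  ss2 <- simulate_sumstats(p, b2, 5e4, seed = 95)
  fit2 <- profile_alpha(ss2, p)
  expect_true(fit2$extended["left"])
  expect_equal(fit2$range_used, c(-2, 1))
})
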