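#' Simulate marginal GWAS summary statistics
#'
#' Per LD block, marginal z statistics are drawn from
#' \eqn{z \sim N(\sqrt{n}\, R\, \beta^*,\; R)}, where R is the block LD
#' correlation matrix and \eqn{\beta^*_j = b_j \sqrt{2 f_j (1-f_j)}} the
#' standardized-scale effects: LD both spreads signal onto correlated null
#' variants ("LD dilution") and correlates the noise. The chi-square
#' statistic is \eqn{S_j = z_j^2}.
#'
#' @param panel A [snp_panel()].
#' @param effects Per-allele effect vector aligned with the panel.
#' @param n GWAS sample size (scalar or per-variant).
#' @param seed Optional integer seed.
#' @return A `sumstats` tibble with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `maf`, `beta`, `se`, `z`, `chisq`, `n` (`beta`/`se` on
#'   the per-allele scale).
#' @export
simulate_sumstats <- function(panel, effects, n, seed = NULL) {
  assert_that(length(effects) == nrow(panel),
              "effects length must match the panel")
  assert_that(all(n > 0), "sample size must be positive")
  local_seed(seed)
  n <- rep_len(n, nrow(panel))

  het <- heterozygosity(panel$maf)
  beta_std <- effects * sqrt(het)
  blocks <- ld_blocks(panel)
  idx <- split(seq_len(nrow(panel)), panel$block_id)

  z <- numeric(nrow(panel))
  sizes <- lengths(idx)
  singles <- unlist(idx[sizes == 1L], use.names = FALSE)
  if (length(singles) > 0) {
    z[singles] <- sqrt(n[singles]) * beta_std[singles] +
      rnorm(length(singles))
  }
  multi <- names(idx)[sizes > 1L]
  pos <- match(multi, names(blocks))
  chol_cache <- list()
  for (k in seq_along(multi)) {
    i <- idx[[multi[k]]]
    r <- blocks[[pos[k]]]
    key <- digest_block(r)
    cf <- chol_cache[[key]]
    if (is.null(cf)) {
      cf <- chol(r + diag(1e-10, nrow(r)))
      chol_cache[[key]] <- cf
    }
    mu <- drop(r %*% (sqrt(n[i]) * beta_std[i]))
    z[i] <- mu + rmvnorm1(chol_sigma = cf)
  }

  se <- 1 / sqrt(n * het)
  out <- tibble::tibble(
    variant_id = panel$variant_id,
    effect_allele = "A",
    other_allele = "G",
    maf = panel$maf,
    beta = z * se,
    se = se,
    z = z,
    chisq = z^2,
    n = as.integer(round(n))
  )
  class(out) <- c("sumstats", class(out))
  out
}

# Cache key for exchangeable block matrices: size + off-diagonal value.
digest_block <- function(r) {
  k <- nrow(r)
  off <- if (k > 1) r[1, 2] else 0
  exch <- k == 1 || max(abs(r[upper.tri(r)] - off)) < 1e-14
  if (exch) sprintf("exch:%d:%.10g", k, off) else
    sprintf("gen:%d:%.10g", k, sum(r^2))
}

#' Simulate a correlated set of metabolite GWAS
#'
#' All metabolites share one causal variant set; per causal variant the
#' effect draws are mixed across metabolites through the Cholesky factor of
#' the genetic correlation matrix, so the genetic correlation between any
#' two metabolites equals the corresponding entry of `spec$genetic_corr`.
#' Each metabolite then gets its own marginal summary statistics.
#'
#' @param spec A [metabolite_panel_spec()].
#' @param panel A [snp_panel()].
#' @param seed Optional integer seed.
#' @return List with `sumstats` (named list of `sumstats` tibbles),
#'   `effects` (variants x metabolites per-allele matrix), `alpha` (true
#'   alpha per metabolite), `h2` (true heritability per metabolite), and
#'   `genetic_corr` (the generative matrix).
#' @export
simulate_metabolite_set <- function(spec, panel, seed = NULL) {
  stopifnot(inherits(spec, "metabolite_panel_spec"))
  local_seed(seed)
  k <- spec$n_metabolites
  n_snps <- nrow(panel)
  arch <- spec$per_metabolite_arch
  het <- heterozygosity(panel$maf)
  w <- panel$snp_weight

  m <- max(1L, round(arch[[1]]$prop_causal * n_snps))
  causal <- sample.int(n_snps, m)
  l_corr <- chol(spec$genetic_corr + diag(1e-10, k))

  # Correlated standard normal draws, then per-metabolite marginal scale.
  zmat <- matrix(rnorm(m * k), m, k) %*% l_corr
  effects <- matrix(0, n_snps, k,
                    dimnames = list(panel$variant_id, spec$names))
  for (j in seq_len(k)) {
    a <- arch[[j]]
    sd_j <- sqrt(a$h2 / sum(w[causal] * het[causal]^(a$alpha + 1)) *
                   w[causal] * het[causal]^a$alpha)
    effects[causal, j] <- sd_j * zmat[, j]
  }

  stats <- lapply(seq_len(k), function(j) {
    simulate_sumstats(panel, effects[, j], n = arch[[j]]$n_samples)
  })
  names(stats) <- spec$names

  list(sumstats = stats,
       effects = effects,
       alpha = setNames(vapply(arch, `[[`, numeric(1), "alpha"), spec$names),
       h2 = setNames(vapply(arch, `[[`, numeric(1), "h2"), spec$names),
       genetic_corr = spec$genetic_corr)
}

#' Simulate a two-sample Mendelian randomization dataset
#'
#' True instrument-exposure effects are
#' \eqn{\beta_X \sim N(0, exposure\_h2\_per\_instr)}; outcome effects are
#' \eqn{\beta_Y = \theta \beta_X + N(0, pleiotropy\_sd^2)}. Observed effects
#' add estimation noise with standard errors \eqn{1/\sqrt{n}} on the
#' standardized scale. Alleles are assigned (including occasional swapped
#' coding in the outcome source) so harmonization can be exercised.
#'
#' @param n_instruments Number of instruments (>= 1).
#' @param theta True causal effect of exposure on outcome.
#' @param exposure_h2_per_instr Variance of true per-instrument exposure
#'   effects (standardized scale).
#' @param n_exp,n_out Exposure and outcome GWAS sample sizes.
#' @param pleiotropy_sd SD of direct (pleiotropic) instrument-outcome
#'   effects; 0 for a valid-instrument design.
#' @param swap_fraction Fraction of instruments whose outcome record is
#'   coded on the other allele (harmonization must flip them back).
#' @param seed Optional integer seed.
#' @return List with `exposure` and `outcome` association tibbles
#'   (`variant_id`, `beta`, `se`, `effect_allele`, `other_allele`) and the
#'   true `theta`.
#' @export
simulate_mr_dataset <- function(n_instruments, theta,
                                exposure_h2_per_instr = 1e-3,
                                n_exp = 1e5, n_out = 1e5,
                                pleiotropy_sd = 0, swap_fraction = 0,
                                seed = NULL) {
  assert_that(n_instruments >= 1, "need at least one instrument")
  assert_that(exposure_h2_per_instr > 0,
              "exposure_h2_per_instr must be positive")
  assert_that(pleiotropy_sd >= 0, "pleiotropy_sd must be nonnegative")
  local_seed(seed)

  id <- sprintf("iv%04d", seq_len(n_instruments))
  bx_true <- rnorm(n_instruments, 0, sqrt(exposure_h2_per_instr))
  by_true <- theta * bx_true +
    (if (pleiotropy_sd > 0) rnorm(n_instruments, 0, pleiotropy_sd) else 0)
  se_x <- rep(1 / sqrt(n_exp), n_instruments)
  se_y <- rep(1 / sqrt(n_out), n_instruments)

  ea <- sample(c("A", "C"), n_instruments, replace = TRUE)
  oa <- ifelse(ea == "A", "G", "T")

  exposure <- tibble::tibble(
    variant_id = id,
    effect_allele = ea, other_allele = oa,
    beta = bx_true + rnorm(n_instruments, 0, se_x),
    se = se_x
  )
  swap <- runif(n_instruments) < swap_fraction
  outcome <- tibble::tibble(
    variant_id = id,
    effect_allele = ifelse(swap, oa, ea),
    other_allele = ifelse(swap, ea, oa),
    beta = (by_true + rnorm(n_instruments, 0, se_y)) * ifelse(swap, -1, 1),
    se = se_y
  )
  list(exposure = exposure, outcome = outcome, theta = theta)
}

#' Simulate Brownian-motion trait values on a phylogeny
#'
#' Tip values are multivariate normal with mean `root_value` and covariance
#' `rate * C(tree)`, where C is the shared root-to-tip branch-length matrix.
#'
#' @param tree An `ape` `phylo` tree with strictly positive branch lengths.
#' @param rate Brownian rate (variance per unit branch length, >= 0).
#' @param root_value Trait value at the root.
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm_traits <- function(tree, rate, root_value = 0, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  assert_that(!is.null(tree$edge.length) && all(tree$edge.length > 0),
              "tree must have strictly positive branch lengths")
  assert_that(rate >= 0, "rate must be nonnegative")
  local_seed(seed)
  tips <- tree$tip.label
  if (rate == 0) return(setNames(rep(root_value, length(tips)), tips))
  cmat <- ape::vcv(tree)
  x <- root_value + rmvnorm1(rate * cmat + diag(1e-12, nrow(cmat)))
  setNames(x, rownames(cmat))
}
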