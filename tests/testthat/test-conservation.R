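test_that("phylogenetic covariance matches shared path lengths", {
  # hand-checked 3-tip tree
  cm <- phylo_covariance(toy_tree())
  expect_equal(cm[c("A", "B", "C"), c("A", "B", "C")],
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
                      dimnames = list(c("A", "B", "C"),
                                      c("A", "B", "C"))))

  # star tree: diagonal t, zero off-diagonal
  cs <- phylo_covariance(star_tree(4, t = 2.5))
  expect_equal(unname(cs), diag(2.5, 4))

  # brute-force path-enumeration oracle on random trees
  withr::with_seed(17, {
    for (r in 1:10) {
      tr <- ape::rtree(sample(4:8, 1))
      expect_equal(phylo_covariance(tr)[tr$tip.label, tr$tip.label],
                   brute_force_vcv(tr), tolerance = 1e-12)
    }
  })

  expect_error(phylo_covariance(toy_tree(), tips = c("A", "Z")), "Z")
})

test_that("Brownian rate GLS matches the star-tree closed form", {
  # star tree: GLS reduces to sample mean and variance / branch length
  x <- c(t1 = 0, t2 = 1, t3 = 2)
  fit <- fit_bm_rate(phylo_covariance(star_tree(3, 1)), x)
  expect_equal(fit$root, 1, tolerance = 1e-12)
  expect_equal(fit$sigma2, 1, tolerance = 1e-12)

  withr::with_seed(23, {
    for (r in 1:8) {
      k <- sample(4:9, 1); t0 <- runif(1, 0.5, 3)
      xv <- rnorm(k)
      names(xv) <- sprintf("t%d", 1:k)
      fit <- fit_bm_rate(phylo_covariance(star_tree(k, t0)), xv)
      expect_equal(fit$sigma2, var(xv) / t0, tolerance = 1e-10)
      expect_equal(fit$root, mean(xv), tolerance = 1e-10)
    }
  })

  # constant values: zero rate, flagged degenerate
  fitc <- fit_bm_rate(phylo_covariance(star_tree(3, 1)),
                      c(t1 = 2, t2 = 2, t3 = 2))
  expect_equal(fitc$sigma2, 0)
  expect_true(fitc$degenerate)
})

test_that("rate recovery is unbiased on a 26-tip tree", {
  withr::with_seed(31, {
    tr <- ape::rtree(26)
    tr$edge.length <- tr$edge.length + 0.05
  })
  cm <- phylo_covariance(tr)
  for (rate in c(0.5, 2)) {
    est <- vapply(1:400, function(s) {
      fit_bm_rate(cm, simulate_bm_traits(tr, rate, seed = 7000 + s))$sigma2
    }, numeric(1))
    expect_lt(abs(mean(est) - rate), 3 * sd(est) / sqrt(length(est)))
  }
})

test_that("conservation scores invert the rate and respect missingness", {
  withr::with_seed(41, {
    tr <- ape::rtree(10)
    tr$edge.length <- tr$edge.length + 0.1
  })
  sp <- tr$tip.label
  conc <- tibble::tibble(metabolite = c("slow", "fast", "sparse"))
  vals_slow <- exp(simulate_bm_traits(tr, 0.5, seed = 1))
  vals_fast <- exp(simulate_bm_traits(tr, 2, seed = 2))
  for (s in sp) {
    conc[[s]] <- c(vals_slow[s], vals_fast[s], NA)
  }
  conc[sp[1:2]][3, ] <- list(1.5, 2.5)  # only 2 species measured

  res <- suppressMessages(conservation_scores(tr, conc, organ = "liver"))
  expect_equal(nrow(res), 2)              # sparse metabolite skipped
  expect_equal(res$score, 1 / res$sigma2)
  expect_message(conservation_scores(tr, conc), "sparse")

  # pruned-tree consistency: missing species equals fit on the subtree
  conc2 <- conc[1, ]
  conc2[[sp[1]]] <- NA
  res2 <- conservation_scores(tr, conc2, organ = "x")
  sub <- ape::keep.tip(tr, sp[-1])
  direct <- fit_bm_rate(phylo_covariance(sub),
                        setNames(log(as.numeric(conc[1, sp[-1]])),
                                 sp[-1]))
  expect_equal(res2$sigma2, direct$sigma2, tolerance = 1e-12)

  # score ordering tracks the generative rates most of the time
  orderings <- vapply(1:100, function(s) {
    a <- fit_bm_rate(phylo_covariance(tr),
                     simulate_bm_traits(tr, 0.5, seed = 100 + s))$sigma2
    b <- fit_bm_rate(phylo_covariance(tr),
                     simulate_bm_traits(tr, 2, seed = 5000 + s))$sigma2
    (1 / a) > (1 / b)
  }, logical(1))
  expect_gte(mean(orderings), 0.9)
})

test_that("aggregation imputes by median, ranks per organ and excludes singletons", {
  scores <- tibble::tibble(
    metabolite = rep(c("m1", "m2", "m3"), each = 2),
    organ = rep(c("o1", "o2"), 3),
    score = c(1, 10, 2, 20, 3, NA))
  # imputation mechanics on a 3 x 2 hand example (all metabolites kept):
  # m3's organ-2 entry is imputed to its cross-organ median 3, which ranks
  # 1st among (10, 20, 3); median ranks are (1.5, 2.5, 2)
  agg <- aggregate_conservation(scores, min_organs = 1)
  expect_equal(agg$aggregate_median_rank, c(1.5, 2.5, 2))
  expect_equal(agg$n_organs_measured, c(2, 2, 1))
  # default excludes the metabolite measured in a single organ
  expect_false("m3" %in% aggregate_conservation(scores)$metabolite)

  # a metabolite measured in one organ only is excluded
  scores1 <- dplyr::bind_rows(scores, tibble::tibble(
    metabolite = "only_once", organ = "o1", score = 99))
  agg1 <- aggregate_conservation(scores1)
  expect_false("only_once" %in% agg1$metabolite)

  expect_error(aggregate_conservation(scores, organs_subset = "o1"),
               "at least 2")

  # rank aggregation is invariant to monotone transforms of the scores
  # (the median imputation commutes with monotone maps)
  agg_def <- aggregate_conservation(scores)
  agg_log <- aggregate_conservation(
    dplyr::mutate(scores, score = log(score)))
  expect_equal(agg_log$aggregate_median_rank,
               agg_def$aggregate_median_rank)

  # reordering metabolites does not change the aggregate
  perm <- scores[c(5, 6, 1, 2, 3, 4), ]
  agg_perm <- aggregate_conservation(perm)
  expect_equal(dplyr::arrange(agg_perm, metabolite),
               dplyr::arrange(agg_def, metabolite))
})

test_that("leave-one-organ-out aggregates stay close to the full aggregate", {
  withr::with_seed(51, {
    organs <- c("brain", "heart", "kidney", "liver")
    scores <- tidyr::expand_grid(
      metabolite = sprintf("m%02d", 1:20), organ = organs)
    base <- rep(exp(rnorm(20)), each = 4)
    scores$score <- base * exp(rnorm(nrow(scores), 0, 0.2))
  })
  full <- aggregate_conservation(scores)
  for (drop_organ in organs) {
    loo <- aggregate_conservation(scores,
                                  organs_subset = setdiff(organs, drop_organ))
    merged <- dplyr::inner_join(full, loo, by = "metabolite")
    expect_gt(cor(merged$aggregate_median_rank.x,
                  merged$aggregate_median_rank.y, method = "spearman"),
              0.8)
  }
})
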