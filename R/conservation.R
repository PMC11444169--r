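#' Shared branch-length (Brownian) covariance of a phylogeny
#'
#' Under Brownian motion the covariance of two tips equals the branch length
#' their root-to-tip paths share; the diagonal holds root-to-tip distances.
#'
#' @param tree An `ape` `phylo` tree with branch lengths.
#' @param tips Optional subset of tip labels; the tree is pruned to them.
#' @return Covariance matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree, tips = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tips)) {
    missing <- setdiff(tips, tree$tip.label)
    assert_that(length(missing) == 0,
                sprintf("tips not in tree: %s",
                        paste(missing, collapse = ", ")))
    if (length(tips) < length(tree$tip.label)) {
      tree <- ape::keep.tip(tree, tips)
    }
  } else {
    tips <- tree$tip.label
  }
  cmat <- ape::vcv(tree)
  cmat[tips, tips, drop = FALSE]
}

#' Fit the Brownian-motion rate by generalized least squares
#'
#' The root state is the GLS mean
#' \eqn{\hat\mu = (1' C^{-1} x)/(1' C^{-1} 1)} and the rate
#' \eqn{\hat\sigma^2 = (x - \hat\mu 1)' C^{-1} (x - \hat\mu 1)/(n-1)}
#' (restricted-likelihood style n-1 denominator, unbiased under the model).
#'
#' @param C Tip covariance matrix from [phylo_covariance()].
#' @param x Tip-value vector (>= 3 values), aligned with `C` (by names when
#'   both are named).
#' @return List with `sigma2`, `root` and `n`; `degenerate = TRUE` when the
#'   residuals are exactly zero (rate 0, conservation score undefined).
#' @export
fit_bm_rate <- function(C, x) {
  assert_that(length(x) >= 3, "need at least 3 tip values")
  assert_that(nrow(C) == length(x), "C and x dimensions differ")
  if (!is.null(names(x)) && !is.null(rownames(C))) {
    assert_that(setequal(names(x), rownames(C)),
                "names of x do not match C")
    x <- x[rownames(C)]
  }
  cinv <- tryCatch(solve(C), error = function(e)
    abort("singular phylogenetic covariance matrix"))
  one <- rep(1, length(x))
  mu <- drop(one %*% cinv %*% x) / drop(one %*% cinv %*% one)
  res <- x - mu
  sigma2 <- drop(res %*% cinv %*% res) / (length(x) - 1)
  list(sigma2 = sigma2, root = mu, n = length(x),
       degenerate = sigma2 <= 0 || !is.finite(sigma2))
}

#' Per-metabolite conservation scores in one organ
#'
#' For each metabolite the tree is pruned to the species with measured
#' concentrations (at least 3 required), values are log-transformed by
#' default (relative concentrations live on a ratio scale), the
#' Brownian-motion rate is fitted and the conservation score is its inverse:
#' slowly evolving metabolites score high.
#'
#' @param tree An `ape` `phylo` tree whose tips are species.
#' @param concentrations Data frame with a `metabolite` column and one
#'   column per species; `NA` marks unmeasured species.
#' @param organ Organ label recorded in the output.
#' @param log_transform Log-transform concentrations before fitting
#'   (requires positive values).
#' @return Tibble with `metabolite`, `organ`, `n_species`, `sigma2`,
#'   `score`, `degenerate`. Metabolites with fewer than 3 measured species
#'   are skipped with a message.
#' @export
conservation_scores <- function(tree, concentrations, organ = "organ",
                                log_transform = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  assert_that("metabolite" %in% names(concentrations),
              "`concentrations` needs a metabolite column")
  species <- intersect(names(concentrations), tree$tip.label)
  assert_that(length(species) >= 3,
              "fewer than 3 species shared between tree and data")

  rows <- purrr::map_dfr(seq_len(nrow(concentrations)), function(i) {
    met <- concentrations$metabolite[i]
    vals <- setNames(as.numeric(unlist(concentrations[i, species])),
                     species)
    keep <- !is.na(vals)
    if (sum(keep) < 3) {
      inform(sprintf(
        "conservation_scores: skipping %s in %s (<3 measured species)",
        met, organ))
      return(NULL)
    }
    x <- vals[keep]
    if (log_transform) {
      assert_that(all(x > 0),
                  sprintf("%s: log transform requires positive values", met))
      x <- log(x)
    }
    cmat <- phylo_covariance(tree, names(x))
    fit <- fit_bm_rate(cmat, x)
    tibble::tibble(metabolite = met, organ = organ,
                   n_species = fit$n, sigma2 = fit$sigma2,
                   score = ifelse(fit$degenerate, NA_real_, 1 / fit$sigma2),
                   degenerate = fit$degenerate)
  })
  rows
}

#' Aggregate conservation scores across organs
#'
#' Missing organ entries are imputed by the metabolite's median score over
#' the organs in which it was measured; scores are then ranked across the
#' metabolome within each organ (average ranks on ties, higher score =
#' higher rank) and the median rank across organs is the aggregate
#' conservation measure. Metabolites measured in at most one organ are
#' excluded. `organs_subset` restricts the aggregation (for leave-one-out
#' robustness checks).
#'
#' @param scores Long tibble with columns `metabolite`, `organ`, `score`
#'   (e.g. rows of [conservation_scores()] bound together).
#' @param organs_subset Optional subset of organs (>= 2).
#' @param min_organs Minimum number of organs a metabolite must be measured
#'   in to enter the aggregate (default 2, i.e. more than one organ; set to
#'   1 to aggregate every metabolite with any measurement).
#' @return Tibble with `metabolite`, `aggregate_median_rank`, `rank_sd`,
#'   `n_organs_measured`.
#' @export
aggregate_conservation <- function(scores, organs_subset = NULL,
                                   min_organs = 2) {
  need <- c("metabolite", "organ", "score")
  assert_that(all(need %in% names(scores)),
              "`scores` needs metabolite, organ, score")
  organs <- organs_subset %||% unique(scores$organ)
  assert_that(length(organs) >= 2, "need at least 2 organs to aggregate")
  scores <- dplyr::filter(scores, .data$organ %in% organs,
                          !is.na(.data$score))

  measured <- scores |>
    dplyr::count(.data$metabolite, name = "n_organs_measured") |>
    dplyr::filter(.data$n_organs_measured >= min_organs)
  scores <- dplyr::semi_join(scores, measured, by = "metabolite")
  assert_that(nrow(scores) > 0,
              "no metabolite measured in more than one organ")

  full <- tidyr::expand_grid(metabolite = unique(scores$metabolite),
                             organ = organs) |>
    dplyr::left_join(scores, by = c("metabolite", "organ")) |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::mutate(score = ifelse(is.na(.data$score),
                                 median(.data$score, na.rm = TRUE),
                                 .data$score)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$organ) |>
    dplyr::mutate(rank = rank(.data$score, ties.method = "average")) |>
    dplyr::ungroup()

  full |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(aggregate_median_rank = median(.data$rank),
                     rank_sd = sd(.data$rank), .groups = "drop") |>
    dplyr::left_join(measured, by = "metabolite")
}
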