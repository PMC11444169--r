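#' Construct a SNP panel
#'
#' A SNP panel is a tibble with one row per variant (`variant_id`, `maf`,
#' `block_id`, `ld_score`, `snp_weight`) carrying the LD-block correlation
#' matrices as an attribute. The LD score of variant j is
#' \eqn{\ell_j = \sum_l r_{jl}^2} over its block (including the unit
#' self-correlation, so \eqn{\ell_j \ge 1}), and the default SNP weight is
#' \eqn{\omega_j = 1/\ell_j}, inversely proportional to the LD score.
#'
#' @param variants A data frame with columns `variant_id`, `maf`, `block_id`.
#' @param blocks Named list of per-block correlation matrices; names are block
#'   ids, dimnames are variant ids. If `NULL`, all variants are treated as
#'   independent (identity blocks).
#' @param annotations Optional numeric matrix (variants x categories) with
#'   rownames matching `variant_id`.
#' @param weights `"inverse_ld"` (default) sets \eqn{\omega_j = 1/\ell_j};
#'   `"unit"` sets \eqn{\omega_j = 1} (the equal-weights architecture, which
#'   is also what LD-score regression assumes of the generative model).
#'
#' @return A tibble of class `snp_panel` with attributes `blocks` and
#'   `annotations`.
#' @export
snp_panel <- function(variants, blocks = NULL, annotations = NULL,
                      weights = c("inverse_ld", "unit")) {
  weights <- match.arg(weights)
  variants <- tibble::as_tibble(variants)
  assert_that(all(c("variant_id", "maf", "block_id") %in% names(variants)),
              "`variants` needs columns variant_id, maf, block_id")
  assert_that(!anyDuplicated(variants$variant_id),
              "duplicate variant ids in panel")
  assert_that(all(variants$maf > 0 & variants$maf <= 0.5),
              "MAF must lie in (0, 0.5]")

  ids_by_block <- split(variants$variant_id, variants$block_id)
  if (is.null(blocks)) {
    blocks <- lapply(ids_by_block, function(ids) {
      m <- diag(length(ids))
      dimnames(m) <- list(ids, ids)
      m
    })
    names(blocks) <- names(ids_by_block)
  }
  assert_that(setequal(names(blocks), names(ids_by_block)),
              "block matrices do not match block ids in panel")
  for (b in names(blocks)) {
    m <- blocks[[b]]
    ids <- ids_by_block[[b]]
    assert_that(is.matrix(m) && nrow(m) == length(ids) &&
                  setequal(rownames(m), ids),
                sprintf("block %s matrix does not match its variants", b))
    blocks[[b]] <- m[ids, ids, drop = FALSE]
    validate_block_corr(blocks[[b]], b)
  }

  ld <- do.call(c, unname(lapply(blocks, function(m) rowSums(m^2))))
  variants$ld_score <- unname(ld[variants$variant_id])
  variants$snp_weight <- if (weights == "unit") {
    rep(1, nrow(variants))
  } else {
    1 / variants$ld_score
  }

  if (!is.null(annotations)) {
    annotations <- as.matrix(annotations)
    assert_that(!is.null(rownames(annotations)) &&
                  setequal(rownames(annotations), variants$variant_id),
                "annotation rownames must match variant ids")
    annotations <- annotations[variants$variant_id, , drop = FALSE]
  }

  structure(variants,
            blocks = blocks,
            annotations = annotations,
            cache = new.env(parent = emptyenv()),
            class = c("snp_panel", class(variants)))
}

validate_block_corr <- function(m, label = "") {
  if (nrow(m) == 1L) {
    assert_that(abs(m[1, 1] - 1) < 1e-10,
                sprintf("block %s correlation matrix has non-unit diagonal",
                        label))
    return(invisible(TRUE))
  }
  assert_that(max(abs(m - t(m))) < 1e-10,
              sprintf("block %s correlation matrix is not symmetric", label))
  assert_that(max(abs(diag(m) - 1)) < 1e-10,
              sprintf("block %s correlation matrix has non-unit diagonal", label))
  assert_that(min_eigenvalue(m) >= -1e-8,
              sprintf("block %s correlation matrix is not positive semidefinite",
                      label))
  invisible(TRUE)
}

#' @export
ld_blocks <- function(panel) attr(panel, "blocks")

#' @export
panel_annotations <- function(panel) attr(panel, "annotations")

#' Simulate a SNP panel with block-exchangeable LD
#'
#' MAFs are drawn uniformly on `[maf_low, maf_high]`; variants are split into
#' `n_blocks` contiguous blocks of near-equal size, each with an exchangeable
#' correlation matrix (off-diagonal `within_block_corr`). LD scores and SNP
#' weights follow from the block matrices.
#'
#' @param n_snps,n_blocks Panel size and number of LD blocks
#'   (`n_snps >= n_blocks >= 1`).
#' @param maf_low,maf_high MAF range, `0 < maf_low <= maf_high <= 0.5`.
#' @param within_block_corr Within-block correlation, `|r| < 1`. A scalar
#'   gives every block the same exchangeable correlation; a length-2 range
#'   draws each block's correlation uniformly from it, so LD scores vary
#'   across blocks (as LD-score regression requires). Must keep every block
#'   matrix positive semidefinite (`r >= -1/(block size - 1)`).
#' @param seed Optional integer seed; the same seed reproduces the panel
#'   exactly.
#'
#' @return A [snp_panel()].
#' @examples
#' p <- simulate_panel(100, 20, within_block_corr = 0.3, seed = 1)
#' @export
simulate_panel <- function(n_snps, n_blocks,
                           maf_low = 0.01, maf_high = 0.5,
                           within_block_corr = 0, seed = NULL,
                           weights = c("inverse_ld", "unit")) {
  assert_that(n_snps >= n_blocks && n_blocks >= 1,
              "need n_snps >= n_blocks >= 1")
  assert_that(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5,
              "need 0 < maf_low <= maf_high <= 0.5")
  assert_that(length(within_block_corr) %in% c(1, 2) &&
                all(abs(within_block_corr) < 1),
              "need |within_block_corr| < 1 (scalar or length-2 range)")
  local_seed(seed)

  block_id <- sort(rep_len(seq_len(n_blocks), n_snps))
  max_size <- max(tabulate(block_id))
  if (max_size > 1 &&
      min(within_block_corr) < -1 / (max_size - 1) + 1e-12) {
    abort(sprintf(
      "within_block_corr = %g makes blocks of size %d non positive semidefinite",
      min(within_block_corr), max_size))
  }

  variants <- tibble::tibble(
    variant_id = sprintf("rs%06d", seq_len(n_snps)),
    maf = runif(n_snps, maf_low, maf_high),
    block_id = block_id
  )
  rho_for_block <- if (length(within_block_corr) == 2) {
    runif(n_blocks, within_block_corr[1], within_block_corr[2])
  } else {
    rep(within_block_corr, n_blocks)
  }
  ids_by_block <- split(variants$variant_id, block_id)
  blocks <- lapply(seq_along(ids_by_block), function(b) {
    ids <- ids_by_block[[b]]
    k <- length(ids)
    m <- matrix(rho_for_block[b], k, k)
    diag(m) <- 1
    dimnames(m) <- list(ids, ids)
    m
  })
  names(blocks) <- names(ids_by_block)
  snp_panel(variants, blocks, weights = weights)
}
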