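#' Read and write GWAS summary statistics
#'
#' Tab-separated with header `SNP A1 A2 MAF BETA SE Z N`; `BETA`/`SE` are on
#' the per-allele scale, `Z = BETA/SE`, and the chi-square statistic is
#' reconstructed as `Z^2` on reading.
#'
#' @param stats A `sumstats` tibble (see [simulate_sumstats()]).
#' @param path File path.
#' @return `write_sumstats` returns `path` invisibly; `read_sumstats`
#'   returns a `sumstats` tibble.
#' @export
write_sumstats <- function(stats, path) {
  out <- tibble::tibble(SNP = stats$variant_id,
                        A1 = stats$effect_allele,
                        A2 = stats$other_allele,
                        MAF = stats$maf,
                        BETA = stats$beta,
                        SE = stats$se,
                        Z = stats$z,
                        N = stats$n)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  out <- tibble::tibble(variant_id = raw$SNP,
                        effect_allele = raw$A1,
                        other_allele = raw$A2,
                        maf = raw$MAF,
                        beta = raw$BETA,
                        se = raw$SE,
                        z = raw$Z,
                        chisq = raw$Z^2,
                        n = as.integer(raw$N))
  class(out) <- c("sumstats", class(out))
  out
}

#' Write and read a SNP panel (LD scores, weights, blocks, MAF)
#'
#' Two artifacts in `dir`: `ldscores.tsv` with columns
#' `SNP L2 WEIGHT BLOCK MAF`, and the block LD matrices as dense
#' tab-separated files `block_<id>.tsv` (variant ids as header) listed in
#' `blocks_manifest.tsv` (`BLOCK FILE SIZE`).
#'
#' @param panel A [snp_panel()].
#' @param dir Directory (created if missing).
#' @return `write_panel` returns `dir` invisibly; `read_panel` a
#'   [snp_panel()].
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tibble::tibble(SNP = panel$variant_id,
                                  L2 = panel$ld_score,
                                  WEIGHT = panel$snp_weight,
                                  BLOCK = panel$block_id,
                                  MAF = panel$maf),
                   file.path(dir, "ldscores.tsv"))
  blocks <- ld_blocks(panel)
  manifest <- tibble::tibble(
    BLOCK = names(blocks),
    FILE = sprintf("block_%s.tsv", names(blocks)),
    SIZE = vapply(blocks, nrow, integer(1)))
  for (i in seq_len(nrow(manifest))) {
    write_matrix_tsv(blocks[[manifest$BLOCK[i]]],
                     file.path(dir, manifest$FILE[i]))
  }
  readr::write_tsv(manifest, file.path(dir, "blocks_manifest.tsv"))
  invisible(dir)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  ld <- readr::read_tsv(file.path(dir, "ldscores.tsv"),
                        show_col_types = FALSE)
  manifest <- readr::read_tsv(file.path(dir, "blocks_manifest.tsv"),
                              show_col_types = FALSE,
                              col_types = readr::cols(
                                BLOCK = readr::col_character()))
  blocks <- lapply(seq_len(nrow(manifest)), function(i) {
    read_matrix_tsv(file.path(dir, manifest$FILE[i]))
  })
  names(blocks) <- manifest$BLOCK
  snp_panel(tibble::tibble(variant_id = ld$SNP, maf = ld$MAF,
                           block_id = ld$BLOCK),
            blocks)
}

#' Write and read a square matrix as TSV with dimnames
#'
#' First column `ID` holds rownames; remaining columns are named by the
#' column ids.
#'
#' @param m Matrix with dimnames.
#' @param path File path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "ID")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$ID
  m
}

#' Write and read per-organ concentration tables
#'
#' Rows are metabolites, columns species; empty cells mark missing
#' measurements.
#'
#' @param concentrations Data frame with `metabolite` plus species columns.
#' @param path File path.
#' @export
write_concentrations <- function(concentrations, path) {
  readr::write_tsv(concentrations, path, na = "")
  invisible(path)
}

#' @rdname write_concentrations
#' @export
read_concentrations <- function(path) {
  readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE)
}

#' Write a correlation/covariance matrix with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records the minimum eigenvalue, bending and
#' zeroing diagnostics.
#'
#' @param covmat A `gencov` object or matrix.
#' @param path TSV path for the matrix.
#' @export
write_gencov <- function(covmat, path) {
  if (inherits(covmat, "gencov")) {
    write_matrix_tsv(covmat$cov, path)
    meta <- list(min_eigenvalue = min_eigenvalue(covmat$cov),
                 bent = covmat$bent,
                 mean_abs_change = covmat$mean_abs_change,
                 n_zeroed = sum(covmat$zeroed) / 2)
  } else {
    m <- as_sigma_matrix(covmat)
    write_matrix_tsv(m, path)
    meta <- list(min_eigenvalue = min_eigenvalue(m))
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read and write per-source association records for MR
#'
#' Tab-separated with header `SNP A1 A2 BETA SE` (standardized scale), the
#' minimal inputs [harmonize()] needs from each side.
#'
#' @param records Tibble with `variant_id`, `beta`, `se`, `effect_allele`,
#'   `other_allele`.
#' @param path File path.
#' @export
write_mr_records <- function(records, path) {
  readr::write_tsv(tibble::tibble(SNP = records$variant_id,
                                  A1 = records$effect_allele,
                                  A2 = records$other_allele,
                                  BETA = records$beta,
                                  SE = records$se), path)
  invisible(path)
}

#' @rdname write_mr_records
#' @export
read_mr_records <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::tibble(variant_id = raw$SNP, effect_allele = raw$A1,
                 other_allele = raw$A2, beta = raw$BETA, se = raw$SE)
}

#' Read and write trees in Newick format
#'
#' Thin wrappers over `ape` so pipeline artifacts stay text-only.
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_tree_newick
#' @export
read_tree_newick <- function(path) {
  ape::read.tree(path)
}
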