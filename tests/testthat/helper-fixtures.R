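# Shared fixtures, built in code.

# Small independent-SNP panel.
tiny_panel <- function(n = 300, seed = 42, ...) {
  simulate_panel(n, n, seed = seed, ...)
}

# Panel with explicit MAFs and no LD (unit weights).
panel_from_maf <- function(maf) {
  snp_panel(tibble::tibble(
    variant_id = sprintf("v%03d", seq_along(maf)),
    maf = maf,
    block_id = seq_along(maf)))
}

# Deterministic small rooted tree with branch lengths.
toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}

# Star tree: k tips all attached to the root at distance t.
star_tree <- function(k, t = 1) {
  txt <- paste0("(", paste(sprintf("t%d:%.17g", seq_len(k), t),
                           collapse = ","), ");")
  ape::read.tree(text = txt)
}

# Brute-force Brownian covariance: shared branch length of root-to-tip
# paths, enumerated edge by edge.
brute_force_vcv <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  root <- n + 1L
  path_edges <- function(tip) {
    edges <- integer(0)
    node <- tip
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0) break
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
      if (node == root) break
    }
    edges
  }
  paths <- lapply(seq_len(n), path_edges)
  out <- matrix(0, n, n, dimnames = list(tips, tips))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(paths[[i]], paths[[j]])
      out[i, j] <- sum(tree$edge.length[shared])
    }
  }
  out
}

# Aligned per-metabolite inputs for the correlation-adjusted tests.
exchangeable_corr <- function(n, rho) {
  m <- matrix(rho, n, n)
  diag(m) <- 1
  m
}
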