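# Configuration-driven orchestration of the full synthetic analysis:
# simulate -> alpha -> gencorr -> mr -> conserve -> stats.

pipeline_stages <- c("simulate", "alpha", "gencorr", "mr", "conserve",
                     "stats")

config_defaults <- function() {
  list(
    stages = paste(pipeline_stages, collapse = ","),
    seed = 1,
    # panel + architectures: LD blocks with heterogeneous correlation so
    # LD scores vary (LD-score regression needs a non-degenerate design)
    n_snps = 6000, n_blocks = 750, maf_low = 0.01, maf_high = 0.5,
    within_block_corr_lo = 0, within_block_corr_hi = 0.7,
    panel_weights = "unit", prop_causal = 1,
    n_metabolites = 12, n_samples = 50000, h2 = 0.5,
    alpha_lo = -0.9, alpha_hi = 0.3, sigma_offdiag = 0.2,
    n_classes = 4,
    # profile-likelihood grid
    grid_lo = -1, grid_hi = 0.5, grid_step = 0.05,
    # thresholds
    p_zero_threshold = 0.05, mr_filter_threshold = 0.5, fdr = 0.05,
    bend_tol = 1e-8,
    # MR design
    n_traits = 4, n_instruments = 30, mr_theta_scale = 0.4,
    mr_theta_noise = 0.05, mr_pleiotropy_sd = 0.02,
    mr_n_exp = 1e5, mr_n_out = 1e5, mr_h2_per_instr = 1e-3,
    # cross-species design
    n_species = 26, organs = "brain,heart,kidney,liver",
    rate_link_intercept = 0, rate_link_slope = 1.5,
    # required
    out_dir = NULL
  )
}

config_required <- "out_dir"

#' Validate a pipeline configuration file
#'
#' Flat `key = value` text format (one pair per line, `#` comments).
#' Unknown keys produce warnings; missing required keys and out-of-range
#' values produce errors; everything else gets a documented default (the
#' profile grid runs from -1 to 0.5 in steps of 0.05, the overlap filter
#' removes causal effects above 0.5 in absolute value, non-significant
#' genetic covariances are zeroed at P > 0.05 and slopes are FDR-flagged
#' at 5%).
#'
#' @param path Path to the config file.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(path) {
  assert_that(file.exists(path), sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  config <- config_defaults()
  for (ln in lines) {
    assert_that(grepl("=", ln, fixed = TRUE),
                sprintf("malformed config line (expected key = value): %s", ln))
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(config)) {
      warn(sprintf("validate_config: unknown key '%s' ignored", key))
      next
    }
    default <- config_defaults()[[key]]
    config[[key]] <- if (is.numeric(default)) {
      num <- suppressWarnings(as.numeric(val))
      assert_that(!is.na(num),
                  sprintf("malformed numeric value for %s: '%s'", key, val))
      num
    } else val
  }
  for (key in config_required) {
    assert_that(!is.null(config[[key]]),
                sprintf("missing required config key: %s", key))
  }
  config$stage_list <- trimws(strsplit(config$stages, ",")[[1]])
  bad <- setdiff(config$stage_list, pipeline_stages)
  assert_that(length(bad) == 0,
              sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  config$organ_list <- trimws(strsplit(config$organs, ",")[[1]])
  assert_that(length(config$organ_list) >= 2, "need at least 2 organs")
  assert_that(config$grid_step > 0, "grid_step must be positive")
  assert_that(config$grid_lo < config$grid_hi,
              "grid_lo must be below grid_hi")
  assert_that(config$p_zero_threshold >= 0 && config$p_zero_threshold <= 1,
              "p_zero_threshold must lie in [0, 1]")
  assert_that(config$fdr > 0 && config$fdr < 1, "fdr must lie in (0, 1)")
  assert_that(config$mr_filter_threshold > 0,
              "mr_filter_threshold must be positive")
  assert_that(config$maf_low > 0 && config$maf_low <= config$maf_high &&
                config$maf_high <= 0.5, "invalid MAF range")
  assert_that(config$panel_weights %in% c("unit", "inverse_ld"),
              "panel_weights must be 'unit' or 'inverse_ld'")
  assert_that(config$n_metabolites >= 2, "need at least 2 metabolites")
  assert_that(config$n_classes >= 2 &&
                config$n_classes <= config$n_metabolites,
              "n_classes must lie in [2, n_metabolites]")
  class(config) <- "run_config"
  config
}

stage_seed <- function(config, stage) {
  as.integer(config$seed * 101 + match(stage, pipeline_stages))
}

require_artifact <- function(path, stage) {
  assert_that(file.exists(path),
              sprintf("stage '%s' needs missing artifact: %s", stage, path))
  path
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in dependency order, writing per-stage
#' tab-separated outputs plus a machine-readable JSON report under
#' `config$out_dir`. All randomness derives deterministically from
#' `config$seed` (one sub-seed per stage), so identical configurations give
#' identical outputs.
#'
#' The synthetic design links the generative quantities the way the
#' scientific question expects: each metabolite's Brownian rate grows with
#' its generative alpha (so strong stabilizing selection means slow
#' cross-species evolution) and causal effects on traits grow as alpha
#' decreases, so the reported alpha-vs-conservation slope is negative when
#' the estimators work.
#'
#' @param config A `run_config` from [validate_config()].
#' @return The run report (also written to `report.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% config$stage_list]
  report <- list(package_version = as.character(utils::packageVersion("metselect")),
                 seed = config$seed, stages = stages, counts = list())

  for (stage in stages) {
    report <- switch(stage,
      simulate = stage_simulate(config, out, report),
      alpha = stage_alpha(config, out, report),
      gencorr = stage_gencorr(config, out, report),
      mr = stage_mr(config, out, report),
      conserve = stage_conserve(config, out, report),
      stats = stage_stats(config, out, report))
  }
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

true_alphas <- function(config) {
  seq(config$alpha_lo, config$alpha_hi,
      length.out = config$n_metabolites)
}

stage_simulate <- function(config, out, report) {
  seed <- stage_seed(config, "simulate")
  rho <- c(config$within_block_corr_lo, config$within_block_corr_hi)
  if (rho[1] == rho[2]) rho <- rho[1]
  panel <- simulate_panel(config$n_snps, config$n_blocks,
                          config$maf_low, config$maf_high,
                          rho, seed = seed,
                          weights = config$panel_weights)
  write_panel(panel, file.path(out, "panel"))

  alphas <- true_alphas(config)
  k <- config$n_metabolites
  sig <- matrix(config$sigma_offdiag, k, k); diag(sig) <- 1
  arch <- lapply(alphas, function(a)
    architecture_spec(h2 = config$h2, alpha = a,
                      prop_causal = config$prop_causal,
                      n_samples = config$n_samples))
  spec <- metabolite_panel_spec(sig, arch)
  set <- simulate_metabolite_set(spec, panel, seed = seed + 1)

  dir.create(file.path(out, "sumstats"), showWarnings = FALSE)
  for (nm in names(set$sumstats)) {
    write_sumstats(set$sumstats[[nm]],
                   file.path(out, "sumstats", paste0(nm, ".tsv")))
  }

  classes <- tibble::tibble(
    metabolite = spec$names,
    class = sprintf("class%d", rep_len(seq_len(config$n_classes), k)))
  readr::write_tsv(classes, file.path(out, "classes.tsv"))

  # Cross-species data: BM rate tied to the generative alpha.
  withr::with_seed(seed + 2, {
    tree <- ape::rtree(config$n_species,
                       tip.label = sprintf("sp%02d", seq_len(config$n_species)))
    tree$edge.length <- tree$edge.length + 0.05
    write_tree_newick(tree, file.path(out, "tree.newick"))
    rates <- exp(config$rate_link_intercept +
                   config$rate_link_slope * alphas)
    for (organ in config$organ_list) {
      conc <- purrr::map_dfr(seq_len(k), function(j) {
        x <- exp(simulate_bm_traits(tree, rates[j], root_value = 0))
        tibble::as_tibble(as.list(x)) |>
          dplyr::mutate(metabolite = spec$names[j], .before = 1)
      })
      write_concentrations(conc,
                           file.path(out, sprintf("concentrations_%s.tsv",
                                                  organ)))
    }
  })

  # MR inputs: causal effects on traits grow as alpha decreases.
  withr::with_seed(seed + 3, {
    dir.create(file.path(out, "mr_input"), showWarnings = FALSE)
    truth <- tidyr::expand_grid(metabolite = spec$names,
                                trait = sprintf("trait%02d",
                                                seq_len(config$n_traits)))
    truth$theta <- -config$mr_theta_scale *
      alphas[match(truth$metabolite, spec$names)] +
      rnorm(nrow(truth), 0, config$mr_theta_noise)
    for (i in seq_len(nrow(truth))) {
      ds <- simulate_mr_dataset(config$n_instruments, truth$theta[i],
                                exposure_h2_per_instr = config$mr_h2_per_instr,
                                n_exp = config$mr_n_exp,
                                n_out = config$mr_n_out,
                                pleiotropy_sd = config$mr_pleiotropy_sd)
      base <- file.path(out, "mr_input",
                        sprintf("%s__%s", truth$metabolite[i],
                                truth$trait[i]))
      write_mr_records(ds$exposure, paste0(base, "__exposure.tsv"))
      write_mr_records(ds$outcome, paste0(base, "__outcome.tsv"))
    }
    readr::write_tsv(truth, file.path(out, "mr_truth.tsv"))
  })

  jsonlite::write_json(
    list(alpha = as.list(setNames(alphas, spec$names)), h2 = config$h2,
         rates = as.list(setNames(exp(config$rate_link_intercept +
                                        config$rate_link_slope * alphas),
                                  spec$names))),
    file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

  report$counts$n_snps <- nrow(panel)
  report$counts$n_metabolites <- k
  inform(sprintf("simulate: %d variants, %d metabolites", nrow(panel), k))
  report
}

read_metabolite_stats <- function(out, stage) {
  dir <- require_artifact(file.path(out, "sumstats"), stage)
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  assert_that(length(files) > 0,
              sprintf("stage '%s' needs missing artifact: %s/*.tsv",
                      stage, dir))
  stats <- lapply(files, read_sumstats)
  names(stats) <- sub("\\.tsv$", "", basename(files))
  stats
}

stage_alpha <- function(config, out, report) {
  panel <- read_panel(require_artifact(file.path(out, "panel"), "alpha"))
  stats <- read_metabolite_stats(out, "alpha")
  rep_tbl <- fit_alpha_report(stats, panel, config$grid_lo, config$grid_hi,
                              config$grid_step)
  readr::write_tsv(rep_tbl, file.path(out, "alpha_report.tsv"))
  dir.create(file.path(out, "profiles"), showWarnings = FALSE)
  fits <- attr(rep_tbl, "fits")
  for (nm in names(fits)) {
    readr::write_csv(fits[[nm]]$profile[, c("alpha", "loglik")],
                     file.path(out, "profiles", paste0(nm, ".csv")))
  }
  report$counts$n_stable_fits <- sum(rep_tbl$stable)
  inform(sprintf("alpha: %d/%d stable fits", sum(rep_tbl$stable),
                 nrow(rep_tbl)))
  report
}

stage_gencorr <- function(config, out, report) {
  panel <- read_panel(require_artifact(file.path(out, "panel"), "gencorr"))
  stats <- read_metabolite_stats(out, "gencorr")
  gc <- gencov_matrix(stats, panel)
  # metabolites with nonpositive estimated heritability cannot enter a
  # correlation matrix; drop them (the real-data analogue: traits whose
  # summary statistics do not support heritability estimation are unusable)
  usable <- which(diag(gc$cov) > 0)
  if (length(usable) < nrow(gc$cov)) {
    inform(sprintf("gencorr: dropping %d metabolite(s) with nonpositive h2",
                   nrow(gc$cov) - length(usable)))
    gc$cov <- gc$cov[usable, usable]
    gc$var_of_est <- gc$var_of_est[usable, usable]
    gc$p <- gc$p[usable, usable]
    gc$zeroed <- gc$zeroed[usable, usable]
  }
  assert_that(length(usable) >= 2,
              "fewer than 2 metabolites with positive estimated h2")
  gc <- sparsify(gc, config$p_zero_threshold)
  gc <- weighted_bending(gc, tol = config$bend_tol)
  write_gencov(gc, file.path(out, "gencov.tsv"))
  ctx <- cov_to_corr(gc)
  write_gencov(ctx, file.path(out, "sigma.tsv"))
  report$counts$n_zeroed_covariances <- sum(gc$zeroed) / 2
  report$gencorr <- list(bent = gc$bent,
                         mean_abs_change = gc$mean_abs_change,
                         min_eigenvalue = ctx$min_eigenvalue)
  inform(sprintf("gencorr: %d covariances zeroed, min eigenvalue %.3g",
                 sum(gc$zeroed) / 2, ctx$min_eigenvalue))
  report
}

stage_mr <- function(config, out, report) {
  dir <- require_artifact(file.path(out, "mr_input"), "mr")
  exp_files <- list.files(dir, pattern = "__exposure\\.tsv$",
                          full.names = TRUE)
  estimates <- purrr::map_dfr(exp_files, function(f) {
    base <- sub("__exposure\\.tsv$", "", basename(f))
    parts <- strsplit(base, "__", fixed = TRUE)[[1]]
    iv <- harmonize(read_mr_records(f),
                    read_mr_records(file.path(dir, paste0(
                      base, "__outcome.tsv"))))
    dplyr::mutate(ivw_estimate(iv), metabolite = parts[1],
                  trait = parts[2], .before = 1)
  })
  estimates <- filter_large_effects(estimates, config$mr_filter_threshold)
  readr::write_tsv(estimates, file.path(out, "mr_estimates.tsv"))
  imp <- importance_scores(estimates)
  readr::write_tsv(imp, file.path(out, "mr_importance.tsv"))
  report$counts$n_mr_estimates <- nrow(estimates)
  report$counts$n_mr_filtered <- sum(estimates$filtered_overlap)
  inform(sprintf("mr: %d estimates, %d filtered", nrow(estimates),
                 sum(estimates$filtered_overlap)))
  report
}

stage_conserve <- function(config, out, report) {
  tree <- read_tree_newick(require_artifact(file.path(out, "tree.newick"),
                                            "conserve"))
  per_organ <- purrr::map_dfr(config$organ_list, function(organ) {
    conc <- read_concentrations(require_artifact(
      file.path(out, sprintf("concentrations_%s.tsv", organ)), "conserve"))
    conservation_scores(tree, conc, organ = organ)
  })
  readr::write_tsv(per_organ, file.path(out, "conservation_per_organ.tsv"))
  agg <- aggregate_conservation(per_organ)
  readr::write_tsv(agg, file.path(out, "conservation.tsv"))
  report$counts$n_conserved_metabolites <- nrow(agg)
  inform(sprintf("conserve: aggregate scores for %d metabolites", nrow(agg)))
  report
}

stage_stats <- function(config, out, report) {
  alpha_rep <- readr::read_tsv(require_artifact(
    file.path(out, "alpha_report.tsv"), "stats"), show_col_types = FALSE)
  sigma_mat <- read_matrix_tsv(require_artifact(
    file.path(out, "sigma.tsv"), "stats"))
  classes <- readr::read_tsv(require_artifact(
    file.path(out, "classes.tsv"), "stats"), show_col_types = FALSE)
  conserve <- readr::read_tsv(require_artifact(
    file.path(out, "conservation.tsv"), "stats"), show_col_types = FALSE)
  importance <- readr::read_tsv(require_artifact(
    file.path(out, "mr_importance.tsv"), "stats"), show_col_types = FALSE)

  merged <- alpha_rep |>
    dplyr::filter(.data$stable, is.finite(.data$alpha_hat)) |>
    dplyr::inner_join(conserve, by = "metabolite") |>
    dplyr::inner_join(importance, by = "metabolite") |>
    dplyr::inner_join(classes, by = "metabolite")
  assert_that(nrow(merged) >= 3,
              "stats stage needs at least 3 metabolites with complete results")
  sub_sigma <- sigma_mat[merged$metabolite, merged$metabolite]

  slope_cons <- adjusted_slope(merged$alpha_hat,
                               merged$aggregate_median_rank, sub_sigma)
  slope_imp <- adjusted_slope(merged$alpha_hat, merged$importance,
                              sub_sigma)
  het <- modified_cochran_q(merged$alpha_hat, merged$se, sub_sigma,
                            merged$class)
  cvr <- purrr::map_dfr(unique(merged$class), function(cl)
    class_vs_rest(merged$alpha_hat, merged$se, sub_sigma, merged$class, cl))
  cvr$p_adjusted <- p.adjust(cvr$p, method = "BH")
  cvr$significant_fdr <- cvr$p_adjusted < config$fdr

  results <- dplyr::bind_rows(
    tibble::tibble(test = "slope_alpha_vs_conservation",
                   statistic = slope_cons$r_hat, df = NA_real_,
                   p = slope_cons$p),
    tibble::tibble(test = "slope_alpha_vs_importance",
                   statistic = slope_imp$r_hat, df = NA_real_,
                   p = slope_imp$p),
    tibble::tibble(test = "modified_cochran_q", statistic = het$Q,
                   df = as.numeric(het$df), p = het$p))
  readr::write_tsv(results, file.path(out, "stats_results.tsv"))
  readr::write_tsv(cvr, file.path(out, "class_vs_rest.tsv"))

  report$stats <- list(
    slope_alpha_vs_conservation = slope_cons$r_hat,
    slope_alpha_vs_conservation_p = slope_cons$p,
    slope_alpha_vs_importance = slope_imp$r_hat,
    slope_alpha_vs_importance_p = slope_imp$p,
    Q = het$Q, Q_df = het$df, Q_p = het$p,
    n_metabolites_used = nrow(merged))
  inform(sprintf(
    "stats: %d metabolites; alpha-vs-conservation slope %.3f (P = %.3g); Q = %.2f (P = %.3g)",
    nrow(merged), slope_cons$r_hat, slope_cons$p, het$Q, het$p))
  report
}
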