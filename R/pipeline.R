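#' Pipeline configuration
#'
#' Builds (and validates) the configuration driving [run_pipeline()]: either
#' paths to a Newick tree and a measurement table, or a [sim_config()] for
#' synthetic mode.  Seeds are explicit; there are no hidden defaults for
#' seeds or generation counts.
#'
#' @param tree_path,measurements_path input files (real-data mode).
#' @param simulate a \code{"sim_config"} (synthetic mode); exactly one of
#'   the two modes must be supplied.
#' @param cutoffs percentile cut-off gradient.
#' @param n_perm permutations for the disparity test.
#' @param mcmc_generations generations per MCMC run.
#' @param shift_lambdas expected-shift-count gradient
#'   (default [shift_prior_presets()]\code{("methods")} = 30, 40, 50).
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir output directory, or \code{NULL} to skip writing files.
#' @param species_mean_scale \code{"raw"} or \code{"log"} specimen
#'   averaging (see [species_means()]).
#' @return a list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(tree_path = NULL, measurements_path = NULL,
                            simulate = NULL,
                            cutoffs = specialization_cutoffs(),
                            n_perm = 999, mcmc_generations = 50000,
                            shift_lambdas = shift_prior_presets("methods"),
                            seed = 1, out_dir = NULL,
                            species_mean_scale = "raw") {
  synthetic <- !is.null(simulate)
  if (synthetic && (!is.null(tree_path) || !is.null(measurements_path)))
    stop("supply either 'simulate' or input paths, not both")
  if (!synthetic) {
    if (is.null(tree_path)) stop("tree_path is required in real-data mode")
    if (is.null(measurements_path))
      stop("measurements_path is required in real-data mode")
  }
  if (any(cutoffs <= 0 | cutoffs >= 50))
    stop("cut-offs must lie strictly between 0 and 50")
  stopifnot(n_perm >= 99, mcmc_generations >= 100, length(shift_lambdas) >= 1)
  structure(list(tree_path = tree_path,
                 measurements_path = measurements_path, simulate = simulate,
                 cutoffs = cutoffs, n_perm = n_perm,
                 mcmc_generations = mcmc_generations,
                 shift_lambdas = shift_lambdas, seed = as.integer(seed),
                 out_dir = out_dir,
                 species_mean_scale = species_mean_scale),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; a \code{simulate}
#' mapping is passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return a \code{"pipeline_config"}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  do.call(pipeline_config, y)
}

.log_line <- function(log, stage, ...) {
  msg <- paste0("stage=", stage, " ", paste(..., collapse = " "))
  c(log, paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", msg))
}

#' Run the full comparative pipeline
#'
#' Chains every stage: data input (or simulation), species means,
#' mechanical advantage, phylogenetic size correction, PCA, per-axis PGLS
#' on MA, the disparity-asymmetry profile across cut-offs, and the
#' state-dependent rate-model grid (cut-offs x shift priors), ending in a
#' Table-1-style summary.  All seeds are derived from \code{config$seed},
#' so rerunning with the same configuration reproduces every output.
#'
#' @param config a \code{"pipeline_config"}.
#' @param run_rates fit the rate-model grid (default \code{TRUE}; set
#'   \code{FALSE} to stop after the disparity profile).
#' @param quiet suppress progress messages.
#' @return a list of class \code{"jaw_report"} with elements \code{tree},
#'   \code{means}, \code{ma}, \code{residuals}, \code{pca},
#'   \code{pgls_table}, \code{disparity}, \code{rate_grid},
#'   \code{rate_summary}, \code{log}, and (in synthetic mode) \code{truth}.
#' @export
run_pipeline <- function(config, run_rates = TRUE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  log <- character(0)
  truth <- NULL

  if (!is.null(config$simulate)) {
    sim <- simulate_dataset(config$simulate)
    tree <- sim$tree
    meas <- sim$measurements
    truth <- sim$truth
    log <- .log_line(log, "simulate", paste0("seed=", config$simulate$seed),
                     paste0("n_species=", config$simulate$n_species))
  } else {
    tree <- read_newick(file = config$tree_path)
    meas <- read_measurements(config$measurements_path)
    hashes <- tools::md5sum(c(config$tree_path, config$measurements_path))
    log <- .log_line(log, "input",
                     paste0("tree_md5=", hashes[1]),
                     paste0("measurements_md5=", hashes[2]))
  }
  say("pipeline: ", length(tree$tip.label), " species, ",
      nrow(meas), " specimens")

  means <- species_means(meas, scale = config$species_mean_scale)
  only_tree <- setdiff(tree$tip.label, means$species)
  only_tab <- setdiff(means$species, tree$tip.label)
  if (length(only_tree) || length(only_tab))
    stop("stage species_join: tree/table mismatch; only in tree: {",
         paste(only_tree, collapse = ","), "}; only in table: {",
         paste(only_tab, collapse = ","), "}")
  means <- means[match(canonical_order(tree), means$species), ]
  ma <- setNames(mechanical_advantage(means$il, means$ol), means$species)
  log <- .log_line(log, "mechanical_advantage",
                   paste0("range=", signif(min(ma), 4), "-",
                          signif(max(ma), 4)))

  resid <- residual_matrix(tree, means)
  C <- bm_covariance(tree)
  log <- .log_line(log, "residuals", paste0("traits=", ncol(resid)))

  pca <- shape_pca(resid)
  pgls_table <- pgls_by_axis(pca, ma, C)
  log <- .log_line(log, "pgls",
                   paste0("significant_axes=",
                          sum(pgls_table$p_value < 0.05)))

  disp <- disparity_profile(resid, ma, percentiles = config$cutoffs,
                            n_perm = config$n_perm,
                            seed = config$seed + 1000L)
  log <- .log_line(log, "disparity",
                   paste0("all_p<0.05=", all(disp$p_velocity_vs_force < 0.05,
                                             na.rm = TRUE)))

  grid <- list()
  rate_summary <- NULL
  run_i <- 0L
  if (run_rates) for (co in config$cutoffs) {
    lab <- classify_specialization(ma, co)
    for (lam in config$shift_lambdas) {
      run_i <- run_i + 1L
      seed_i <- config$seed + 10000L + run_i
      say("  rate model: cutoff ", co, "th, lambda ", lam,
          " (seed ", seed_i, ")")
      post <- run_mcmc(tree, resid, lab,
                       priors = rate_priors(shift_lambda = lam),
                       n_gen = config$mcmc_generations, seed = seed_i)
      grid[[run_i]] <- list(cutoff = co, shift_lambda = lam,
                            posterior = post)
      log <- .log_line(log, "rates", paste0("cutoff=", co),
                       paste0("lambda=", lam), paste0("seed=", seed_i),
                       paste0("pp=", signif(post$pp, 4)),
                       paste0("unconverged=", post$unconverged))
    }
  }
  if (run_rates) rate_summary <- summarize_grid(grid)

  report <- structure(list(tree = tree, n_specimens = nrow(meas),
                           means = means, ma = ma,
                           residuals = resid, pca = pca,
                           pgls_table = pgls_table, disparity = disp,
                           rate_grid = grid, rate_summary = rate_summary,
                           truth = truth, config = config, log = log),
                      class = "jaw_report")
  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

.write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                       row.names = FALSE)
  w(report$means, "species_means.csv")
  w(data.frame(species = names(report$ma), ma = report$ma),
    "mechanical_advantage.csv")
  w(data.frame(species = rownames(report$residuals), report$residuals,
               check.names = FALSE), "residuals.csv")
  w(data.frame(trait = rownames(report$pca$loadings),
               report$pca$loadings, check.names = FALSE),
    "pca_loadings.csv")
  w(data.frame(species = rownames(report$pca$scores), report$pca$scores,
               check.names = FALSE), "pca_scores.csv")
  w(report$pgls_table, "pgls.csv")
  w(report$disparity, "disparity_profile.csv")
  if (!is.null(report$rate_summary))
    w(report$rate_summary, "rate_summary.csv")
  write_newick(report$tree, file.path(dir, "tree.nwk"))
  writeLines(report$log, file.path(dir, "pipeline.log"))
  invisible(dir)
}

#' @export
print.jaw_report <- function(x, ...) {
  cat("Velocity-force trade-off pipeline report\n")
  cat("  species:", length(x$tree$tip.label),
      " MA range:", signif(min(x$ma), 3), "-", signif(max(x$ma), 3), "\n")
  cat("  PGLS axes with p < 0.05:", sum(x$pgls_table$p_value < 0.05),
      "of", nrow(x$pgls_table), "\n")
  cat("  disparity velocity > force at",
      sum(x$disparity$d_obs > 0), "of", nrow(x$disparity), "cut-offs\n")
  if (!is.null(x$rate_summary)) {
    cat("  rate-model summary:\n")
    print(x$rate_summary, row.names = FALSE)
  }
  invisible(x)
}
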