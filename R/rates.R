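.state_levels <- c("velocity", "unspecialized", "force")

## postorder edge arrays (0-based) for the C++ core
.tree_arrays <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  po <- ape::reorder.phylo(tree, "postorder")
  list(ntip = length(tree$tip.label),
       edge = matrix(as.integer(po$edge - 1L), ncol = 2),
       len = po$edge.length, tree = po)
}

## map a per-branch vector aligned with tree$edge rows onto postorder rows
.match_edges <- function(tree, po_tree) {
  key <- function(e) paste(e[, 1], e[, 2])
  match(key(po_tree$edge), key(tree$edge))
}

.align_traits <- function(tree, traits) {
  traits <- as.matrix(traits)
  if (!is.null(rownames(traits))) {
    missing <- setdiff(tree$tip.label, rownames(traits))
    if (length(missing))
      stop("trait matrix is missing species: ", paste(missing, collapse = ", "))
    traits <- traits[tree$tip.label, , drop = FALSE]
  } else if (nrow(traits) != length(tree$tip.label)) {
    stop("trait matrix must have one row per tip")
  }
  if (anyNA(traits)) stop("missing values in trait matrix")
  traits
}

.align_states <- function(tree, labels) {
  if (!is.null(names(labels))) labels <- labels[tree$tip.label]
  if (anyNA(labels)) stop("tip states missing for some species")
  st <- as.integer(factor(as.character(labels), levels = .state_levels)) - 1L
  if (anyNA(st))
    stop("tip states must be among: ", paste(.state_levels, collapse = ", "))
  st
}

#' Multivariate Brownian-motion log-likelihood (pruning algorithm)
#'
#' Log density of a species x traits matrix under correlated Brownian
#' motion: tip covariance \eqn{\sigma^2 C \otimes R} where \eqn{C} is built
#' from rate-scaled branch lengths and \eqn{R} is the trait correlation
#' matrix.  Per-trait root states are profiled out at their GLS estimates.
#' Computed by Felsenstein's pruning algorithm in O(tips x traits^2), after
#' decorrelating the traits with the Cholesky factor of \eqn{R}.
#'
#' @param tree a \code{"phylo"} object.
#' @param traits species x traits matrix, rows named by (or ordered as) the
#'   tips.
#' @param branch_rates optional positive per-branch rate multipliers aligned
#'   with \code{tree$edge} rows (default all 1).
#' @param R trait correlation matrix (default identity).
#' @param sigma2 overall rate scalar (default 1).
#' @return the log-likelihood (scalar).
#' @export
mvbm_loglik <- function(tree, traits, branch_rates = NULL, R = NULL,
                        sigma2 = 1) {
  ta <- .tree_arrays(tree)
  Y <- .align_traits(tree, traits)
  p <- ncol(Y)
  if (is.null(R)) R <- diag(p)
  stopifnot(nrow(R) == p, ncol(R) == p)
  if (sigma2 <= 0) stop("sigma2 must be positive")
  eff <- ta$len
  if (!is.null(branch_rates)) {
    if (length(branch_rates) != nrow(tree$edge))
      stop("'branch_rates' must have one entry per branch")
    if (any(branch_rates <= 0)) stop("branch rates must be positive")
    eff <- ta$len * branch_rates[.match_edges(tree, ta$tree)]
  }
  mvbm_loglik_cpp(ta$ntip, ta$edge, eff, Y, as.matrix(R), sigma2)
}

#' Sample a character history by stochastic mapping
#'
#' Draws a full three-state history (velocity / unspecialized / force) on the
#' tree conditional on the tip states, under a symmetric continuous-time
#' Markov chain with per-pair exchange rate \code{q}.  Node states are drawn
#' by the pruning recursion; within-branch paths by uniformization (which for
#' the symmetric 3-state chain never needs rejection).
#'
#' @param tree a \code{"phylo"} object.
#' @param tip_states factor/character of states named by tip label (levels
#'   \code{velocity, unspecialized, force}).
#' @param q CTMC exchange rate (> 0).
#' @return list of class \code{"character_history"}: \code{node_states}
#'   (state label per node, tips first), \code{jumps} (data.frame with
#'   postorder-edge index, position from the parent end, and the state
#'   entered), \code{n_transitions}, and the postorder tree used.
#' @export
sample_history <- function(tree, tip_states, q) {
  if (q <= 0) stop("q must be positive")
  ta <- .tree_arrays(tree)
  st <- .align_states(tree, tip_states)
  res <- sample_history_cpp(ta$ntip, ta$edge, ta$len, st, q)
  structure(list(
    node_states = .state_levels[res$node_states + 1L],
    jumps = data.frame(edge = res$jump_edge + 1L, pos = res$jump_pos,
                       state = .state_levels[res$jump_state + 1L]),
    n_transitions = res$n_transitions,
    tree_postorder = ta$tree
  ), class = "character_history")
}

#' Priors for the state-dependent rate model
#'
#' @param shift_lambda expected number of background rate shifts
#'   (compound-Poisson prior on the shift count).
#' @param shift_size_sd standard deviation of lognormal shift sizes
#'   (default 0.587, i.e. a typical shift of about 2-fold).
#' @param q_rate rate of the exponential prior on the CTMC exchange rate.
#' @param sigma2_scale scale of the half-Cauchy prior on the overall rate.
#' @return a named list.
#' @export
rate_priors <- function(shift_lambda = 40, shift_size_sd = 0.587,
                        q_rate = 1, sigma2_scale = 1) {
  stopifnot(shift_lambda > 0, shift_size_sd > 0, q_rate > 0,
            sigma2_scale > 0)
  list(shift_lambda = shift_lambda, shift_size_sd = shift_size_sd,
       q_rate = q_rate, sigma2_scale = sigma2_scale)
}

#' Shift-number prior presets
#'
#' Two presets for the expected-shift-count gradient used to probe prior
#' sensitivity: \code{"methods"} = 30, 40, 50 and \code{"alternative"} =
#' 20, 40, 60.
#'
#' @param which \code{"methods"} (default) or \code{"alternative"}.
#' @return numeric vector of three expected shift counts.
#' @export
shift_prior_presets <- function(which = c("methods", "alternative")) {
  which <- match.arg(which)
  if (which == "methods") c(30, 40, 50) else c(20, 40, 60)
}

#' Fit the state-dependent multivariate Brownian rate model by MCMC
#'
#' Bayesian MuSSCRat-style model: the six size-corrected traits evolve by
#' correlated Brownian motion whose rate along each branch segment is
#' \code{sigma2} times a state multiplier (\code{zeta}, mean pinned at 1 by
#' a scaled flat Dirichlet prior, switched on/off by the state-dependence
#' indicator \code{delta} with prior 0.5) times compound-Poisson background
#' shift multipliers.  The discrete history is resampled by stochastic
#' mapping within the MCMC, so discrete and continuous evolution are
#' estimated jointly.  The posterior probability of state dependence (PP)
#' is the posterior mean of \code{delta}; rate ratios are posterior means of
#' \code{zeta} ratios conditional on \code{delta = 1}.
#'
#' @param tree a \code{"phylo"} object.
#' @param traits species x traits residual matrix (rows named by species).
#' @param labels specialization labels from [classify_specialization()].
#' @param priors list from [rate_priors()].
#' @param n_gen number of MCMC generations.
#' @param seed integer seed (mandatory; fully determines the run).
#' @param burn_frac fraction of generations discarded as burn-in.
#' @param n_keep maximum number of retained samples after thinning.
#' @param likelihood set \code{FALSE} for a prior-only run (the continuous
#'   likelihood is switched off; used for prior-recovery checks).
#' @param background include background rate shifts (default \code{TRUE}).
#' @param state_rates \code{"sample"} the indicator (default), or fix it
#'   \code{"on"} / \code{"off"}.
#' @param history_every resample the character history every this many
#'   generations.
#' @return an object of class \code{"rate_posterior"}: \code{samples}
#'   (data.frame of retained draws), \code{pp}, \code{rr} (three rate
#'   ratios as posterior means; these are heavy-tailed when a state
#'   multiplier approaches zero), \code{rr_median} (the more robust
#'   posterior medians of the same ratios), \code{ess} per scalar trace,
#'   \code{unconverged} flag, and the settings used.
#' @export
run_mcmc <- function(tree, traits, labels, priors = rate_priors(),
                     n_gen = 50000, seed = 1, burn_frac = 0.1,
                     n_keep = 5000, likelihood = TRUE, background = TRUE,
                     state_rates = c("sample", "on", "off"),
                     history_every = 1) {
  state_rates <- match.arg(state_rates)
  ta <- .tree_arrays(tree)
  Y <- .align_traits(tree, traits)
  st <- .align_states(tree, labels)
  if (n_gen < 100) stop("n_gen too small")
  set.seed(as.integer(seed))
  delta_mode <- switch(state_rates, sample = -1L, on = 1L, off = 0L)
  res <- run_musscrat_cpp(ta$ntip, ta$edge, ta$len, Y, st,
                          priors$shift_lambda, priors$shift_size_sd,
                          priors$q_rate, priors$sigma2_scale,
                          as.integer(n_gen), burn_frac, as.integer(n_keep),
                          likelihood, background, delta_mode,
                          as.integer(history_every))
  sm <- res$samples
  p <- ncol(Y)
  pair_names <- if (p > 1) {
    idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
    idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
    paste0("r_", idx[, "row"], "_", idx[, "col"])
  } else character(0)
  colnames(sm) <- c("delta", "zeta_velocity", "zeta_unspecialized",
                    "zeta_force", "sigma2", "q", "n_shifts", "n_transitions",
                    "loglik", pair_names)
  sm <- as.data.frame(sm)
  pp <- mean(sm$delta)
  on <- sm$delta == 1
  rr <- rr_median <- c(force_velocity = NA_real_,
                       velocity_unspecialized = NA_real_,
                       force_unspecialized = NA_real_)
  if (any(on)) {
    ratios <- cbind(force_velocity = sm$zeta_force[on] / sm$zeta_velocity[on],
                    velocity_unspecialized =
                      sm$zeta_velocity[on] / sm$zeta_unspecialized[on],
                    force_unspecialized =
                      sm$zeta_force[on] / sm$zeta_unspecialized[on])
    rr <- colMeans(ratios)
    rr_median <- apply(ratios, 2, stats::median)
  }
  ess <- vapply(sm, ess_iact, numeric(1))
  unconverged <- any(ess[is.finite(ess)] < 200)
  structure(list(samples = sm, pp = pp, rr = rr, rr_median = rr_median,
                 ess = ess,
                 unconverged = unconverged,
                 settings = list(n_gen = n_gen, seed = seed,
                                 burn_frac = burn_frac, thin = res$thin,
                                 priors = priors, likelihood = likelihood,
                                 background = background,
                                 state_rates = state_rates,
                                 n_species = ta$ntip, n_traits = p)),
            class = "rate_posterior")
}

#' @export
print.rate_posterior <- function(x, ...) {
  cat("State-dependent mvBM posterior (", nrow(x$samples), " samples, ",
      x$settings$n_gen, " generations)\n", sep = "")
  cat("  PP(state-dependent) =", signif(x$pp, 3), "\n")
  cat("  RR force:velocity   =", signif(x$rr["force_velocity"], 3),
      "(median", paste0(signif(x$rr_median["force_velocity"], 3), ")"), "\n")
  cat("  RR velocity:unsp    =", signif(x$rr["velocity_unspecialized"], 3),
      "(median",
      paste0(signif(x$rr_median["velocity_unspecialized"], 3), ")"), "\n")
  cat("  RR force:unsp       =", signif(x$rr["force_unspecialized"], 3),
      "(median",
      paste0(signif(x$rr_median["force_unspecialized"], 3), ")"), "\n")
  if (x$unconverged)
    cat("  WARNING: flagged unconverged (some ESS < 200)\n")
  invisible(x)
}

#' Effective sample size of an MCMC trace
#'
#' Initial-positive-sequence (Geyer) estimator of the integrated
#' autocorrelation time; ESS = n / IACT, capped at n.  A constant trace
#' returns \code{Inf} (nothing to estimate).
#'
#' @param x numeric trace.
#' @return effective sample size.
#' @export
ess_iact <- function(x) {
  n <- length(x)
  if (n < 10) return(n)
  if (var(x) == 0) return(Inf)
  lag_max <- min(n - 1, 2000)
  rho <- drop(acf(x, lag.max = lag_max, plot = FALSE)$acf)
  tau <- 1
  k <- 1
  while (k + 1 <= lag_max) {
    g <- rho[k + 1] + ifelse(k + 2 <= lag_max + 1, rho[k + 2], 0)
    if (g <= 0) break
    tau <- tau + 2 * g
    k <- k + 2
  }
  min(n, n / tau)
}

#' Summarize a grid of posteriors across cut-offs and shift priors
#'
#' Produces the standard per-cut-off summary table: the posterior
#' probability of state dependence and the three rate ratios, averaged over
#' shift-prior replicates, with a convergence mark.
#'
#' @param grid a list of entries, each a list with elements \code{cutoff},
#'   \code{shift_lambda}, and \code{posterior} (a \code{"rate_posterior"}).
#' @return data.frame with columns \code{Model}, \code{PP},
#'   \code{RR_force_velocity}, \code{RR_velocity_unsp},
#'   \code{RR_force_unsp}, \code{unconverged}.
#' @export
summarize_grid <- function(grid) {
  if (!length(grid)) stop("empty grid")
  cutoffs <- sort(unique(vapply(grid, `[[`, numeric(1), "cutoff")))
  rows <- lapply(cutoffs, function(co) {
    cell <- Filter(function(g) g$cutoff == co, grid)
    pp <- mean(vapply(cell, function(g) g$posterior$pp, numeric(1)))
    rrm <- function(nm) mean(vapply(cell, function(g)
      g$posterior$rr[[nm]], numeric(1)))
    data.frame(Model = paste0(co, "th"), PP = pp,
               RR_force_velocity = rrm("force_velocity"),
               RR_velocity_unsp = rrm("velocity_unspecialized"),
               RR_force_unsp = rrm("force_unspecialized"),
               unconverged = any(vapply(cell, function(g)
                 g$posterior$unconverged, logical(1))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a posterior's parameter traces as a plain-text table
#'
#' One column per scalar, one row per retained sample, suitable for
#' standard MCMC-diagnostic tools.
#'
#' @param posterior a \code{"rate_posterior"} object.
#' @param path output file path (tab-separated).
#' @export
write_trace <- function(posterior, path) {
  stopifnot(inherits(posterior, "rate_posterior"))
  utils::write.table(posterior$samples, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
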