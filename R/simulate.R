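#' Configuration for the synthetic percid-like data generator
#'
#' Defines the generative conditions the analysis assumes: a birth-death
#' tree rescaled to unit root depth, Brownian evolution of ln mechanical
#' advantage (tuned so species MA spans roughly 0.22-0.56, about
#' three-fold), allometric scaling of six ln-traits on ln standard length
#' with correlated Brownian residuals whose rate is scaled by the
#' specialization state and by compound-Poisson background shifts, and
#' specimen-level lognormal measurement noise (2-5 specimens per species,
#' so ~89 species yield ~300 specimens).
#'
#' @param n_species number of tips (default 89).
#' @param birth,death birth-death rates for the tree (birth > death >= 0).
#' @param ma_root root mechanical advantage.
#' @param ma_bm_rate Brownian rate of ln MA.
#' @param ma_jump optional ln-MA increment applied to one recently arising
#'   clade holding roughly 20-35 percent of the tips (0 = off).  Emulates a
#'   single subclade evolving force-modified jaws near the present, as
#'   opposed to tail membership arising diffusely across the tree.
#' @param ma_velocity_jumps number of small, mutually distant clades pushed
#'   toward low MA (default 0); emulates velocity-modified jaws arising
#'   independently in several anciently diverged lineages.
#' @param ma_velocity_jump ln-MA decrement applied to each such clade.
#' @param ma_tip_sd SD of an iid species-level component added to ln MA
#'   (default 0); makes tail membership partly idiosyncratic rather than
#'   purely clade-determined.
#' @param label_percentile percentile cut-off used to generate the true
#'   specialization states.
#' @param q_true CTMC exchange rate of the latent state history.
#' @param slopes,intercepts allometric coefficients per trait
#'   (ln trait = intercept + slope * ln SL + Brownian residual).
#' @param sigma2_true Brownian rate of the trait residuals.
#' @param trait_cor exchangeable correlation among trait residuals.
#' @param zeta_true three positive state rate multipliers (velocity,
#'   unspecialized, force); rescaled to mean 1.
#' @param true_shift_lambda expected number of background rate-shift events.
#' @param shift_size_sd_true SD of lognormal shift sizes.
#' @param sl_root root standard length (mm).
#' @param sl_bm_rate Brownian rate of ln standard length.
#' @param specimens_range inclusive range of specimens per species.
#' @param noise_sd lognormal measurement noise SD (ln scale).
#' @param velocity_disparity_inflation extra species-level SD (ln scale)
#'   added to the traits of velocity-tail species; emulates the greater
#'   phenotypic spread of velocity-modified jaws accumulated over their
#'   longer evolutionary history (0 = off).
#' @param seed integer seed; the full dataset is deterministic given it.
#' @return a list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_species = 89, birth = 1, death = 0.25,
                       ma_root = 0.35, ma_bm_rate = 0.06, ma_jump = 0,
                       ma_velocity_jumps = 0, ma_velocity_jump = 0.45,
                       ma_tip_sd = 0, label_percentile = 17.5, q_true = 0.3,
                       slopes = c(pm = 1.1, mx = 1.0, na = 1.0, oc = 1.05,
                                  snl = 1.1, ol = 1.0),
                       intercepts = c(pm = -2.5, mx = -2.3, na = -3.0,
                                      oc = -1.6, snl = -2.2, ol = -1.8),
                       sigma2_true = 0.02, trait_cor = 0.3,
                       zeta_true = c(1, 1, 1), true_shift_lambda = 10,
                       shift_size_sd_true = 0.4, sl_root = 60,
                       sl_bm_rate = 0.05, specimens_range = c(2, 5),
                       noise_sd = 0.01, velocity_disparity_inflation = 0,
                       seed = 1) {
  stopifnot(n_species >= 2, birth > death, death >= 0, ma_root > 0,
            ma_bm_rate > 0, q_true > 0, sigma2_true > 0,
            true_shift_lambda >= 0, shift_size_sd_true > 0, sl_root > 0,
            sl_bm_rate > 0, noise_sd >= 0, length(zeta_true) == 3,
            all(zeta_true > 0), length(slopes) == length(intercepts),
            length(slopes) > 0, abs(trait_cor) < 1,
            label_percentile > 0, label_percentile < 50)
  structure(as.list(environment()), class = "sim_config")
}

#' Generative scenario mirroring an asymmetrical constraint
#'
#' Preset encoding the trade-off-as-asymmetrical-constraint hypothesis:
#' specialized jaws evolve slower than unspecialized ones, most severely on
#' the velocity side (state rate multipliers 0.25, 1.9, 0.85 for velocity,
#' unspecialized, force, i.e. a force:velocity rate ratio of 3.4), while
#' force-modified jaws are confined to a single recently arising clade
#' (\code{ma_jump}) and velocity-modified jaws are scattered across
#' anciently diverged lineages (\code{ma_tip_sd}).  The velocity tail then
#' spans deep divergences and accumulates more disparity than the young,
#' clustered force tail despite its slower rate - the "time to evolve"
#' signature.
#'
#' @param ... overrides passed on to [sim_config()].
#' @return a \code{"sim_config"}.
#' @export
sim_config_asymmetry <- function(...) {
  sim_config(zeta_true = c(0.25, 1.9, 0.85), ma_root = 0.3,
             ma_bm_rate = 0.02, ma_jump = 0.5, ma_tip_sd = 0.22,
             true_shift_lambda = 5, shift_size_sd_true = 0.3,
             trait_cor = 0.15, ...)
}

#' Simulate a birth-death phylogeny rescaled to unit depth
#'
#' @param config a \code{"sim_config"} (its \code{n_species}, \code{birth},
#'   \code{death} fields are used; RNG state is taken as-is, so call
#'   \code{set.seed()} or use [simulate_dataset()] for determinism).
#' @return an ultrametric \code{"phylo"} with root depth 1.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- ape::rphylo(config$n_species, birth = config$birth,
                      death = config$death)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}

## multivariate Brownian tip deviations for given effective edge lengths:
## increment along edge e is N(0, sigma2 * eff[e] * R)
.sim_mvbm_tips <- function(ta, eff, sigma2, R) {
  p <- nrow(R)
  UR <- chol(R)
  ntip <- ta$ntip
  nn <- max(ta$edge) + 1L
  dev <- matrix(0, nn, p)
  for (e in rev(seq_len(nrow(ta$edge)))) {  # preorder
    par <- ta$edge[e, 1] + 1L; ch <- ta$edge[e, 2] + 1L
    dev[ch, ] <- dev[par, ] + sqrt(sigma2 * eff[e]) * drop(rnorm(p) %*% UR)
  }
  dev[seq_len(ntip), , drop = FALSE]
}

## Brownian motion along the tree; returns values at every node
.sim_bm <- function(tree, root_value, rate) {
  po <- ape::reorder.phylo(tree, "postorder")
  nn <- length(tree$tip.label) + tree$Nnode
  x <- numeric(nn)
  x[length(tree$tip.label) + 1L] <- root_value
  for (e in rev(seq_len(nrow(po$edge)))) {  # preorder
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    x[ch] <- x[par] + rnorm(1, 0, sqrt(rate * po$edge.length[e]))
  }
  x
}

#' Simulate a full synthetic dataset
#'
#' Generates a tree, evolves ln mechanical advantage by Brownian motion,
#' derives true specialization labels with the same classifier the analysis
#' uses, draws a three-state history consistent with those labels, scales
#' correlated Brownian trait residuals by state and background-shift rate
#' multipliers, adds the allometric size component, and emits a
#' specimen-level measurement table whose in- and out-levers reproduce each
#' species' MA exactly.  Fully deterministic given \code{config$seed}.
#'
#' @param config a \code{"sim_config"}.
#' @return a list of class \code{"jaw_sim"} with \code{tree},
#'   \code{measurements} (specimen table) and \code{truth} (latent values
#'   and true parameters for recovery tests).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_species < 10)
    stop("simulate_dataset needs at least 10 species")
  set.seed(as.integer(config$seed))
  traits <- names(config$slopes)
  p <- length(traits)
  tree <- simulate_tree(config)
  tree$tip.label <- sprintf("sp%03d", seq_len(config$n_species))
  ntip <- config$n_species

  lnma_nodes <- .sim_bm(tree, log(config$ma_root), config$ma_bm_rate)
  lnma <- setNames(lnma_nodes[seq_len(ntip)], tree$tip.label)
  force_clade <- character(0)
  parts <- ape::prop.part(tree)
  sizes <- lengths(parts)
  depths <- ape::node.depth.edgelength(tree)
  part_tips <- lapply(parts, function(i) attr(parts, "labels")[i])
  if (config$ma_jump != 0) {
    ## shift one recently arising, mid-sized clade along the MA axis
    eligible <- which(sizes >= max(3, 0.22 * ntip) & sizes <= 0.38 * ntip)
    if (!length(eligible))
      eligible <- which(sizes >= max(3, 0.1 * ntip) & sizes <= 0.38 * ntip)
    if (!length(eligible)) eligible <- which(sizes < ntip)
    pick <- eligible[which.max(depths[ntip + eligible])]
    force_clade <- part_tips[[pick]]
    lnma[force_clade] <- lnma[force_clade] + config$ma_jump
  }
  if (config$ma_velocity_jumps > 0) {
    ## push several small, mutually disjoint clades toward low MA
    taken <- force_clade
    eligible <- which(sizes >= 3 & sizes <= max(3, 0.08 * ntip))
    eligible <- eligible[order(depths[ntip + eligible])]  # oldest first
    placed <- 0L
    for (i in eligible) {
      if (placed >= config$ma_velocity_jumps) break
      if (length(intersect(part_tips[[i]], taken))) next
      lnma[part_tips[[i]]] <- lnma[part_tips[[i]]] - config$ma_velocity_jump
      taken <- c(taken, part_tips[[i]])
      placed <- placed + 1L
    }
  }
  if (config$ma_tip_sd > 0)
    lnma <- lnma + rnorm(ntip, 0, config$ma_tip_sd)
  ma <- exp(lnma)
  labels <- classify_specialization(ma, config$label_percentile)

  hist <- sample_history(tree, labels, config$q_true)
  ta <- .tree_arrays(tree)

  n_shift <- if (config$true_shift_lambda > 0)
    rpois(1, config$true_shift_lambda) else 0L
  total_len <- sum(ta$len)
  bg_edge <- integer(0); bg_pos <- numeric(0); bg_ls <- numeric(0)
  if (n_shift > 0) {
    u <- runif(n_shift) * total_len
    cum <- cumsum(ta$len)
    bg_edge <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
    bg_pos <- u - c(0, cum)[bg_edge]
    bg_ls <- rnorm(n_shift, 0, config$shift_size_sd_true)
  }

  zeta <- 3 * config$zeta_true / sum(config$zeta_true)
  st_int <- match(hist$node_states, .state_levels) - 1L
  eff <- edge_eff_lengths_cpp(ta$ntip, ta$edge, ta$len, st_int,
                              as.integer(hist$jumps$edge - 1L),
                              hist$jumps$pos,
                              match(hist$jumps$state, .state_levels) - 1L,
                              as.integer(bg_edge - 1L), bg_pos, bg_ls,
                              zeta, 1L)

  R_true <- matrix(config$trait_cor, p, p); diag(R_true) <- 1
  dev <- .sim_mvbm_tips(ta, eff, config$sigma2_true, R_true)

  lnsl_nodes <- .sim_bm(tree, log(config$sl_root), config$sl_bm_rate)
  lnsl <- setNames(lnsl_nodes[seq_len(ntip)], tree$tip.label)
  latent <- matrix(rep(config$intercepts, each = ntip), ntip, p,
                   dimnames = list(tree$tip.label, traits)) +
    outer(lnsl, config$slopes) + dev

  if (config$velocity_disparity_inflation > 0) {
    iv <- which(labels == "velocity")
    latent[iv, ] <- latent[iv, ] +
      matrix(rnorm(length(iv) * p, 0, config$velocity_disparity_inflation),
             length(iv), p)
  }

  rows <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    k <- if (config$specimens_range[1] == config$specimens_range[2])
      config$specimens_range[1]
    else sample(config$specimens_range[1]:config$specimens_range[2], 1)
    noise <- function(m) exp(m + rnorm(k, 0, config$noise_sd))
    d <- data.frame(species = rep(tree$tip.label[i], k))
    d$sl <- noise(lnsl[i])
    for (tr in traits) d[[tr]] <- noise(latent[i, tr])
    ## standard columns not among the simulated response traits are filled
    ## with neutral isometric measurements so the table schema is complete
    for (cn in c("ol", "pm", "mx", "na", "oc", "snl"))
      if (!cn %in% traits) d[[cn]] <- noise(config$intercepts[1] + lnsl[i])
    d$il <- ma[i] * d$ol   # specimen levers reproduce the species MA exactly
    rows[[i]] <- d[, c("species", "sl", "il", "ol", "pm", "mx", "na", "oc",
                       "snl")]
  }
  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL

  structure(list(
    tree = tree, measurements = measurements,
    truth = list(config = config, lnma = lnma, ma = ma, labels = labels,
                 history = hist, bg = data.frame(edge = bg_edge,
                                                 pos = bg_pos, ls = bg_ls),
                 eff = eff, zeta_true = setNames(zeta, .state_levels),
                 sigma2_true = config$sigma2_true, R_true = R_true,
                 lnsl = lnsl, latent = latent)
  ), class = "jaw_sim")
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Emits the Newick tree, the specimen measurement CSV, and a plain-text
#' truth sidecar (YAML) with the generating parameters for recovery tests.
#'
#' @param sim a \code{"jaw_sim"} from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "jaw_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tree_path <- file.path(dir, "tree.nwk")
  meas_path <- file.path(dir, "measurements.csv")
  truth_path <- file.path(dir, "truth.yaml")
  write_newick(sim$tree, tree_path)
  utils::write.csv(sim$measurements, meas_path, row.names = FALSE)
  cfg <- sim$truth$config
  yaml::write_yaml(list(
    seed = cfg$seed, n_species = cfg$n_species,
    zeta_true = as.numeric(sim$truth$zeta_true),
    sigma2_true = cfg$sigma2_true,
    true_shift_lambda = cfg$true_shift_lambda,
    label_percentile = cfg$label_percentile, q_true = cfg$q_true,
    ma_range = as.numeric(range(sim$truth$ma))), truth_path)
  invisible(c(tree = tree_path, measurements = meas_path,
              truth = truth_path))
}
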