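test_that("mvbm_loglik matches the closed form on a 2-tip star", {
  tr <- read_newick("(A:1,B:1);")
  y <- matrix(c(0.3, -0.8), 2, 1, dimnames = list(c("A", "B"), NULL))
  ll <- mvbm_loglik(tr, y)
  # contrast density N(0, 2) at y1 - y2, plus the GLS-mean term N(mu, 1/2)
  expected <- dnorm(0.3 - (-0.8), 0, sqrt(2), log = TRUE) +
    dnorm(0, 0, sqrt(0.5), log = TRUE)
  expect_equal(ll, expected, tolerance = 1e-12)
})

test_that("mvbm_loglik equals the dense multivariate normal density", {
  set.seed(20)
  for (i in 1:10) {
    n <- sample(4:12, 1); p <- sample(1:4, 1)
    tr <- random_tree(n)
    Y <- matrix(rnorm(n * p), n, p, dimnames = list(tr$tip.label, NULL))
    rates <- runif(nrow(tr$edge), 0.3, 3)
    R <- random_corr(p)
    s2 <- runif(1, 0.5, 2)
    expect_equal(mvbm_loglik(tr, Y, rates, R, s2),
                 dense_mvbm_loglik(tr, Y, rates, R, s2), tolerance = 1e-8)
  }
})

test_that("rate and time are confounded exactly", {
  set.seed(21)
  tr <- random_tree(9)
  Y <- matrix(rnorm(27), 9, 3, dimnames = list(tr$tip.label, NULL))
  tr2 <- tr; tr2$edge.length <- tr2$edge.length / 2
  expect_equal(mvbm_loglik(tr, Y, sigma2 = 1),
               mvbm_loglik(tr2, Y, sigma2 = 2), tolerance = 1e-12)
  badR <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(mvbm_loglik(tr, Y[, 1:2], R = badR), "positive definite")
})

test_that("stochastic mapping respects endpoint constraints", {
  tr <- read_newick("(A:1,B:1);")
  mono <- c(A = "force", B = "force")
  set.seed(22)
  h <- sample_history(tr, mono, q = 1e-8)
  expect_equal(h$n_transitions, 0)
  expect_true(all(h$node_states == "force"))

  het <- c(A = "velocity", B = "force")
  for (i in 1:50) {
    h <- sample_history(tr, het, q = 0.5)
    expect_gte(h$n_transitions, 1)
    expect_equal(h$node_states[1:2], c("velocity", "force"))
  }
})

test_that("sampled histories are internally consistent and seeded", {
  set.seed(23)
  tr <- random_tree(12)
  states <- setNames(sample(c("velocity", "unspecialized", "force"), 12,
                            replace = TRUE), tr$tip.label)
  set.seed(5); h1 <- sample_history(tr, states, 0.7)
  set.seed(5); h2 <- sample_history(tr, states, 0.7)
  expect_identical(h1$jumps, h2$jumps)
  # jump trail along each edge ends in the child node's state
  lv <- c("velocity", "unspecialized", "force")
  po <- h1$tree_postorder
  for (e in seq_len(nrow(po$edge))) {
    jj <- h1$jumps[h1$jumps$edge == e, ]
    start <- h1$node_states[po$edge[e, 1]]
    end <- if (nrow(jj)) jj$state[nrow(jj)] else start
    expect_equal(end, h1$node_states[po$edge[e, 2]])
  }
})

test_that("run_mcmc returns a seeded, well-formed posterior", {
  sim <- simulate_dataset(sim_config(n_species = 25, seed = 30))
  resid <- residual_matrix(sim$tree, species_means(sim$measurements))
  post <- run_mcmc(sim$tree, resid, sim$truth$labels,
                   priors = rate_priors(shift_lambda = 10),
                   n_gen = 3000, seed = 99)
  expect_s3_class(post, "rate_posterior")
  expect_true(post$pp >= 0 && post$pp <= 1)
  expect_true(all(post$rr > 0, na.rm = TRUE))
  # zeta stays on the mean-1 simplex
  zsum <- rowSums(post$samples[, c("zeta_velocity", "zeta_unspecialized",
                                   "zeta_force")])
  expect_equal(zsum, rep(3, length(zsum)), tolerance = 1e-9)
  expect_true(all(post$samples$sigma2 > 0))
  expect_true(all(post$samples$q > 0))
  expect_true(all(post$samples$delta %in% c(0, 1)))
  expect_true(is.logical(post$unconverged))
  expect_true(all(c("delta", "sigma2", "q", "n_shifts") %in%
                    names(post$ess)))

  post2 <- run_mcmc(sim$tree, resid, sim$truth$labels,
                    priors = rate_priors(shift_lambda = 10),
                    n_gen = 3000, seed = 99)
  expect_identical(post$samples, post2$samples)

  f <- tempfile(fileext = ".tsv")
  write_trace(post, f)
  tr_in <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tr_in), nrow(post$samples))
})

test_that("PP and rate ratios are stable under trait rescaling and column order", {
  sim <- simulate_dataset(sim_config(n_species = 60, seed = 31,
                                     zeta_true = c(1, 2, 6),
                                     label_percentile = 33))
  resid <- residual_matrix(sim$tree, species_means(sim$measurements))
  base <- run_mcmc(sim$tree, resid, sim$truth$labels,
                   priors = rate_priors(shift_lambda = 10),
                   n_gen = 15000, seed = 7)
  resc <- run_mcmc(sim$tree, resid * 4, sim$truth$labels,
                   priors = rate_priors(shift_lambda = 10),
                   n_gen = 15000, seed = 7)
  perm <- run_mcmc(sim$tree, resid[, c(3, 1, 6, 2, 5, 4)],
                   sim$truth$labels,
                   priors = rate_priors(shift_lambda = 10),
                   n_gen = 15000, seed = 7)
  expect_lt(abs(base$pp - resc$pp), 0.15)
  expect_lt(abs(base$pp - perm$pp), 0.15)
  rr <- function(x) log(x$rr[["force_velocity"]])
  expect_lt(abs(rr(base) - rr(resc)), log(1.6))
  expect_lt(abs(rr(base) - rr(perm)), log(1.6))
})

test_that("state-specific rates concentrate around truth without background", {
  cfg <- sim_config(n_species = 200, seed = 32,
                    slopes = c(pm = 1), intercepts = c(pm = -2.5),
                    zeta_true = c(0.5, 1, 1.5), true_shift_lambda = 0,
                    label_percentile = 33, noise_sd = 0,
                    specimens_range = c(1, 1))
  sim <- simulate_dataset(cfg)
  resid <- residual_matrix(sim$tree, species_means(sim$measurements),
                           traits = "pm")
  post <- run_mcmc(sim$tree, resid, sim$truth$labels,
                   priors = rate_priors(shift_lambda = 10),
                   n_gen = 30000, seed = 8, background = FALSE,
                   state_rates = "on")
  truth_rate <- cfg$sigma2_true * sim$truth$zeta_true
  est <- colMeans(post$samples$sigma2 *
                    post$samples[, c("zeta_velocity", "zeta_unspecialized",
                                     "zeta_force")])
  expect_true(all(abs(est / truth_rate - 1) < 0.3))
})

test_that("summarize_grid averages across shift priors per cut-off", {
  fake <- function(pp, rr, unc = FALSE)
    structure(list(pp = pp,
                   rr = c(force_velocity = rr,
                          velocity_unspecialized = 0.5,
                          force_unspecialized = rr / 2),
                   unconverged = unc), class = "rate_posterior")
  grid <- list(
    list(cutoff = 10, shift_lambda = 30, posterior = fake(0.8, 2)),
    list(cutoff = 10, shift_lambda = 40, posterior = fake(1.0, 4)),
    list(cutoff = 33, shift_lambda = 30, posterior = fake(0.6, 1, TRUE))
  )
  tab <- summarize_grid(grid)
  expect_equal(tab$Model, c("10th", "33th"))
  expect_equal(tab$PP, c(0.9, 0.6))
  expect_equal(tab$RR_force_velocity, c(3, 1))
  expect_equal(tab$unconverged, c(FALSE, TRUE))
  expect_error(summarize_grid(list()), "empty")

  tab1 <- summarize_grid(grid[1])
  expect_equal(tab1$PP, 0.8)
  expect_equal(tab1$RR_force_velocity, 2)
})

test_that("shift prior presets match their two published gradients", {
  expect_equal(shift_prior_presets("methods"), c(30, 40, 50))
  expect_equal(shift_prior_presets("alternative"), c(20, 40, 60))
})

test_that("ess_iact is sane on iid and autocorrelated traces", {
  set.seed(33)
  x <- rnorm(4000)
  expect_gt(ess_iact(x), 2000)
  y <- as.numeric(stats::filter(rnorm(4000), 0.95, "recursive"))
  expect_lt(ess_iact(y), 1000)
  expect_equal(ess_iact(rep(2, 100)), Inf)
})
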