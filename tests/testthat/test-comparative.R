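test_that("shape_pca recovers a single axis of variation", {
  set.seed(10)
  s <- rnorm(40)
  X <- cbind(s, 0) + matrix(rnorm(80, 0, 1e-8), 40, 2)
  colnames(X) <- c("a", "b")
  pc <- shape_pca(X)
  expect_equal(abs(pc$loadings[, 1]), c(a = 1, b = 0), tolerance = 1e-6)
  expect_gt(pc$loadings[which.max(abs(pc$loadings[, 1])), 1], 0)
  expect_equal(pc$variance_fractions[1], 1, tolerance = 1e-10)
})

test_that("shape_pca scores are uncorrelated and reconstruct the data", {
  set.seed(11)
  X <- matrix(rnorm(200), 40, 5)
  pc <- shape_pca(X)
  S <- cov(pc$scores)
  expect_lt(max(abs(S - diag(diag(S)))), 1e-10)
  expect_equal(sum(pc$variance_fractions), 1, tolerance = 1e-10)
  expect_true(all(diff(pc$sdev) <= 1e-12))
  rec <- pc$scores %*% t(pc$loadings) +
    matrix(pc$center, 40, 5, byrow = TRUE)
  expect_equal(unname(rec), unname(X), tolerance = 1e-10)
})

test_that("shape_pca keeps zero-variance components on rank-deficient data", {
  set.seed(12)
  base <- matrix(rnorm(60), 20, 3)
  X <- cbind(base, base[, 1] + base[, 2])  # 4 traits, rank 3
  pc <- shape_pca(X)
  expect_equal(ncol(pc$loadings), 4)
  expect_lt(pc$sdev[4], 1e-10)
})

test_that("isotropic data give near-equal variance fractions", {
  set.seed(13)
  pc <- shape_pca(matrix(rnorm(30000), 10000, 3))
  expect_lt(max(abs(pc$variance_fractions - 1 / 3)), 0.02)
})

test_that("pgls matches the textbook OLS t-test on a star tree", {
  set.seed(14)
  n <- 20
  star <- read_newick(paste0("(", paste0("t", 1:n, ":1", collapse = ","),
                             ");"))
  C <- bm_covariance(star)
  x <- rnorm(n); y <- 0.3 * x + rnorm(n)
  fit <- pgls(y, x, C)
  s <- summary(lm(y ~ x))$coefficients
  expect_equal(fit$slope, s[2, 1], tolerance = 1e-10)
  expect_equal(fit$slope_se, s[2, 2], tolerance = 1e-10)
  expect_equal(fit$t_stat, s[2, 3], tolerance = 1e-10)
  expect_equal(fit$p_value, s[2, 4], tolerance = 1e-10)
  expect_equal(fit$df, n - 2)
})

test_that("pgls handles perfect fits and small samples", {
  tr <- random_tree(10)
  C <- bm_covariance(tr)
  x <- rnorm(10)
  fit <- pgls(3 * x, x, C)
  expect_equal(fit$slope, 3, tolerance = 1e-8)
  expect_equal(fit$p_value, 0)
  expect_error(pgls(rnorm(3), rnorm(3), diag(3)), "at least 4")
})

test_that("pgls type-I error is calibrated under independent Brownian traits", {
  set.seed(15)
  rej <- 0
  nsim <- 500
  trees <- replicate(5, random_tree(100), simplify = FALSE)
  chols <- lapply(trees, function(tr) chol(bm_covariance(tr)))
  Cs <- lapply(trees, bm_covariance)
  for (i in seq_len(nsim)) {
    k <- ((i - 1) %% 5) + 1
    x <- drop(crossprod(chols[[k]], rnorm(100)))
    y <- drop(crossprod(chols[[k]], rnorm(100)))
    if (pgls(y, x, Cs[[k]])$p_value < 0.05) rej <- rej + 1
  }
  expect_gte(rej / nsim, 0.03)
  expect_lte(rej / nsim, 0.07)
})

test_that("disparity is the mean squared distance to the centroid", {
  expect_equal(disparity(matrix(1, 5, 3)), 0)
  expect_equal(disparity(rbind(c(0, 0), c(2, 0))), 1)
  expect_equal(disparity(matrix(7, 1, 4)), 0)
  expect_error(disparity(matrix(numeric(0), 0, 2)), "empty")

  set.seed(16)
  X <- matrix(rnorm(60), 20, 3)
  expect_equal(disparity(X), sum(diag(cov(X))) * 19 / 20, tolerance = 1e-12)
  # translation and rotation invariant; scales as c^2
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(disparity(sweep(X, 2, c(5, -2, 1), "+")), disparity(X))
  expect_equal(disparity(X %*% Q), disparity(X), tolerance = 1e-12)
  expect_equal(disparity(3 * X), 9 * disparity(X), tolerance = 1e-12)
})

test_that("disparity_asymmetry behaves at the degenerate extremes", {
  set.seed(17)
  X <- rbind(matrix(rnorm(40), 10), matrix(rnorm(40), 10))
  rownames(X) <- paste0("s", 1:20)
  lab <- factor(rep(c("velocity", "force"), each = 10),
                levels = c("velocity", "unspecialized", "force"))
  names(lab) <- rownames(X)

  # identical groups: D = 0 and every permutation ties
  Xsame <- rbind(X[1:10, ], X[1:10, ])
  rownames(Xsame) <- paste0("s", 1:20)
  dt <- disparity_asymmetry(Xsame, lab, n_perm = 199, seed = 1)
  expect_equal(dt$d_obs, 0)
  expect_equal(dt$p_value, 1)

  # valid, reproducible p-values
  d1 <- disparity_asymmetry(X, lab, n_perm = 299, seed = 9)
  d2 <- disparity_asymmetry(X, lab, n_perm = 299, seed = 9)
  expect_identical(d1$p_value, d2$p_value)
  expect_gt(d1$p_value, 0)
  expect_lte(d1$p_value, 1)
  expect_error(disparity_asymmetry(X, lab, n_perm = 50), "at least 99")

  # undersized tail is flagged, not silently tested
  lab2 <- lab; lab2[2:10] <- "unspecialized"
  dt2 <- disparity_asymmetry(X, lab2, n_perm = 199)
  expect_true(dt2$flagged)
  expect_true(is.na(dt2$p_value))
})

test_that("disparity_asymmetry detects a 10x variance ratio", {
  set.seed(18)
  hits <- 0
  for (i in 1:20) {
    X <- rbind(matrix(rnorm(60, 0, sqrt(10)), 15), matrix(rnorm(60), 15))
    rownames(X) <- paste0("s", 1:30)
    lab <- setNames(factor(rep(c("velocity", "force"), each = 15),
                           levels = c("velocity", "unspecialized", "force")),
                    rownames(X))
    if (disparity_asymmetry(X, lab, n_perm = 999)$p_value < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("ancestral states under BM match symmetry and the ML optimum", {
  tr <- read_newick("(A:1,B:1);")
  expect_equal(unname(ancestral_states_bm(tr, c(A = 0, B = 2))), 1)

  tr2 <- random_tree(8)
  const <- setNames(rep(3.5, 8), tr2$tip.label)
  expect_equal(unname(ancestral_states_bm(tr2, const)), rep(3.5, 7),
               tolerance = 1e-10)

  # numeric-optimizer oracle: maximize the joint Brownian likelihood over
  # internal states (root included) and compare
  set.seed(19)
  tr3 <- random_tree(10)
  x <- setNames(rnorm(10), tr3$tip.label)
  est <- ancestral_states_bm(tr3, x)
  po <- ape::reorder.phylo(tr3, "postorder")
  negll <- function(anc) {
    st <- c(x[tr3$tip.label], anc)
    -sum(dnorm(st[po$edge[, 2]], st[po$edge[, 1]],
               sqrt(po$edge.length), log = TRUE))
  }
  opt <- optim(rep(mean(x), 9), negll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(unname(est), opt$par, tolerance = 1e-5)

  # cross-check against an established implementation
  if (requireNamespace("phytools", quietly = TRUE)) {
    fa <- phytools::fastAnc(tr3, x)
    expect_equal(unname(est), unname(as.numeric(fa)), tolerance = 1e-6)
  }
})
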