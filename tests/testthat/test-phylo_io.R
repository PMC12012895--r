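test_that("read_newick parses small trees and validates structure", {
  tr <- read_newick("(A:1,B:1):0;")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(sort(tr$edge.length), c(1, 1))

  tr2 <- read_newick("((A:1,B:1):1,C:2):0;")
  depths <- ape::node.depth.edgelength(tr2)
  expect_equal(unname(depths[1:3]), c(2, 2, 2))
})

test_that("read_newick rejects malformed input with located errors", {
  expect_error(read_newick("((A:1,B:1):1;"), "unclosed")
  expect_error(read_newick("(A:1,B:1)):1;"), "offset")
  expect_error(read_newick("(A:1,B);"), "branch length")
  expect_error(read_newick("(A:1,A:1);"), "duplicate")
  expect_error(read_newick(), "exactly one")
})

test_that("polytomies resolve deterministically into zero-length branches", {
  tr <- read_newick("(A:1,B:1,C:1,D:1);")
  expect_true(ape::is.binary(tr))
  expect_equal(sum(tr$edge.length == 0), 2)
  tr2 <- read_newick("(A:1,B:1,C:1,D:1);")
  expect_identical(write_newick(tr), write_newick(tr2))
  # downstream covariance is unaffected by the zero-length resolution
  C <- bm_covariance(tr)
  expect_equal(unname(C), diag(4), tolerance = 1e-12)
})

test_that("newick round-trip is lossless on simulated trees", {
  set.seed(101)
  for (i in 1:100) {
    tr <- random_tree(sample(4:40, 1))
    tr2 <- read_newick(write_newick(tr))
    expect_equal(ape::Ntip(tr2), ape::Ntip(tr))
    d1 <- ape::cophenetic.phylo(tr)
    d2 <- ape::cophenetic.phylo(tr2)
    expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-12)
  }
})

test_that("prune_to preserves pairwise path lengths", {
  tr <- read_newick("((A:1,B:1):1,C:2):0;")
  pr <- prune_to(tr, c("A", "B"))
  expect_setequal(pr$tip.label, c("A", "B"))
  expect_equal(ape::cophenetic.phylo(pr)["A", "B"], 2)

  pr_all <- prune_to(tr, tr$tip.label)
  expect_equal(ape::cophenetic.phylo(pr_all), ape::cophenetic.phylo(tr))

  expect_error(prune_to(tr, c("A", "Z", "Q")), "Z, Q")
  expect_error(prune_to(tr, "A"), "at least 2")

  set.seed(102)
  for (i in 1:50) {
    big <- random_tree(sample(8:40, 1))
    keep <- sample(big$tip.label, sample(3:ape::Ntip(big), 1))
    d_before <- ape::cophenetic.phylo(big)[keep, keep]
    d_after <- ape::cophenetic.phylo(prune_to(big, keep))[keep, keep]
    expect_equal(d_after, d_before, tolerance = 1e-10)
  }
})

test_that("bm_covariance reads shared root paths", {
  star <- read_newick("(A:3,B:3,C:3,D:3);")
  expect_equal(unname(bm_covariance(star)), 3 * diag(4), tolerance = 1e-12)

  tr <- read_newick("((A:1,B:1):1,C:2):0;")
  C <- bm_covariance(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "A"], 2)
  expect_equal(C["A", "C"], 0)

  # rate-weighted version: doubling all rates doubles the covariance
  r <- rep(2, nrow(tr$edge))
  expect_equal(bm_covariance(tr, r), 2 * C)
  expect_error(bm_covariance(tr, rep(-1, nrow(tr$edge))), "positive")
  expect_error(bm_covariance(tr, 1:3), "per branch")
})

test_that("bm_covariance is PSD and matches brute-force BM simulation", {
  set.seed(103)
  for (i in 1:20) {
    tr <- random_tree(sample(5:30, 1))
    rates <- runif(nrow(tr$edge), 0.2, 3)
    C <- bm_covariance(tr, rates)
    expect_gte(min(eigen(C, symmetric = TRUE)$values), -1e-9)
  }
  # simulation oracle: edge-wise BM draws reproduce the analytic covariance
  tr <- random_tree(20)
  C <- bm_covariance(tr)
  po <- ape::reorder.phylo(tr, "postorder")
  nsim <- 50000
  x <- matrix(0, ape::Ntip(tr) + tr$Nnode, nsim)
  for (e in rev(seq_len(nrow(po$edge)))) {
    x[po$edge[e, 2], ] <- x[po$edge[e, 1], ] +
      rnorm(nsim, 0, sqrt(po$edge.length[e]))
  }
  Cemp <- cov(t(x[seq_len(ape::Ntip(tr)), ]))
  dimnames(Cemp) <- list(tr$tip.label, tr$tip.label)
  expect_lt(max(abs(Cemp[rownames(C), colnames(C)] - C)), 0.03)
})

test_that("measurement tables validate, read, and collapse to species means", {
  tab <- data.frame(species = c("a", "a", "b"), sl = c(10, 20, 30),
                    il = 1:3, ol = 4:6, pm = 1:3, mx = 1:3, na = 1:3,
                    oc = 1:3, snl = 1:3)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  rd <- read_measurements(f)
  expect_equal(nrow(rd), 3)

  m <- species_means(rd)
  expect_equal(nrow(m), 2)
  expect_equal(m$sl[m$species == "a"], 15)
  expect_equal(m$sl[m$species == "b"], 30)

  mg <- species_means(rd, scale = "log")
  expect_equal(mg$sl[mg$species == "a"], exp(mean(log(c(10, 20)))))

  bad <- tab; bad$sl[2] <- -5
  expect_error(validate_measurements(bad), "row 2")
  expect_error(validate_measurements(tab[, -2]), "sl")
})

test_that("specimen tables with ~303 rows collapse to 89 species", {
  sim <- simulate_dataset(sim_config(seed = 42))
  expect_equal(length(unique(sim$measurements$species)), 89)
  expect_gt(nrow(sim$measurements), 200)
  m <- species_means(sim$measurements)
  expect_equal(nrow(m), 89)
})
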