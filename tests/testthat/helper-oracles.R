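# Independent oracles used across test files.

# random birth-death tree rescaled to unit depth
random_tree <- function(n, birth = 1, death = 0.3) {
  tr <- ape::rphylo(n, birth, death)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

# random correlation matrix
random_corr <- function(p) {
  A <- matrix(rnorm(p * p), p, p)
  stats::cov2cor(crossprod(A) + diag(p))
}

# dense multivariate-normal log-likelihood oracle for correlated Brownian
# motion with per-trait GLS root states profiled out
dense_mvbm_loglik <- function(tree, Y, rates = NULL, R = NULL, sigma2 = 1) {
  C <- bm_covariance(tree, rates)
  Y <- Y[rownames(C), , drop = FALSE]
  n <- nrow(Y); p <- ncol(Y)
  if (is.null(R)) R <- diag(p)
  Ci <- solve(C)
  one <- rep(1, n)
  mu <- drop((t(one) %*% Ci %*% Y) / drop(t(one) %*% Ci %*% one))
  r <- as.vector(t(Y - outer(one, mu)))
  S <- sigma2 * kronecker(C, R)
  -0.5 * (length(r) * log(2 * pi) +
            as.numeric(determinant(S)$modulus) +
            drop(t(r) %*% solve(S) %*% r))
}

# symmetric 3-state CTMC transition probability matrix
ctmc_pmat <- function(q, t) {
  E <- exp(-3 * q * t)
  m <- matrix((1 - E) / 3, 3, 3)
  diag(m) <- (1 + 2 * E) / 3
  m
}

# exact joint distribution of internal-node states given tips, by
# enumeration (small trees only)
ctmc_node_posterior <- function(tree, tip_states_int, q) {
  po <- ape::reorder.phylo(tree, "postorder")
  ed <- po$edge; el <- po$edge.length
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1):(ntip + tree$Nnode)
  combs <- as.matrix(expand.grid(rep(list(1:3), length(nodes))))
  prob <- apply(combs, 1, function(cc) {
    st <- c(tip_states_int, cc)
    pr <- 1 / 3
    for (e in seq_len(nrow(ed)))
      pr <- pr * ctmc_pmat(q, el[e])[st[ed[e, 1]], st[ed[e, 2]]]
    pr
  })
  list(combs = combs, prob = prob / sum(prob), edge = ed, len = el,
       tip_states = tip_states_int, ntip = ntip)
}

# expected i->j transition counts on one branch conditional on endpoints
ctmc_expected_counts_branch <- function(a, b, t, q) {
  m <- matrix(0, 3, 3)
  Pab <- ctmc_pmat(q, t)[a, b]
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    f <- function(u) ctmc_pmat(q, u)[a, i] * ctmc_pmat(q, t - u)[j, b]
    m[i, j] <- q * stats::integrate(Vectorize(f), 0, t,
                                    rel.tol = 1e-10)$value / Pab
  }
  m
}

# expected transition-count matrix over the whole tree given tip states
ctmc_expected_counts_tree <- function(tree, tip_states_int, q) {
  post <- ctmc_node_posterior(tree, tip_states_int, q)
  Etot <- matrix(0, 3, 3)
  for (e in seq_len(nrow(post$edge))) {
    for (ci in seq_len(nrow(post$combs))) {
      st <- c(post$tip_states, post$combs[ci, ])
      a <- st[post$edge[e, 1]]; b <- st[post$edge[e, 2]]
      Etot <- Etot +
        post$prob[ci] * ctmc_expected_counts_branch(a, b, post$len[e], q)
    }
  }
  Etot
}

# count realized transitions of a sampled history, split by (from, to)
history_transition_matrix <- function(h) {
  lv <- c("velocity", "unspecialized", "force")
  m <- matrix(0, 3, 3)
  if (nrow(h$jumps) == 0) return(m)
  for (e in unique(h$jumps$edge)) {
    jj <- h$jumps[h$jumps$edge == e, ]
    prev <- match(h$node_states[h$tree_postorder$edge[e, 1]], lv)
    for (k in seq_len(nrow(jj))) {
      cur <- match(jj$state[k], lv)
      m[prev, cur] <- m[prev, cur] + 1
      prev <- cur
    }
  }
  m
}

# simulate correlated multivariate Brownian tips directly from the dense
# covariance (independent of the package's preorder simulation)
dense_mvbm_sim <- function(C, R, sigma2, nsims) {
  n <- nrow(C); p <- nrow(R)
  L <- chol(sigma2 * kronecker(C, R))
  Z <- matrix(rnorm(nsims * n * p), nsims) %*% L
  Z  # each row: vec(t(Y)) with species-major blocks of length p
}
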