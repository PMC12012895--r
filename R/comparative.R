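#' Principal components of size-corrected shape
#'
#' Ordinary (non-phylogenetic) PCA of the column-centered residual matrix,
#' giving uncorrelated axes of craniofacial shape.  The sign of each
#' component is fixed so that its largest-magnitude loading is positive.
#' Rank-deficient inputs keep their trailing zero-variance components so
#' there is always one component per trait.
#'
#' @param residuals species x traits matrix from [residual_matrix()].
#' @return a list of class \code{"jaw_pca"} with \code{loadings}
#'   (traits x components), \code{scores} (species x components),
#'   \code{variance_fractions} and \code{sdev}.
#' @export
shape_pca <- function(residuals) {
  residuals <- as.matrix(residuals)
  if (nrow(residuals) < 2 || ncol(residuals) < 2)
    stop("need at least 2 species and 2 traits")
  if (anyNA(residuals)) stop("missing values in residual matrix")
  p <- ncol(residuals)
  pc <- prcomp(residuals, center = TRUE, scale. = FALSE)
  load <- pc$rotation
  scores <- pc$x
  sdev <- pc$sdev
  if (ncol(load) < p) {                      # retain zero-variance components
    extra <- p - ncol(load)
    load <- cbind(load, matrix(0, p, extra))
    scores <- cbind(scores, matrix(0, nrow(scores), extra))
    sdev <- c(sdev, rep(0, extra))
    colnames(load) <- colnames(scores) <- paste0("PC", seq_len(p))
  }
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, `*`)
  scores <- sweep(scores, 2, flip, `*`)
  vf <- sdev^2 / sum(sdev^2)
  structure(list(loadings = load, scores = scores,
                 variance_fractions = vf, sdev = sdev,
                 center = pc$center),
            class = "jaw_pca")
}

#' Phylogenetic generalized least squares regression
#'
#' Regresses a response (typically a PC score axis) on a predictor
#' (typically mechanical advantage) with Brownian error covariance
#' \code{C}.  Slope standard error uses
#' \eqn{\hat\sigma^2 = r' C^{-1} r / (n - 2)}; the two-sided p-value comes
#' from the t distribution with \eqn{n - 2} degrees of freedom.  On a star
#' phylogeny (\code{C} proportional to the identity) the fit reduces exactly
#' to ordinary least squares.
#'
#' @param y response values, tip order.
#' @param x predictor values, tip order.
#' @param C Brownian covariance from [bm_covariance()].
#' @return a list of class \code{"pgls_fit"}: \code{slope},
#'   \code{intercept}, \code{slope_se}, \code{t_stat}, \code{p_value},
#'   \code{df}.
#' @export
pgls <- function(y, x, C) {
  n <- length(y)
  if (n < 4) stop("need at least 4 species (df would be <= 1)")
  stopifnot(length(x) == n, nrow(C) == n, ncol(C) == n)
  fit <- .gls_fit(y, cbind(1, x), C)
  df <- n - 2
  s2 <- fit$rss_w / df
  if (s2 < 1e-300) {            # exact linear relationship
    se <- 0
    tval <- sign(fit$beta[2]) * Inf
    pval <- 0
  } else {
    se <- sqrt(s2 * fit$XtX_inv[2, 2])
    tval <- fit$beta[2] / se
    pval <- 2 * pt(-abs(tval), df)
  }
  structure(list(slope = unname(fit$beta[2]), intercept = unname(fit$beta[1]),
                 slope_se = se, t_stat = tval, p_value = pval, df = df),
            class = "pgls_fit")
}

#' PGLS of every shape axis on mechanical advantage
#'
#' @param pca a \code{"jaw_pca"} object.
#' @param ma per-species mechanical advantage, tip order.
#' @param C Brownian covariance.
#' @param holm apply a Holm correction across axes (off by default; each
#'   axis is reported at its nominal p-value).
#' @return data.frame with one row per component.
#' @export
pgls_by_axis <- function(pca, ma, C, holm = FALSE) {
  stopifnot(inherits(pca, "jaw_pca"))
  fits <- lapply(seq_len(ncol(pca$scores)), function(k)
    pgls(pca$scores[, k], ma, C))
  out <- data.frame(
    axis = colnames(pca$scores),
    variance_fraction = pca$variance_fractions,
    slope = vapply(fits, `[[`, numeric(1), "slope"),
    slope_se = vapply(fits, `[[`, numeric(1), "slope_se"),
    t_stat = vapply(fits, `[[`, numeric(1), "t_stat"),
    p_value = vapply(fits, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  if (holm) out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  rownames(out) <- NULL
  out
}

#' Morphological disparity of a group
#'
#' Disparity is the variance of a group in trait space: the mean squared
#' Euclidean distance of its members from the group centroid
#' (\eqn{V = \frac{1}{n}\sum_i \|x_i - \bar x\|^2}), equivalently the trace
#' of the maximum-likelihood covariance matrix.
#'
#' @param points species x traits matrix (or vector for one trait).
#' @return a nonnegative scalar; 0 for a single row or identical rows.
#' @export
disparity <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("empty group")
  ctr <- colMeans(points)
  mean(rowSums(sweep(points, 2, ctr)^2))
}

#' Permutation test of disparity asymmetry between the trade-off extremes
#'
#' Tests whether velocity- and force-modified jaws differ in disparity.
#' The statistic is \eqn{D = V_{velocity} - V_{force}}; the null is built by
#' randomly reassigning the velocity/force labels among the pooled tail
#' species with group sizes fixed, and the two-sided p-value is
#' \eqn{(1 + \#\{|D^*| \ge |D|\}) / (n_{perm} + 1)}.
#'
#' @param residuals species x traits residual matrix, rows named by species.
#' @param labels specialization factor from [classify_specialization()].
#' @param n_perm number of permutations (at least 99; default 999).
#' @param seed optional seed for reproducibility.
#' @return list of class \code{"disparity_test"} with the three group
#'   disparities, \code{d_obs}, \code{p_value} (NA when a tail has fewer
#'   than 2 species, with \code{flagged = TRUE}), and tail sizes.
#' @export
disparity_asymmetry <- function(residuals, labels, n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  residuals <- as.matrix(residuals)
  stopifnot(length(labels) == nrow(residuals))
  if (!is.null(seed)) set.seed(seed)
  iv <- which(labels == "velocity")
  iff <- which(labels == "force")
  iu <- which(labels == "unspecialized")
  if (!length(iv) || !length(iff)) stop("both tails must be non-empty")
  dv <- disparity(residuals[iv, , drop = FALSE])
  df_ <- disparity(residuals[iff, , drop = FALSE])
  du <- if (length(iu)) disparity(residuals[iu, , drop = FALSE]) else NA_real_
  d_obs <- dv - df_
  flagged <- length(iv) < 2 || length(iff) < 2
  p <- NA_real_
  if (!flagged) {
    pool <- residuals[c(iv, iff), , drop = FALSE]
    m <- nrow(pool)
    n1 <- length(iv)
    sq <- rowSums(pool^2)
    dstar <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      idx <- sample.int(m)
      i1 <- idx[seq_len(n1)]
      i2 <- idx[(n1 + 1):m]
      v1 <- mean(sq[i1]) - sum(colMeans(pool[i1, , drop = FALSE])^2)
      v2 <- mean(sq[i2]) - sum(colMeans(pool[i2, , drop = FALSE])^2)
      dstar[b] <- v1 - v2
    }
    p <- (1 + sum(abs(dstar) >= abs(d_obs))) / (n_perm + 1)
  }
  structure(list(disparity_velocity = dv, disparity_force = df_,
                 disparity_unspecialized = du, d_obs = d_obs, p_value = p,
                 n_velocity = length(iv), n_force = length(iff),
                 flagged = flagged, n_perm = n_perm),
            class = "disparity_test")
}

#' Disparity asymmetry profile across the cut-off gradient
#'
#' Runs [disparity_asymmetry()] at each percentile cut-off and returns one
#' row per cut-off, mirroring the usual velocity-vs-force disparity plot:
#' points off the 1:1 line indicate an asymmetrical constraint.
#'
#' @param residuals species x traits residual matrix.
#' @param ma per-species mechanical advantage, same row order.
#' @param percentiles cut-off gradient (default [specialization_cutoffs()]).
#' @param n_perm permutations per cut-off.
#' @param seed optional seed.
#' @return data.frame with one row per cut-off.
#' @export
disparity_profile <- function(residuals, ma,
                              percentiles = specialization_cutoffs(),
                              n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(percentiles, function(pp) {
    lab <- classify_specialization(ma, pp)
    dt <- disparity_asymmetry(residuals, lab, n_perm = n_perm)
    data.frame(percentile = pp,
               disparity_velocity = dt$disparity_velocity,
               disparity_force = dt$disparity_force,
               disparity_unspecialized = dt$disparity_unspecialized,
               d_obs = dt$d_obs, p_velocity_vs_force = dt$p_value,
               n_velocity = dt$n_velocity, n_force = dt$n_force,
               flagged = dt$flagged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' GLS/ML estimates of internal-node states for a continuous trait under
#' Brownian motion; the root estimate equals the GLS grand mean of the tips.
#'
#' @param tree a \code{"phylo"} object.
#' @param x named tip values (tip order of the tree).
#' @return named vector of estimates for internal nodes (ape node numbers).
#' @export
ancestral_states_bm <- function(tree, x) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (length(x) != n) stop("need one value per tip")
  if (!is.null(names(x))) x <- x[tree$tip.label]
  D <- ape::dist.nodes(tree)
  root <- n + 1L
  depth <- D[root, ]
  nodes <- (n + 1L):(n + tree$Nnode)
  Ctt <- outer(depth[1:n], depth[1:n], `+`) - D[1:n, 1:n]
  Ctt <- Ctt / 2
  Cat <- (outer(depth[nodes], depth[1:n], `+`) - D[nodes, 1:n, drop = FALSE]) / 2
  U <- .chol_factor(Ctt)
  ones <- rep(1, n)
  Ci1 <- backsolve(U, backsolve(U, ones, transpose = TRUE))
  mu <- sum(Ci1 * x) / sum(Ci1)
  w <- backsolve(U, backsolve(U, x - mu, transpose = TRUE))
  est <- drop(mu + Cat %*% w)
  names(est) <- nodes
  est
}
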