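#' Mechanical advantage of a lever
#'
#' The mechanical advantage (MA) of the lower jaw is the ratio of the
#' in-lever to the out-lever.  Low MA transmits velocity, high MA transmits
#' force; a lever cannot do both, which is the trade-off the whole pipeline
#' interrogates.  MA is dimensionless and invariant to uniform rescaling of
#' both levers.
#'
#' @param il in-lever length(s), positive.
#' @param ol out-lever length(s), positive.
#' @return \code{il / ol}, with names retained from \code{il}.
#' @export
mechanical_advantage <- function(il, ol) {
  if (any(il <= 0) || any(ol <= 0))
    stop("lever lengths must be strictly positive")
  il / ol
}

## Cholesky solve with a small diagonal jitter retry; zero-length branches
## from polytomy resolution can leave C numerically singular.
.chol_factor <- function(C) {
  U <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(U))
    U <- chol(C + diag(1e-10 * mean(diag(C)), nrow(C)))
  U
}

.gls_fit <- function(y, X, C) {
  U <- .chol_factor(C)                       # C = U'U
  yt <- backsolve(U, y, transpose = TRUE)    # U'^-1 y
  Xt <- backsolve(U, X, transpose = TRUE)
  XtX <- crossprod(Xt)
  if (rcond(XtX) < 1e-12)
    stop("size has no variance (singular GLS design)")
  beta <- solve(XtX, crossprod(Xt, yt))
  r <- y - X %*% beta
  rt <- yt - Xt %*% beta
  list(beta = drop(beta), residuals = drop(r), rss_w = drop(crossprod(rt)),
       XtX_inv = solve(XtX))
}

#' Phylogenetic (GLS) residuals of a trait on body size
#'
#' Fits the allometric regression of an ln-trait on ln-standard-length by
#' generalized least squares with Brownian error covariance \code{C}, and
#' returns the residuals used as size-corrected shape variables.  The GLS
#' estimate is \eqn{\hat\beta = (X' C^{-1} X)^{-1} X' C^{-1} y} with
#' \eqn{X = [1, x]}; residuals satisfy \eqn{X' C^{-1} r = 0}.
#'
#' @param y ln-trait values, one per species (tip order of the tree).
#' @param x ln-standard-length values, same order.
#' @param C Brownian covariance from [bm_covariance()].
#' @return a list with \code{residuals}, \code{intercept}, \code{slope}.
#' @export
phylo_residuals <- function(y, x, C) {
  n <- length(y)
  stopifnot(length(x) == n, nrow(C) == n, ncol(C) == n)
  fit <- .gls_fit(y, cbind(1, x), C)
  res <- fit$residuals
  names(res) <- names(y)
  list(residuals = res, intercept = fit$beta[1], slope = fit$beta[2])
}

#' Size-corrected trait matrix from species means
#'
#' Joins a species-mean measurement table to a tree, ln-transforms the
#' craniofacial traits, and removes allometry by phylogenetic residuals of
#' each ln-trait on ln-standard-length.  The out-lever (mandible length) is
#' retained as a shape trait; the in-lever is used only for mechanical
#' advantage and is excluded from the response matrix.
#'
#' @param tree a \code{"phylo"} object.
#' @param means species-mean table from [species_means()].
#' @param traits response trait columns (default the six craniofacial
#'   traits \code{pm, mx, na, oc, snl, ol}).
#' @return a species x traits matrix of residuals, rows in canonical tip
#'   order, with attributes \code{slopes} and \code{intercepts}.
#' @export
residual_matrix <- function(tree, means,
                            traits = c("pm", "mx", "na", "oc", "snl", "ol")) {
  stopifnot(inherits(tree, "phylo"))
  only_tree <- setdiff(tree$tip.label, means$species)
  only_tab <- setdiff(means$species, tree$tip.label)
  if (length(only_tree) || length(only_tab))
    stop("species mismatch between tree and measurements; only in tree: {",
         paste(only_tree, collapse = ", "), "}; only in table: {",
         paste(only_tab, collapse = ", "), "}")
  means <- means[match(canonical_order(tree), means$species), , drop = FALSE]
  C <- bm_covariance(tree)
  lnsl <- log(means$sl)
  out <- matrix(NA_real_, nrow(means), length(traits),
                dimnames = list(means$species, traits))
  slopes <- intercepts <- setNames(numeric(length(traits)), traits)
  for (tr in traits) {
    fit <- phylo_residuals(log(means[[tr]]), lnsl, C)
    out[, tr] <- fit$residuals
    slopes[tr] <- fit$slope
    intercepts[tr] <- fit$intercept
  }
  attr(out, "slopes") <- slopes
  attr(out, "intercepts") <- intercepts
  out
}

#' Specialization cut-off gradient
#'
#' The percentile cut-offs used to deem a jaw velocity- or force-modified:
#' the 10th, 15th, 17.5th, 22.5th, and 33rd percentiles along each extreme
#' of mechanical advantage.
#'
#' @return numeric vector of percentiles.
#' @export
specialization_cutoffs <- function() c(10, 15, 17.5, 22.5, 33)

#' Classify species along the velocity-force trade-off
#'
#' Species with mechanical advantage at or below the lower percentile
#' cut-off are velocity-modified; those at or above the upper
#' (100 - percentile) cut-off are force-modified; the rest are
#' unspecialized.  Percentiles use linear interpolation between order
#' statistics (R's default quantile type 7); ties at a threshold go to the
#' specialized class so tails are never empty.
#'
#' @param ma named vector of per-species mechanical advantage.
#' @param percentile tail percentile in the open interval (0, 50).
#' @return a named factor with levels
#'   \code{velocity, unspecialized, force} and attributes \code{percentile}
#'   and \code{cutoffs} (the two MA threshold values).
#' @export
classify_specialization <- function(ma, percentile) {
  if (length(percentile) != 1 || percentile <= 0 || percentile >= 50)
    stop("percentile must lie strictly between 0 and 50 (tails would overlap)")
  if (length(ma) < 3) stop("need at least 3 species")
  if (any(ma <= 0)) stop("mechanical advantage must be positive")
  if (length(unique(ma)) == 1) stop("no MA variance")
  lo <- unname(quantile(ma, percentile / 100, type = 7))
  hi <- unname(quantile(ma, 1 - percentile / 100, type = 7))
  if (lo >= hi) stop("cut-offs overlap; too many tied MA values")
  lab <- rep("unspecialized", length(ma))
  lab[ma <= lo] <- "velocity"
  lab[ma >= hi] <- "force"
  lab <- factor(lab, levels = c("velocity", "unspecialized", "force"))
  names(lab) <- names(ma)
  attr(lab, "percentile") <- percentile
  attr(lab, "cutoffs") <- c(lower = lo, upper = hi)
  lab
}
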