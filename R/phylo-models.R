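#' Brownian-motion phylogenetic covariance matrix
#'
#' Under Brownian motion the covariance of trait values at tips i and j is
#' proportional to the shared root-to-MRCA path length, so
#' `C[i, j] = depth of mrca(i, j)` and `C[i, i] = depth of tip i`.
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @return an n x n symmetric matrix with tip labels as dimnames.
#' @export
bm_covariance <- function(tree) {
  tree <- validate_phylo(tree)
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Phylogenetic distance matrices
#'
#' Computes the patristic distance matrix (sum of branch lengths along the
#' path between two tips) and the "one minus correlation" distance
#' `D = 1 - R`, `R[i, j] = C[i, j] / sqrt(C[i, i] * C[j, j])`, used to
#' weight the phylogenetic autocovariate in [phylo_autocovariate()].
#'
#' @param tree a `"phylo"` object.
#' @return a list with elements `patristic` and `one_minus_corr` (both
#'   n x n, zero diagonal) and `labels`.
#' @export
phylo_distances <- function(tree) {
  tree <- validate_phylo(tree)
  C <- bm_covariance(tree)
  pat <- as.matrix(stats::cophenetic(tree))[rownames(C), colnames(C)]
  R <- C / sqrt(outer(diag(C), diag(C)))
  D <- 1 - R
  diag(D) <- 0
  off <- D[upper.tri(D)]
  if (any(off <= 0))
    warning("tips with phylogenetic correlation 1 (distance 0) present")
  list(patristic = pat, one_minus_corr = D, labels = rownames(C))
}

#' Pagel's lambda transform of a Brownian covariance
#'
#' Multiplies the off-diagonal entries of `C` by `lambda`, leaving the
#' diagonal untouched.  `lambda = 1` is Brownian motion; `lambda = 0`
#' removes all phylogenetic covariance (a star tree).
#'
#' @param C covariance matrix from [bm_covariance()].
#' @param lambda scalar in `[0, 1]`.
#' @return the transformed covariance matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  V <- lambda * C
  diag(V) <- diag(C)
  V
}

#' Ornstein-Uhlenbeck covariance on an ultrametric tree
#'
#' For a stationary OU process with strength `alpha` on an ultrametric tree
#' of depth `T`, with `t_ij` the shared path length (the BM covariance),
#' `V[i, j] = exp(-2 * alpha * (T - t_ij)) * (1 - exp(-2 * alpha * t_ij)) /
#' (2 * alpha)`.  As `alpha -> 0` this approaches the BM covariance; for
#' large `alpha` it approaches `diag(1 / (2 * alpha))` (white noise).
#'
#' @param tree an ultrametric `"phylo"` object (depth spread at most
#'   `1e-6` of the depth); non-ultrametric trees are rejected —
#'   ultrametricize outside this package if needed.
#' @param alpha constraint strength, `> 0`, in 1/time units of the tree.
#' @return the OU covariance matrix.
#' @export
ou_transform <- function(tree, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0)
    stop("alpha must be a single positive value")
  C <- bm_covariance(tree)
  depths <- diag(C)
  T_ <- mean(depths)
  if (diff(range(depths)) > 1e-6 * T_)
    stop("tree is not ultrametric (tip depth spread ",
         signif(diff(range(depths)), 3), "); the OU transform requires an ",
         "ultrametric tree — ultrametricize before calling")
  V <- exp(-2 * alpha * (T_ - C)) * (1 - exp(-2 * alpha * C)) / (2 * alpha)
  dimnames(V) <- dimnames(C)
  V
}

#' Profiled Gaussian GLS log-likelihood
#'
#' The likelihood engine shared by every stage: for `y ~ N(X beta,
#' sigma2 * V)` it profiles out `beta` and `sigma2` analytically,
#' `beta = (X' V^-1 X)^-1 X' V^-1 y`, `sigma2 = r' V^-1 r / n` (ML divisor
#' `n`), and returns `loglik = -(n * log(2 * pi * sigma2) + log|V| + n) / 2`.
#' Solves go through the Cholesky factor of `V`; `V` is never inverted
#' explicitly.  A near-singular `V` gets one diagonal jitter of
#' `1e-10 * mean(diag(V))` with a warning.  A perfect fit (`sigma2 = 0`)
#' returns a large finite log-likelihood sentinel with `degenerate = TRUE`
#' so optimizers stay well behaved.
#'
#' @param y numeric response vector.
#' @param X design matrix (include the intercept column yourself).
#' @param V positive-definite covariance structure matrix, rows aligned
#'   with `y`.
#' @return a list with `beta`, `sigma2`, `loglik`, `logdetV`, `rss`, `n`,
#'   `p`, `degenerate`, and the whitened design (`zy`, `zX`) used for
#'   standard errors downstream.
#' @export
gls_profile_loglik <- function(y, X, V) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n)
    stop("dimension mismatch between y, X and V")
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    warning("V is not positive definite; adding diagonal jitter ",
            "1e-10 * mean(diag(V))")
    V <- V + diag(1e-10 * mean(diag(V)), n)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) {
      ev <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
      stop("V is not positive definite (smallest eigenvalue ",
           signif(ev, 4), ")")
    }
  }
  zy <- backsolve(R, y, transpose = TRUE)
  zX <- backsolve(R, X, transpose = TRUE)
  qz <- qr(zX)
  if (qz$rank < ncol(X))
    stop("design matrix is rank deficient after whitening (rank ", qz$rank,
         " < ", ncol(X), ")")
  beta <- qr.coef(qz, zy)
  resid <- zy - zX %*% beta
  rss <- sum(resid^2)
  logdetV <- 2 * sum(log(diag(R)))
  sigma2 <- rss / n
  degenerate <- rss <= 1e-12 * max(1, sum(zy^2))
  loglik <- if (degenerate) {
    warning("exact fit: sigma2 = 0; returning a large finite log-likelihood")
    1e10
  } else {
    -0.5 * (n * log(2 * pi * sigma2) + logdetV + n)
  }
  list(beta = stats::setNames(as.numeric(beta), colnames(X)),
       sigma2 = sigma2, loglik = loglik, logdetV = logdetV, rss = rss,
       n = n, p = ncol(X), degenerate = degenerate,
       zy = as.numeric(zy), zX = zX, qr = qz)
}

# profile the lambda transform over [0, 1] for fixed y, X, C.
# coarse grid then golden-section refinement in the bracketing interval;
# endpoints compared explicitly because the profile can be flat or bimodal
# on small trees.
profile_lambda <- function(y, X, C, grid_n = 21L, tol = 1e-7) {
  f <- function(lam)
    suppressWarnings(gls_profile_loglik(y, X, lambda_transform(C, lam))$loglik)
  grid <- seq(0, 1, length.out = grid_n)
  ll <- vapply(grid, f, numeric(1))
  if (any(!is.finite(ll)))
    stop("non-finite profile likelihood at lambda = ",
         paste(signif(grid[!is.finite(ll)], 3), collapse = ", "))
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_n, i + 1L)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
  if (opt$objective >= ll[i])
    list(lambda = opt$maximum, loglik = opt$objective, profile = cbind(
      lambda = grid, loglik = ll))
  else
    list(lambda = grid[i], loglik = ll[i], profile = cbind(
      lambda = grid, loglik = ll))
}
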