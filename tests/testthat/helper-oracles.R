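# Independent oracles used across the test files.  Each re-derives a
# quantity by a route the implementation does not take.

# Brownian covariance by explicit path enumeration: for every pair of tips,
# accumulate the branch lengths shared by both root-to-tip paths.
bf_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  nn <- max(tree$edge)
  parent <- integer(nn)
  elen <- numeric(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_nodes <- function(tip) {
    v <- tip
    out <- integer(0)
    while (v != root) {
      out <- c(out, v)
      v <- parent[v]
    }
    out
  }
  paths <- lapply(seq_len(n), path_nodes)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n))
    C[i, j] <- sum(elen[intersect(paths[[i]], paths[[j]])])
  C
}

# patristic distances as weighted shortest paths in an undirected graph
ig_patristic <- function(tree) {
  g <- igraph::graph_from_edgelist(
    apply(tree$edge, 2, as.character), directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  d <- igraph::distances(g)
  ids <- as.character(seq_along(tree$tip.label))
  out <- d[ids, ids]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# minimum check loss over every p-subset of interpolating points (every LP
# vertex); the quantile-regression optimum must match it
enum_qr_objective <- function(y, X, tau) {
  n <- length(y)
  p <- ncol(X)
  best <- Inf
  idx <- utils::combn(n, p)
  for (k in seq_len(ncol(idx))) {
    h <- idx[, k]
    b <- tryCatch(solve(X[h, , drop = FALSE], y[h]),
                  error = function(e) NULL)
    if (is.null(b)) next
    r <- y - as.numeric(X %*% b)
    best <- min(best, sum(r * (tau - (r < 0))))
  }
  best
}

# GLS estimates and log-likelihood by explicit matrix inversion and a
# direct multivariate-normal density evaluation
direct_gls <- function(y, X, V) {
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - as.numeric(X %*% beta)
  n <- length(y)
  s2 <- as.numeric(t(r) %*% Vi %*% r) / n
  S <- s2 * V
  ll <- -0.5 * (n * log(2 * pi) +
                  as.numeric(determinant(S)$modulus) +
                  as.numeric(t(r) %*% solve(S) %*% r))
  list(beta = as.numeric(beta), sigma2 = s2, loglik = ll)
}

# double-loop autocovariate
bf_autocov <- function(r, D) {
  n <- length(r)
  a <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    den <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      w <- 1 / D[i, j]^2
      num <- num + w * r[j]
      den <- den + w
    }
    a[i] <- num / den
  }
  a
}

# a fixed small comparative dataset used by several files
make_small_sim <- function(seed = 7, n = 36, ...) {
  simulate_trait_env_dataset(sim_config(seed = seed, n_taxa = n, ...))
}
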