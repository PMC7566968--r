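# Bounded-variable two-phase revised simplex:
#   minimize c'x  subject to  A x = b,  0 <= x <= u
# Small-basis problems only (m = number of equality constraints is the
# regression dimension here, so m <= ~4 while n can be hundreds).  Entering
# variable by Dantzig's rule with deterministic smallest-index tie-breaks,
# falling back to Bland's rule after a run of degenerate pivots so cycling
# is impossible.  The basis system is re-solved from scratch every
# iteration (m is tiny), which keeps the arithmetic exact to solver
# precision with no accumulated update error.
#
# Returns list(x, value, basis, pi, iter).  `pi` are the equality-constraint
# multipliers at the optimum (for the quantile-regression dual these are
# minus the primal coefficients).
lp_bounded_simplex <- function(A, b, cvec, upper, tol = 1e-9,
                               max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(b) == m, length(cvec) == n, length(upper) == n)
  if (is.null(max_iter)) max_iter <- 100L * (n + m) + 1000L
  s <- ifelse(b >= 0, 1, -1)
  A2 <- cbind(A, diag(s, m))
  upper2 <- c(upper, rep(Inf, m))
  N <- n + m
  basis <- n + seq_len(m)
  in_basis <- c(rep(FALSE, n), rep(TRUE, m))
  at_upper <- rep(FALSE, N)
  structural <- c(rep(TRUE, n), rep(FALSE, m))

  xB_of <- function(basis, at_upper) {
    up <- which(!in_basis & at_upper & upper2 < Inf)
    rhs <- b
    if (length(up)) rhs <- rhs - A2[, up, drop = FALSE] %*% upper2[up]
    as.numeric(solve(A2[, basis, drop = FALSE], rhs))
  }

  run_phase <- function(costs, allow_enter) {
    degen_run <- 0L
    for (it in seq_len(max_iter)) {
      B <- A2[, basis, drop = FALSE]
      xB <- xB_of(basis, at_upper)
      pi <- as.numeric(solve(t(B), costs[basis]))
      d <- costs - as.numeric(crossprod(A2, pi))
      elig <- !in_basis & allow_enter &
        ((!at_upper & d < -tol) | (at_upper & d > tol))
      if (!any(elig)) {
        return(list(pi = pi, xB = xB, iter = it))
      }
      cand <- which(elig)
      if (degen_run > 3L * m + 20L) {           # Bland's rule
        q <- cand[1L]
      } else {                                   # Dantzig, ties -> smallest
        q <- cand[which.max(abs(d[cand]))]
      }
      dir <- if (at_upper[q]) -1 else 1
      w <- as.numeric(solve(B, A2[, q]))
      delta <- dir * w                           # xB changes by -delta * t
      lim <- rep(Inf, m)
      dec <- delta > tol
      inc <- delta < -tol & is.finite(upper2[basis])
      lim[dec] <- xB[dec] / delta[dec]
      lim[inc] <- (upper2[basis[inc]] - xB[inc]) / (-delta[inc])
      lim <- pmax(lim, 0)
      t_flip <- upper2[q]
      t_star <- min(t_flip, lim)
      if (!is.finite(t_star)) stop("LP is unbounded")
      if (t_star <= 1e-11) degen_run <- degen_run + 1L else degen_run <- 0L
      hit <- which(lim <= t_star + 1e-12)
      if (t_flip <= t_star + 1e-12 && length(hit) == 0L) {
        at_upper[q] <<- !at_upper[q]             # bound flip, basis unchanged
      } else {
        leave <- hit[which.min(basis[hit])]      # deterministic tie-break
        lv <- basis[leave]
        in_basis[lv] <<- FALSE
        at_upper[lv] <<- delta[leave] < 0        # left at its upper bound
        basis[leave] <<- q
        in_basis[q] <<- TRUE
        at_upper[q] <<- FALSE
      }
    }
    stop("simplex iteration limit reached (", max_iter, ")")
  }

  # phase 1: drive the artificials to zero
  costs1 <- c(rep(0, n), rep(1, m))
  res1 <- run_phase(costs1, allow_enter = structural)
  art_in <- basis > n
  if (sum(res1$xB[art_in]) > 1e-7 * max(1, max(abs(b))))
    stop("LP is infeasible")
  # pivot remaining (degenerate) artificials out of the basis
  guard <- 0L
  while (any(basis > n)) {
    guard <- guard + 1L
    if (guard > m + 1L) stop("design matrix is rank deficient")
    i <- which(basis > n)[1L]
    B <- A2[, basis, drop = FALSE]
    cand <- which(structural & !in_basis)
    Wc <- solve(B, A2[, cand, drop = FALSE])
    j <- cand[which(abs(Wc[i, ]) > 1e-7)][1L]
    if (is.na(j)) stop("design matrix is rank deficient")
    lv <- basis[i]
    in_basis[lv] <- FALSE
    at_upper[lv] <- FALSE
    basis[i] <- j
    in_basis[j] <- TRUE
    at_upper[j] <- FALSE
  }
  # phase 2: original objective, artificials locked out
  costs2 <- c(cvec, rep(0, m))
  res2 <- run_phase(costs2, allow_enter = structural)
  x <- numeric(n)
  x[!in_basis[seq_len(n)] & at_upper[seq_len(n)]] <-
    upper[!in_basis[seq_len(n)] & at_upper[seq_len(n)]]
  x[basis] <- res2$xB
  list(x = x, value = sum(cvec * x), basis = sort(basis), pi = res2$pi,
       iter = res2$iter)
}
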