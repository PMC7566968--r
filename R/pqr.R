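#' Linear quantile regression by exact linear programming
#'
#' Minimizes the check-function loss `sum(rho_tau(y - X b))`,
#' `rho_tau(u) = u * (tau - 1(u < 0))`, by solving the Koenker-Bassett dual
#' linear program `max y'a` s.t. `X'a = (1 - tau) X'1`, `0 <= a <= 1` with
#' a bounded-variable simplex, so the solution is an exact LP vertex: at
#' least `p` observations are interpolated and the coefficient vector is
#' recovered from the interpolating basis.  Deterministic tie-breaking
#' makes repeated calls identical.
#'
#' @param y numeric response vector.
#' @param X design matrix (include the intercept column yourself).
#' @param tau quantile level in (0, 1).
#' @return an object of class `"quantile_fit"`: `beta`, `tau`,
#'   `objective` (check loss at the optimum), `interpolated` (row indices
#'   of the basic, exactly-fitted observations), `residuals`.
#' @export
quantile_regression <- function(y, X, tau) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("tau must be a single value in (0, 1)")
  if (nrow(X) != n) stop("nrow(X) != length(y)")
  if (n <= p) stop("need more observations than parameters")
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  sol <- lp_bounded_simplex(A = t(X), b = (1 - tau) * colSums(X),
                            cvec = -y, upper = rep(1, n))
  h <- sol$basis
  beta <- tryCatch(solve(X[h, , drop = FALSE], y[h]),
                   error = function(e) -sol$pi)
  beta_pi <- -sol$pi
  rho <- function(b) {
    r <- y - as.numeric(X %*% b)
    sum(r * (tau - (r < 0)))
  }
  if (rho(beta_pi) < rho(beta) - 1e-12) beta <- beta_pi
  r <- y - as.numeric(X %*% beta)
  structure(list(beta = stats::setNames(as.numeric(beta), colnames(X)),
                 tau = tau, objective = sum(r * (tau - (r < 0))),
                 interpolated = h, residuals = r, n = n, p = p),
            class = "quantile_fit")
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("Quantile regression (tau = %.2f, n = %d)\n", x$tau, x$n))
  print(x$beta, digits = 5)
  cat(sprintf("check loss = %.6g; interpolated points: %s\n", x$objective,
              paste(x$interpolated, collapse = ", ")))
  invisible(x)
}

#' Phylogenetic autocovariate from regression residuals
#'
#' For each species i, the inverse-distance-squared weighted mean of the
#' other species' residuals,
#' `a_i = sum_j w_ij r_j / sum_j w_ij`, `w_ij = 1 / d_ij^2`, where `d` is
#' the "one minus phylogenetic correlation" distance
#' (see [phylo_distances()]).  Each `a_i` is a convex combination of the
#' other residuals.  Off-diagonal zero distances (tips with correlation 1)
#' are replaced by the smallest positive off-diagonal distance times 1e-3,
#' with a warning.
#'
#' @param residuals named numeric vector of residuals (names are species).
#' @param D distance matrix whose dimnames cover the residual names.
#' @return a list with `a` (named vector) and `mean_a` (its arithmetic
#'   mean over the fitted species).
#' @export
phylo_autocovariate <- function(residuals, D) {
  if (is.null(names(residuals))) stop("residuals must be named by species")
  lab <- names(residuals)
  if (!all(lab %in% rownames(D)))
    stop("species missing from distance matrix: ",
         paste(setdiff(lab, rownames(D)), collapse = ", "))
  Ds <- D[lab, lab, drop = FALSE]
  n <- length(lab)
  if (n < 2L) stop("need at least 2 species")
  off <- Ds[row(Ds) != col(Ds)]
  if (any(off <= 0)) {
    pos <- off[off > 0]
    if (!length(pos))
      stop("all phylogenetic distances are zero; cannot weight")
    warning("zero phylogenetic distances between distinct species; ",
            "replaced by min positive distance * 1e-3")
    Ds[Ds <= 0 & row(Ds) != col(Ds)] <- min(pos) * 1e-3
  }
  W <- 1 / Ds^2
  diag(W) <- 0
  a <- as.numeric(W %*% residuals) / rowSums(W)
  names(a) <- lab
  list(a = a, mean_a = mean(a))
}

#' Phylogenetic quantile regression boundaries
#'
#' The four-step procedure for each quantile level: (1) fit the
#' non-phylogenetic quantile regression of the response on the predictor;
#' (2) take its residuals; (3) compute the phylogenetic autocovariate of
#' those residuals ([phylo_autocovariate()]); (4) refit the quantile
#' regression with the autocovariate as an extra regressor.  The reported
#' boundary line fixes the autocovariate at its average over the fitted
#' species, so it describes species with average phylogenetic residual
#' context.  The 10% and 90% levels (default) give the lower and upper
#' trait boundaries; threatened species are excluded from fitting (default
#' subset) and only classified afterwards ([classify_species()]).  The two
#' quantile levels are fitted independently; crossing inside the fitted
#' predictor range is recorded as a warning flag, not an error.
#'
#' @param data an `"ecophylo_data"` object.
#' @param response,predictor trait column names.
#' @param taus quantile levels, default `c(0.10, 0.90)`.
#' @param subset species subset the boundaries are fitted on (default
#'   `"non_threatened"`).
#' @param resid_tau `"same"` (default): step-1 residuals come from the
#'   same-tau fit; `"median"`: from the tau = 0.5 fit.
#' @return an object of class `"pqr_boundary"`: `lines` (data.frame with
#'   `tau`, `intercept`, `slope`, `beta_autocov`, `mean_a`,
#'   `coverage_below` — the in-sample fraction of fitted species strictly
#'   below their own fitted boundary, i.e. at their own autocovariate
#'   value; the intercept is already evaluated at the mean autocovariate),
#'   `fits`, `crossing` flag, and the fitted data.  Note that when
#'   residuals are strongly phylogenetically correlated the autocovariate
#'   tightens the conditional quantile, so the displayed mean-autocovariate
#'   line lies inside the marginal trait envelope; the per-species
#'   boundaries, not the displayed line, carry the tau-level coverage.
#' @export
fit_pqr_boundary <- function(data, response, predictor,
                             taus = c(0.10, 0.90),
                             subset = "non_threatened",
                             resid_tau = c("same", "median")) {
  resid_tau <- match.arg(resid_tau)
  stopifnot(inherits(data, "ecophylo_data"))
  d <- subset_aligned(data, subset, needed = c(response, predictor))
  y <- d$data[[response]]
  x <- d$data[[predictor]]
  sp <- d$data$species
  X1 <- cbind("(Intercept)" = 1, x)
  colnames(X1)[2] <- predictor
  D <- phylo_distances(d$tree)$one_minus_corr
  fits <- list()
  lines <- data.frame()
  constant_a <- FALSE
  for (tau in taus) {
    t1 <- if (resid_tau == "same") tau else 0.5
    f1 <- quantile_regression(y, X1, t1)
    ac <- phylo_autocovariate(stats::setNames(f1$residuals, sp), D)
    if (stats::sd(ac$a) < 1e-12) {
      # degenerate reduction: a constant autocovariate carries no signal,
      # so the boundary is the plain quantile line
      constant_a <- TRUE
      f2 <- if (t1 == tau) f1 else quantile_regression(y, X1, tau)
      beta <- c(f2$beta, 0)
    } else {
      X2 <- cbind(X1, autocov = ac$a)
      f2 <- quantile_regression(y, X2, tau)
      beta <- f2$beta
    }
    fits[[as.character(tau)]] <- list(step1 = f1, autocov = ac, step4 = f2)
    lines <- rbind(lines, data.frame(
      tau = tau, intercept = beta[1] + beta[3] * ac$mean_a,
      slope = beta[2], beta_autocov = beta[3], mean_a = ac$mean_a,
      coverage_below = mean(f2$residuals < 0)))
  }
  rownames(lines) <- NULL
  crossing <- FALSE
  if (length(taus) >= 2L) {
    lo <- lines[which.min(lines$tau), ]
    hi <- lines[which.max(lines$tau), ]
    ends <- range(x)
    if (any(lo$intercept + lo$slope * ends >
            hi$intercept + hi$slope * ends)) {
      crossing <- TRUE
      warning("quantile boundaries cross inside the fitted predictor range")
    }
  }
  structure(list(response = response, predictor = predictor, taus = taus,
                 lines = lines, fits = fits, crossing = crossing,
                 constant_autocov = constant_a,
                 species = sp, x = stats::setNames(x, sp),
                 y = stats::setNames(y, sp), subset = subset,
                 resid_tau = resid_tau),
            class = "pqr_boundary")
}

#' @export
print.pqr_boundary <- function(x, ...) {
  cat(sprintf("PQR boundaries: %s ~ %s (fitted on %d %s species)\n",
              x$response, x$predictor, length(x$species), x$subset))
  print(x$lines, digits = 5, row.names = FALSE)
  if (x$crossing) cat("note: boundaries cross in the fitted range\n")
  invisible(x)
}

#' Evaluate a PQR boundary line
#'
#' @param boundary a `"pqr_boundary"` object.
#' @param tau which fitted level.
#' @param x predictor values.
#' @return boundary response values at `x` (autocovariate at its mean).
#' @export
pqr_boundary_line <- function(boundary, tau, x) {
  ln <- boundary$lines[boundary$lines$tau == tau, ]
  if (nrow(ln) != 1L) stop("no fitted boundary at tau = ", tau)
  ln$intercept + ln$slope * x
}

#' Classify focal species against PQR boundaries
#'
#' A species is `below_lower` if its response lies strictly below the
#' lowest-tau boundary at its predictor value, `above_upper` if strictly
#' above the highest-tau boundary, and `within` otherwise.  Values within
#' `tol` of a boundary count as `within` and are flagged as ties.
#'
#' @param boundary a `"pqr_boundary"` object.
#' @param newdata data.frame containing the boundary's response and
#'   predictor columns (and optionally `species`).
#' @param tol tie tolerance (default 1e-12).
#' @return a data.frame: species, x, y, lower, upper, class, tie.
#' @export
classify_species <- function(boundary, newdata, tol = 1e-12) {
  stopifnot(inherits(boundary, "pqr_boundary"))
  for (col in c(boundary$predictor, boundary$response))
    if (!col %in% names(newdata)) stop("newdata lacks column '", col, "'")
  x <- newdata[[boundary$predictor]]
  y <- newdata[[boundary$response]]
  lower <- pqr_boundary_line(boundary, min(boundary$taus), x)
  upper <- pqr_boundary_line(boundary, max(boundary$taus), x)
  tie <- abs(y - lower) <= tol | abs(y - upper) <= tol
  cls <- ifelse(!tie & y < lower, "below_lower",
                ifelse(!tie & y > upper, "above_upper", "within"))
  data.frame(species = if ("species" %in% names(newdata))
               newdata$species else seq_along(x),
             x = x, y = y, lower = lower, upper = upper,
             class = cls, tie = tie, stringsAsFactors = FALSE)
}
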