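# resolve (y, tree) from either an aligned dataset + trait name or a
# phylo + named trait vector
.resolve_trait <- function(x, trait) {
  if (inherits(x, "ecophylo_data")) {
    if (!trait %in% names(x$data)) stop("no trait column '", trait, "'")
    keep <- !is.na(x$data[[trait]])
    if (sum(keep) < 3L) stop("fewer than 3 species with trait '", trait, "'")
    d <- align_tree_and_table(x$tree, x$data[keep, , drop = FALSE])
    list(tree = d$tree,
         y = stats::setNames(d$data[[trait]], d$data$species))
  } else if (inherits(x, "phylo")) {
    y <- trait
    if (is.null(names(y))) stop("trait vector must be named by species")
    keep <- intersect(x$tip.label, names(y)[!is.na(y)])
    if (length(keep) < 3L) stop("fewer than 3 species with the trait")
    tree <- if (length(keep) < length(x$tip.label))
      ape::drop.tip(x, setdiff(x$tip.label, keep)) else x
    list(tree = tree, y = y[tree$tip.label])
  } else stop("x must be an 'ecophylo_data' or a 'phylo' object")
}

#' Pagel's lambda with a likelihood-ratio test
#'
#' Maximizes the profiled GLS likelihood of an intercept-only model over the
#' lambda transform on `[0, 1]` and tests lambda = 0 (no phylogenetic
#' dependence) by a likelihood ratio.  Because lambda = 0 lies on the
#' boundary of the parameter space, the mixture p-value
#' `0.5 * P(chisq_1 >= LR)` is reported alongside the plain chi-square
#' p-value (`p_chisq`), which is what comparable software prints.
#'
#' @param x an `"ecophylo_data"` object (then `trait` is a column name) or
#'   a `"phylo"` tree (then `trait` is a named numeric vector).
#' @param trait trait column name, or named vector.
#' @return an object of class `"pagel_lambda"`: `lambda`, `loglik`,
#'   `loglik0`, `lr`, `p_chisq`, `p_mixture`, `n`.
#' @export
fit_pagel_lambda <- function(x, trait) {
  rt <- .resolve_trait(x, trait)
  C <- bm_covariance(rt$tree)
  X <- matrix(1, length(rt$y), 1, dimnames = list(NULL, "(Intercept)"))
  prof <- profile_lambda(rt$y, X, C)
  ll0 <- suppressWarnings(
    gls_profile_loglik(rt$y, X, lambda_transform(C, 0))$loglik)
  lr <- max(0, 2 * (prof$loglik - ll0))
  structure(list(lambda = prof$lambda, loglik = prof$loglik, loglik0 = ll0,
                 lr = lr,
                 p_chisq = stats::pchisq(lr, df = 1, lower.tail = FALSE),
                 p_mixture = if (lr == 0) 1 else
                   0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE),
                 n = length(rt$y), profile = prof$profile),
            class = "pagel_lambda")
}

#' @export
print.pagel_lambda <- function(x, ...) {
  cat(sprintf("Pagel's lambda = %.4f (n = %d)\n", x$lambda, x$n))
  cat(sprintf("  logLik %.3f vs lambda=0 %.3f; LR = %.3f\n",
              x$loglik, x$loglik0, x$lr))
  cat(sprintf("  P (chi-square 1 df) = %.4g; P (boundary mixture) = %.4g\n",
              x$p_chisq, x$p_mixture))
  invisible(x)
}

#' Phylogenetic signal representation (PSR) curve and area
#'
#' Gower double-centers minus one half of the patristic distance matrix,
#' eigendecomposes it, and regresses the trait by OLS on the first k
#' phylogenetic eigenvectors for k = 1..K (eigenvalues below `1e-10` of
#' the largest are dropped).  The patristic distance between two tips is
#' the squared-divergence scale of Brownian motion (expected squared trait
#' difference grows linearly with path length), so the double-centered
#' matrix equals the centered BM covariance and a BM trait's curve tracks
#' the diagonal in expectation.  The curve plots cumulative R-squared
#' against the cumulative eigenvalue fraction `u`, anchored at the origin;
#' its signed area relative to the diagonal — the trapezoidal integral of
#' `R2(u) - u` — indexes departure from Brownian motion (negative: trait
#' more phylogenetically conserved than BM).
#'
#' @inheritParams fit_pagel_lambda
#' @return an object of class `"psr_result"`: `curve` (data.frame with
#'   `u`, `r2`), `area`, `eigenvalues`.
#' @export
psr_curve <- function(x, trait) {
  rt <- .resolve_trait(x, trait)
  y <- rt$y
  n <- length(y)
  if (n < 4L) stop("PSR requires at least 4 species")
  if (stats::sd(y) == 0) stop("trait is constant; R-squared undefined")
  Dp <- as.matrix(stats::cophenetic(rt$tree))[names(y), names(y)]
  A <- -0.5 * Dp
  B <- A - rowMeans(A)[row(A)] - colMeans(A)[col(A)] + mean(A)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- eig$values > 1e-10 * max(eig$values)
  vals <- eig$values[keep]
  vecs <- eig$vectors[, keep, drop = FALSE]
  u <- cumsum(vals) / sum(vals)
  # eigenvectors of the double-centered matrix are orthonormal and centered,
  # so cumulative OLS R-squared is a cumulative sum of squared projections
  yc <- y - mean(y)
  proj <- as.numeric(crossprod(vecs, yc))
  r2 <- cumsum(proj^2) / sum(yc^2)
  r2 <- pmin(r2, 1)
  ux <- c(0, u)
  ry <- c(0, r2)
  area <- sum(diff(ux) * (utils::head(ry, -1) + utils::tail(ry, -1)) / 2) - 0.5
  structure(list(curve = data.frame(u = u, r2 = r2), area = area,
                 eigenvalues = vals, n = n),
            class = "psr_result")
}

#' @export
print.psr_result <- function(x, ...) {
  cat(sprintf("PSR curve: %d axes, area = %.4f (n = %d)\n",
              nrow(x$curve), x$area, x$n))
  invisible(x)
}

#' Compare white-noise, Brownian-motion and Ornstein-Uhlenbeck models
#'
#' Fits an intercept-only GLS under three covariance structures — identity
#' (WN), the BM covariance, and the OU transform with `alpha` maximized
#' over a log-spaced bracket (`alpha * depth` in `[1e-6, 50]`, 60 points)
#' followed by golden-section refinement — and ranks them by AIC
#' (`2 k - 2 logLik`; k = 2 for WN and BM, k = 3 for OU: mean, sigma2, and
#' alpha).
#'
#' @inheritParams fit_pagel_lambda
#' @return an object of class `"evo_model_comparison"`: a `table`
#'   data.frame (model, k, loglik, aic, delta_aic), `best`, `alpha`,
#'   `alpha_boundary`.
#' @export
fit_evolution_models <- function(x, trait) {
  rt <- .resolve_trait(x, trait)
  y <- rt$y
  n <- length(y)
  if (n < 4L) stop("model comparison requires at least 4 species")
  C <- bm_covariance(rt$tree)
  T_ <- mean(diag(C))
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  ll_wn <- gls_profile_loglik(y, X, diag(n))$loglik
  ll_bm <- gls_profile_loglik(y, X, C)$loglik
  f_ou <- function(a)
    suppressWarnings(gls_profile_loglik(y, X, ou_transform(rt$tree, a))$loglik)
  agrid <- exp(seq(log(1e-6), log(50), length.out = 60L)) / T_
  ll <- vapply(agrid, f_ou, numeric(1))
  i <- which.max(ll)
  opt <- stats::optimize(f_ou, c(agrid[max(1L, i - 1L)],
                                 agrid[min(length(agrid), i + 1L)]),
                         maximum = TRUE, tol = 1e-9)
  if (opt$objective >= ll[i]) {
    alpha <- opt$maximum; ll_ou <- opt$objective
  } else {
    alpha <- agrid[i]; ll_ou <- ll[i]
  }
  boundary <- alpha <= agrid[1L] * 1.01 || alpha >= agrid[60L] * 0.99
  k <- c(wn = 2, bm = 2, ou = 3)
  loglik <- c(wn = ll_wn, bm = ll_bm, ou = ll_ou)
  aic <- 2 * k - 2 * loglik
  tab <- data.frame(model = names(k), k = as.numeric(k),
                    loglik = as.numeric(loglik), aic = as.numeric(aic),
                    delta_aic = as.numeric(aic - min(aic)),
                    row.names = names(k))
  structure(list(table = tab, best = names(which.min(aic)), alpha = alpha,
                 alpha_boundary = boundary, n = n),
            class = "evo_model_comparison")
}

#' @export
print.evo_model_comparison <- function(x, ...) {
  cat("Evolutionary model comparison (n =", x$n, ")\n")
  print(x$table[, c("model", "k", "loglik", "aic", "delta_aic")],
        row.names = FALSE, digits = 6)
  cat("best:", x$best, " alpha =", signif(x$alpha, 4),
      if (x$alpha_boundary) "(search boundary)" else "", "\n")
  invisible(x)
}

#' Phylogenetic signal summary table
#'
#' One row per trait: Pagel's lambda and its p-values, the PSR area, the
#' per-model delta-AIC, and the best-fitting model.
#'
#' @param data an `"ecophylo_data"` object.
#' @param traits character vector of trait column names.
#' @return a data.frame, one row per trait.
#' @export
signal_summary <- function(data, traits) {
  rows <- lapply(traits, function(tr) {
    lam <- fit_pagel_lambda(data, tr)
    psr <- psr_curve(data, tr)
    mc <- fit_evolution_models(data, tr)
    data.frame(trait = tr, n = lam$n, lambda = lam$lambda,
               p_chisq = lam$p_chisq, p_mixture = lam$p_mixture,
               psr_area = psr$area,
               daic_bm = mc$table["bm", "delta_aic"],
               daic_ou = mc$table["ou", "delta_aic"],
               daic_wn = mc$table["wn", "delta_aic"],
               best_model = mc$best, alpha = mc$alpha)
  })
  do.call(rbind, rows)
}
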