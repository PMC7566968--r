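#' Phylogenetic generalized least squares regression
#'
#' Bivariate (or small multiple) regression with phylogenetically
#' correlated errors: `y ~ N(X beta, sigma2 * V(lambda))` where `V(lambda)`
#' is the Pagel transform of the Brownian covariance of the pruned tree.
#' `lambda` is either estimated by maximizing the profiled ML jointly with
#' the regression (the default) or fixed.  Coefficient standard errors use
#' the unbiased scale `rss / (n - p)`; `r2` is the coefficient of
#' determination computed in the whitened space (the GLS analogue of OLS
#' R-squared, against the GLS intercept-only fit at the same lambda).
#'
#' @param data an `"ecophylo_data"` object.
#' @param response response trait column name.
#' @param predictor single predictor column name (one predictor at a time,
#'   mirroring slope-table reproductions), or a character vector for a
#'   multiple regression.
#' @param subset `"all"`, `"non_threatened"` or `"threatened"` — which
#'   species the model is fitted on.
#' @param transform `"none"` or `"loglog"`: log10 of minus the response and
#'   log10 of the predictor (for P50 against hydraulic diameter, where
#'   theory predicts P50 proportional to 1/d_h, i.e. slope -1 on log-log
#'   axes); both sides must be strictly sign-appropriate.
#' @param standardize_predictor if `TRUE`, predictors are z-scored on the
#'   fitted subset before the fit (slopes are then per standard deviation
#'   of the predictor — the convention for climate gradients); default
#'   `FALSE` (trait-trait fits).
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @return an object of class `"pgls_fit"` with a `coefficients`
#'   data.frame (`estimate`, `se`, `t`, `p`), `lambda`, `r2`, `loglik`,
#'   `sigma2`, `n`, `df`, and bookkeeping fields.
#' @export
pgls_fit <- function(data, response, predictor,
                     subset = c("all", "non_threatened", "threatened"),
                     transform = c("none", "loglog"),
                     standardize_predictor = FALSE, lambda = "ML") {
  subset <- match.arg(subset)
  transform <- match.arg(transform)
  stopifnot(inherits(data, "ecophylo_data"))
  d <- subset_aligned(data, subset, needed = c(response, predictor))
  y <- d$data[[response]]
  Xr <- sapply(predictor, function(p) d$data[[p]])
  if (transform == "loglog") {
    if (length(predictor) != 1L)
      stop("loglog transform expects a single predictor")
    if (any(y >= 0)) stop("loglog transform needs a strictly negative ",
                          "response (it fits log10(-response))")
    if (any(Xr <= 0)) stop("loglog transform needs a strictly positive ",
                           "predictor")
    y <- log10(-y)
    Xr <- log10(Xr)
  }
  Xr <- as.matrix(Xr)
  colnames(Xr) <- predictor
  if (any(apply(Xr, 2, stats::sd) == 0))
    stop("constant predictor: ",
         paste(predictor[apply(Xr, 2, stats::sd) == 0], collapse = ", "))
  scaling <- NULL
  if (standardize_predictor) {
    scaling <- list(center = colMeans(Xr), scale = apply(Xr, 2, stats::sd))
    Xr <- scale(Xr, center = scaling$center, scale = scaling$scale)
  }
  n <- length(y)
  X <- cbind("(Intercept)" = 1, Xr)
  p <- ncol(X)
  if (n <= p + 1L) stop("too few species (", n, ") for ", p, " parameters")
  C <- bm_covariance(d$tree)
  if (identical(lambda, "ML")) {
    prof <- profile_lambda(y, X, C)
    lam <- prof$lambda
  } else {
    lam <- lambda
  }
  V <- lambda_transform(C, lam)
  core <- gls_profile_loglik(y, X, V)
  df <- n - p
  sigma2_u <- core$rss / df
  XtX_inv <- chol2inv(qr.R(core$qr))
  se <- sqrt(diag(XtX_inv) * sigma2_u)
  tval <- core$beta / se
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  core0 <- gls_profile_loglik(y, X[, 1, drop = FALSE], V)
  r2 <- 1 - core$rss / core0$rss
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = core$beta,
                              se = se, t = tval, p = pval,
                              row.names = colnames(X)),
    lambda = lam, lambda_ml = identical(lambda, "ML"), r2 = r2,
    loglik = core$loglik, sigma2 = core$sigma2, n = n, df = df,
    response = response, predictor = predictor, subset = subset,
    transform = transform, scaling = scaling,
    species = d$data$species, fitted_core = core),
    class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS: %s ~ %s  (subset: %s, n = %d, lambda = %.3f%s)\n",
              x$response, paste(x$predictor, collapse = " + "), x$subset,
              x$n, x$lambda, if (x$lambda_ml) " ML" else " fixed"))
  print(x$coefficients[, c("estimate", "se", "t", "p")], digits = 4)
  cat(sprintf("R2 = %.3f, logLik = %.3f, df = %d\n", x$r2, x$loglik, x$df))
  invisible(x)
}

#' Batch PGLS slope table
#'
#' Runs one bivariate PGLS per (response, predictor) pair and assembles a
#' slope table in the "P (R2, t)" layout of trait-environment analyses.
#'
#' @param data an `"ecophylo_data"` object.
#' @param panels a data.frame with columns `response`, `predictor` and
#'   optionally `transform` and `standardize` (logical).
#' @param subset passed to [pgls_fit()].
#' @return a data.frame with one row per panel: slope, se, t, p, r2,
#'   lambda, n.
#' @export
pgls_batch <- function(data, panels, subset = "non_threatened") {
  rows <- lapply(seq_len(nrow(panels)), function(i) {
    tr <- if ("transform" %in% names(panels)) panels$transform[i] else "none"
    stdz <- if ("standardize" %in% names(panels)) panels$standardize[i]
            else FALSE
    fit <- pgls_fit(data, panels$response[i], panels$predictor[i],
                    subset = subset, transform = tr,
                    standardize_predictor = isTRUE(stdz))
    co <- fit$coefficients[2, ]
    data.frame(response = panels$response[i],
               predictor = panels$predictor[i], n = fit$n,
               lambda = fit$lambda, intercept =
                 fit$coefficients["(Intercept)", "estimate"],
               slope = co$estimate, se = co$se, t = co$t, p = co$p,
               r2 = fit$r2)
  })
  do.call(rbind, rows)
}

#' Principal component analysis of environmental variables
#'
#' Z-scores the environmental variables on the fitted species set,
#' eigendecomposes their correlation matrix, and scores both the fitted
#' species and any projected species (e.g. threatened species held out of
#' downstream regressions) with the same standardization and loadings.
#' Axis signs are fixed deterministically: within each axis, the loading of
#' largest magnitude is made positive.
#'
#' @param data an `"ecophylo_data"` object or a species data.frame.
#' @param vars environmental variable columns (default the six climate and
#'   position variables).
#' @param fit_on `"all"` (default: the PCA is fitted over every species
#'   with complete variables, threatened included) or `"non_threatened"`.
#' @return an object of class `"env_pca"`: `loadings` (variables x axes),
#'   `variance_explained` (percent per axis), `scores` (data.frame with
#'   species, fitted flag, one column per axis), `center`, `scale`.
#' @export
env_pca <- function(data, vars = c("latitude", "altitude", "mat", "map",
                                   "mtcm", "wd"),
                    fit_on = c("all", "non_threatened")) {
  fit_on <- match.arg(fit_on)
  df <- if (inherits(data, "ecophylo_data")) data$data else data
  missing_vars <- setdiff(vars, names(df))
  if (length(missing_vars))
    stop("missing environmental column(s): ",
         paste(missing_vars, collapse = ", "))
  complete <- stats::complete.cases(df[, vars, drop = FALSE])
  fitted_rows <- complete &
    (fit_on == "all" | as.character(df$status) == "non_threatened")
  if (sum(fitted_rows) < length(vars) + 1L)
    stop("too few complete species to fit the PCA")
  Xf <- as.matrix(df[fitted_rows, vars, drop = FALSE])
  center <- colMeans(Xf)
  scale_ <- apply(Xf, 2, stats::sd)
  if (any(scale_ == 0))
    stop("zero-variance environmental variable: ",
         paste(vars[scale_ == 0], collapse = ", "))
  Zf <- scale(Xf, center = center, scale = scale_)
  eig <- eigen(stats::cor(Xf), symmetric = TRUE)
  load <- eig$vectors
  # deterministic sign: dominant loading positive within each axis
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(vars, paste0("pc", seq_along(vars)))
  var_expl <- 100 * eig$values / sum(eig$values)
  Zall <- scale(as.matrix(df[complete, vars, drop = FALSE]),
                center = center, scale = scale_)
  scores <- as.data.frame(Zall %*% load)
  scores <- cbind(species = df$species[complete],
                  fitted = fitted_rows[complete], scores)
  rownames(scores) <- scores$species
  structure(list(loadings = load, variance_explained = var_expl,
                 scores = scores, center = center, scale = scale_,
                 vars = vars, fit_on = fit_on),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  cat("Environmental PCA (fitted on", x$fit_on, "species)\n")
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance\n",
              x$variance_explained[1], x$variance_explained[2]))
  print(round(x$loadings[, 1:2], 3))
  invisible(x)
}

#' Attach PCA scores to an aligned dataset
#'
#' Adds `pc1`, `pc2`, ... columns (from [env_pca()]) to the dataset's trait
#' table so PC axes can be used as predictors in [pgls_fit()] and
#' [fit_pqr_boundary()].
#'
#' @param data an `"ecophylo_data"` object.
#' @param pca an `"env_pca"` object.
#' @param axes how many axes to attach (default 2).
#' @return the dataset with score columns added.
#' @export
add_pca_scores <- function(data, pca, axes = 2L) {
  stopifnot(inherits(data, "ecophylo_data"), inherits(pca, "env_pca"))
  for (j in seq_len(axes)) {
    col <- paste0("pc", j)
    data$data[[col]] <- pca$scores[match(data$data$species,
                                         pca$scores$species), col]
  }
  data
}
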