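# default correlation structure of the six environmental variables:
# temperature variables (mat, mtcm) strongly coupled and opposed to
# latitude; the moisture pair (map, wd) strongly opposed; altitude mildly
# cooling.  Verified positive definite at load time in tests.
.default_env_cor <- function() {
  v <- c("latitude", "altitude", "mat", "map", "mtcm", "wd")
  R <- diag(6)
  dimnames(R) <- list(v, v)
  set_ <- function(i, j, r) {
    R[i, j] <<- r
    R[j, i] <<- r
  }
  set_("latitude", "mat", -0.70)
  set_("latitude", "mtcm", -0.75)
  set_("latitude", "map", -0.30)
  set_("latitude", "wd", 0.20)
  set_("altitude", "mat", -0.40)
  set_("altitude", "mtcm", -0.35)
  set_("altitude", "map", 0.10)
  set_("mat", "mtcm", 0.85)
  set_("mat", "map", 0.40)
  set_("mat", "wd", -0.30)
  set_("map", "mtcm", 0.35)
  set_("map", "wd", -0.60)
  set_("mtcm", "wd", -0.25)
  R
}

.default_env_means <- c(latitude = 38, altitude = 1400, mat = 9,
                        map = 900, mtcm = -4, wd = 0)
.default_env_sds <- c(latitude = 12, altitude = 900, mat = 6,
                      map = 420, mtcm = 8, wd = 1)

#' Simulation configuration
#'
#' Collects every knob of the synthetic study generator with defaults that
#' mirror the compiled conifer dataset the analyses are designed for: a
#' 36-taxon ultrametric pure-birth tree, 7 threatened species, a hydraulic
#' safety trait (`p50`) responding linearly to a moisture gradient with
#' phylogenetically correlated (lambda-model) residuals, a second trait
#' (`pn`) evolving under Brownian motion, and threatened species displaced
#' below the true 10% residual envelope.
#'
#' @param seed integer seed; every draw is reproducible from it.
#' @param n_taxa number of tips (default 36).
#' @param birth_rate pure-birth speciation rate (default 1).
#' @param n_threatened species planted as threatened outliers (default 7).
#' @param response,predictor names of the regression trait and the
#'   environmental driver (defaults `"p50"`, `"map"`).
#' @param beta0,beta1 regression intercept and slope (slope per standard
#'   deviation of the predictor; defaults -4 and 0.31).
#' @param sigma residual standard deviation (default 0.6).
#' @param resid_model `"lambda"` (default), `"bm"` or `"ou"` residual
#'   phylogenetic structure.
#' @param lambda,alpha residual-model parameters (defaults lambda 0.8).
#' @param delta outlier displacement in residual standard deviations
#'   beyond the true envelope (default 5; `0` means no displacement).
#' @param direction `"below"` (default) or `"above"`: which envelope the
#'   outliers are pushed past.
#' @param taus envelope quantile levels (default `c(0.10, 0.90)`).
#' @param env_means,env_sds,env_cor moments of the six environmental
#'   variables.
#' @param second_trait parameters of the independent BM trait:
#'   `list(name, root, sigma2)`.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_taxa = 36L, birth_rate = 1,
                       n_threatened = 7L, response = "p50",
                       predictor = "map", beta0 = -4, beta1 = 0.31,
                       sigma = 0.6, resid_model = c("lambda", "bm", "ou"),
                       lambda = 0.8, alpha = 1, delta = 5,
                       direction = c("below", "above"),
                       taus = c(0.10, 0.90),
                       env_means = .default_env_means,
                       env_sds = .default_env_sds,
                       env_cor = .default_env_cor(),
                       second_trait = list(name = "pn", root = 8,
                                           sigma2 = 4)) {
  resid_model <- match.arg(resid_model)
  direction <- match.arg(direction)
  stopifnot(n_taxa >= 4L, birth_rate > 0, sigma > 0,
            n_threatened >= 0L, n_threatened < n_taxa / 2,
            all(env_sds > 0), delta >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a pure-birth (Yule) tree
#'
#' Ultrametric by construction; reproducible under the seed.
#'
#' @param n_taxa number of tips (>= 3).
#' @param birth_rate speciation rate (1/time).
#' @param seed optional integer seed.
#' @return a `"phylo"` tree with tips `t1 ... tn`.
#' @export
simulate_yule_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  if (n_taxa < 3L) stop("n_taxa must be at least 3")
  if (!is.null(seed)) set.seed(seed)
  ape::rphylo(n_taxa, birth = birth_rate, death = 0)
}

# covariance structure matrix for a residual/trait model on a tree
.model_vcv <- function(tree, model, lambda = NULL, alpha = NULL) {
  C <- bm_covariance(tree)
  switch(model,
         bm = C,
         lambda = lambda_transform(C, lambda),
         ou = ou_transform(tree, alpha),
         wn = diag(nrow(C)) * mean(diag(C)),
         stop("unknown trait model: ", model))
}

#' Simulate a trait on a tree
#'
#' One draw from the multivariate normal with mean `root` and covariance
#' `sigma2 * V(model)` where `V` is the Brownian covariance, its lambda
#' transform, the OU covariance, or (for `"wn"`) a diagonal matrix scaled
#' to the mean tip depth so the marginal variance matches a BM trait.
#'
#' @param tree a `"phylo"` tree.
#' @param model `"bm"`, `"lambda"`, `"ou"` or `"wn"`.
#' @param sigma2 rate/variance scale (>= 0; 0 returns the root state).
#' @param root root state (mean).
#' @param lambda,alpha model parameters where relevant.
#' @param seed optional integer seed.
#' @return named numeric vector of tip values.
#' @export
simulate_trait <- function(tree, model = "bm", sigma2 = 1, root = 0,
                           lambda = NULL, alpha = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- validate_phylo(tree)
  n <- length(tree$tip.label)
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  if (sigma2 == 0)
    return(stats::setNames(rep(root, n), tree$tip.label))
  V <- .model_vcv(tree, model, lambda, alpha)
  L <- chol(sigma2 * V + diag(1e-12 * mean(diag(V)) * sigma2, n))
  stats::setNames(root + as.numeric(crossprod(L, stats::rnorm(n))),
                  tree$tip.label)
}

#' Simulate a trait-environment comparative dataset with known truth
#'
#' Generates the full study-shaped dataset: a Yule tree rescaled to unit
#' depth (so residual marginal standard deviations equal `sigma` exactly),
#' six correlated environmental variables, a response trait
#' `beta0 + beta1 * z(predictor) + residual` with phylogenetically
#' correlated residuals, an independent BM second trait, and
#' `n_threatened` species relabelled threatened and — when `delta > 0` —
#' displaced `delta` residual standard deviations beyond the true
#' `taus[1]` (or `taus[2]`) residual quantile.  The true envelope is
#' defined from the known residual distribution, never from a fitted
#' model.
#'
#' @param config a [sim_config()] object.
#' @return a list with `data` (an `"ecophylo_data"`) and `truth` (list:
#'   `beta0`, `beta1`, `sigma`, `resid_model`, `lambda`/`alpha`,
#'   `envelope` (intercept/slope per tau on the z-scored predictor scale),
#'   `outliers` (species), `direction`, `predictor_center`,
#'   `predictor_scale`).
#' @export
simulate_trait_env_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- ape::rphylo(config$n_taxa, birth = config$birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  n <- config$n_taxa
  vars <- names(config$env_means)
  Lr <- chol(config$env_cor)
  Z <- matrix(stats::rnorm(n * length(vars)), n) %*% Lr
  env <- sweep(sweep(Z, 2, config$env_sds[vars], "*"), 2,
               config$env_means[vars], "+")
  colnames(env) <- vars
  zpred <- as.numeric(scale(Z[, match(config$predictor, vars)]))
  V <- .model_vcv(tree, config$resid_model, config$lambda, config$alpha)
  L <- chol(V)
  resid <- config$sigma * as.numeric(crossprod(L, stats::rnorm(n)))
  outliers <- sort(sample.int(n, config$n_threatened))
  q <- stats::qnorm(config$taus) * config$sigma
  if (config$delta > 0 && length(outliers)) {
    displaced <- if (config$direction == "below")
      q[1] - config$delta * config$sigma
    else q[2] + config$delta * config$sigma
    resid[outliers] <- displaced
  }
  y <- config$beta0 + config$beta1 * zpred + resid
  trait2 <- config$second_trait
  y2 <- simulate_trait(tree, "bm", sigma2 = trait2$sigma2,
                       root = trait2$root)
  status <- rep("non_threatened", n)
  status[outliers] <- "threatened"
  records <- data.frame(species = tree$tip.label, status = status,
                        stringsAsFactors = FALSE)
  records[[config$response]] <- y
  records[[trait2$name]] <- as.numeric(y2)
  for (v in vars) records[[v]] <- env[, v]
  records$status <- factor(records$status,
                           levels = c("non_threatened", "threatened"))
  data <- align_tree_and_table(tree, records)
  zcenter <- mean(env[, config$predictor])
  zscale <- stats::sd(env[, config$predictor])
  truth <- list(beta0 = config$beta0, beta1 = config$beta1,
                sigma = config$sigma, resid_model = config$resid_model,
                lambda = config$lambda, alpha = config$alpha,
                envelope = data.frame(tau = config$taus,
                                      intercept = config$beta0 + q,
                                      slope = config$beta1),
                outliers = tree$tip.label[outliers],
                direction = config$direction,
                predictor = config$predictor,
                predictor_center = zcenter, predictor_scale = zscale,
                zpred = stats::setNames(zpred, tree$tip.label))
  list(data = data, truth = truth)
}

#' Write a simulated dataset (tree, table, ground truth) to disk
#'
#' Emits exactly the formats [read_newick()] and [read_species_table()]
#' read, plus the ground truth as JSON.
#'
#' @param sim result of [simulate_trait_env_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree_path <- file.path(dir, "tree.nwk")
  table_path <- file.path(dir, "traits.csv")
  truth_path <- file.path(dir, "truth.json")
  write_newick(sim$data$tree, tree_path)
  write_species_table(sim$data$data, table_path)
  truth <- sim$truth
  truth$zpred <- as.list(truth$zpred)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tree = tree_path, table = table_path, truth = truth_path))
}

#' Simulate a light-response curve
#'
#' Model values from [nrh_assimilation()] on an irradiance grid (default:
#' the nine-level measurement sequence 0-1500) plus Gaussian noise.
#'
#' @param phi,theta,pn,rd model parameters.
#' @param irradiance grid of irradiance levels.
#' @param noise_sd Gaussian noise standard deviation (0 for exact values).
#' @param seed optional seed.
#' @return data.frame with `I` and `A`.
#' @export
simulate_light_curve <- function(phi = 0.05, theta = 0.7, pn = 6, rd = 0.5,
                                 irradiance = c(0, 30, 50, 100, 300, 500,
                                                800, 1200, 1500),
                                 noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- nrh_assimilation(irradiance, phi, theta, pn, rd)
  if (noise_sd > 0) A <- A + stats::rnorm(length(A), sd = noise_sd)
  data.frame(I = irradiance, A = A)
}

#' Simulate a xylem vulnerability curve
#'
#' PLC from [plc_sigmoid()] on a pressure grid plus Gaussian noise,
#' truncated to `[0, 100]`.
#'
#' @param a,b sigmoid parameters (`b` = P50, MPa).
#' @param psi pressure grid (MPa, negative), default -1 to -8.
#' @param noise_sd Gaussian PLC noise standard deviation.
#' @param seed optional seed.
#' @return data.frame with `psi` and `plc`.
#' @export
simulate_vc_curve <- function(a = 1.5, b = -5.64, psi = -(1:8),
                              noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  plc <- plc_sigmoid(psi, a, b)
  if (noise_sd > 0) plc <- plc + stats::rnorm(length(plc), sd = noise_sd)
  data.frame(psi = psi, plc = pmin(100, pmax(0, plc)))
}

#' Simulate tracheid diameters
#'
#' Log-normal diameters, the standard right-skewed model for lumen sizes.
#'
#' @param meanlog,sdlog log-scale mean and standard deviation.
#' @param n number of tracheids.
#' @param seed optional seed.
#' @return numeric vector of diameters (um).
#' @export
simulate_tracheid_diameters <- function(meanlog = log(7), sdlog = 0.25,
                                        n = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::rlnorm(n, meanlog, sdlog)
}
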