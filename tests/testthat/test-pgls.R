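test_that("PGLS at lambda = 0 is ordinary least squares", {
  sim <- make_small_sim(seed = 3, n_threatened = 0)
  fit <- pgls_fit(sim$data, "p50", "map", lambda = 0)
  ols <- stats::lm(p50 ~ map, data = sim$data$data)
  expect_equal(fit$coefficients$estimate, unname(stats::coef(ols)),
               tolerance = 1e-8)
  expect_equal(fit$coefficients$se,
               unname(summary(ols)$coefficients[, 2]), tolerance = 1e-8)
  expect_equal(fit$r2, summary(ols)$r.squared, tolerance = 1e-8)
})

test_that("t statistics, p values and rescaling behave like a regression should", {
  sim <- make_small_sim(seed = 5, n_threatened = 0)
  fit <- pgls_fit(sim$data, "p50", "map")
  co <- fit$coefficients
  expect_equal(abs(co$t), abs(co$estimate / co$se), tolerance = 1e-10)
  expect_equal(co$p, 2 * stats::pt(abs(co$t), fit$df, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(fit$r2 >= 0 && fit$r2 <= 1)
  # affine predictor rescaling: p invariant, slope reciprocal
  sim$data$data$map_k <- sim$data$data$map / 1000
  fit2 <- pgls_fit(sim$data, "p50", "map_k")
  expect_equal(fit2$coefficients["map_k", "p"], co["map", "p"],
               tolerance = 1e-6)
  expect_equal(fit2$coefficients["map_k", "estimate"],
               co["map", "estimate"] * 1000, tolerance = 1e-4)
})

test_that("standardized predictors give slopes per standard deviation", {
  sim <- make_small_sim(seed = 6, n_threatened = 0)
  raw <- pgls_fit(sim$data, "p50", "map")
  std <- pgls_fit(sim$data, "p50", "map", standardize_predictor = TRUE)
  s <- stats::sd(sim$data$data$map)
  expect_equal(std$coefficients["map", "estimate"],
               raw$coefficients["map", "estimate"] * s, tolerance = 1e-4)
  expect_equal(std$coefficients["map", "p"], raw$coefficients["map", "p"],
               tolerance = 1e-6)
})

test_that("the log-log transform fits the inverse-proportionality scale", {
  # exact power law P50 = -c / d_h  =>  slope -1 on log-log axes
  set.seed(8)
  tr <- simulate_yule_tree(20, 1)
  d <- align_tree_and_table(tr, data.frame(
    species = tr$tip.label,
    d_h = exp(rnorm(20, log(10), 0.3))))
  d$data$p50 <- -30 / d$data$d_h
  # noiseless data trip the exact-fit sentinel during the lambda profile
  expect_warning(fit <- pgls_fit(d, "p50", "d_h", transform = "loglog"),
                 "exact fit")
  expect_equal(fit$coefficients["d_h", "estimate"], -1, tolerance = 1e-6)
  expect_error(pgls_fit(d, "d_h", "d_h", transform = "loglog"),
               "negative response")
})

test_that("whitened residuals are standard under a correctly specified model", {
  sim <- simulate_trait_env_dataset(sim_config(seed = 9, n_taxa = 100,
                                               n_threatened = 0,
                                               lambda = 0.8))
  fit <- pgls_fit(sim$data, "p50", "map", standardize_predictor = TRUE)
  core <- fit$fitted_core
  z <- (core$zy - as.numeric(core$zX %*% core$beta)) / sqrt(core$sigma2)
  expect_lt(abs(mean(z)), 0.1)
  expect_true(stats::var(z) > 0.7 && stats::var(z) < 1.3)
})

test_that("degenerate PGLS inputs error clearly", {
  sim <- make_small_sim(seed = 10, n_threatened = 0)
  sim$data$data$const <- 1
  expect_error(pgls_fit(sim$data, "p50", "const"), "constant predictor")
})

test_that("the environmental PCA matches prcomp up to axis sign", {
  sim <- make_small_sim(seed = 12)
  pca <- env_pca(sim$data)
  ref <- stats::prcomp(sim$data$data[, pca$vars], center = TRUE,
                       scale. = TRUE)
  for (j in 1:2) {
    ratio <- pca$loadings[, j] / ref$rotation[, j]
    expect_equal(abs(ratio), rep(1, 6), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(stats::sd(ratio), 0, tolerance = 1e-8)
  }
  expect_equal(pca$variance_explained,
               100 * ref$sdev^2 / sum(ref$sdev^2), tolerance = 1e-8)
  expect_equal(sum(pca$variance_explained), 100, tolerance = 1e-10)
  # fitted scores are centered; dominant loading positive
  fitted_scores <- pca$scores[pca$scores$fitted, paste0("pc", 1:2)]
  expect_lt(max(abs(colMeans(fitted_scores))), 1e-10)
  for (j in 1:2)
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
})

test_that("a perfectly correlated variable pair loads on a common axis", {
  set.seed(13)
  n <- 40
  base <- rnorm(n)
  df <- data.frame(species = paste0("s", 1:n),
                   status = factor(rep("non_threatened", n),
                                   levels = c("non_threatened",
                                              "threatened")),
                   v1 = base, v2 = 2 * base + 5, v3 = rnorm(n),
                   v4 = rnorm(n))
  pca <- env_pca(df, vars = c("v1", "v2", "v3", "v4"))
  expect_equal(abs(pca$loadings["v1", 1]), abs(pca$loadings["v2", 1]),
               tolerance = 1e-6)
  expect_gt(pca$variance_explained[1], 49)
  df$v5 <- 3
  expect_error(env_pca(df, vars = c("v1", "v2", "v5")), "zero-variance.*v5")
})

test_that("projected species are scored with the fitted standardization", {
  sim <- make_small_sim(seed = 14)
  pca <- env_pca(sim$data, fit_on = "non_threatened")
  th <- sim$data$data[sim$data$data$status == "threatened", ][1, ]
  z <- (unlist(th[pca$vars]) - pca$center) / pca$scale
  expect_equal(unname(as.numeric(pca$scores[th$species, paste0("pc", 1:6)])),
               unname(as.numeric(z %*% pca$loadings)), tolerance = 1e-10)
  expect_false(pca$scores[th$species, "fitted"])
})

test_that("the batch runner reproduces per-panel fits", {
  sim <- make_small_sim(seed = 15)
  panels <- data.frame(response = "p50",
                       predictor = c("map", "wd"),
                       transform = "none", standardize = TRUE)
  tab <- pgls_batch(sim$data, panels)
  expect_equal(nrow(tab), 2)
  one <- pgls_fit(sim$data, "p50", "wd", subset = "non_threatened",
                  standardize_predictor = TRUE)
  expect_equal(tab$slope[2], one$coefficients["wd", "estimate"],
               tolerance = 1e-10)
  expect_equal(tab$p[2], one$coefficients["wd", "p"], tolerance = 1e-10)
})
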