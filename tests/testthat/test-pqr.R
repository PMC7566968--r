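test_that("intercept-only quantile fits return sample quantiles", {
  f <- quantile_regression(c(1, 2, 3, 4, 5), matrix(1, 5, 1), 0.5)
  expect_equal(unname(f$beta), 3)
  f9 <- quantile_regression(1:10, matrix(1, 10, 1), 0.9)
  # any optimal basic solution is an order statistic with the enumerated
  # minimum loss
  expect_equal(f9$objective, enum_qr_objective(1:10, matrix(1, 10, 1), 0.9),
               tolerance = 1e-12)
  expect_true(unname(f9$beta) %in% 1:10)
})

test_that("the LP optimum equals exhaustive vertex enumeration", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(5:12, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    X <- cbind(1, x)
    tau <- runif(1, 0.05, 0.95)
    fit <- quantile_regression(y, X, tau)
    expect_equal(fit$objective, enum_qr_objective(y, X, tau),
                 tolerance = 1e-9)
    # vertex property: p points interpolated exactly
    expect_length(fit$interpolated, 2)
    expect_lt(max(abs(fit$residuals[fit$interpolated])), 1e-9)
  }
})

test_that("repeated solves are deterministic and degenerate designs error", {
  set.seed(18)
  y <- rnorm(20)
  X <- cbind(1, rnorm(20))
  a <- quantile_regression(y, X, 0.25)
  b <- quantile_regression(y, X, 0.25)
  expect_identical(a$beta, b$beta)
  expect_error(quantile_regression(y, cbind(1, rep(1, 20)), 0.5),
               "rank deficient")
  expect_error(quantile_regression(y, X, 1.2), "tau")
})

test_that("the autocovariate matches hand-computable cases and brute force", {
  # two species: each autocovariate is the other's residual
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  ac <- phylo_autocovariate(c(a = 1, b = 5), D2)
  expect_equal(unname(ac$a), c(5, 1))
  # equal distances: mean of the other residuals
  n <- 5
  De <- matrix(0.3, n, n)
  diag(De) <- 0
  dimnames(De) <- list(letters[1:n], letters[1:n])
  r <- stats::setNames(c(2, 4, 6, 8, 10), letters[1:n])
  ac2 <- phylo_autocovariate(r, De)
  expect_equal(unname(ac2$a), sapply(1:n, function(i) mean(r[-i])))
  # brute-force double loop on random inputs, and convexity bounds
  set.seed(19)
  for (i in 1:5) {
    m <- 20
    D <- as.matrix(stats::dist(matrix(rnorm(m * 2), m)))
    dimnames(D) <- list(paste0("s", 1:m), paste0("s", 1:m))
    rr <- stats::setNames(rnorm(m), rownames(D))
    ac3 <- phylo_autocovariate(rr, D)
    expect_equal(unname(ac3$a), bf_autocov(rr, D), tolerance = 1e-12)
    expect_true(all(ac3$a >= min(rr) - 1e-12 & ac3$a <= max(rr) + 1e-12))
  }
})

test_that("the autocovariate is translation equivariant and guards zero distances", {
  set.seed(20)
  m <- 10
  D <- as.matrix(stats::dist(matrix(rnorm(m * 2), m)))
  dimnames(D) <- list(paste0("s", 1:m), paste0("s", 1:m))
  r <- stats::setNames(rnorm(m), rownames(D))
  a0 <- phylo_autocovariate(r, D)$a
  a7 <- phylo_autocovariate(r + 7, D)$a
  expect_equal(a7, a0 + 7, tolerance = 1e-12)
  Dz <- D
  Dz[1, 2] <- Dz[2, 1] <- 0
  expect_warning(az <- phylo_autocovariate(r, Dz), "zero phylogenetic")
  expect_true(all(is.finite(az$a)))
})

test_that("a zeroed autocovariate reduces the boundary to the plain quantile line", {
  # responses exactly affine in the predictor: step-1 residuals are all
  # zero, the autocovariate is constant, and the refit must drop it
  set.seed(21)
  tr <- simulate_yule_tree(12, 1)
  d <- align_tree_and_table(tr, data.frame(
    species = tr$tip.label, x = rnorm(12)))
  d$data$y <- 2 - 3 * d$data$x
  bd <- fit_pqr_boundary(d, "y", "x", subset = "all")
  expect_true(bd$constant_autocov)
  expect_equal(bd$lines$intercept, c(2, 2), tolerance = 1e-9)
  expect_equal(bd$lines$slope, c(-3, -3), tolerance = 1e-9)
  expect_equal(bd$lines$beta_autocov, c(0, 0))
})

test_that("PQR recovers planted envelopes under exchangeable residuals", {
  set.seed(22)
  errs <- t(sapply(1:20, function(i) {
    sim <- simulate_trait_env_dataset(sim_config(
      seed = 3000 + i, n_taxa = 300, n_threatened = 0, lambda = 0))
    sim$data$data$z <- sim$truth$zpred[sim$data$data$species]
    bd <- fit_pqr_boundary(sim$data, "p50", "z")
    truth <- sim$truth$envelope
    c(lo = abs(bd$lines$intercept[1] - truth$intercept[1]) /
        abs(truth$intercept[1]),
      hi = abs(bd$lines$intercept[2] - truth$intercept[2]) /
        abs(truth$intercept[2]),
      slope = abs(bd$lines$slope[1] - truth$slope[1]))
  }))
  expect_lt(mean(errs[, "lo"]), 0.10)
  expect_lt(mean(errs[, "hi"]), 0.10)
})

test_that("boundaries are ordered in tau over the fitted range", {
  sim <- simulate_trait_env_dataset(sim_config(seed = 23, n_taxa = 100,
                                               n_threatened = 0))
  sim$data$data$z <- sim$truth$zpred[sim$data$data$species]
  bd <- fit_pqr_boundary(sim$data, "p50", "z")
  xs <- seq(min(bd$x), max(bd$x), length.out = 50)
  expect_true(all(pqr_boundary_line(bd, 0.1, xs) <=
                    pqr_boundary_line(bd, 0.9, xs)))
  expect_false(bd$crossing)
})

test_that("classification separates outliers, insiders and exact ties", {
  sim <- make_small_sim(seed = 24, delta = 5)
  sim$data$data$z <- sim$truth$zpred[sim$data$data$species]
  bd <- fit_pqr_boundary(sim$data, "p50", "z")
  th <- sim$data$data[sim$data$data$status == "threatened", ]
  cl <- classify_species(bd, th)
  expect_true(all(cl$class == "below_lower"))
  # a point exactly on the lower line is a flagged tie, classified within
  tie <- data.frame(species = "probe", z = 0,
                    p50 = pqr_boundary_line(bd, 0.1, 0))
  clt <- classify_species(bd, tie)
  expect_equal(clt$class, "within")
  expect_true(clt$tie)
  above <- data.frame(species = "hi", z = 0,
                      p50 = pqr_boundary_line(bd, 0.9, 0) + 1)
  expect_equal(classify_species(bd, above)$class, "above_upper")
})
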