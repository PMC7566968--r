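test_that("the light-response model honours its anchors", {
  expect_equal(nrh_assimilation(0, 0.05, 0.7, 6, 0.5), -0.5)
  # curve is nondecreasing and bounded by Pn - Rd
  I <- seq(0, 3000, by = 10)
  A <- nrh_assimilation(I, 0.05, 0.7, 6, 0.5)
  expect_true(all(diff(A) >= -1e-12))
  expect_true(all(A <= 6 - 0.5 + 1e-12))
  # concavity
  expect_true(all(diff(diff(A)) <= 1e-10))
})

test_that("the joint fit recovers noiseless light-curve parameters", {
  truth <- c(phi = 0.05, theta = 0.7, pn = 6, rd = 0.5)
  lc <- simulate_light_curve(truth["phi"], truth["theta"], truth["pn"],
                             truth["rd"])
  fit <- fit_light_response(lc, method = "joint")
  expect_equal(c(fit$phi, fit$theta, fit$pn, fit$rd), unname(truth),
               tolerance = 1e-6)
  expect_equal(nrh_assimilation(0, fit$phi, fit$theta, fit$pn, fit$rd),
               -fit$rd, tolerance = 1e-12)
})

test_that("the two-stage procedure approximates the truth and rejects non-curves", {
  lc <- simulate_light_curve(0.05, 0.7, 6, 0.5)
  fit <- fit_light_response(lc)
  expect_lt(abs(fit$pn - 6) / 6, 0.15)
  expect_gt(fit$phi, 0)
  expect_true(fit$theta > 0 && fit$theta <= 1)
  dark <- data.frame(I = c(0, 30, 50, 100, 300, 500, 800),
                     A = c(5, 4, 3.5, 3, 2, 1.5, 1))
  expect_error(fit_light_response(dark), "not positive")
  expect_error(fit_light_response(lc[1:4, ]), "at least 6")
})

test_that("the compensation point matches the analytic root and is monotone in Rd", {
  fit <- list(phi = 0.05, theta = 0.7, pn = 6, rd = 0.5)
  lcp <- light_compensation_point(fit)
  closed <- with(fit, rd * (pn - theta * rd) / (phi * (pn - rd)))
  expect_equal(lcp, closed, tolerance = 1e-6)
  expect_equal(nrh_assimilation(lcp, fit$phi, fit$theta, fit$pn, fit$rd), 0,
               tolerance = 1e-7)
  expect_equal(light_compensation_point(list(phi = 0.05, theta = 0.7,
                                             pn = 6, rd = 0)), 0)
  lcps <- sapply(seq(0.1, 2, by = 0.1), function(rd)
    light_compensation_point(list(phi = 0.05, theta = 0.7, pn = 6,
                                  rd = rd)))
  expect_true(all(diff(lcps) > 0))
  expect_error(light_compensation_point(list(phi = 0.05, theta = 0.7,
                                             pn = 1, rd = 2)), "Rd >= Pn")
})

test_that("percentage loss of conductivity is the defining ratio", {
  expect_equal(percent_loss_conductivity(2, 2), 0)
  expect_equal(percent_loss_conductivity(2, 0), 100)
  expect_equal(percent_loss_conductivity(2, 1), 50)
  expect_warning(out <- percent_loss_conductivity(2, 2.5), "clipped")
  expect_equal(out, 0)
  expect_error(percent_loss_conductivity(0, 1), "positive")
})

test_that("the vulnerability fit recovers noiseless parameters with PLC 50 at b", {
  vc <- simulate_vc_curve(a = 1.5, b = -5.64)
  fit <- fit_vulnerability_curve(vc)
  expect_equal(fit$a, 1.5, tolerance = 1e-6)
  expect_equal(fit$b, -5.64, tolerance = 1e-6)
  expect_identical(plc_sigmoid(fit$b, fit$a, fit$b), 50)
  expect_identical(fit$p50, fit$b)
})

test_that("positive injection pressures are negated and thin data rejected", {
  vc <- simulate_vc_curve(a = 1.5, b = -5.64)
  pos <- data.frame(psi = -vc$psi, plc = vc$plc)
  expect_warning(fit <- fit_vulnerability_curve(pos), "negated|psi")
  expect_equal(fit$b, -5.64, tolerance = 1e-6)
  flat <- data.frame(psi = -(1:6), plc = c(1, 2, 3, 4, 5, 6))
  expect_error(fit_vulnerability_curve(flat), "span")
})

test_that("PLC computed from conductivities refits the generating curve", {
  a <- 2
  b <- -4
  psi <- -(1:8)
  kh_max <- 3
  kh_i <- kh_max * (1 - plc_sigmoid(psi, a, b) / 100)
  plc <- percent_loss_conductivity(kh_max, kh_i)
  fit <- fit_vulnerability_curve(data.frame(psi = psi, plc = plc))
  expect_equal(c(fit$a, fit$b), c(a, b), tolerance = 1e-6)
})

test_that("hydraulic metrics are the defining quotients", {
  m <- hydraulic_metrics(flow = 1e-6, gradient = 40, sapwood_area = 5e-6,
                         leaf_area = 5e-3, dry_mass = 1.1,
                         fresh_volume = 2.0)
  expect_equal(m$ks, 1e-6 / (5e-6 * 40))
  expect_equal(m$kl, 1e-6 / (5e-3 * 40))
  expect_equal(m$huber, 1e-3)
  expect_equal(m$wood_density, 0.55)
  m2 <- hydraulic_metrics(2e-6, 40, 5e-6, 5e-3, 1.1, 2.0)
  expect_equal(m2$ks, 2 * m$ks)
  expect_equal(m2$kl, 2 * m$kl)
  expect_equal(hydraulic_metrics(1, 1, 2, 2, 1, 1)$huber, 1)
  expect_error(hydraulic_metrics(-1, 1, 1, 1, 1, 1), "positive")
})

test_that("the hydraulic diameter is a power mean between mean and max", {
  expect_equal(hydraulic_diameter(c(3, 3, 3)), 3)
  expect_equal(hydraulic_diameter(c(1, 2)), 33 / 17)
  set.seed(30)
  for (i in 1:10) {
    d <- stats::rlnorm(50, log(8), 0.4)
    dh <- hydraulic_diameter(d)
    expect_gte(dh, mean(d))
    expect_lte(dh, max(d))
  }
  expect_error(hydraulic_diameter(numeric(0)), "empty")
  expect_error(hydraulic_diameter(c(1, -2)), "positive")
})
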