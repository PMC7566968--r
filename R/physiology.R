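#' Non-rectangular hyperbola light-response model
#'
#' Net assimilation as a function of irradiance:
#' `A(I) = (phi I + Pn - sqrt((phi I + Pn)^2 - 4 theta phi I Pn)) /
#' (2 theta) - Rd`.  At `I = 0`, `A = -Rd`; as `I -> Inf`, `A -> Pn - Rd`.
#'
#' @param I irradiance (umol photon m-2 s-1).
#' @param phi quantum yield (initial slope).
#' @param theta convexity in (0, 1].
#' @param pn light-saturated gross rate (umol CO2 m-2 s-1).
#' @param rd dark respiration (umol CO2 m-2 s-1).
#' @return assimilation rate(s).
#' @export
nrh_assimilation <- function(I, phi, theta, pn, rd) {
  s <- phi * I + pn
  disc <- pmax(s^2 - 4 * theta * phi * I * pn, 0)
  (s - sqrt(disc)) / (2 * theta) - rd
}

#' Fit the non-rectangular hyperbola to a light-response curve
#'
#' The default two-stage procedure: (1) ordinary least squares of `A` on
#' `I` for points with `I < low_light_cut` gives the quantum yield `phi`
#' (slope) and dark respiration `Rd` (minus the intercept); (2) with `phi`
#' and `Rd` frozen, `Pn` and `theta` are estimated by nonlinear least
#' squares over all points, `theta` constrained to (0, 1].
#' `method = "joint"` instead refines all four parameters jointly
#' (initialized from the two-stage fit) — the right choice when the model
#' is exact and full-precision parameter recovery matters.
#'
#' @param data data.frame with columns `I` (irradiance, >= 0, distinct
#'   values) and `A` (net assimilation).
#' @param low_light_cut irradiance threshold for stage 1 (default 150).
#' @param method `"two_stage"` (the field procedure) or `"joint"`.
#' @return an object of class `"light_response_fit"`: `phi`, `theta`,
#'   `pn`, `rd`, `lcp`, `rss`, `method`.
#' @export
fit_light_response <- function(data, low_light_cut = 150,
                               method = c("two_stage", "joint")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), all(c("I", "A") %in% names(data)))
  I <- as.numeric(data$I)
  A <- as.numeric(data$A)
  if (any(I < 0)) stop("irradiance must be non-negative")
  if (anyDuplicated(I)) stop("irradiance values must be distinct")
  if (length(I) < 6L) stop("need at least 6 points")
  low <- I < low_light_cut
  if (sum(low) < 2L) stop("need at least 2 points below the low-light cut")
  if (sum(!low) < 3L) stop("need at least 3 points above the low-light cut")
  st1 <- stats::lm(A[low] ~ I[low])
  phi <- unname(stats::coef(st1)[2])
  rd <- -unname(stats::coef(st1)[1])
  if (!is.finite(phi) || phi <= 0)
    stop("stage-1 slope (quantum yield) is not positive; ",
         "data do not look like a light response")
  df <- data.frame(I = I, A = A)
  start <- list(pn = max(A) + max(rd, 0), theta = 0.8)
  fit2 <- NULL
  for (th0 in c(start$theta, 0.5, 0.95, 0.2)) {
    fit2 <- tryCatch(minpack.lm::nlsLM(
      A ~ nrh_assimilation(I, phi, theta, pn, rd),
      data = df, start = list(pn = start$pn, theta = th0),
      lower = c(pn = 1e-8, theta = 1e-6), upper = c(pn = Inf, theta = 1),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit2)) break
  }
  if (is.null(fit2))
    stop("stage-2 fit did not converge after multistart")
  pn <- unname(stats::coef(fit2)["pn"])
  theta <- unname(stats::coef(fit2)["theta"])
  if (method == "joint") {
    fitj <- tryCatch(minpack.lm::nlsLM(
      A ~ nrh_assimilation(I, phi, theta, pn, rd),
      data = df, start = list(phi = phi, theta = theta, pn = pn, rd = rd),
      lower = c(phi = 1e-10, theta = 1e-6, pn = 1e-8, rd = 0),
      upper = c(phi = Inf, theta = 1, pn = Inf, rd = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fitj)) stop("joint fit did not converge")
    cf <- stats::coef(fitj)
    phi <- unname(cf["phi"]); theta <- unname(cf["theta"])
    pn <- unname(cf["pn"]); rd <- unname(cf["rd"])
    rss <- sum(stats::resid(fitj)^2)
  } else {
    rss <- sum(stats::resid(fit2)^2)
  }
  out <- structure(list(phi = phi, theta = theta, pn = pn, rd = rd,
                        rss = rss, method = method, n = length(I)),
                   class = "light_response_fit")
  out$lcp <- light_compensation_point(out)
  out
}

#' @export
print.light_response_fit <- function(x, ...) {
  cat(sprintf(paste0("Light-response fit (%s): phi = %.4f, theta = %.3f, ",
                     "Pn = %.3f, Rd = %.3f\n"),
              x$method, x$phi, x$theta, x$pn, x$rd))
  cat(sprintf("  LCP = %.3f umol m-2 s-1, RSS = %.4g (n = %d)\n",
              x$lcp, x$rss, x$n))
  invisible(x)
}

#' Light compensation point
#'
#' The irradiance at which modelled net assimilation is zero, found by
#' bisection to 1e-8 on a bracket grown upward from zero.  `Rd = 0` gives
#' `LCP = 0`; `Rd >= Pn` means respiration can never be compensated and is
#' an error.
#'
#' @param fit a `"light_response_fit"`, or a list with `phi`, `theta`,
#'   `pn`, `rd`.
#' @return the light compensation point (umol photon m-2 s-1).
#' @export
light_compensation_point <- function(fit) {
  phi <- fit$phi; theta <- fit$theta; pn <- fit$pn; rd <- fit$rd
  if (phi <= 0) stop("phi must be positive")
  if (rd == 0) return(0)
  if (rd >= pn) stop("Rd >= Pn: no compensation point exists")
  f <- function(I) nrh_assimilation(I, phi, theta, pn, rd)
  hi <- 1
  for (k in 1:200) {
    if (f(hi) > 0) break
    hi <- hi * 2
  }
  if (f(hi) <= 0) stop("failed to bracket the compensation point")
  lo <- 0
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Percentage loss of hydraulic conductivity
#'
#' `PLC = 100 * (kh_max - kh_i) / kh_max`.  Conductivities above the
#' flushed maximum are clipped to it with a warning.
#'
#' @param kh_max maximum (flushed) hydraulic conductivity, > 0.
#' @param kh_i conductivity measured after pressurization step i (vector).
#' @return PLC values in percent.
#' @export
percent_loss_conductivity <- function(kh_max, kh_i) {
  if (!is.numeric(kh_max) || length(kh_max) != 1L || kh_max <= 0)
    stop("kh_max must be a single positive value")
  if (any(kh_i < 0)) stop("conductivities must be non-negative")
  if (any(kh_i > kh_max)) {
    warning("conductivity above the flushed maximum; clipped")
    kh_i <- pmin(kh_i, kh_max)
  }
  100 * (kh_max - kh_i) / kh_max
}

#' Sigmoidal PLC model for vulnerability curves
#'
#' `PLC(psi) = 100 / (1 + exp(a * (psi - b)))` with `psi` the (negative)
#' xylem pressure in MPa.  `b` is P50 — the fitted PLC at `psi = b` is 50
#' exactly — and `a` is the steepness (1/MPa).
#'
#' @param psi xylem pressure (MPa, negative).
#' @param a steepness, > 0.
#' @param b P50 (MPa).
#' @return PLC in percent.
#' @export
plc_sigmoid <- function(psi, a, b) 100 / (1 + exp(a * (psi - b)))

#' Fit the exponential sigmoid vulnerability curve
#'
#' Nonlinear least squares of PLC on xylem pressure under [plc_sigmoid()].
#' Starting values come from the logit linearization
#' `log(100 / PLC - 1) = a * (psi - b)` on points with PLC in `[2, 98]`
#' (exact 0/100 points are excluded from the initializer only); all points
#' are weighted equally in the fit.
#'
#' @param data data.frame with columns `psi` (MPa; positive injection
#'   pressures are accepted and negated with a warning) and `plc`
#'   (percent, in `[0, 100]`).
#' @return an object of class `"vulnerability_fit"`: `a`, `b` (= P50),
#'   `rss`, `n`, `psi_negated` flag.
#' @export
fit_vulnerability_curve <- function(data) {
  stopifnot(is.data.frame(data), all(c("psi", "plc") %in% names(data)))
  psi <- as.numeric(data$psi)
  plc <- as.numeric(data$plc)
  negated <- FALSE
  if (all(psi >= 0) && any(psi > 0)) {
    warning("positive injection pressures supplied; using psi = -pressure")
    psi <- -psi
    negated <- TRUE
  }
  if (length(psi) < 5L) stop("need at least 5 points")
  if (any(plc < 0 | plc > 100)) stop("PLC must be within [0, 100]")
  if (diff(range(plc)) < 50)
    stop("PLC span is below 50 percentage points; curve not identifiable")
  if (max(plc) < 85)
    warning("maximum PLC below 85%; the campaign stopping rule was not met")
  mid <- plc >= 2 & plc <= 98
  if (sum(mid) >= 2L) {
    lin <- stats::lm(log(100 / plc[mid] - 1) ~ psi[mid])
    a0 <- unname(stats::coef(lin)[2])
    b0 <- -unname(stats::coef(lin)[1]) / a0
    if (!is.finite(a0) || a0 <= 0) { a0 <- 1; b0 <- stats::median(psi) }
  } else {
    a0 <- 1; b0 <- stats::median(psi)
  }
  df <- data.frame(psi = psi, plc = plc)
  fit <- NULL
  for (st in list(c(a0, b0), c(1, stats::median(psi)), c(3, mean(psi)))) {
    fit <- tryCatch(minpack.lm::nlsLM(
      plc ~ plc_sigmoid(psi, a, b), data = df,
      start = list(a = st[1], b = st[2]),
      lower = c(a = 1e-6, b = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("vulnerability-curve fit did not converge ",
                         "after multistart")
  cf <- stats::coef(fit)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 p50 = unname(cf["b"]), rss = sum(stats::resid(fit)^2),
                 n = length(psi), psi_negated = negated),
            class = "vulnerability_fit")
}

#' @export
print.vulnerability_fit <- function(x, ...) {
  cat(sprintf("Vulnerability curve: a = %.4f MPa-1, P50 = b = %.4f MPa ",
              x$a, x$b))
  cat(sprintf("(RSS = %.4g, n = %d)\n", x$rss, x$n))
  invisible(x)
}

#' Branchlet hydraulic metrics
#'
#' Specific conductivity `ks = flow / (sapwood_area * gradient)`,
#' leaf-specific conductivity `kl = flow / (leaf_area * gradient)`, Huber
#' value `= sapwood_area / leaf_area`, and wood density
#' `W = dry_mass / fresh_volume`.
#'
#' @param flow maximum flow rate (kg s-1).
#' @param gradient pressure gradient (MPa m-1).
#' @param sapwood_area cross-section sapwood area (m2).
#' @param leaf_area distal leaf area (m2).
#' @param dry_mass segment dry mass (g).
#' @param fresh_volume segment fresh volume (cm3).
#' @return a list: `ks`, `kl` (kg m-1 MPa-1 s-1), `huber` (m2 m-2),
#'   `wood_density` (g cm-3).
#' @export
hydraulic_metrics <- function(flow, gradient, sapwood_area, leaf_area,
                              dry_mass, fresh_volume) {
  vals <- c(flow, gradient, sapwood_area, leaf_area, dry_mass, fresh_volume)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all inputs must be positive and finite")
  list(ks = flow / (sapwood_area * gradient),
       kl = flow / (leaf_area * gradient),
       huber = sapwood_area / leaf_area,
       wood_density = dry_mass / fresh_volume)
}

#' Mean hydraulic tracheid diameter
#'
#' The flow-weighted mean diameter `d_h = sum(d^5) / sum(d^4)`, which lies
#' between the arithmetic mean and the maximum of the diameters.
#'
#' @param diameters tracheid diameters (um), all positive.
#' @return `d_h` in the units of the input.
#' @export
hydraulic_diameter <- function(diameters) {
  d <- as.numeric(diameters)
  if (!length(d)) stop("empty diameter list")
  if (any(!is.finite(d)) || any(d <= 0))
    stop("diameters must be positive and finite")
  sum(d^5) / sum(d^4)
}
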