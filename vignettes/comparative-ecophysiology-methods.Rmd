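---
title: "Methods: phylogenetic comparative analysis of hydraulic safety and photosynthetic capacity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic comparative analysis of hydraulic safety and photosynthetic capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ecophylo` implements a comparative eco-physiology workflow for woody
plants: given a time-calibrated phylogeny and a species table of hydraulic
safety (branchlet P50, the xylem pressure at 50% conductivity loss, MPa),
photosynthetic capacity (Pn, light-saturated net assimilation), threat
status and climate covariates, it answers three questions. (1) How strong
is the phylogenetic signal in each trait? (2) Which environmental
gradients drive the traits across non-threatened species, and do the
traits trade off against each other? (3) Do threatened species sit outside
the trait envelopes of their non-threatened relatives? It also fits the
two laboratory curve models the traits come from: the non-rectangular
hyperbola light response and the sigmoidal xylem vulnerability curve.

This vignette records the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open.

## The GLS core

Every comparative stage rests on one likelihood. For a trait vector $y$
over $n$ species, design matrix $X$, and a covariance structure $V$
derived from the tree,
$$y \sim \mathcal{N}(X\beta,\ \sigma^2 V),$$
with $\beta$ and $\sigma^2$ profiled analytically:
$\hat\beta = (X^\top V^{-1}X)^{-1}X^\top V^{-1}y$,
$\hat\sigma^2 = r^\top V^{-1} r / n$ (ML divisor $n$), and
$$\ell = -\tfrac12\left[n\log(2\pi\hat\sigma^2) + \log|V| + n\right].$$
All solves go through the Cholesky factor of $V$; $V$ is never inverted
explicitly, and $\log|V|$ comes from the factor. Numerical guards:

* a non-positive-definite $V$ (coincident tips) receives one diagonal
  jitter of $10^{-10}\,\overline{\mathrm{diag}(V)}$, with a warning;
* an exact fit ($\hat\sigma^2 = 0$) returns a large finite log-likelihood
  sentinel ($10^{10}$) with a `degenerate` flag instead of $+\infty$, so
  scalar optimizers over $\lambda$ or $\alpha$ remain well behaved.

Covariance structures: Brownian motion ($C_{ij}$ = shared root-to-MRCA
path length), Pagel's $\lambda$ transform (off-diagonals of $C$ scaled by
$\lambda\in[0,1]$; values above 1 are out of scope because they are not
ultrametric-safe), the stationary Ornstein–Uhlenbeck transform
$$V_{ij} = \frac{e^{-2\alpha(T - t_{ij})}\left(1 - e^{-2\alpha t_{ij}}\right)}{2\alpha}$$
(ultrametric trees only — a non-ultrametric tree is rejected rather than
silently approximated; $t_{ij} = C_{ij}$, $T$ the depth), and the identity
for white noise.

## Question 1 — phylogenetic signal

**Pagel's $\lambda$** is estimated by profiling the intercept-only GLS
likelihood over $\lambda\in[0,1]$: a 21-point grid locates the basin (the
profile can be flat or bimodal on small trees), then golden-section
refinement to $10^{-7}$ inside the bracketing interval, with the endpoints
compared explicitly. The test of $\lambda = 0$ sits on the boundary of the
parameter space, so the likelihood-ratio statistic is compared both to a
plain $\chi^2_1$ (what comparable software prints, reported as `p_chisq`)
and to the 50:50 $\chi^2_0{:}\chi^2_1$ mixture (`p_mixture`); neither is
privileged.

**The PSR curve** regresses the trait on successive phylogenetic
eigenvectors. The eigenvectors come from Gower double-centering $-D/2$,
where $D$ is the *patristic* distance matrix. The patristic distance is
already the squared-divergence scale of Brownian motion — the expected
squared trait difference between two tips grows linearly with the path
length between them — so the double-centered matrix equals the centered BM
covariance and a BM trait's curve tracks the diagonal in expectation.
(Centering squared patristic distances, the convention for metric
embedding of arbitrary dissimilarities, breaks that calibration: simulated
BM traits then give mean areas near $-0.14$ on 50-tip trees.) Axes with
eigenvalues below $10^{-10}$ of the largest are dropped; the curve is
anchored at the origin; the area is the trapezoidal integral of
$R^2(u) - u$. Because the eigenvectors are orthonormal and centered, the
cumulative $R^2$ is a cumulative sum of squared projections, hence
nondecreasing by construction. At $n = 50$ the area statistic retains a
small finite-sample bias of about $-0.04$ under BM (the $R^2$ ratio is not
mean-unbiased when the leading eigenvalue dominates); tests of the
BM-diagonal property use enough replicates that the Monte Carlo mean
reflects this expectation rather than seed noise.

**Model comparison** fits WN, BM and OU to each trait and ranks them by
$\mathrm{AIC} = 2k - 2\ell$ with $k = 2, 2, 3$ (the OU optimum and root
mean are collapsed into a single mean parameter, so OU adds only
$\alpha$). $\alpha$ is maximized over a log-spaced bracket
$\alpha T \in [10^{-6}, 50]$ (60 points) followed by golden-section
refinement; an estimate at either end of the bracket is flagged as a
boundary solution. The lower end of the bracket reproduces BM (checked to
$10^{-3}$ in the tests), the upper end white noise, so the three models
are mutually calibrated.

## Question 2 — PGLS and the environmental PCA

Trait–environment and trait–trait regressions are bivariate PGLS fits with
$\lambda$ estimated jointly with the regression by ML (the same profile
machinery). Standard errors use the unbiased scale $r^\top V^{-1}r/(n-p)$;
p-values are two-sided Student-$t$ with $n - p$ degrees of freedom.
Choices that the analysis leaves open, and how they are fixed here:

* **$R^2$** is not uniquely defined for GLS; the package reports
  $1 - \mathrm{RSS}_V/\mathrm{TSS}_V$ computed in the whitened space
  against the GLS intercept-only fit at the same $\lambda$ — the direct
  analogue of OLS $R^2$, equal to it when $\lambda = 0$.
* **Predictor standardization.** Climate variables live on incommensurate
  scales, and slope tables in this literature are most interpretable per
  standard deviation of the predictor. `standardize_predictor` defaults to
  off in `pgls_fit()`; the batch runner turns it on for environmental
  panels and leaves it off for trait–trait panels. Standardization never
  changes $t$, $p$ or $R^2$, only the slope units.
* **One predictor at a time.** The reproduction path is deliberately
  bivariate (a slope table, not a multiple regression); multiple
  predictors are accepted but not used by the batch runner.

The environmental PCA z-scores the six variables (latitude, altitude,
MAT, MAP, MTCM, water deficit) and eigendecomposes their correlation
matrix. It is fitted on **all** species — threatened included — so that
threatened species carry genuine PC scores when they are later projected
onto the trait envelopes; regressions then use non-threatened species
only. Axis signs are arbitrary in any eigendecomposition, so the loading
of largest magnitude within each axis is made positive, making outputs
deterministic across platforms.

## Question 3 — phylogenetic quantile regression

The PQR procedure per quantile level $\tau \in \{0.10, 0.90\}$:

1. fit the non-phylogenetic quantile regression of the trait on the
   predictor;
2. take its residuals;
3. compute the phylogenetic autocovariate
   $a_i = \sum_{j\ne i} d_{ij}^{-2} r_j \big/ \sum_{j\ne i} d_{ij}^{-2}$,
   with $d$ the "one minus phylogenetic correlation" distance;
4. refit the quantile regression with $a$ as an extra regressor.

The reported boundary fixes $a$ at its average, describing a species with
average phylogenetic residual context. Species outside the 10%/90%
boundaries are classified `below_lower` / `above_upper` by strict
inequality; equality within $10^{-12}$ is classified `within` and flagged
as a tie. Boundaries are fitted on non-threatened species only; threatened
species are projected and classified afterwards.

Design points:

* **Exact LP solver.** The check-loss minimization is solved as the
  Koenker–Bassett dual linear program with a bounded-variable two-phase
  revised simplex written for this package (basis size = number of
  regression parameters, so hundreds of observations cost milliseconds).
  The solution is an exact LP vertex — at least $p$ observations are
  interpolated — and deterministic tie-breaking (Dantzig entering with
  smallest-index ties, Bland fallback after degenerate runs) makes
  repeated solves identical. Tests verify the optimum against exhaustive
  vertex enumeration.
* **Residual source.** The autocovariate is built from the same-$\tau$
  step-1 residuals by default; `resid_tau = "median"` switches to
  $\tau = 0.5$ residuals, and the choice is recorded in the result.
* **Zero distances** between distinct tips (phylogenetic correlation 1)
  are replaced by the smallest positive off-diagonal distance times
  $10^{-3}$, with a warning.
* **Coverage semantics.** When residuals are strongly phylogenetically
  correlated, the autocovariate explains part of the spread and the
  conditional quantile tightens: the displayed mean-autocovariate line
  then lies *inside* the marginal trait envelope, and the fraction of
  fitted species below the displayed 10% line exceeds 0.10 (about 0.18 at
  $n = 500$ under $\lambda = 0.8$ residuals). The $\tau$-level coverage
  property belongs to each species' own fitted boundary (its own
  autocovariate value); that in-sample fraction is reported as
  `coverage_below` and is what the coverage checks use. Under
  exchangeable residuals the two notions coincide and the boundary
  recovers the marginal envelope (verified to within a few percent at
  $n = 300$).
* **Crossing.** The two levels are fitted independently; crossing inside
  the fitted range is flagged, not repaired.
* A constant autocovariate (for instance when step-1 residuals are all
  zero) is dropped from the refit with its coefficient reported as 0,
  reducing the boundary to the plain quantile line.

## Physiology: the two curve models

**Light response** (non-rectangular hyperbola):
$$A(I) = \frac{\phi I + P_n - \sqrt{(\phi I + P_n)^2 - 4\Theta\phi I P_n}}{2\Theta} - R_d.$$
The default fit follows the two-stage field procedure: OLS of $A$ on $I$
below 150 µmol m⁻² s⁻¹ gives $\phi$ (slope) and $R_d$ (minus intercept);
then $P_n$ and $\Theta$ are fitted by Levenberg–Marquardt least squares
with $\phi, R_d$ frozen, $\Theta \in (10^{-6}, 1]$ (convexity bounds the
model gives no reason to relax). Because the model is curved even at low
light, the two-stage $\phi$ and $R_d$ are slightly biased on exact data;
`method = "joint"` refines all four parameters jointly from the two-stage
start and recovers noiseless parameters to $10^{-6}$ — it is the method
used wherever full-precision recovery is the point, while `"two_stage"`
remains the default because it is the procedure the trait definitions come
from. The light compensation point ($A(I) = 0$) is found by bisection to
$10^{-8}$ on a bracket grown upward from zero; it agrees with the closed
form $I = R_d(P_n - \Theta R_d)/(\phi(P_n - R_d))$, and $R_d = 0$ gives
LCP $= 0$ exactly.

**Vulnerability curve**:
$\mathrm{PLC}(\Psi) = 100/(1 + e^{a(\Psi - b)})$ with $\Psi$ the negative
of the injection pressure; $b$ is P50 by construction (fitted PLC at
$\Psi = b$ is exactly 50) and $a > 0$ the steepness. Starting values come
from the logit linearization $\log(100/\mathrm{PLC} - 1) = a(\Psi - b)$ on
points with PLC in $[2, 98]$ (exact 0s and 100s are excluded from the
initializer only); the nonlinear fit weights all points equally. Curves
whose PLC span is below 50 points are rejected as unidentifiable; a
maximum PLC below 85% (the measurement campaign's stopping rule) warns but
does not stop the fit. Positive pressure grids are accepted and negated
with a warning. At the default 8-level pressure grid with Gaussian PLC
noise of 5, the P50 estimator is unbiased to well under 0.1 MPa.

Supporting arithmetic: PLC from conductivities is
$100(K_h - K_{hi})/K_h$ with above-maximum conductivities clipped;
specific and leaf-specific conductivity, Huber value and wood density are
the defining quotients; the hydraulic mean diameter is
$\sum d^5/\sum d^4$, a power mean lying between the arithmetic mean and
the maximum. The theoretical pit-pore quantity sometimes invoked alongside
these is never computed; the package only provides the log–log PGLS
transform for testing $P_{50} \propto 1/d_h$.

## The synthetic-data generator

The generator emulates the statistical *structure* the analyses assume,
with the shape of the compiled conifer dataset as defaults: a 36-taxon
pure-birth tree (rescaled to unit depth so residual marginal SDs equal
$\sigma$ exactly), 7 threatened species, six environmental variables with
a fixed realistic correlation matrix (temperature pair coupled at 0.85 and
opposed to latitude; moisture pair opposed at $-0.6$), a hydraulic-safety
response $\beta_0 + \beta_1 z(\mathrm{MAP}) + \varepsilon$ with
$\beta_0 = -4$ MPa, $\beta_1 = 0.31$ per predictor SD, $\sigma = 0.6$ and
$\lambda = 0.8$ residuals (implying $R^2 \approx 0.2$, the magnitude of
the relationships the method targets), and an independent BM second trait
standing in for photosynthetic capacity. Threatened species are displaced
$\delta$ residual SDs past the true $10\%$ (or $90\%$) residual quantile
— the envelope is defined from the known residual distribution, never from
a fitted model — with $\delta = 5$ by default and $\delta = 0$ meaning no
displacement at all. Every draw is reproducible from the config seed.

What it does **not** emulate: real climate marginals (WorldClim-like
skew), sampling biases of trait databases, intraspecific variation or
measurement error, non-ultrametric trees, or correlated missingness.
Passing tests therefore demonstrate estimator correctness under the
models' own assumptions, not robustness to the failure modes of compiled
field data.

## Problem sizes and reproducibility

The test suite and the acceptance script use Monte Carlo sizes chosen so
each property's estimate is decisively more precise than its acceptance
band: 200 replicates for λ-recovery regimes and model selection, 1000 for
the PSR BM-diagonal property (whose band is only ~0.006 wide relative to
the finite-sample expectation), 200/500 for PGLS recovery and size, 100
for outlier-detection power, and $n = 500$ for quantile coverage. The full
suite runs in about a minute on one core. Every stochastic step is seeded;
the pipeline itself (`run_full_analysis()`) is a pure function of its
inputs, and `write_report()` emits no timestamps, so regeneration from the
same inputs is byte-identical.

## Known limitations

* $\lambda > 1$, Pagel's $\kappa$/$\delta$, early-burst and trend models
  are out of scope; OU requires an ultrametric input tree.
* No measurement-error variance term in the GLS; no multivariate-trait
  models.
* PQR boundaries are affine; no smoothing, no bootstrap bands, no
  crossing constraint.
* Polytomies are accepted as-is; no tree inference, dating or taxonomy
  resolution.
* The PCA projects threatened species with the fitted standardization;
  species missing any environmental variable are silently absent from the
  score table (they are reported as dropped at alignment instead).
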