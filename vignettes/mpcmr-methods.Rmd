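---
title: "Estimating time-varying exposure effects with mpcmr: models, choices, limitations"
author: "mpcmr maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating time-varying exposure effects with mpcmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the model

Most exposures studied in Mendelian randomization (MR) vary over a lifetime,
yet a genetic variant is fixed at conception. When the variant's association
with the exposure *changes* with age, that variation identifies more than a
single lifetime-averaged effect: it carries information about *when* the
exposure matters. `mpcmr` estimates the effect function \(\beta(t)\) in the
structural outcome model

\[
Y \;=\; \beta_0 + \int_0^T \beta(t)\, X(t)\, dt \;+\; g\!\left(\vec U, \epsilon_Y\right),
\]

where \(X(t)\) is the exposure trajectory on \([0, T]\), \(\vec U\) is an
unobserved (possibly time-varying) confounder process, and \(\beta(t)\) is
the direct effect of exposure at time \(t\) on the end-of-window outcome.
Under the usual IV core conditions (relevance at every \(t\),
exchangeability, exclusion restriction for the whole trajectory), a known
intervention \(a(t)\) added to the trajectory shifts the mean outcome by
\(\int_0^T \beta(t) a(t) dt\) — this is what `interventionEffect()` reports.

Estimating a whole function from finitely many variants is ill-posed, so the
trajectory is first compressed. By the Karhunen–Loève representation,

\[
X(t) = \mu(t) + \sum_{k=1}^{K} \xi_k \phi_k(t) + e(t),
\]

with orthonormal eigenfunctions \(\phi_k\) and subject-specific scores
\(\xi_k\) ("pseudo-exposures"). Substituting into the outcome model turns
the functional problem into a \(K\)-variable multivariable MR model for the
scores, with coefficients \(\beta_k^* = \int \beta(t)\phi_k(t)dt\). The
truncation remainder \(e(t)\) induces *structural pleiotropy* if it is
correlated with the instruments — the reason the package insists on a high
fraction of variance explained (FVE) before trusting a fit.

## Stage 1 — sparse FPCA with PACE scores

Real longitudinal exposures are observed sparsely (a handful of visits, at
different ages for different people). `fitFpca()` therefore estimates:

* the mean curve, by local-linear Epanechnikov smoothing of the pooled
  records;
* the covariance surface, by 2-D local-linear smoothing of the raw
  between-observation cross-products of mean-removed values (same-observation
  products are excluded, since they carry the measurement-error variance);
* the measurement-error variance \(\sigma^2\), as the average gap between
  the smoothed same-observation diagonal and the surface diagonal over the
  central half of the domain, floored at zero;
* eigenfunctions and eigenvalues, from the trapezoid-weighted
  eigenproblem of the discretised covariance operator; and
* per-subject scores, by best linear prediction (PACE):
  \(\hat\xi_{ik} = \lambda_k \phi_k(\mathbf t_i)' \Sigma_i^{-1}
  (\mathbf x_i - \mu(\mathbf t_i))\) with
  \(\Sigma_i = \Phi_i \Lambda \Phi_i' + \sigma^2 I\) at subject \(i\)'s own
  observation times. Scores are shrunk toward zero exactly as a conditional
  expectation should be; a subject observed at the mean gets a zero score.

Numerical details that matter:

* **Binned smoothing with exact moments.** Raw points are binned to the
  output-grid cells, but the exact within-cell sums of \(t\), \(t^2\), and
  \(t \cdot y\) are retained; only the kernel is evaluated at cell centers.
  The weighted least-squares fit is exact for linear signals whatever the
  weights, so noiseless linear data are reproduced to machine precision
  while the surface smoother reduces to a handful of small matrix products
  (the per-evaluation cost is independent of both sample size and the
  number of raw pairs).
* **Bandwidths.** Defaults are 10% of the domain width for the mean and 15%
  for the surface — ordinary fixed-bandwidth PACE practice, deterministic,
  and wide enough that every grid point has kernel support at ten
  observations per subject. Both are overridable (`bwMean`, `bwCov`); a
  too-small bandwidth raises an error naming the unsupported grid points
  rather than returning a ragged surface.
* **Orientation.** Eigenfunction signs are fixed so
  \(\int \phi_k(t)\,t\,dt \ge 0\) (ties broken by \(\int\phi_k \ge 0\)),
  making fits comparable across replicates. Negative eigenvalues are
  truncated and dropped; FVE is computed over the positive spectrum.
* **Output grid.** 101 equally spaced points by default; curves are moved
  between grids by linear interpolation.
* **Degenerate subjects.** Single-observation subjects contribute to the
  mean and receive scores, but cannot contribute covariance cross-products.
  If \(\sigma^2 = 0\) and a subject has duplicated times, the conditional
  covariance solve is ridge-stabilised with a warning.

\(K\) is chosen as the smallest number of components reaching
`fveThreshold` (default 95%).

## Stage 2 — basis choice and instrumented fitting

The effect function is parameterised on a basis,
\(\beta(t) = \sum_{l=1}^L \gamma_l b_l(t)\) with \(L \le K\). Two bases are
built in: the eigenfunctions themselves (then the transformation matrix
\(B = \int \phi b' dt\) is the identity and \(\gamma = \beta^*\)), and
polynomials. Polynomials are evaluated on the rescaled time \(u = t/T\) to
keep the design conditioned on domains stretching to 50+ time units;
`polyCoefOnTimeScale()` maps fitted coefficients back to the natural
\(t^{l-1}\) scale. The transformed pseudo-exposures are
\(\xi^* = B'\xi\) (`transformScores()`).

`cueGmm()` fits the instrumented model with moment vector
\(\hat g(\gamma) = E_n\!\left(Z(Y - \xi^{*\prime}\gamma)\right)\) and the
homoskedastic continuously-updating weighting
\(\hat\Omega(\gamma) = E_n(ZZ')\, E_n\!\left((Y - \xi^{*\prime}\gamma)^2\right)\).
Because this weighting factorises into a fixed matrix times a scalar, the
minimisation is run as iterated linear GMM steps with the scalar re-evaluated
each round; the iteration is stationary at the two-stage least squares
solution, and the reported covariance
\((\hat G'\hat\Omega^{-1}\hat G)^{-1}/n\) coincides with the classical
homoskedastic 2SLS covariance. We note the trade-off explicitly: the exact
minimiser of the *ratio* objective is the LIML-type solution of a
generalised eigenproblem, which differs from the fixed point by \(O(1/n)\);
we prefer the fixed point because it is closed-form, exactly reproducible,
and the difference is far inside sampling noise at the sample sizes where
the method is usable at all. The objective value at the fit is kept — it is
the Hansen-J over-identification statistic used by `overidQ()`. A
numerically perfect fit (zero residual) would make the objective \(0/0\);
it is defined as 0 there.

All variables are mean-centered before fitting, which absorbs the
intercept; centering, subject alignment (sorted identifiers, so results do
not depend on input row order) and removal of zero-variance instruments
live in `buildIvData()`.

`associationFit()` is the deliberately naive comparator: ordinary least
squares of the outcome on the scores, no instruments. With confounded
trajectories its curve is biased at every timepoint — the package keeps it
because the contrast against the instrumented fit is the clearest practical
demonstration of why the instruments are needed.

## Stage 3 — identification-robust inference

Genetic associations with different principal components are often nearly
proportional, so the scores can be *conditionally* weak instruments even
when each is marginally strong. Point-estimate-based (Wald) intervals are
then unreliable. `lmStat()` implements Kleibergen's Lagrange-multiplier
statistic: the moment vector at a candidate \(\gamma_0\) is projected onto
an orthogonalised Jacobian
\(\hat D_k = \hat G_k - \hat\Delta_k' \hat\Omega^{-1}\hat g\)
(with per-component covariance blocks
\(\hat\Delta_k = E_n(-Z \xi^*_k (Y - \xi^{*\prime}\gamma_0) Z')\)), giving a
statistic that is asymptotically \(\chi^2_L\) at the true parameter
*regardless of instrument strength*. The matrix square root
\(\hat\Omega^{-1/2}\) is the symmetric eigendecomposition root. If the
projected direction matrix is numerically rank-deficient, the projection
uses its numerical range and the reduced rank is reported as the degrees of
freedom.

`lmRegion()` inverts the test over an \(m^L\) lattice spanning ±`width`
standard errors around the point estimate (defaults: `m = 41`,
`width = 4`, level 5%). The accepted set may be empty (warning: widen the
search or suspect misspecification) or disconnected — both are reported
as-is, as weak-instrument confidence regions genuinely take such shapes.
`regionToBand()` maps the accepted set through the basis to pointwise bands
\([\min_{\gamma_0} b(t)'\gamma_0,\ \max_{\gamma_0} b(t)'\gamma_0]\); because
the lattice region is a joint \(\chi^2_L\) region, its per-coordinate
projection is wider than a marginal Wald interval by about
\(\sqrt{\chi^2_{L,0.95}/\chi^2_{1,0.95}}\) even with strong instruments —
that conservatism is the price of robustness. `globalNullTest()` evaluates
the statistic at \(\gamma_0 = 0\): a test of no causal effect anywhere in
the time window.

Degrees of freedom follow the number of fitted parameters \(L\) (the
transformed-exposure substitution carries the chi-square reference along
with it).

## Instrument diagnostics

`conditionalF()` reports Sanderson–Windmeijer-type conditional
F-statistics: for each pseudo-exposure, the other exposures are partialled
out through their instrument-predicted values, and the F-statistic of the
instruments in the residual regression is computed with numerator degrees
of freedom \(J - L + 1\) (the \(J/(J-L+1)\) correction) and denominator
\(n - J - L\). With one exposure this is exactly the classical first-stage
F. The published construction leaves some freedom in the degrees-of-freedom
convention; the one above is fixed here and validated against the reference
simulation magnitudes to within a few percent. `alphaCurves()` reassembles
each variant's time-varying association with the exposure from its score
associations, \(\hat\alpha_j(t) = \sum_k \widehat{\mathrm{cov}}(Z_j,\xi_k)/
\widehat{\mathrm{var}}(Z_j)\,\phi_k(t)\) — useful for checking that the
genetic associations genuinely vary with time, without which no method can
resolve \(\beta(t)\).

## The simulation engine

`simulateDataset()` reproduces the validation design end-to-end on
\([0, 50]\):

* dosages \(G_j \sim \mathrm{Binomial}(2, 0.3)\), \(J = 30\) variants;
* exposure \(X(t) = \sum_j \alpha_j(t) G_j + U_0 + U(t) + \epsilon_X(t)\),
  with \(U_0 \sim N(0,1)\) and \(U\), \(\epsilon_X\) independent Wiener
  processes scaled to unit variance at \(t = 50\);
* genetic-effect curves: sinusoidal
  \(\alpha_j(t) = 0.05\sin(a_j t) + b_j\) (Scenario A,
  \(a_j, b_j \sim U(-0.1, 0.1)\)) or linear \(a_j + b_j t\) with slope range
  \(U(-0.004, 0.004)\) (B) or \(U(-0.01, 0.01)\) (C) — increasing
  time-variation and hence increasing conditional instrument strength;
* six effect-function shapes: null, constant 0.1, increasing \(0.02t\),
  sign-change \(0.5 - 0.02t\), early-age-only, later-age-only;
* outcome \(Y = \int_0^{50}\beta(t)X(t)dt + 10[U_0 + U(50)] + \epsilon_Y\)
  with strong confounding through \(U_0\) and \(U(50)\);
* ten observation times per subject drawn uniformly without replacement
  from the dense grid.

Choices the design leaves open, fixed here once: the dense simulation grid
is 501 points (0.1 spacing, matching measurement times rounded to a tenth
of a time unit); \(\epsilon_Y\) is an independent Wiener process evaluated
at the endpoint, i.e. \(N(0, 1)\); integrals use the trapezoid rule on the
dense grid (deterministic, and exact against closed forms on piecewise
linear integrands, which the tests exploit); the master seed expands into
independent sub-seeds per component (genotypes, coefficients, paths,
sampling, outcome noise) so components can be regenerated independently.

What the generator emulates well: sparse irregular sampling, strong
confounding shared between trajectory and outcome, time-varying genetic
associations of controlled strength (the variants explain roughly 4–5% of
single-timepoint exposure variance in Scenarios A/B). What it does not
emulate: measurement error distinct from the rough trajectory component
(the Wiener exposure noise is *part* of the path, and the PACE nugget
absorbs its short-range roughness), assortative or stratified genotype
structure, selection or survival processes, time-varying instruments,
binary outcomes, and per-individual observation windows. Passing the
simulation suite therefore demonstrates internal correctness and
calibration under this data-generating law, not robustness to these
additional real-data complications.

## Validation problem sizes

The test-suite checks run at sizes chosen to keep the whole suite in the
tens of minutes on one core while leaving Monte-Carlo error well below the
tolerances: conditional-F magnitudes use 30–60 replicates of the full
\(n = 10000\) design per scenario (per-replicate spread is ±2–4 F-units, so
the mean is stable to a few percent; the sinusoidal scenario, which runs
closest to its reference values, gets the larger count); pointwise band
coverage uses 200 replicates per scenario cell at \(n = 800\) with a
21-point-per-parameter lattice searched over ±8 standard errors — at that
reduced sample size the components are conditionally much weaker than at
full scale, and a ±4 window would truncate the genuinely wider robust
region; the LM size check uses 1000 direct linear-IV replicates at
\(n = 2000\). The acceptance script re-runs the full-scale quantities from
scratch with seeds derived from its `--seed` argument.

## Known limitations

* Eigenfunction estimation uncertainty is ignored downstream, as is usual
  in FPCA-based two-step pipelines; bands can be slightly anti-conservative
  where the basis approximation error is comparable to the band width (the
  interior timepoints of steep effect functions under the strongest
  instrument scenarios show exactly this).
* Only \(L \le K\) effect shapes are estimable, and in practice \(K\) is
  small (2 in the validation design at 95% FVE): complex effect functions
  — thresholds, non-monotone shapes — are out of reach without stronger,
  more time-differentiated instruments. Misspecified bases (the threshold
  scenarios 5–6 of the engine) yield interpretable but biased linear
  summaries.
* The two-sample and summary-statistic variants of the estimator, variable
  per-subject time windows, and binary outcomes are not implemented.
* The conditional-F degrees-of-freedom convention follows the operational
  recipe above; alternative conventions differ by factors of order
  \(J/(J-L+1)\), immaterial at \(J = 30\) but worth noting when comparing
  against other software at small \(J\).
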