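---
title: "Genotype-aware DBH modeling from LiDAR metrics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-aware DBH modeling from LiDAR metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lidardbh)
```

## The model and its assumptions

`lidardbh` predicts individual-tree diameter at breast height (DBH, cm)
from two LiDAR-derived canopy metrics — tree height `lh` (m) and crown
diameter `lcd` (m) — in plantations whose trees belong to known genotypes
(clones) planted at two densities. The working model is a single-level
nonlinear mixed-effects (NLME) model:

$$
\mathrm{DBH}_{ij} = a_1\,
\mathrm{LH}_{ij}^{\,b_1 + u_{1i} + (b_2 + u_{2i})P_{ij}}\,
\mathrm{LCD}_{ij}^{\,c_1} + \varepsilon_{ij},
\qquad
\mathbf{u}_i \sim N(\mathbf 0, \Psi),
\qquad
\varepsilon_{ij} \sim N\!\left(0,\ \sigma^2 \mathrm{LH}_{ij}^{2\gamma}\right).
$$

Its assumptions, in decreasing order of importance:

* **Power-law allometry.** Mean DBH scales as a product of powers of
  height and crown diameter. Among the four candidate base forms shipped
  (logistic, exponential, power, Richards — `model_form()`), the power
  form is the one extended with density and genotype structure, because
  it combines fit quality with a residual pattern amenable to a variance
  function and with cheap analytic gradients.
* **Density acts on the height exponent.** The 0/1 indicator `p1`
  (1 = high-density planting) shifts the `lh` exponent by `b2`. The two
  alternative placements (on the scale `a1`, on the `lcd` exponent) are
  available as `dummy_slot = "on_a"` / `"on_c"` for the model-selection
  stage. The indicator encodes planting density only; other treatment
  differences between plots are deliberately not modeled.
* **Genotype affects the height exponents.** Random effects enter
  additively on `b1` and `b2` in the default configuration; all
  $2^4 - 1 = 15$ coefficient subsets can be searched
  (`search_random_effects()`), ranked by AIC, then BIC, then subset size.
  $\Psi$ is unstructured.
* **Independent heteroscedastic residuals.** Within-genotype errors are
  independent (no autocorrelation term) with variance a power of `lh`;
  an exponential variance function and a constant one are the
  alternatives (`variance_spec()`). With $\gamma = 0$ both reduce to
  homoscedasticity, which makes the $\gamma$ likelihood-ratio test a
  clean heteroscedasticity check.

## Parameters that matter

| parameter | meaning | unit / scale | default |
|---|---|---|---|
| `a1` | allometric scale | cm at LH = LCD = 1 m | fitted; reference 0.8403 |
| `b1` | height exponent, low density | – | fitted; reference 1.1829 |
| `b2` | height-exponent shift at high density | – | fitted; reference −0.1427 |
| `c1` | crown-diameter exponent | – | fitted; reference 0.2726 |
| `Psi` | genotype covariance of (u1, u2) | exponent² | fitted; reference diag 7.763e−3, 5.401e−3, cov −4.857e−3 |
| `sigma` | residual scale | cm · m^(−γ) | fitted; reference 0.3482 |
| `gamma` | variance-function exponent | – | fitted; reference 0.8415 |

The reference values are the published estimates for the *Catalpa bungei*
clonal trial this package's defaults emulate; `dbh_reference_fit()`
returns them as a ready-to-use fitted object (its dispersion is
$\sigma^2 = 0.1212$ and its variance exponent $2\gamma = 1.683$).

Data-filtering defaults mirror the trial's protocol: trees are removed
when **both** the LiDAR height and the field height fall below 1.3 m (the
breast height at which DBH is defined), then genotypes with fewer than 30
surviving trees are dropped. The sentence-level ambiguity between an AND
and an OR reading of the height rule is real, so `filter_dataset()`
exposes `height_rule = "and"` (default) / `"or"`; the height filter runs
before the genotype-count filter so the count threshold applies to
surviving trees.

## Estimation

`fit_nlme()` maximizes the linearization-based marginal likelihood by the
alternating Lindstrom–Bates scheme:

1. **PNLS step.** Given the variance components, minimize
   $\sum_i \|(y_i - f_i)\|^2_{\Lambda_i^{-1}} + u_i^\top D^{-1} u_i$
   (with $\Psi = \sigma^2 D$) jointly in the fixed effects and all
   per-genotype $u_i$ by Gauss–Newton with step halving. The normal
   equations have arrowhead structure, so each $u_i$ block is eliminated
   by a small $q \times q$ Cholesky solve.
2. **LME step.** Re-linearize the mean function at the current estimates,
   form the working response $w_i = y_i - f_i + X_i\hat\beta + Z_i\hat
   u_i$, and maximize the working model's likelihood profiled over
   $\beta$ (GLS) and $\sigma^2$ with respect to the log-Cholesky factor
   of $D$ and $\gamma$ (box-constrained quasi-Newton; the log-Cholesky
   parameterization keeps $\Psi$ positive semi-definite by
   construction).

Alternation stops when the relative log-likelihood change drops below
1e−8 and the maximum parameter change below 1e−6 (cap 200 rounds); a
final PNLS pass makes the reported per-genotype effects the posterior
modes at the converged variance components. Estimation is maximum
likelihood (not REML) throughout, so likelihood-ratio tests on fixed
effects are valid, and the reported `k` counts mean coefficients +
residual scale + $q(q+1)/2$ covariance components + one per
variance-function parameter; BIC uses the number of tree records, not
the number of genotypes.

Numerical choices worth knowing: power-family starting values come from
ordinary least squares on the log scale (with `lcd` clipped to 0.05 m,
the smallest crown the generator emits, to avoid `log(0)`); the
fixed-effects fitter is Levenberg–Marquardt with up to five seeded
jittered restarts; a variance floor of 1e−12 guards the exact-fit
degenerate case; `0^0` is taken as 1 and a zero crown diameter with a
positive exponent predicts 0 cm. Two implementations of the same
approximate likelihood can stop at slightly different fixed points of the
alternation; the test suite checks ours against the independent `nlme`
implementation on a common dataset at tolerances that reflect this
(log-likelihoods to about a unit, conditional fitted surfaces to a few
hundredths of a cm, variance exponents to 0.05).

## EBLUP calibration

For a genotype with a few measured trees, `eblup()` predicts its random
effects by iterating

$$
\hat{\mathbf u}_i \leftarrow \hat\Psi Z_i^\top
\left(\hat R_i + Z_i \hat\Psi Z_i^\top\right)^{-1}
\left[\,y_i - f(\hat\beta, \mathbf u_i^*, x_i) + Z_i \mathbf u_i^*\right]
$$

from $\mathbf u^* = \mathbf 0$, where $Z_i$ is the Jacobian of the mean
function in the random effects (analytic for the power family:
$\partial f/\partial u_1 = f\ln \mathrm{LH}$,
$\partial f/\partial u_2 = f \ln \mathrm{LH}\, P$) and $\hat R_i$ is
diagonal from the fitted variance function at the calibration trees' own
covariates. Iteration runs to a 1e−6 max-norm tolerance (cap 50) rather
than a fixed number of passes; a `fixed_pass` option provides the
fixed-pass behaviour where that is wanted. The linear solve uses a
symmetric factorization, never an explicit inverse. Genotypes with no
calibration data — including genotypes never seen in training, the
intended use case — are predicted at the population level
($\mathbf u = \mathbf 0$). The tests verify the iterate against a
brute-force optimizer of the equivalent joint penalized least-squares
objective, and that predicted effects shrink monotonically as the
residual variance grows.

## Sampling strategies and evaluation

`select_calibration_trees()` implements four per-genotype schemes: the k
smallest or largest trees by DBH (ties broken by record order), k random
trees among those strictly between the genotype's 20th and 80th DBH
percentiles (linear-interpolation percentiles; "between" read as strict
interior), and k random trees regardless of size.
`evaluate_strategies()` sweeps kind × k, calibrates, and pools fit
statistics. Two scopes are offered because either could be meant by a
calibration curve: the default evaluates only non-calibration trees
(no leakage — the tests assert disjointness), `scope = "all"` evaluates
every tree. Stochastic schemes are averaged over 10 seeded repeats by
default.

`loocv_by_genotype()` holds each genotype out in turn, refits on the
rest, calibrates on `calibration_k = 2` random held-out trees, and
predicts the remainder. Refitting per fold is the default (it matches
the definition of the validation); `refit = FALSE` is a fast mode that
keeps the global variance components and re-runs only the penalized
least-squares pass per fold — appropriate for large simulation sweeps,
and what the structural tests use to stay quick. Per-fold calibration
seeds are `seed + fold` for reproducibility.

## The synthetic stand generator

`simulate_stand()` emulates the trial's data structure so the pipeline is
testable without any external data: 78 genotypes × 37 trees (2,886 trees,
within 0.5% of the trial's 2,899), one third of genotypes at high
density (density constant within genotype, as field plots are), and DBH
generated from the reference model above.

* **Height marginal.** `lh` is truncated normal on [1.3, 10.6] m. The
  parent normal's parameters are moment-matched so the *truncated*
  distribution has mean 3.97 m and SD 1.78 m — the trial's reported
  moments; a naive parameterization would be biased upward by the 1.3 m
  truncation.
* **Crown link.** `lcd = 0.7 + 0.3·lh + N(0, 0.45²)`, clipped to
  [0.05, 6.0] m. These are calibration constants chosen once to land
  near the trial's crown-diameter moments, not published values.
* **Field variables.** Optional `h` and `cd` are emitted through linear
  links whose noise is derived from the realized covariate spread so the
  `lh`–`h` and `lcd`–`cd` agreements land near R² 0.92 and 0.76, the
  level typical of field-vs-LiDAR comparisons; they exist so the
  filtering and summary stages are exercisable.
* **Positivity.** Trees with DBH ≤ 0.1 cm are redrawn (rejection, cap
  100 attempts) rather than clipped, so no point mass distorts the
  variance-function estimate.

What the generator does **not** emulate: the trial pooled three
measurement campaigns, so real tables may contain repeated measures of
the same trees with correlated errors — the generator emits a single
cross-section; there is no spatial arrangement or competition; covariate
measurement error in `lh`/`lcd` is absorbed into the residual. Passing
tests therefore demonstrate correctness of the statistical machinery
under the stated generating process, not robustness to those real-data
features.

## Problem sizes and runtime posture

The test suite runs the full estimator at 20 genotypes × 15 trees (about
six seconds a fit) and the acceptance workflow at the study scale of
78 × 37 (ten to thirty seconds a fit); the EBLUP and strategy machinery
is effectively instant at any of these sizes. Cross-validation tests use
the fast mode; full-refit cross-validation at study scale is supported
but is a multi-minute computation, so it is left to explicit user calls.

## Known limitations

* The marginal likelihood is the Lindstrom–Bates linearization, not an
  exact (quadrature) likelihood; with small groups and large random
  effects the approximation error is the usual price of this class of
  estimator.
* Random-effect variances are intrinsically hard to pin down with ~78
  groups: expect meaningful Monte-Carlo spread in $\Psi$ even when fixed
  effects and $\gamma$ recover tightly. The smallness of `b2` also means
  a few-percent relative band on it corresponds to roughly one standard
  error at the trial's design size.
* Single grouping level only (genotype); crossed or nested
  (genotype-within-plot) effects are out of scope, as are prediction
  intervals for the calibrated predictions.
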