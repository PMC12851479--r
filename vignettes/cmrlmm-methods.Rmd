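---
title: "Methods: joint mixed modelling of time-use compositions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint mixed modelling of time-use compositions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrlmm)
```

## The problem and the model

A day's time use — say sleep, sedentary behaviour (SB), light physical
activity (LPA) and moderate-to-vigorous physical activity (MVPA) — is a
composition: D strictly positive parts carrying only relative information,
closed to a constant $\kappa$ (1440 min/day). Ordinary multivariate
regression on the raw minutes is degenerate (the parts are perfectly
collinear), and modelling each behaviour or each log-ratio separately
ignores how behaviours trade off against each other within the day.

`cmrlmm` expresses the composition in $D-1$ orthonormal log-ratio (olr,
also called ilr) coordinates $\mathbf z = V^\top \ln \mathbf x$ and fits all
coordinates *jointly* in one linear mixed model. For subject $i$ at
occasion $j$, coordinate $r$:

$$z_{rij} = \beta_{0r} + (\text{time and covariate terms})_r + b_{0ri} + \varepsilon_{rij},$$
$$\mathbf b_{0i} \sim \mathrm{MVN}(\mathbf 0,\, G), \qquad
  \boldsymbol\varepsilon_{ij} \sim \mathrm{MVN}(\mathbf 0,\, E),$$

with $G$ and $E$ unstructured $(D-1)\times(D-1)$ covariance matrices: $G$
captures how subjects' long-run coordinate levels co-vary (e.g. whether
children who sleep relatively more also accumulate relatively more SB in
their waking day), $E$ the occasion-to-occasion co-fluctuation. Every
fixed-effect term is interacted with the coordinate index and there is no
pooled intercept, so the fixed-effect vector is a full
$(D-1) \times q$ block. Operationally the $D-1$ responses are "stacked"
into one response column with indicator dummies (`stack_olr()`), which is
how the same model can also be expressed in a univariate mixed-model
fitter; the package's own estimator works directly on the per-subject
multivariate normal likelihood.

The payoff of the unstructured $G$ and $E$ is *basis invariance*: after
back-transforming with $\mathrm{olr}^{-1}$, coefficients, fitted
compositions and joint tests do not depend on which olr basis was used.
Constraining $G$ and $E$ to diagonal reproduces the "multiple univariate
models" practice, whose back-transformed results do depend on the basis —
`compare_approaches()` demonstrates both facts on any dataset.

## Coordinate systems

Bases are built from a sequential binary partition (`sbp_basis()`): a
$(D-1)\times D$ sign matrix whose first row splits all parts into a $+$ and
a $-$ group and whose later rows split exactly one previously created group,
until all groups are singletons. Column $j$ of the contrast matrix carries
$+\sqrt{n_j/(p_j(p_j+n_j))}$ on the $p_j$ numerator parts and
$-\sqrt{p_j/(n_j(p_j+n_j))}$ on the $n_j$ denominator parts (the sign
convention is fixed: $+1$ parts form the numerator). Pivot coordinates
(`pivot_basis()`) are the special case contrasting part $j$ against the
geometric mean of the later parts; the first pivot coordinate is
$\sqrt{D/(D-1)}$ times the first clr coordinate. Bases reference parts by
label, never by column position, so a permuted data file cannot silently
permute coordinates. The additive log-ratio (alr) is deliberately not
provided (it is not isometric), and parts equal to zero are a hard error
with a pointer to the zero-replacement literature — no imputation happens
anywhere in the package.

Compositions are stored internally closed to 1; the closure constant
$\kappa$ is metadata applied on output, which makes every simplex operation
scale invariant by construction.

## Estimation

Per subject $i$ with $J_i$ observed occasions, the stacked response
$\mathbf y_i$ (length $J_i(D-1)$) has covariance
$V_i = \mathbf 1\mathbf 1^\top \otimes G + I \otimes E$, which depends on
the subject only through $J_i$. The restricted (REML, default) or full (ML)
likelihood is maximised over a log-Cholesky parameterisation of $G$ and $E$
(log diagonal, free off-diagonal of the Cholesky factor — positive
definiteness is guaranteed throughout), with $\boldsymbol\beta$ profiled
out by generalised least squares at each step. Subjects are grouped by
$J_i$ so each likelihood evaluation takes one Cholesky factorisation per
missingness pattern and whitens all subjects of a pattern in a single
triangular solve; a full 241-subject, 5-occasion, 4-part fit takes a
couple of seconds on one core.

Numerical choices, in order of application:

* **Starting values**: method-of-moments. Per-coordinate OLS residuals give
  $E^{(0)}$ from the within-subject covariance and $G^{(0)}$ from the
  covariance of subject-mean residuals minus the attenuation term
  $\bar{J^{-1}}E^{(0)}$; both are pushed to the nearest comfortably
  positive-definite matrix before use.
* **Optimiser**: BFGS on the profiled criterion with an accurate
  central-difference gradient, relative criterion tolerance $10^{-10}$.
  Convergence requires the gradient infinity norm below
  $10^{-6}\,(1+|\text{criterion}|)$ — the tolerance is relative because an
  absolute $10^{-6}$ sits below finite-difference noise at criterion
  magnitudes in the hundreds. Up to 3 deterministic jittered restarts.
* **Newton polish** (default on): a few damped Newton steps with a
  finite-difference Hessian sharpen the optimum so that the same model
  fitted in two rotated coordinate systems back-transforms to identical
  compositions to well below $10^{-6}$ min. It can be disabled
  (`cmrlmm_control(polish = FALSE)`) in large simulation loops where the
  last digits of the optimum are irrelevant.
* **Boundary fits**: when a variance component or an eigenvalue of $G$ or
  $E$ collapses toward zero, the interior first-order condition cannot be
  met; the fit is accepted when the relative-change criterion holds, and is
  flagged (`$boundary`) and warned about — never silently truncated.
* **Degenerate inputs**: rank-deficient designs fail naming the aliased
  columns; duplicated (subject, occasion) pairs, zeros and row sums off by
  more than the closure tolerance (default 5% relative) are errors;
  row sums within tolerance are re-closed with a warning. A subject-occasion
  is all-or-nothing across the $D-1$ coordinates because they derive from
  one composition; subjects simply contribute the occasions they have
  (no imputation).

REML is the default and is the right criterion for comparing covariance
structures with identical fixed effects; `lrt()` refuses REML comparisons
across different fixed effects and asks for ML instead. The dense-matrix
oracle `loglik_oracle()` / `gls_oracle()` re-evaluates the criterion and the
GLS solution through a deliberately naive separate code path and is used in
the tests to certify the optimised implementation to $10^{-6}$.

## Inference

`joint_test()` forms the Wald statistic
$F = (L\hat\beta)^\top(L \hat V L^\top)^{-1}(L\hat\beta)/\mathrm{rank}(L)$
for the block of all coordinates of one design term; for such full-term
blocks the statistic is basis invariant. The denominator df uses the
between–within ("inner–outer") counting rule: every term in the stacked
layout varies within subjects, so
$\mathrm{den\,df} = n_{\text{stacked}} - n_{\text{subjects}} - p$. This is
a counting approximation — not Satterthwaite or Kenward–Roger, which are
out of scope — and is documented as such; a $\chi^2$ form is available by
flag, and the two converge as den df grows. Per-coefficient t tests are
provided (`coef_tests()`), with the explicit note that reading many
per-coordinate tests inflates type-I error and the joint tests are
preferred; no multiplicity adjustment is applied across terms.

## Back-transformation and uncertainty

`compositional_coef()` maps the intercept block to a baseline composition
closed to $\kappa$ and every other block to a perturbation vector closed
to 1; both closure conventions are printed in the output header because
misreading one for the other is the easiest mistake to make. Perturbation
parts above $1/D$ reallocate time toward that behaviour
(`perturbation_vs_neutral()` labels the directions). Predictions
(`predict()`, `predict_composition()`) close to $\kappa$ exactly, with or
without subject BLUPs. "Average participant" predictions
(`reference_grid()`) put numeric covariates at their sample mean and
factors at their reference level — the phrase is ambiguous, so the
convention is stated in the grid object itself and is overridable.
Differences between predicted compositions are reported as the clr
difference $\mathrm{clr}(a) - \mathrm{clr}(b)$ (`logratio_difference()`);
this reading of a "log-ratio difference between groups" is an
implementation choice, documented here, since more than one definition
circulates.

`cases_bootstrap()` resamples whole subjects with replacement (fresh
identifiers, so duplicates are distinct grouping units), refits, and takes
type-7 percentile intervals at the requested level from the converged
replicates (default B = 1000, level 0.95). Non-converged replicates are
dropped and counted; more than 5% failures flags the interval unreliable.
Intervals are computed per part from closed replicate compositions; they
are marginal, not joint, and the vector of endpoints need not itself be a
composition. The master seed spawns one sub-seed per replicate, so results
are a pure function of (data, specification, quantity, B, seed).

## The synthetic-data generator

`simulate_cmrlmm()` draws data with exactly the generative structure the
model assumes: $b_i \sim \mathrm{MVN}(0, G)$ per subject,
$\varepsilon_{ij} \sim \mathrm{MVN}(0, E)$ per occasion, coordinates
$X\beta + b_i + \varepsilon_{ij}$, behaviours $\mathrm{olr}^{-1}$ closed to
$\kappa$. Its defaults emulate a longitudinal cohort of 241 primary-school
children measured at five timepoints (two school years with an intervening
summer-holiday timepoint): a 4-part sleep/SB/LPA/MVPA composition in the
balance basis of `loh_basis()`, fixed effects anchored at that study's
reported coordinate estimates (e.g. holiday-timepoint contrasts
0.09/0.22/0.21), between-subject standard deviations 0.11/0.29/0.22 with
correlations 0.75/0.64/0.49, and residual standard deviations
0.12/0.24/0.26 with correlations 0.68/0.64/0.64. Covariate distributions
are invented but fixed: standard-normal zBMI and a 3-level income category
with probabilities 0.5/0.3/0.2 (the source study does not report covariate
distributions). Missingness is missing-completely-at-random per occasion
with the first occasion always retained.

What the generator does *not* emulate: accelerometer measurement error and
minute-classification error, rounded or zero minutes, informative dropout,
school-level clustering, serial (AR) correlation across occasions, and
non-normal coordinate distributions. Passing tests therefore certify the
estimator and its inferential calibration *under the model's own
assumptions*, not robustness to these real-data features.

## Validation studies shipped in the test suite

The package chooses these problem sizes for its simulation-based checks:

* parameter recovery: 100 replicates at 241 subjects x 5 occasions with the
  generator's reference parameters; fixed effects are required to land
  within 3 Monte-Carlo standard errors, covariance entries within 10% mean
  relative bias, and pooled 95% Wald coverage within [0.90, 0.99];
* test calibration: 500 replicates each at 40 subjects x 5 occasions for
  the joint time test under null time effects (acceptance band 3–7%
  rejection at $\alpha = 0.05$) and for the df-6 covariance LRT under truly
  diagonal $G$ and $E$ (band 2–8%; the diagonal constraint fixes
  correlations at zero, an interior point, so the plain $\chi^2_6$
  reference applies);
* oracle equivalence on a 6-subject x 3-occasion fixture, and an
  independent cross-fit of the identical stacked model in `nlme::lme`
  (`pdSymm` random intercepts, `varIdent` + `corSymm` residuals), which
  agrees with this package's estimator to $10^{-6}$ in log-likelihood.

## Known limitations

One grouping level (subject) and random intercepts only — no random slopes,
no third level, no serial residual correlation, no heterogeneous $E$ across
occasions; these are extension points, not supported options. Denominator
df are a counting approximation. AIC/BIC use the stacked observation count
as $n$ for BIC — a stated convention, since no single convention exists for
stacked multivariate layouts. Zeros in the composition must be handled
before the package sees the data.
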