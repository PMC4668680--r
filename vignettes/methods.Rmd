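---
title: "Models and methods behind mchbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mchbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mchbench` estimates subnational levels and trends of maternal and child
health (MCH) indicators from the kind of evidence that actually exists in
most low-resource settings: a handful of household surveys of different
families (DHS-style surveys, malaria indicator surveys, national household
surveys, censuses), each observing a few years, each with its own sampling
design and its own systematic quirks. The statistical task is to turn those
sparse, noisy, mutually inconsistent region-year-source estimates into
complete annual series with honest uncertainty, for every region, over a
two-decade grid — and then to benchmark regions against each other with a
composite coverage index and its relation to under-5 mortality.

This vignette documents the models, every tunable that matters, the
numerical choices, and the limits of what the tests demonstrate.

## 1. From microdata to observation points

**Design-weighted coverage.** Survey coverage estimates are weighted ratio
means with Taylor-linearized (cluster-robust) standard errors treating
clusters as primary sampling units: with cluster residual totals
$z_c = \sum_{k \in c} w_k (y_k - \hat p)$ over $m$ clusters and total
weight $W$,
$$\widehat{\mathrm{var}}(\hat p) = \frac{m}{m-1} \frac{\sum_c z_c^2}{W^2}.$$
This is the standard first-order approximation for multistage designs when
later stages are absorbed into the PSU totals; deeper stratification is out
of scope. Indicator definitions carry an age window in months that is
applied *before* estimation — e.g. immunization indicators exclude children
under 12 months because of dosing schedules, and indicators asked only
about the most recent birth (antenatal care, skilled attendance) restrict
to 0–12 months to avoid parity bias.

**Transforms.** Proportions are modeled on the logit scale and
positive-valued indicators (e.g. years of maternal education) on the log
scale, with delta-method variances
$\mathrm{var}(\mathrm{logit}\,p) = \mathrm{var}(p)/(p(1-p))^2$ and
$\mathrm{var}(\log x) = \mathrm{var}(x)/x^2$. Before the logit, estimates
are clamped to $[1/(4n_\mathrm{eff}),\ 1 - 1/(4n_\mathrm{eff})]$ (fallback
$[0.001, 0.999]$ when the effective sample size is unknown): boundary
estimates are legitimate data ("all sampled children vaccinated") but have
degenerate transformed variance, and the clamp is the variance-stable way
to keep them. Sources that publish only a point estimate get their
transformed variance imputed as the 90th percentile of same-indicator
variances — deliberately conservative, so low-provenance points can inform
but never dominate.

**Direct under-5 mortality.** From complete birth histories, 5q0 for a
calendar period is estimated by a synthetic-cohort life table over age
segments $\{0, 1\text{–}5, 6\text{–}11, 12\text{–}23, 24\text{–}35,
36\text{–}47, 48\text{–}59\}$ months (the convention of the
synthetic-cohort method family; configurable). Each segment's death
probability is weighted deaths over the weighted risk set of children who
entered the segment during the period while under observation, and
$\,_5q_0 = 1 - \prod_a (1 - q_a)$. We use risk-set counts (discrete
exposure) rather than a continuous-hazard conversion because the discrete
form makes the boundary cases exact: if every entrant dies, $q_a = 1$
exactly. Children censored mid-segment contribute to neither numerator nor
denominator of that segment (independent censoring). The standard error is
a leave-one-mother-out jackknife, which respects the within-mother
correlation of sibling outcomes; the estimator itself is invariant to
mother ordering.

## 2. The two-stage coverage smoother

**Stage 1 — spline mixed model.** On the transformed scale, for indicator
value $y_{it}$ in region $i$, year $t$:
$$g(y_{it}) = \beta_0 + \beta_1 h_1(t) + \beta_2 h_2(t)
 + \gamma_{0i} + \gamma_{1i} h_1(t) + \gamma_{2i} h_2(t) + \varepsilon_{it},$$
where $h_1, h_2$ are the two basis functions of a natural cubic spline
with one interior knot and the $\gamma$s are correlated region random
effects (intercept and spline slopes), so levels *and* trend shapes vary by
region. The knot sits at the midpoint of the year range (2000.5 for
1990–2011) with boundary knots at the endpoints; the natural (linear-tail)
constraint is what makes extrapolation beyond the data merely linear
rather than cubic. Estimation is REML via `lme4`, falling back to ML and
then to a fixed-effects-only least-squares fit if the mixed model cannot
converge (always the case with a single region, where region effects are
unidentifiable). Singular (zero) random-effect variance estimates are
allowed and flagged, not treated as failure. Predictions for a region
include its best linear unbiased predictions — the random effects are
exactly what makes the prior region-specific, so they belong in it.

**Stage 2 — Gaussian process regression.** The stage-1 region prediction
is the mean function of a GP prior with Matern covariance
(smoothness $\nu \in \{1/2, 3/2, 5/2\}$, default $3/2$; length-scale in
years, default 10). The posterior is exact Gaussian conditioning on that
region's transformed observations, each with total variance = its sampling
variance + a non-sampling variance floor. Multiple observations in one
region-year are kept as separate heteroskedastic conditioning points — the
GP handles replicates natively, and pre-averaging would discard the
between-source information. Estimates and 95% intervals are the median and
2.5th/97.5th percentiles of 1,000 posterior draws back-transformed to the
natural scale, which automatically respects the indicator's domain.

**Hyperparameter defaults.** The two-stage smoother needs an
amplitude and a non-sampling floor; neither is identifiable enough at six
observations per region to estimate by marginal likelihood (a deliberate
non-goal), so both derive from a moment heuristic: let $\hat\sigma^2_1$ be
the stage-1 residual variance and $\bar v$ the mean sampling variance of
the indicator's observations. The *excess* $e = \max(\hat\sigma^2_1 - \bar
v, 10^{-6})$ estimates how much the truth departs from the spline curve
beyond sampling noise; we set amplitude $= 1.5\sqrt{e}$ and floor $= e$.
Using the raw residual variance instead would count sampling noise twice
(it is already in the per-observation variances) and systematically
over-widens the intervals — in recovery experiments realized 95% coverage
sits at 99–100% with the raw rule and 97–99% with the excess rule, at
identical RMSE. Both values are overridable in `gpr_config()`.

A known blind spot of any residual-moment heuristic: truth deviations that
are smooth on the survey-year spacing get absorbed into the per-region
spline coefficients and never reach the residuals, so the heuristic cannot
see them. The calibration test therefore distinguishes two questions: with
*known* hyperparameters the GPR machinery is provably calibrated (checked
by simulation from the assumed model), while the *heuristic* is validated
against logistic scale-up truths, the regime the pipeline is built for.

**National series.** The same machinery runs on nation-pooled
observations, with the population-level (fixed-effects) stage-1 curve as
prior and all regions' observations as conditioning points.

## 3. The hierarchical spatiotemporal mortality model

Logit under-5 mortality observed by source $s$ in region $i$, year $t$:
$$\mathrm{logit}(\,_5q_{0,its}) \sim N(\theta_{its}, \sigma^2), \qquad
\theta_{its} = \beta_0 + \beta_1 t + \beta_2 I_{s \notin \mathrm{DHS}}
 + u_i + v_i t + w_t + \delta_{it} + \gamma_{is},$$
with intrinsic CAR priors on the region intercepts $u$ and slopes $v$
(precision $\tau Q$, $Q$ the graph Laplacian), an RW1 prior on the year
effect $w$, the Kronecker RW1 $\otimes$ ICAR prior on the space-time
interaction $\delta$, iid normal region-source effects $\gamma$, and a
fixed additive adjustment $\beta_2$ for non-DHS sources. The year
covariate is centered at the grid midpoint (decorrelates intercept and
slope; predictions unchanged). Priors are weakly informative: $N(0,
31.6^2)$ on fixed effects and $\mathrm{Gamma}(1, 0.01)$ on every precision
including the observation precision $1/\sigma^2$.

**Inference.** Blocked Gibbs sampling. Every Gaussian family has a
closed-form Gaussian full conditional given the precisions, and every
precision a conjugate gamma update whose degrees of freedom equal the rank
of its structure matrix. Three implementation choices matter:

* *Exact constraints.* Intrinsic priors are improper; each family is
  sampled directly in the orthogonal complement of its prior null space
  (via a precomputed orthonormal basis), so $\sum_i u_i = \sum_i v_i =
  \sum_t w_t = 0$ and all row/column sums of $\delta$ are zero exactly at
  every iteration — and the full conditionals remain proper even when most
  grid years are unobserved, where naive sampling plus post-hoc centering
  would face a singular precision.
* *Identifiability of the trend.* The linear component of a random walk is
  almost unpenalized, so $w$ would absorb the global slope and leave
  $\beta_1$ unidentified. $w$ is therefore additionally constrained
  orthogonal to linear time — the convention that the fixed effects own
  the global level and slope, and the year effect owns the non-linear
  deviations. The simulator applies the same convention, so calibration
  experiments compare like with like.
* *Joint fixed-effect/source-effect block.* $\beta_2$ and the mean of the
  non-DHS $\gamma$s compete for the same level; a one-scalar-at-a-time
  scan mixes through that ridge very slowly. Updating $(\beta, \gamma)$ as
  a single Gaussian block removes the coupling.

Predictions for region-year $(i,t)$ use the DHS-consistent predictor —
$\beta_2$ and $\gamma$ set to zero — so estimates track the reference
source family rather than the average of shifted sources; quantiles of the
$\theta$ samples are taken first and inverse-logit transformed after
(valid by monotonicity). Convergence is summarized by split-$\hat R$ on
the fixed effects, $\sigma^2$ and log precisions, warning above 1.1.

Gamma priors are placed on the precisions themselves — the standard
conjugate construction for Gaussian hierarchical models (a gamma
distribution on a *log* precision would confine precisions above 1 and
lose conjugacy). Source effects are indexed region-by-source, matching
their role of absorbing within-source, within-region autocorrelation.
Per-observation sampling variances from the birth-history estimation are
not part of this model (a single shared $\sigma^2$ is); an extension flag
could weight observations, but is not needed for the analyses here.

## 4. Overall coverage index and benchmarking

The overall intervention coverage index is the unweighted mean of 11
components spanning the intervention spectrum — ITN-or-IRS household
coverage, IPTp2, ACT receipt, exclusive breastfeeding, BCG, measles, OPV3,
pentavalent, ANC4, skilled birth attendance, and child nutrition entering
as 1 − underweight prevalence. Equal weights are a transparency choice,
not an effectiveness claim. Draw-level propagation: index draw $d$ is the
mean of the components' draw $d$, preserving within-year correlation;
region-years missing any component are dropped, never imputed. Pearson
correlations between series (overall coverage vs mortality, vs
socioeconomic series) pool all region-years by default, matching the
single-coefficient summary convention; by-year and by-region variants are
available.

## 5. The synthetic world

Every stage is testable without restricted microdata because the package
generates its own study:

* **Region graphs** — ring, line, grid or custom edge lists; a documented
  10-region default with a capital region and neighbouring blocks. The
  real region adjacency is an input everywhere, never hard-coded into the
  math.
* **Truth surfaces** — four-parameter logistic scale-up trends per region
  (floor, ceiling, midpoint year, steepness), the canonical shape of
  intervention roll-out; underweight declines; education grows on the log
  scale.
* **Survey observations** — normal on the transformed scale around
  truth + shift·(1 − is_DHS), with variance $1/(n_\mathrm{eff}\,p(1-p))$.
  The default non-DHS shift is 0.15 on the logit scale (a few percentage
  points at mid-range coverage), a realistic magnitude for between-family
  discrepancies; the default schedule has DHS-style rounds at
  1995/2000/2006/2011 and a non-DHS family interleaved (1992, 2005, 2009),
  mirroring a real multi-source record of 2–8 survey-years per indicator.
* **Microdata** — clusters within regions with Beta-distributed cluster
  prevalences (mean = truth, so weighted means converge to truth while the
  design effect exceeds one), lognormal weights, uniform ages.
* **Birth histories** — piecewise-constant age-specific hazards solved so
  the implied cohort 5q0 equals the truth for each birth year; births
  uniform over the grid; censoring at a simulated survey date.
* **Mortality observations** — the generative twin of the hierarchical
  model, with latent effects returned for recovery testing. Defaults
  emulate a high-burden decline: 5q0 around 0.20 in 1990 falling by about
  half, a +0.3 logit non-DHS shift, observation noise sd 0.05.

Deterministic seeding: every operation derives its own stream from a
master seed and an operation tag (`child_seed()`), so adding, removing or
reordering simulations never changes any other simulation, and end-to-end
runs are byte-identical.

What the synthetic world does *not* emulate: non-sampling biases that are
not a constant transformed-scale shift (recall error, sample-frame
exclusions drifting over time), indirect mortality from summary birth
histories, real redistricting, or spatially correlated survey error.
Passing recovery tests therefore demonstrates the estimators do what they
claim under the stated statistical structure — not that real surveys obey
that structure.

## 6. Numerical choices and problem sizes

* GPR conditioning uses a Cholesky factorization of $(K_{dd} + D)$; if it
  fails, one jitter of $10^{-8}$ is added, then failure is an error.
  Posterior covariances are symmetrized and draws use an
  eigenvalue-truncated factor when the covariance is singular (degenerate
  posteriors then collapse cleanly to their mean).
* Pipelines sort observations internally, so input row order never
  affects output; ranks in the league table use `ties.method = "min"`.
* Test problem sizes: recovery experiments use 10 regions × 22 years with
  six survey-years per region; mortality calibration uses 20 replicate
  datasets of 10 regions × 22 years × 3 sources fit with 2 chains × 5,000
  iterations (half burn-in); oracle equivalences use 50 randomized
  instances. These sizes make the full suite run in minutes on one CPU
  while keeping every check at the study's actual grid dimensions.
* The demonstration `run_all()` uses 2 chains × 2,000 iterations for the
  mortality stage — enough for stable medians in a demo; analyses meant
  for interpretation should use the calibration-scale settings.

## 7. Known limitations

* Stage-1 uncertainty is not propagated into the GP prior mean; the
  amplitude heuristic compensates on average but is not a substitute for
  a joint model. Far outside the data (notably pre-first-survey years),
  intervals reflect the amplitude, and the point estimate inherits the
  spline's linear-tail extrapolation — which systematically undershoots a
  flattening trend (and overshoots a saturating one). Early-grid estimates
  from records that start late should be read accordingly.
* The non-DHS adjustment in the mortality model assumes one shared shift
  across all non-DHS families; the coverage smoother has no shift
  adjustment at all, so a shifted source biases coverage series toward its
  level in the years it anchors alone.
* ICAR/RW1 priors are improper and their scaling interacts with graph
  density; precisions are comparable across analyses only on the same
  graph.
* The jackknife SE for direct 5q0 treats mothers as independent;
  cluster-level dependence beyond mothers is not captured unless clusters
  are supplied as mothers.
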