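---
title: "Methods: long-term registry survival trend analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-term registry survival trend analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cancer registries publish *relative (net) survival*: the ratio of the
observed survival of patients to the expected survival of a matched
general population, which isolates mortality attributable to the cancer
from background mortality. National series of 1- and 5-year relative
survival, reported per 5-year calendar period over several decades, are
the raw material for asking *when* survival improved, whether the pace of
improvement itself changed, and how countries differ. `survtrend`
implements that full chain for registry-style data: estimating
age-standardized net survival per period from individual records,
smoothing the period estimates over continuous calendar time with a
Bayesian measurement-error model, and extracting interpretable trend
features -- conditional 5/1-year survival, annual change, plausible-trend
intervals and breakpoints. A synthetic-registry generator with known
ground truth makes every stage testable without access to microdata.

## Net survival estimation

**Estimator.** We use the Pohar Perme estimator: each subject's at-risk
and event contributions are weighted by the inverse of their expected
survival $w_i(t) = 1/S_{P,i}(t)$, where $S_{P,i}$ comes from a population
life table matched on country, sex, age and calendar year. The cumulative
excess hazard is

$$\hat\Lambda_E(t) = \int_0^t
  \frac{\sum_i w_i(u)\, dN_i(u) - \sum_i w_i(u) Y_i(u)\lambda_{P,i}(u)\,du}
       {\sum_i w_i(u) Y_i(u)},
\qquad \hat S_E(t) = e^{-\hat\Lambda_E(t)},$$

which may exceed 1 (net survival is not bounded above by 1 in finite
samples). The variance is the Poisson-type sum
$\sum w_i^2\,dN_i / (\sum w_j Y_j)^2$; confidence intervals are formed on
the log cumulative-excess-hazard scale when $\hat\Lambda_E>0$ (keeping
bounds plausible) and linearly on the survival scale otherwise.

**Numerical conventions.** Two conventions pin the estimator down
exactly, and the test-suite oracle implements the identical definition
through an independent brute-force code path:

* population hazards are piecewise constant over whole *follow-up* years:
  during follow-up year $k$, attained age is $\lfloor a_0\rfloor + k$ and
  calendar year $\lfloor d_0\rfloor + k$, so age and calendar time
  advance together at diagnosis anniversaries;
* the weights $1/S_{P,i}(t)$ are frozen within each follow-up year at
  their mid-year value $\exp(H_i(k) + \tfrac12\lambda_{i,k})$. The
  deviation from continuously-updated weights is second order in the
  annual population hazard (population hazards are at most a few percent
  per year below age 90), and the freeze makes the estimator an
  $O(n\log n)$ pass over sorted event times.

Ties are resolved events-before-censorings. Delayed entry (left
truncation) is supported for the hybrid design.

**Designs.** Cohort estimates include patients diagnosed within the
5-year window with full follow-up; they are exact when the window's
potential follow-up is complete. The hybrid design for the final window
combines cohort information from diagnosis years whose potential 5-year
follow-up is complete with period-style contributions (delayed entry at
the window start, administrative censoring at the study end) from more
recent diagnosis years, reaching back `horizon` years before the window
so late follow-up times remain informed. The upstream description of the
hybrid method is cited without algorithmic detail in the source material
for this package; the construction above is the established one, and the
degenerate case -- every eligible diagnosis year fully followed --
reduces exactly to the cohort design.

**Age standardization** averages band-specific curves with external
weights ($\sum w_a S_a$, variance $\sum w_a^2 \mathrm{Var}(S_a)$). The
default 5-band survival standard (0--44 / 45--54 / 55--64 / 65--74 /
75--89 with weights 0.07/0.12/0.23/0.29/0.29) and the Segi/Doll world
standard population for incidence rates ship as replaceable CSV assets:
the exact tables used by any given registry website are a data choice,
not program logic. Empty bands are dropped with a warning and the
remaining weights renormalized -- silent NaN propagation in small
synthetic cohorts would be worse.

## Descriptive rates

Age-standardized rates are $\sum_a w_a (c_a/y_a) \times 10^5$ per
100,000 person-years; the 0--74 cumulative risk is
$100(1-\exp(-\sum_a \Delta_a r_a))$ over complete bands below age 75.
Rate series are smoothed for display only with `stats::smooth.spline`
(`spar = 0.4`, 15 knots); the smoother never feeds inference, and no
numeric equivalence with any other smoothing implementation is promised.

## The trend model

Period-wise survival estimates $y_{gj}$ (percent, group $g$, period
midyear $t_j$ = period start + 2) carry known standard errors $s_{gj}$
derived from published confidence intervals,
$s = (\mathrm{hi}-\mathrm{lo})/(2\times 1.959964)$. The observation model
is Gaussian with identity link and *fixed* observation SD $s_{gj}$ -- a
measurement-error (meta-regression) model with no extra dispersion term,
matching the source procedure in which the reported SEs were supplied to
the smoother directly.

$$y_{gj} = \beta_0 + u_g + f_g(t_j) + \varepsilon_{gj},
  \qquad \varepsilon_{gj}\sim N(0, s_{gj}^2),$$

with a flat prior on $\beta_0$, $u_g \sim N(0, 20^2)$ (percent units),
and a group-specific smooth $f_g$ on a shared basis.

**Basis.** $f_g$ uses the one-dimensional thin-plate spline family:
radial basis functions $|t-\kappa|^3$ at 5 knots placed at quantiles of
the observed midyears, restricted to the thin-plate constraint null
space, plus a per-group linear term (flat prior). The nonlinear columns
are orthogonalized against $\{1, t\}$ over the observed midyears -- the
sum-to-zero identifiability constraint -- and rescaled so their penalty
(the integrated squared second derivative, computed exactly because the
integrand is piecewise quadratic) is the identity, making the coefficient
prior $N(0,\tau^2 I)$ the standard random-effect form of a penalized
smooth. The basis carries analytic first- and second-derivative and
antiderivative evaluators; everything downstream that differentiates a
curve uses them, never finite differences of a mean curve.

**Posterior.** The model is fully Gaussian given the smoothing scale
$\tau$, so the default mode is exact: the restricted marginal likelihood
of $\tau$ (flat fixed effects integrated analytically) is evaluated on a
log-spaced grid, combined with a half-Cauchy(0, 5) prior and
trapezoid-normalized; each posterior draw samples $\tau$ from that grid
and then the coefficient vector from its exact Gaussian conditional.
This is fast, seed-stable, and free of convergence failures. A generic
MCMC mode (exact Gaussian conditional for coefficients, slice updates of
$\log\tau$) retains the source procedure's sampler preset -- 2 chains of
7000 iterations including 2000 warmup -- for parity checks; the parity
test in the suite bounds the discrepancy of posterior medians. Split-
$\hat R$ and an effective-sample-size proxy are computed at the observed
midyears for both modes and attached to the result; a fit failing
$\hat R \le 1.01$ or ESS $\ge 400$ is flagged with a warning, never
silently returned.

Draws are evaluated on a 0.25-year grid extending 2 years beyond the
first and last midyears (bounded extrapolation only; the grid must be
finer than 1 year for the run-length rules below). Draws are *not*
clipped to [0, 100]: the identity-link Gaussian can exceed the bounds,
and the conditional ratio must see unclipped draws.

## Derived quantities

**Conditional 5/1-year survival** divides 5-year by 1-year posterior
draws, paired by draw index ($100\,S_5/S_1$). Pairing by index induces
artificial independence between the two posteriors -- as in the source
procedure, which fits the horizons separately. Derivatives of the ratio
are propagated analytically by the quotient rule. Draws with a
non-positive 1-year value anywhere on the grid are excluded and counted.

**Annual change** is the posterior of $f'$ summarized per grid point
(median and 95% equal-tailed interval), in percent units per calendar
year.

**Plausible trends** are maximal sign-constant runs of grid points where
the 95% credible interval of $f'$ excludes zero, kept when the run spans
at least 5 calendar years (last minus first grid point, boundaries
counting). **Breakpoints** apply the same rule to $f''$ with a 3-year
minimum; within a qualifying run the breakpoint is the grid point
maximizing $|\mathrm{median}\,f''|$, with direction the sign of the
median (upward = accelerating improvement). All qualifying runs are
reported, ordered by year; nothing is suppressed.

Two conventions here were genuinely open. First, whether the "peak" of a
breakpoint run is the maximum of $f''$ with fixed sign or of $|f''|$: a
run is sign-constant by construction, so the two coincide; $|f''|$ is
used and recorded. Second, a time-reversal note: reversing a series in
time mirrors breakpoint *years*, but the *direction* is invariant --
if $g(t) = f(2c-t)$ then $g''(t) = f''(2c-t)$, a convex kink stays
convex -- so the suite tests mirrored years with unchanged direction.

## The synthetic registry

The generator states one world and keeps it:

* ten 5-year periods 1971--2020, diagnosis years uniform within periods;
* ages at diagnosis uniform on 15--89 by default (no case-mix model is
  given for the emulated data; uniform keeps age-standardization tests
  transparent);
* background mortality from a Gompertz--Makeham life table
  $\lambda(a) = a_0 + b_0 e^{c_0 a}$, default
  $(5\times10^{-4},\,3\times10^{-5},\,0.09)$ -- roughly of the order of
  modern Nordic adult mortality -- optionally improving by a fixed factor
  per calendar year;
* the excess (cancer) hazard is constant over follow-up within a
  diagnosis year, calibrated as $\lambda_E(d) = -\log S_5(d)/5$ so the
  configured trend is exactly the 5-year net survival; this is the
  simplest family whose net survival is analytically invertible from the
  trend curve;
* administrative censoring at the study end; loss to follow-up is
  optional exponential censoring, off by default (the emulated registries
  report minimal loss to follow-up);
* simulated period-wise survival points add Gaussian noise on the percent
  scale with the stated SE -- exactly the trend stage's observation
  model -- and are clipped to [0, 100] with the clip count logged.

What the generator does *not* emulate: stage shifts and case-mix drift
over calendar time, attained-time-varying excess hazards (cure fractions,
late excess mortality), registration delay and coding changes, and
correlated errors between adjacent period estimates. A green simulation
test therefore establishes that the machinery recovers the stated world,
not that real registry series satisfy these assumptions.

## Numerical and interface choices

* Period midyear convention: `start_year + 2` (1971--1975 → 1973),
  applied identically in simulation, estimation and modeling -- trend
  timing depends on it.
* Derivative validation uses a 4th-order central difference (h = 0.01
  years), which is exact for piecewise cubics away from knots; evaluation
  points within 2h of a knot are skipped because the spline's third
  derivative jumps there and no finite difference is valid across the
  jump.
* The per-draw fundamental-theorem check integrates the analytic first
  derivative by knot-aware composite Simpson quadrature (exact for the
  piecewise-quadratic derivative) and compares with the draw's endpoint
  difference.
* Run configurations serialize as JSON rather than YAML: the target
  environment ships a JSON parser but no YAML parser, and nothing in the
  config needs YAML-specific syntax.
* Degenerate inputs: windows with no eligible records, weight tables not
  summing to one, reversed confidence intervals, non-positive SEs and
  grids coarser than 1 year are all rejected with named errors; malformed
  export rows are rejected per row with line numbers, conserving row
  counts.

## Known limitations

* The exact-posterior mode shares one smoothing scale $\tau$ across
  groups (the hierarchical per-group variant would need the MCMC path);
  in practice the group-specific linear terms absorb most between-group
  differences in trend level.
* The weight-frozen Pohar Perme deviates from the continuous-weight
  estimator at second order in the annual population hazard; for
  high-mortality strata (ages near 90+) the bias, while small against
  sampling error at registry scale, is not exactly zero.
* Breakpoint years inherit the grid resolution (0.25 years) and, for
  nearly-symmetric second-derivative humps, can sit anywhere near the
  hump's plateau; the qualifying interval is the honest uncertainty
  statement, not the point year.
* Published-figure reproduction is out of scope by design: the upstream
  numbers derive from registry microdata that are not redistributable;
  all acceptance checking is property-based on synthetic data.
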