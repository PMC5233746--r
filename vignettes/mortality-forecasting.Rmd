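---
title: "Forecasting mortality from rates of improvement: models and methods"
author: "romicast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting mortality from rates of improvement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Why improvement rates

The level of today's death rates fixes today's life expectancy; it is the
age-specific *pace of decline* that determines tomorrow's. That pace has
historically been rather independent of the mortality level itself, and its
age profile drifts: the largest improvements moved from infant ages a
century ago to ages above 80 today. `romicast` therefore models the
annual rate of mortality improvement

$$\rho_{x,t} = -\left(\frac{m_{x,t+1}}{m_{x,t}} - 1\right),$$

positive when mortality falls, on a Lexis grid of single ages 0 to an open
age group (default 100+) by calendar year. Modelling $\rho$ rather than
$\log m$ lets the forecast carry a *time-varying* age profile of change,
which level-based extrapolations such as Lee–Carter hold fixed.

The transform requires strictly positive rates: zero-rate cells (zero
observed deaths) are flagged missing by the readers rather than patched,
and the likelihood simply skips missing cells.

## The two core models

**Linear hierarchy.** Within age $x$,
$\rho_{x,t} \sim N(\beta_{1,x} + \beta_{2,x}\,t,\ \sigma^2)$; between ages,
$(\beta_{1,x}, \beta_{2,x}) \sim N_2\big((\mu_1, \mu_2), \Omega\big)$ with
$$\Omega = \begin{pmatrix}\omega_1^2 & \rho_c\,\omega_1\omega_2\\
\rho_c\,\omega_1\omega_2 & \omega_2^2\end{pmatrix},$$
$\rho_c$ being the intercept–slope correlation (named `rhoCorr` in code to
avoid colliding with the improvement rate). The between-age precision is
the matrix inverse $\Omega^{-1}$: we read the hierarchy as a genuinely
bivariate normal, since the covariance structure above explicitly couples
intercepts and slopes. The hierarchy is what makes forecasts *coherent
across ages*: the data decide how strongly each age's trend is shrunk
toward the common one. The linear model can forecast negative improvement
(worsening mortality), and extrapolates each age's trend indefinitely.

**Exponential (log-linear) model.**
$\rho_{x,t} \sim N\big(\exp(\beta_{1,x} + \beta_{2,x}\log t),\ \sigma^2\big)$,
with coefficient priors $\beta_{j,x} \sim N(\hat\theta_{j,x}, \sigma_j^2)$
anchored at per-age ordinary least squares of $\log\rho_{x,t}$ on
$(1, \log t)$ over the base period. Negative observed $\rho$ would make the
logarithm undefined, so the pre-fit floors them at $10^{-4}$ — far below
the 0.005 clip minimum, keeping the log finite while leaving ordinary
values untouched. This model forecasts decelerating, strictly positive
improvement; it cannot represent mortality increases, which is exactly why
it is preferred for medium- and long-run projections where unbounded linear
extrapolation of improvement becomes implausible.

**Time origin.** Model time is $t = 1$ at the first base-period transition
and increases by one per year; forecast years continue at $T+1, T+2,
\dots$. A positive origin is required by $\log t$, and it keeps the
$U(-0.1, 0.1)$ priors on $\mu_1, \mu_2$ sensible at the data's scale.

**Priors.** Defaults are weakly informative uniforms:
$\sigma, \omega_1, \omega_2, \sigma_1, \sigma_2 \sim U(0,1)$;
$\mu_1, \mu_2 \sim U(-0.1, 0.1)$; $\rho_c \sim U(-1, 1)$. All are
configurable per parameter (`priorSpec()`): a rescaled Beta or a truncated
Normal on the same support for sensitivity analysis, or `"fixed"` to pin a
value. Supports are hard: the log-posterior is $-\infty$ outside them and
samplers never leave them.

## Sampling

`runSampler()` uses adaptive Metropolis-within-Gibbs, with the block
structure chosen to exploit every available conjugacy:

* linear model — per-age $(\beta_{1,x}, \beta_{2,x})$ given the hypers are
  conjugate bivariate normal (updated jointly, vectorized over ages);
  $(\mu_1, \mu_2)$ given the coefficients is normal truncated to its
  uniform-prior box, sampled by alternating univariate truncated-normal
  conditionals; $\sigma, \omega_1, \omega_2, \rho_c$ move by scalar
  random-walk Metropolis on an interval-logit scale (with the Jacobian in
  the target).
* exponential model — the nonlinear mean breaks conjugacy, so each age's
  coefficient pair moves by its own random-walk Metropolis step (all ages
  proposed and accepted/rejected in parallel); $\sigma, \sigma_1, \sigma_2$
  as above.

Proposal scales adapt every 50 iterations during burn-in toward roughly
30% acceptance (a standard target for scalar random walks) and are frozen
afterwards, so the retained chain satisfies detailed balance. Acceptance
rates below 1% after adaptation trigger a warning; `NaN` in a target is an
error, never silently dropped.

Defaults follow the package's standard run length: 5 chains, 5200
iterations each after a burn-in of 200, thinning 5 — 1040 retained draws
per chain, 5200 pooled. (Where run-length conventions are stated
ambiguously in the literature — "5200 iterations" versus "a total of 5000"
— we fix the convention as: `nIterations` counts post-burn-in iterations
per chain and the pool is whatever survives thinning.) Identical seed and
configuration give bit-identical draws; chain seeds derive
deterministically from the run seed.

Diagnostics: per-parameter traces, autocorrelation functions, split-chain
potential scale reduction, and the Raftery–Lewis run-length diagnostic
(dichotomize at the empirical quantile, find minimal thinning by BIC
between first- and second-order Markov fits, then burn-in and required
length from the two-state transition matrix; for an independent chain the
closed-form minimum at $q = 0.025$, $r = 0.005$, $s = 0.95$ is
$N_{\min} = \lceil q(1-q)(z_{0.975}/r)^2\rceil = 3746$).

## From draws to forecasts

For each retained parameter draw, the mean improvement path over the
forecast years is evaluated and, by default, an independent
$N(0, \sigma^2)$ innovation per cell is added — the posterior-predictive
rather than the posterior-mean distribution; whether to include the
observation-level noise is a switch (`includeNoise`). Draws are then
clamped to the clip bounds $[0.005, 0.035]$: a sustained decline below
0.5% or above 3.5% a year lies outside what smoothed developed-country
surfaces display (3.5% a year halves mortality in about 19.5 years).
Clipping applies to *forecast draws only*, never to observed ROMIs, and
can be disabled (`clipBounds(-Inf, Inf)`).

Death rates follow by the recursion $m_{x,t} = m_{x,t-1}(1 - \rho_{x,t})$
from the jump-off rates — by default the *smoothed* rates of the last base
year, which makes the observed-to-forecast transition seamless (no
jump-off bias); observed jump-off is a configuration option. The default
propagation is *quantile-path*: take the per-cell quantiles of the ROMI
draws first, then run the recursion per quantile. This is the convention
the recursion above is written in, and it guarantees
quantile surfaces that never cross. A *trajectory* mode (propagate each
draw, then take per-cell rate quantiles at level $1-p$ for level $p$, so
that higher level still means lower mortality) is kept for sensitivity
checks; the two coincide for a degenerate posterior. Note that
quantile-path bands move all ages and years together and therefore
overstate the *marginal* per-year spread of derived summaries; for
calibration measurement the package exposes `e0FromDraws()`, the per-draw
life-expectancy trajectories, whose per-year quantiles are the honest
marginal prediction interval. The package's calibration tests use exactly
that object, with clipping disabled, because the synthetic truth is
generated unclipped.

**Mortality convergence.** When a country's trend is expected to approach
that of reference countries, the forecast draws are blended cell-wise with
the reference trend: $(1 - w_t)\rho^{COI} + w_t\rho^{RC}$, with $w_t$
non-decreasing. The reference trend is produced by fitting the same core
model to the cell-wise mean of the reference countries' observed ROMI
surfaces and drawing from its posterior predictive. The default schedule
is a linear ramp $w_t = t/H$; a delayed ramp (zero until a start year)
models later onsets of convergence. The choice of reference countries and
schedule is explicitly a forecaster's judgment, not estimated from data.

## Life tables

Life expectancy comes from standard single-age period life tables:
$q_x = m_x / (1 + (1 - a_x) m_x)$ with $a_x = 0.5$ for $x \ge 1$; the open
age group is closed with $L_A = l_A / m_A$, $e_A = 1/m_A$. The infant
separation factor $a_0$ uses the Andreev–Kingkade piecewise-linear
functions of $m_0$ (sex-specific, the HMD-protocol convention), with a
fixed-$a_0$ fallback. Death probabilities above one are clamped with a
warning. Because $a_x$ conventions vary slightly across sources,
forecast-level checks on life expectancy are property-based (oracle
recursion, monotonicity, interval nesting) rather than matched to any
published table.

## Smoothing

Raw ROMIs at ages with few deaths are extremely noisy, so death rates may
be smoothed before the transform: penalized Poisson regression of deaths
with a log-exposure offset on a cubic B-spline basis (one knot interval
per five grid points — deliberate over-parameterization), a difference
penalty of order 2 by default (its null space is log-rates linear in time,
i.e. constant improvement), and the smoothing parameter chosen by
minimizing $\mathrm{BIC} = \mathrm{deviance} + \log(n)\cdot
\mathrm{ED}(\lambda)$ over a user grid. The default smooths each age's
time series independently — one-dimensional smoothing is enough to
stabilize the year-on-year ratios the transform takes — and a 2D age×time
smoother with a shared $\lambda$ on the Kronecker basis is available.
Smoothing is off by default and unnecessary when the input rates are
already smooth. The penalized IRLS is checked in the test suite against an
independent brute-force implementation, including the BIC grid argmin and
the monotone decrease of effective dimension in $\lambda$.

## The synthetic world

`scenarioSpec()` defines the study conditions the test suite and the
acceptance script run under; its defaults were chosen once, on demographic
grounds, and are not tuned:

* 101 single ages, a 26-year base period, a 21-year horizon — a validating
  forecast with at least as many reference years as forecast years;
* Gompertz–Makeham baseline $m_{x,0} = 5\times10^{-5} e^{0.1x} +
  5\times10^{-4}$: adult mortality doubling roughly every 7 years, a
  background hazard of $5\times10^{-4}$, life expectancy in the low 70s at
  the start — a developed population some decades ago;
* improvement schedules: constant; linear-in-$t$ with per-age coefficients
  drawn from the bivariate hierarchy ($\mu_1 = 0.012$, $\mu_2 =
  2\times10^{-4}$, $\omega_1 = 0.004$, $\omega_2 = 1.5\times10^{-4}$,
  $\rho_c = -0.4$ — mean improvement near 1.5% a year, well inside the
  0.5–3.5% band); or log-linear ($\theta_1 = \log 0.025$, $\theta_2 =
  -0.15$ — decelerating from 2.5% a year). An optional Gaussian-in-age
  bump with a drifting centre emulates the aging of mortality decline;
* observation noise $\sigma = 0.005$ on the ROMI scale, which also drives
  the evolution of the generated rate surface (so a generated world is one
  draw from the model's own stochastic process), and/or Poisson death
  counts at a configurable exposure;
* a convergent pair: the country of interest stagnates
  ($\rho \approx 0.002$) over a configurable window and afterwards resumes
  by converging to the reference country's trend, which runs 0.6
  percentage points faster throughout — the canonical turning-point
  situation that motivates blending.

What the generator does *not* emulate: cohort effects running along
diagonals, age-misstatement and small-count artifacts at the oldest ages,
wars and pandemics, or heterogeneity between sexes. Passing tests
therefore demonstrate correctness of the machinery and calibration under
the model's own assumptions — not that any real population follows them.

## Numerical choices

* Interval-supported parameters move on an interval-logit scale; the
  correlation uses the same transform on $(-1, 1)$, which keeps $\Omega$
  positive definite by construction.
* Truncated-normal sampling uses inverse-CDF draws; if the box has
  numerically zero mass the conditional mean is clamped into the interval.
* The per-age conjugate update solves the $2\times2$ system in closed form
  (scalar algebra vectorized over ages) rather than per-age matrix calls.
* Surface CSVs print 17 significant digits so write-read round-trips are
  bit-exact; JSON truth records round-trip to ~15 digits.
* The ROMI/rate recursions are exact inverses of each other up to floating
  rounding; tests assert relative error below $10^{-12}$.
* Improvement rates $\ge 1$ (which would drive rates non-positive) are a
  hard error in the recursion, not a clamp.

Problem sizes in the test suite (the package's own choices for a
single-CPU desk run): parameter recovery uses 20 replicate fits of 21 ages
× 26 ROMI years at 2 chains × 2000 iterations; predictive calibration uses
10 replicate worlds × 5 horizon years at 101 ages; prior sensitivity
refits three families at 2 × 1500 iterations. The acceptance script runs
the full default MCMC (5 × 5200) at 101 ages.

## Known limitations

* The exponential model cannot forecast mortality increases; use the
  linear model where deterioration is plausible.
* Blending weights and reference-country choice are subjective inputs; the
  package deliberately does not estimate them.
* Quantile-path bands are joint, not marginal; use `e0FromDraws()` when
  the marginal per-year interval is the quantity of interest.
* Single-population, single-sex runs only; no fertility/migration, so no
  population projection.
* The HMD reader accepts period 1×1 layouts only (no Lexis triangles, no
  abridged ages).
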