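---
title: "Modelling and projecting mesothelioma mortality from reconstructed asbestos exposure"
author: "mesoproj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and projecting mesothelioma mortality from reconstructed asbestos exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
library(mesoproj)
```

Mesothelioma is a cancer of the pleura and peritoneum caused predominantly
by inhaled asbestos fibres, with a latency of 15 to 60 years between
exposure and death.  Because the disease is almost uniformly fatal and
exposure in Britain was overwhelmingly occupational and male, national
death-register counts of male mesothelioma deaths carry a readable imprint
of the country's historical asbestos usage.  This package implements a
Poisson regression model of that imprint: the expected number of recorded
male deaths at single year of age $A$ and calendar year $T$ is modelled,
fitted by Markov chain Monte Carlo, and propagated forward over population
projections to give annual death forecasts with credible and prediction
intervals.

The registry data that motivated this model are not publicly deposited, so
the package ships a synthetic-data generator that plays the role of the
register: smooth person-years surfaces resembling the British male
population and Poisson death counts drawn from the model itself at a known
parameter set.  Everything downstream — fitting, diagnostics, projection —
can therefore be exercised and tested end to end without any external data.

## The model

A man dying at age $A$ in year $T$ accumulated exposure over his lifetime.
Indexing years before death by $l$, he was aged $A-l$ and exposed to the
population-average dose $W_{A-l}\, D_{T-l}$, where

* $D_T$ is the unit-free collective asbestos dose in the male breathing
  zone in year $T$ (the *exposure curve*), and
* $W_A$ is the relative exposure potential at age $A$, piecewise constant
  over nine age bands (0–4, 5–15, 16–19, 20–29, 30–39, 40–49, 50–59,
  60–64, 65+) with the 20–29 band fixed at 1 as baseline.

Each year of exposure contributes to the death rate $l$ years later
proportionally to a power of time since exposure, lagged by $L$ years, and
attenuated by clearance of fibres from the lung with half-life $H$:

$$
\lambda_{A,T} \;=\; p_T \left( c \, P_{A,T} \sum_{l=0}^{A}
  W_{A-l}\, D_{T-l}\, 2^{-l/H} \,(l-L)_+^{k} \;+\; B_{A,T} \right),
$$

where $P_{A,T}$ are person-years at risk, $k$ is the power of time since
exposure, $(x)_+ = \max(x, 0)$, $B_{A,T}$ is a background of cases not
attributable to asbestos, and $p_T$ is the proportion of true deaths
actually recorded (the *diagnostic trend*).  The sum stops at $l = A$:
exposure before birth contributes nothing.  The background distributes a
rate of `rate` cases per million person-years over ages in proportion to
$(A-L)_+^k$, the same shape the asbestos term has under constant lifetime
exposure.  Observed counts $Y_{A,T}$ are Poisson with mean
$\lambda_{A,T}$, giving the likelihood that drives all inference.

Two conventions are worth stating because the algebra does not force them:

* **Lag indicator.** Contributions with $l \le L$ are zero.  A convention
  that admitted $l = L - 1$ would require evaluating $(l-L)^k$ at negative
  base for non-integer $k$; zeroing everything inside the lag matches the
  $(A-L)^k$ background form and is what we implement.
* **Normalisation.** The constant $c$ is not free: it is chosen so that
  the fitted total over the fit window equals the observed total $M$,
  i.e. $c = (M - \sum p_T B_{A,T}) / \sum p_T\, u_{A,T}$ with $u$ the
  unnormalised asbestos term.  This removes the non-identifiability
  between the overall level of $D$ and a proportionality constant, and it
  is carried unchanged into projection years.

The diagnostic trend assumes diagnosis essentially complete (98%) from
1997 onwards, with the fraction of missed cases growing by $\alpha$
percent per year going backwards.  In the final model the diagnostic trend
is off (`alpha = NULL`, $p_T \equiv 1$): including it does not improve the
fit, and any drift in completeness is absorbed by the exposure curve and
background.  The clearance half-life defaults to $H = 10^6$ years —
effectively no clearance, the best-fitting regime — and the lag to
$L = 10$ years.

## The exposure curve

```{r curve}
curve <- build_exposure_curve(growth_rate_knots(default_knot_rates()), 1963)
plot(curve)
```

$D_T$ is parameterised through annual growth rates (percent per year) at
knots placed at offsets $-65, -55, \dots, -5, +5, +15$ years around the
peak exposure year (`peakyear`), with the rate at the peak itself zero by
definition; rates between knots are linearly interpolated, and the curve
evolves multiplicatively, $D_{T+1} = D_T (1 + r_T / 100)$, anchored at
$D_{\text{peakyear}} = 1$.  The three earliest knots are fixed at 0, 1000
and 100000 percent per year, forcing a negligible exposure level in the
distant past that rises extremely steeply towards the late 1920s; the
remaining six are estimated.  Beyond the last estimated year
(`peakyear + 15`) the curve follows fixed regulatory-assessment
assumptions: a linear decline to 4% of the peak in 2000, then linear
interpolation through 2% in 2010 and 0.75% in 2050.  An alternative
`"levelled-1978"` scenario holds exposure at its last estimated level
indefinitely, for sensitivity analyses of long-term projections.

Numerical choices here, made once and kept:

* The curve is anchored at the peak and propagated outwards in both
  directions.  (Growing it forward from a tiny floor would let the fixed
  steep early rates compound into an early-century level astronomically
  above the peak, contradicting the definition of the peak year.)
* Each multiplicative step uses the interpolated rate of its **source**
  year; the convention matters only at one-year granularity and is fixed
  so that log-differences of $D$ reproduce `log(1 + rate/100)` exactly,
  which the tests assert.
* The default year range is 1860–2050: wide enough that every cohort on a
  20–89 × 1968+ grid has its full exposure history, for any peak year in
  the 1950–2000 prior support.  Before `peakyear - 65` the rate is the
  fixed 0, leaving the early level constant and vanishingly small.
* The printed source for the steepest fixed rate is ambiguous between
  100000 and 1000000; we default to 100000 and expose an override
  (`growth_rate_knots(fixed = ...)`).  At either value exposure before
  ~1925 is negligible, so the choice is inconsequential for the fit.

## Priors, sampler, and the geometry of this posterior

All free parameters get uniform priors over generous ranges: $k \sim
U(0,10)$, each free $W \sim U(0,10)$, each free knot rate $\sim
U(-100,200)$ (a decline cannot exceed 100% per year), background rate
$\sim U(0,20)$ per million, and the peak year discrete uniform on the
integers 1950–2000.  When the diagnostic trend is estimated, $\alpha \sim
U(-7, 9)$ percent per year.

Sampling is component-wise random-walk Metropolis–Hastings: one parameter
at a time in a fixed sweep order, normal proposals (symmetric integer
steps for the peak year), acceptance by the posterior ratio, proposals
outside the prior support rejected outright.  Proposal standard deviations
are tuned in a pilot phase toward a 20–45% acceptance band by doubling or
halving after each pilot round, and frozen before any retained draw.  The
reference analysis scale is a burn-in of 20000 sweeps with 35000 retained
draws; the package defaults are a desk-scale run (burn-in 2000, 5000
retained) that finishes in minutes and is sufficient for the synthetic
studies below.  All randomness flows from a single seed; R's default
Mersenne-Twister generator is recorded in run manifests, and identical
seeds reproduce chains bit for bit.

Two structural features of this posterior deserve honesty:

* **The peak year and the knots are glued together.**  Knot positions are
  defined relative to `peakyear`, so a proposal that moves the peak year
  alone drags the whole reconstructed history with it and is almost
  always rejected once the knots have adapted.  A chain started at the
  wrong peak year cannot migrate.  `fit_mortality_model()` therefore
  profiles the discrete peak year before sampling: every candidate on a
  coarse grid gets a short adaptive pilot with the peak year held fixed,
  the worse half of candidates is culled and the survivors continue with
  the freed budget (successive halving), and the best few surviving
  states are carried through full proposal tuning.
* **The curve subspace is multimodal.**  Besides the data-supported
  reconstruction with a sharp local 1930 peak, there is a competing
  smooth-history mode typically a dozen or so log-posterior units worse.
  A single tuning run lands in one basin or the other depending on its
  random path, so the whole profile-and-tune search is replicated
  (`n_chains`, default 4) and the retained chain starts from the best
  tuned state found.  The model also enforces, as part of its support,
  that the exposure curve attains its maximum at the nominal peak year —
  without this the free knots can relocate the true peak while the
  `peakyear` parameter wanders, leaving it meaningless (and the
  recovered $k$ biased).  Starting values are prior midpoints with two
  exceptions: the peak year starts at 1975 (profiling revisits this
  anyway), and the two post-peak growth rates start at $-20$ rather than
  the midpoint $+50$, since exposure rising after its own peak would
  contradict the peak-year definition.

Chains are summarised by posterior medians with equal-tailed 90% credible
intervals (linear-interpolation percentiles); the discrete peak year by
its posterior mode, and discrete-year intervals use outward-inclusive
order statistics so that the endpoints are attained years.

## Goodness of fit

The Poisson deviance $2\sum [Y \ln(Y/\lambda) - (Y - \lambda)]$ measures
fit; for cell-level diagnostics the surface is aggregated into 14
five-year age bands crossed with 9 calendar periods (1968–71, eight
4-year bands, 2000–06), giving 126 aggregated cells on the standard grid,
and each cell's signed deviance residual
$r = \mathrm{sign}(Y - \lambda)\sqrt{d}$ is computed.  Under a good fit
these are approximately standard normal, so about 95% should lie in
$[-2, 2]$.  The banding is a package convention (the level of aggregation
at which such residual counts are conventionally reported), is labelled as
such in output, and is configurable through `deviance_residuals()`.

## Projection

`project_mortality()` rebuilds the full expected-death surface for each
retained draw over 1968–2050 (the draw's own normalisation constant
carried forward from the fit window), sums over ages, and summarises
across draws: percentiles of the expected totals give the credible
interval for the expectation, and percentiles of Poisson counts drawn from
those totals give the prediction interval, which thus carries both
parameter and sampling uncertainty.  Short chains draw several Poisson
replicates per retained draw so even a degenerate one-draw chain yields a
proper Poisson interval.  Peak summaries are per-draw argmaxes (ties to
the earlier year).  Since roughly 99% of male mesothelioma deaths occur at
ages 20–89, all-ages series are obtained per draw by a multiplicative
factor, default $1/0.99$; both series are labelled explicitly in output.

Prediction-interval calibration deserves one nuance.  Nominal 90%
coverage is a statement averaged over repeated data sets; conditional on
one fitted data set, coverage of replicate futures is close to nominal
only while Poisson noise dominates — the first decade or so of the
projection.  Further out, small parameter deviations compound over
decades of extrapolated exposure decline, and conditional coverage
becomes unstable: it can saturate towards 100% when the parameter spread
dominates, or fall well below nominal when the fitted trajectory drifts
a few percent from the truth.  Calibration claims, and the coverage
check in the acceptance suite, are therefore made for the first
projection decade, the horizon on which a model of this kind claims
predictive validity; longer-horizon intervals should be read as
scenario-conditional uncertainty, not calibrated forecasts.

The lag sweep (`lag_sensitivity()`) is a *local* sensitivity analysis, as
such analyses are usually run: each candidate lag is refit with identical
priors starting from the posterior median of a reference fit, and the
deviance at each refit's posterior median is tabulated together with the
projected peak.  On data generated with $L = 10$ the deviance profile
over $\{0, 5, 10, 15\}$ bottoms out at 10, and a lag of 0 pushes the
recovered mortality peak later than a lag of 15 — both reproduced as
properties in the acceptance suite.

## The synthetic-data generator

`population_model()` / `make_population()` produce a deterministic, smooth
person-years surface: a Gaussian age profile over ages 20–89 whose mode
and spread drift upward over time, scaled to about 21.3 million males aged
20–89 in 2006 and growing 0.2% per year.  The drift rates (mode +0.15
years of age per year, spread +0.05 per year) were set so the older
population grows by roughly a quarter between 2006 and 2020 — the order of
the British experience — which in turn places the projected mortality peak
a few years beyond the end of the fit window rather than immediately at
it.  The generator emulates *smoothness, scale and ageing*; it does not
attempt cohort-level demographic realism (war cohorts, migration), and
passing tests say nothing about those features of real data.

`simulate_deaths()` runs the model forward at a known parameter set and
draws Poisson counts.  Crucially it does **not** use the fitter's
$M$-normalisation (which would be circular — the scale would be defined by
its own random output); it takes an explicit absolute scale `c_scale`,
calibrated once by `calibrate_scale()` so that the *expected* fit-window
total is 34000 deaths, the order of the British male register total for
1968–2006.  Every simulated dataset carries a truth manifest (JSON) from
which it can be regenerated bit-identically.

The default generating truth (`default_parameters()`) is the
posterior-median estimate from the British register analysis: $k = 2.42$,
background rate 1.08 per million, peak exposure year 1963, no clearance,
lag 10, the reference growth-rate knots and age-band weights.  Simulated
yearly totals then rise more than ten-fold from 1968 to 2006, echoing the
registered experience.

## Problem sizes and what the studies show

The studies in the test suite and `scripts/acceptance.R` run at desk
scale, chosen to be decisive but quick: parameter recovery fits 5000
retained draws after a 2000-sweep burn-in on a ~34000-death surface
(minutes on one CPU with the vectorised likelihood); residual calibration
averages 20 simulated registers; prediction-interval coverage uses 200
replicate futures; the lag study spans 10 simulated registers with 4
local refits each.  At these sizes the synthetic studies recover the
generating $k$, background rate, peak year and 30–39 exposure weight
within their credible intervals, keep ~95% of banded residuals in
$[-2,2]$, and cover future yearly totals at close to the nominal 90%.

## Known limitations

* Identification of the exposure curve rests on the fixed early rates and
  the post-2000 assumptions; the data cannot distinguish exposure shapes
  whose induced death surfaces coincide, and real prediction uncertainty
  beyond 1978 exposure assumptions is larger than the intervals express
  (the `"levelled-1978"` scenario gives a sense of that sensitivity).
* The background rate and the high-age exposure weights (50+) are weakly
  identified and their posteriors lean on the prior ranges; the 65+
  weight in particular recovers only to within a wide interval.
* Component-wise Metropolis–Hastings with multi-start search finds the
  dominant mode reliably in the synthetic studies, but it samples within
  one basin; posterior mass in subdominant basins is not represented.
* The all-ages rescaling treats the outside-20–89 share as a constant 1%,
  per draw, with no age structure of its own.
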