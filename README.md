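# mesoproj

Bayesian modelling and projection of male mesothelioma mortality from a
reconstructed population asbestos-exposure history.

Mesothelioma is an almost uniformly fatal cancer of the pleura and
peritoneum caused predominantly by inhaled asbestos, with 15–60 years of
latency between exposure and death.  National death registers therefore
record, decades later, the imprint of a country's historical asbestos use.
This package is for epidemiologists and biostatisticians who want to fit
that imprint with an interpretable mechanistic model and project it
forward: how high will annual deaths peak, when, and with what
uncertainty?

## The model

Expected recorded male deaths at age $A$ in year $T$:

$$
\lambda_{A,T} = p_T\Big(c\,P_{A,T}\sum_{l=0}^{A}
W_{A-l}\,D_{T-l}\,2^{-l/H}\,(l-L)_+^{k} + B_{A,T}\Big),
\qquad Y_{A,T}\sim\text{Poisson}(\lambda_{A,T})
$$

* $D_T$ — unit-free collective asbestos dose (the exposure curve),
  reconstructed from percent-per-year growth-rate knots around the peak
  exposure year, with fixed assumptions after 2000 (4%, 2% and 0.75% of
  the peak in 2000, 2010 and 2050);
* $W_A$ — relative exposure potential in nine age bands (20–29 baseline);
* $(l-L)_+^k$ — power-of-time risk growth, lagged $L$ years ($L=10$);
* $2^{-l/H}$ — lung clearance with half-life $H$ ($10^6$ years: none);
* $B_{A,T}$ — background cases (per-million rate, age shape $(A-L)_+^k$);
* $p_T$ — diagnostic completeness (98% from 1997; off by default);
* $c$ — normalisation tying the fitted total to the observed total.

Inference is component-wise random-walk Metropolis–Hastings under uniform
priors, with proposal tuning to a 20–45% acceptance band, peak-year
profiling with successive halving, and multi-start search (the
exposure-curve posterior is multimodal).  Projections propagate posterior
draws over future population surfaces, giving 90% credible intervals for
expected deaths and 90% prediction intervals for realised counts.

Because the underlying death register is not public, the package includes
a first-class synthetic-data generator (`make_population()`,
`simulate_deaths()`) that emulates the register's statistical structure,
so the full simulate → fit → diagnose → project pipeline runs and is
tested without any external data.

## Worked example

```r
library(mesoproj)

## reconstructed exposure curve at the reference estimates
curve <- build_exposure_curve(growth_rate_knots(default_knot_rates()),
                              peakyear = 1963)
exposure_at(curve, c(1963, 1978, 2000, 2010, 2050))
#> [1] 1.0000000 0.2242755 0.0400000 0.0200000 0.0075000

## a synthetic register: smooth population, Poisson deaths at the
## reference parameters, expected total 34000 over 1968-2006
pop <- make_population(population_model())
sim <- simulate_deaths(default_parameters(), pop, seed = 20260919)
sim
#> <meso_surface> ages 20-89, years 1968-2006, total deaths 33 870

## fit (burn-in 2000, 5000 retained draws; a few minutes on one CPU)
fit <- fit_mortality_model(sim, seed = 101)
fit$summary[1:3, ]
#>   parameter   median    lower   upper mode
#> 1         k    2.478    2.384    2.58   NA
#> 2      rate    0.893    0.663    1.14   NA
#> 3  peakyear 1963.000 1963.000 1963.00 1963
```

The generating values were $k = 2.42$, rate $= 1.08$ per million and peak
year 1963: the sampler recovers the exponent of time within 3%, the peak
exposure year exactly, and the background rate within its 90% credible
interval (the rate posterior is wide — a per-million nuisance quantity
identified mainly by the early, low-count years).

```r
## goodness of fit at the posterior median
deviance_residuals(sim, fitted_median_surface(fit))
#> <meso_deviance> 126 aggregated cells, 96.8% of residuals in [-2, 2],
#>                 total deviance 2372.1

## projection to 2050 with credible and prediction intervals
proj <- project_mortality(fit, pop, n_draws = 500, seed = 1)
proj
#> <meso_projection> 500 draws x 83 years
#> peak (ages 20-89): 1969 deaths in 2012 (90% CI 2011-2013)
```

About 95% of banded deviance residuals in $[-2,2]$ indicates an adequate
Poisson fit; the projection peaks a few years after the end of the fitted
window and then declines as the exposed cohorts die out, with the
prediction interval (parameter + Poisson uncertainty) enclosing the
credible interval for the expectation each year.

A command-line pipeline wrapping the same functions lives in
`inst/cli/mesoproj.R`:

```sh
Rscript inst/cli/mesoproj.R simulate --out-dir out --seed 1
Rscript inst/cli/mesoproj.R fit      --out-dir out --iters 5000
Rscript inst/cli/mesoproj.R project  --out-dir out
```

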