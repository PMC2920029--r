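## Shared fixtures, built once per test run and cached.  The expensive one
## is the reference synthetic-data fit (used by several acceptance checks);
## everything is generated in code under fixed seeds.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

## smooth synthetic population, 1900-2050
fx_pop <- function() fx("pop", function() make_population(population_model()))

## reference generating truth (posterior-median parameter set)
fx_truth <- function() default_parameters()

## synthetic register: deaths 1968-2006 at the truth, ~34k expected deaths
fx_sim <- function() fx("sim", function()
  simulate_deaths(fx_truth(), fx_pop(), seed = 20260919))

## the reference desk-scale fit: 5000 retained draws
fx_fit <- function() fx("fit", function()
  fit_mortality_model(fx_sim(), seed = 101))

## tiny toy grid for hand-checked and loop-oracle computations
fx_toy_surface <- function(n_ages = 5, n_years = 5, seed = 3) {
  set.seed(seed)
  ages <- 60:(60 + n_ages - 1)
  years <- 1990:(1990 + n_years - 1)
  py <- matrix(stats::runif(n_ages * n_years, 5e4, 2e5), n_ages)
  deaths <- matrix(stats::rpois(n_ages * n_years, 20), n_ages)
  mortality_surface(ages, years, deaths, py)
}

## brute-force triple-loop oracle for the asbestos surface
oracle_asbestos <- function(params, curve, pop, years = NULL) {
  cols <- if (is.null(years)) seq_along(pop$years) else
    which(pop$years >= years[1] & pop$years <= years[2])
  yrs <- pop$years[cols]
  u <- matrix(0, length(pop$ages), length(yrs))
  for (i in seq_along(pop$ages)) {
    A <- pop$ages[i]
    for (j in seq_along(yrs)) {
      T <- yrs[j]
      s <- 0
      for (l in 0:A) {
        w <- age_weight(A - l, params$W)
        d <- exposure_at(curve, T - l)
        rw <- if (l > params$L) (l - params$L)^params$k else 0
        s <- s + w * d * 2^(-l / params$H) * rw
      }
      u[i, j] <- pop$person_years[i, cols[j]] * s
    }
  }
  dimnames(u) <- list(pop$ages, yrs)
  u
}

## batch-means standard error for an autocorrelated chain
batch_se <- function(x, n_batch = 50) {
  n <- length(x)
  b <- floor(n / n_batch)
  means <- vapply(seq_len(n_batch),
                  function(i) mean(x[((i - 1) * b + 1):(i * b)]),
                  numeric(1))
  stats::sd(means) / sqrt(n_batch)
}
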