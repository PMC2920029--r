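## Synthetic data generation: smooth person-years surfaces emulating a
## national male population, and Poisson death counts drawn from the model
## run forward at a known parameter set.  The generator uses an explicit
## absolute scale c_true (it never normalises to its own output), so
## parameter recovery against the generated data is well posed.

#' Smooth population model
#'
#' Defines a deterministic, smooth person-years surface for males by single
#' year of age: a Gaussian-shaped age structure over ages 20-89 whose mode
#' drifts upward over time (an ageing population), scaled to a total that
#' grows at a constant annual rate through a reference year.  The defaults
#' give roughly 21.3 million males aged 20-89 in 2006, drifting upward --
#' the order of magnitude of the British male population -- without
#' attempting demographic realism beyond smoothness.
#'
#' @param total_ref total person-years over ages 20-89 in `ref_year`.
#' @param ref_year reference calendar year for `total_ref`.
#' @param annual_growth relative growth of the total per year.
#' @param age_mode age-structure mode in `ref_year`.
#' @param age_mode_drift upward drift of the mode, years of age per
#'   calendar year (an ageing population).
#' @param age_sd spread of the age structure in `ref_year`.
#' @param age_sd_drift growth of the spread per calendar year; together
#'   with the mode drift this grows the older population over time (the
#'   defaults give roughly 25% more males aged 60-89 in 2020 than in 2006,
#'   the order of the British experience).
#' @param ages,years grid of the surface (years as `c(first, last)`).
#' @return object of class `meso_popmodel` (a list of these settings).
#' @export
population_model <- function(total_ref = 21.3e6, ref_year = 2006L,
                             annual_growth = 0.002, age_mode = 42,
                             age_mode_drift = 0.15, age_sd = 18,
                             age_sd_drift = 0.05,
                             ages = 20:89, years = c(1900L, 2050L)) {
  structure(list(total_ref = total_ref, ref_year = as.integer(ref_year),
                 annual_growth = annual_growth, age_mode = age_mode,
                 age_mode_drift = age_mode_drift, age_sd = age_sd,
                 age_sd_drift = age_sd_drift,
                 ages = as.integer(ages),
                 years = as.integer(years[1]):as.integer(years[2])),
            class = "meso_popmodel")
}

#' Generate a person-years surface from a population model
#'
#' Deterministic and smooth in both age and year (the `seed` argument is
#' accepted for interface symmetry with [simulate_deaths()] and recorded,
#' but the surface itself is noise-free: demographic noise is not part of
#' what the generator emulates).
#'
#' @param model a [population_model()].
#' @param seed recorded seed (unused by the deterministic construction).
#' @return a person-years-only [mortality_surface()].
#' @export
make_population <- function(model = population_model(), seed = NULL) {
  sd_drift <- if (is.null(model$age_sd_drift)) 0 else model$age_sd_drift
  P <- vapply(model$years, function(T) {
    m <- model$age_mode + model$age_mode_drift * (T - model$ref_year)
    s <- model$age_sd + sd_drift * (T - model$ref_year)
    w <- exp(-0.5 * ((model$ages - m) / s)^2)
    tot <- model$total_ref *
      (1 + model$annual_growth)^(T - model$ref_year)
    tot * w / sum(w)
  }, numeric(length(model$ages)))
  mortality_surface(model$ages, model$years, person_years = P)
}

#' Calibrate the absolute scale of the asbestos component
#'
#' Returns the constant `c_true` such that the expected total of recorded
#' deaths over the fit window equals `target_deaths` when the model is run
#' forward at `truth` on `pop`.
#'
#' @param truth a [parameter_set()] (the generating truth).
#' @param pop person-years surface.
#' @param target_deaths expected fit-window death total (default 34000, the
#'   order of the 1968-2006 register total).
#' @param fit_window `c(first, last)` years.
#' @return scalar `c_true`.
#' @export
calibrate_scale <- function(truth, pop, target_deaths = 34000,
                            fit_window = c(1968L, 2006L)) {
  curve <- build_exposure_curve(truth$knots, truth$peakyear,
                                years = CURVE_RANGE)
  fs <- fitted_surface(truth, curve, pop, c_scale = 1, years = fit_window)
  pu <- sum(t(fs$asbestos) * fs$p)
  pB <- sum(t(fs$background) * fs$p)
  if (pB >= target_deaths)
    stop("background alone exceeds the target death total")
  (target_deaths - pB) / pu
}

#' Simulate a death surface from known parameters
#'
#' Runs the model forward at `truth` with absolute scale `c_scale` and draws
#' `Y[A, T] ~ Poisson(lambda[A, T])` over the fit window.  Deterministic
#' given `seed`.  The returned surface carries a truth manifest (attribute
#' `"truth"`) from which the dataset can be regenerated bit-identically.
#'
#' @param truth generating [parameter_set()].
#' @param pop person-years surface covering the fit window.
#' @param fit_window simulated years.
#' @param c_scale absolute scale of the asbestos component; default
#'   calibrated so the expected fit-window total is `target_deaths`.
#' @param target_deaths see [calibrate_scale()].
#' @param seed integer seed.
#' @return a [mortality_surface()] with simulated deaths and the matching
#'   person-years, with attribute `truth` (list: `params`, `c_scale`,
#'   `fit_window`, `seed`, `expected_total`).
#' @export
#' @examples
#' pop <- make_population(population_model())
#' sim <- simulate_deaths(default_parameters(), pop, seed = 42)
#' sim
simulate_deaths <- function(truth, pop, fit_window = c(1968L, 2006L),
                            c_scale = NULL, target_deaths = 34000,
                            seed = 1L) {
  if (is.null(c_scale))
    c_scale <- calibrate_scale(truth, pop, target_deaths, fit_window)
  curve <- build_exposure_curve(truth$knots, truth$peakyear,
                                years = CURVE_RANGE)
  fs <- fitted_surface(truth, curve, pop, c_scale = c_scale,
                       years = fit_window)
  if (any(!is.finite(fs$lambda)))
    stop("non-finite expected deaths under the generating parameters")
  set.seed(seed)
  Y <- matrix(stats::rpois(length(fs$lambda), fs$lambda),
              nrow(fs$lambda))
  cols <- surface_year_cols(pop, fit_window)
  out <- mortality_surface(pop$ages, fs$years, deaths = Y,
                           person_years = pop$person_years[, cols])
  attr(out, "truth") <- list(params = truth, c_scale = c_scale,
                             fit_window = as.integer(fit_window),
                             seed = as.integer(seed),
                             expected_total = sum(fs$lambda))
  out
}

#' Write / apply a truth manifest
#'
#' The manifest records everything needed to regenerate a simulated dataset
#' bit-identically: the generating parameters, the absolute scale, the fit
#' window and the seed (the population surface is regenerated from its own
#' model settings, stored alongside).
#'
#' @param sim a [simulate_deaths()] result.
#' @param path JSON output path.
#' @param popmodel the [population_model()] used (stored in the manifest).
#' @return path, invisibly.
#' @export
write_truth_manifest <- function(sim, path,
                                 popmodel = population_model()) {
  tr <- attr(sim, "truth")
  if (is.null(tr)) stop("surface carries no truth manifest")
  p <- tr$params
  manifest <- list(
    params = list(k = p$k, H = p$H, L = p$L, rate = p$rate,
                  alpha = p$alpha, peakyear = p$peakyear,
                  knot_rates = as.list(stats::setNames(p$knots$rates,
                                                       p$knots$offsets)),
                  W = as.list(p$W)),
    c_scale = tr$c_scale, fit_window = tr$fit_window, seed = tr$seed,
    popmodel = unclass(popmodel))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_manifest
#' @export
simulate_from_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  pm <- do.call(population_model, c(
    man$popmodel[c("total_ref", "ref_year", "annual_growth", "age_mode",
                   "age_mode_drift", "age_sd", "age_sd_drift", "ages")],
    list(years = range(man$popmodel$years))))
  pop <- make_population(pm)
  p <- man$params
  kr <- unlist(p$knot_rates)
  truth <- parameter_set(
    k = p$k, H = p$H, L = p$L, rate = p$rate,
    alpha = if (is.numeric(p$alpha) && length(p$alpha)) p$alpha,
    peakyear = p$peakyear,
    ## the stored rates carry the fixed knots too; honour them verbatim
    knots = growth_rate_knots(kr, fixed = kr[c("-65", "-55", "-45")]),
    W = unlist(p$W))
  simulate_deaths(truth, pop, fit_window = man$fit_window,
                  c_scale = man$c_scale, seed = man$seed)
}
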