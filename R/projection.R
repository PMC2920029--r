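## Forward projection of annual deaths with credible and prediction
## intervals, peak summaries, all-ages rescaling and the lag sensitivity
## sweep.

#' Project annual mesothelioma deaths from a fitted chain
#'
#' For each retained posterior draw the full expected-death surface is
#' rebuilt over `horizon` (normalisation constant carried from the fit
#' window), summed over ages into an annual total, and a Poisson count is
#' drawn from that total.  Percentiles across draws of the expected totals
#' give the credible interval (uncertainty in the expectation); percentiles
#' of the Poisson counts give the prediction interval (parameter plus
#' sampling uncertainty).
#'
#' @param fit a [fit_mortality_model()] result (or a list with elements
#'   `chain`, `data`, `fixed`, `diagnostic_trend`, `scenario`).
#' @param pop a [mortality_surface()] with person-years covering `horizon`
#'   (future population projections merged with the fit-window population).
#' @param horizon `c(first, last)` years to project (default 1968-2050).
#' @param level interval level (default 0.90).
#' @param n_draws number of posterior draws used (evenly thinned from the
#'   chain); default all.
#' @param pred_reps Poisson replicates drawn per posterior draw for the
#'   prediction interval; default scales so at least ~2000 replicate
#'   realisations back the interval even for short (or one-draw) chains.
#' @param all_ages_factor multiplicative rescaling from the 20-89 age range
#'   to all ages, applied per draw; the default 1/0.99 reflects that about
#'   99% of male mesothelioma deaths occur at ages 20-89.
#' @param seed seed for the Poisson prediction draws.
#' @return object of class `meso_projection`: list with `table` (data.frame:
#'   `year`, `median`, `ci_lower`, `ci_upper`, `pi_lower`, `pi_upper`, and
#'   the same rescaled to all ages with prefix `all_`), `peak` (list:
#'   per-draw summaries of peak year and peak deaths), `cumulative`
#'   (summaries of per-draw totals over the horizon and over 2007 onwards),
#'   `draws_total` (draw x year matrix of expected totals, ages 20-89),
#'   `level`, `all_ages_factor`.
#' @export
project_mortality <- function(fit, pop, horizon = c(1968L, 2050L),
                              level = 0.90, n_draws = NULL,
                              pred_reps = NULL,
                              all_ages_factor = 1 / 0.99, seed = 1L) {
  chain <- fit$chain
  nd <- nrow(chain$draws)
  if (nd == 0) stop("empty chain")
  if (is.null(n_draws)) n_draws <- nd
  keep <- unique(round(seq(1, nd, length.out = min(n_draws, nd))))
  yrs <- horizon[1]:horizon[2]
  ctx <- risk_context(pop, horizon, CURVE_RANGE)
  ## normalisation constants are computed on the fit data's own surface and
  ## carried into the horizon unchanged
  ctx_fit <- risk_context(fit$data, NULL, CURVE_RANGE)
  M <- total_deaths(fit$data)
  H <- fit$fixed$H; L <- fit$fixed$L
  anchors <- c(`2000` = 0.04, `2010` = 0.02, `2050` = 0.0075)
  dn <- paste0("D.", FREE_KNOT_OFFSETS)
  wn <- paste0("W.", FREE_W_BANDS)
  iw_free <- match(FREE_W_BANDS, AGE_BANDS)
  iw_base <- match(BASELINE_BAND, AGE_BANDS)
  knot_template <- growth_rate_knots(default_knot_rates())$rates
  ik_free <- match(FREE_KNOT_OFFSETS, KNOT_OFFSETS)

  set.seed(seed)
  R <- length(keep)
  totals <- matrix(NA_real_, R, length(yrs), dimnames = list(NULL, yrs))
  for (r in seq_len(R)) {
    th <- chain$draws[keep[r], ]
    rates <- knot_template
    rates[ik_free] <- th[dn]
    D <- curve_values(rates, as.integer(th[["peakyear"]]),
                      CURVE_RANGE[1], CURVE_RANGE[2], anchors,
                      fit$scenario)
    W9 <- numeric(9L); W9[iw_free] <- th[wn]; W9[iw_base] <- 1
    alpha <- if (fit$diagnostic_trend) th[["alpha"]] else NULL
    uf <- asbestos_core(ctx_fit, W9, th[["k"]], H, L, D)
    Bf <- background_core(ctx_fit, th[["rate"]], th[["k"]], L)
    pf <- diagnostic_proportion(ctx_fit$years, alpha)
    cc <- (M - sum(t(Bf) * pf)) / sum(t(uf) * pf)
    u <- asbestos_core(ctx, W9, th[["k"]], H, L, D)
    B <- background_core(ctx, th[["rate"]], th[["k"]], L)
    p <- diagnostic_proportion(ctx$years, alpha)
    totals[r, ] <- colSums(t(t(cc * u + B) * p))
  }
  if (is.null(pred_reps)) pred_reps <- max(1L, ceiling(2000 / R))
  rep_tot <- totals[rep(seq_len(R), each = pred_reps), , drop = FALSE]
  pred <- matrix(stats::rpois(length(rep_tot), rep_tot), nrow(rep_tot))
  summarise_projection(totals, pred, yrs, level, all_ages_factor)
}

## shared summarisation so degenerate inputs (one draw) follow the same path
summarise_projection <- function(totals, pred, yrs, level,
                                 all_ages_factor) {
  a <- (1 - level) / 2
  qs <- function(m, p) apply(m, 2, stats::quantile, probs = p, names = FALSE)
  tab <- data.frame(year = yrs,
                    median = qs(totals, 0.5),
                    ci_lower = qs(totals, a), ci_upper = qs(totals, 1 - a),
                    pi_lower = qs(pred, a), pi_upper = qs(pred, 1 - a))
  f <- all_ages_factor
  tab$all_median <- tab$median * f
  tab$all_pi_lower <- qs(pred * f, a)
  tab$all_pi_upper <- qs(pred * f, 1 - a)
  pk <- peak_per_draw(totals, yrs)
  pk_pred <- peak_per_draw(pred, yrs)
  peak <- list(
    year_mode = as.numeric(names(which.max(table(pk$year)))),
    year_median = stats::median(pk$year),
    year_ci = discrete_interval(pk$year, level),
    deaths_median = stats::median(pk$value),
    deaths_ci = stats::quantile(pk$value, c(a, 1 - a), names = FALSE),
    deaths_pi = stats::quantile(pk_pred$value, c(a, 1 - a), names = FALSE),
    monotone = pk$monotone)
  cum <- function(m) {
    s <- rowSums(m)
    c(median = stats::median(s),
      lower = stats::quantile(s, a, names = FALSE),
      upper = stats::quantile(s, 1 - a, names = FALSE))
  }
  from2007 <- yrs >= 2007
  cumulative <- list(horizon = cum(totals),
                     from_2007 = if (any(from2007))
                       cum(totals[, from2007, drop = FALSE]))
  structure(list(table = tab, peak = peak, cumulative = cumulative,
                 draws_total = totals, level = level,
                 all_ages_factor = all_ages_factor),
            class = "meso_projection")
}

#' Equal-tailed interval for integer-valued draws
#'
#' For discrete draws (peak years) the interval endpoints are themselves
#' attained values: the lower endpoint is the smallest value with at least
#' `alpha` cumulative probability below-or-at it, the upper the largest
#' value with at least `alpha` probability at-or-above it.  Draws
#' `{2015 x5, 2016 x90, 2017 x5}` at the 90% level give (2015, 2017).
#'
#' @param x integer-valued draws.
#' @param level interval level.
#' @return length-2 numeric vector.
#' @export
discrete_interval <- function(x, level = 0.90) {
  a <- (1 - level) / 2
  xs <- sort(x)
  n <- length(xs)
  lo <- xs[max(1L, which(seq_len(n) / n >= a)[1])]
  hi <- rev(xs)[max(1L, which(seq_len(n) / n >= a)[1])]
  c(lo, hi)
}

## per-draw peak year (ties broken to the earlier year) and peak value
peak_per_draw <- function(m, yrs) {
  idx <- apply(m, 1, which.max)          # which.max takes the first maximum
  list(year = yrs[idx], value = m[cbind(seq_len(nrow(m)), idx)],
       monotone = all(idx == ncol(m)) || all(idx == 1L))
}

#' Peak-year and peak-deaths distributions of a projection
#'
#' Recomputes the per-draw peak (argmax year, ties to the earlier year) from
#' the stored draw-by-year totals and summarises it.  A series that is
#' monotone over the horizon (no interior peak) is reported via the
#' `monotone` flag, not an error.
#'
#' @param projection a [project_mortality()] result.
#' @param level interval level.
#' @return list with `year_mode`, `year_median`, `year_ci`, `deaths_median`,
#'   `deaths_ci`, `monotone`.
#' @export
find_peak <- function(projection, level = projection$level) {
  a <- (1 - level) / 2
  yrs <- as.integer(colnames(projection$draws_total))
  pk <- peak_per_draw(projection$draws_total, yrs)
  list(year_mode = as.numeric(names(which.max(table(pk$year)))),
       year_median = stats::median(pk$year),
       year_ci = discrete_interval(pk$year, level),
       deaths_median = stats::median(pk$value),
       deaths_ci = stats::quantile(pk$value, c(a, 1 - a), names = FALSE),
       monotone = pk$monotone)
}

#' Rescale an age-20-89 death series to all ages
#'
#' Deaths outside ages 20-89 are rare (about 1% of male mesothelioma
#' deaths), so all-ages totals are obtained by a multiplicative factor,
#' default `1/0.99`.
#'
#' @param series numeric vector/matrix of 20-89 totals.
#' @param factor rescaling factor, must be `>= 1`.
#' @return rescaled series.
#' @export
rescale_all_ages <- function(series, factor = 1 / 0.99) {
  if (factor < 1) stop("all-ages rescaling factor must be >= 1")
  series * factor
}

#' @export
print.meso_projection <- function(x, ...) {
  cat("<meso_projection> ", nrow(x$draws_total), " draws x ",
      ncol(x$draws_total), " years\n", sep = "")
  cat("peak (ages 20-89): ", round(x$peak$deaths_median), " deaths in ",
      x$peak$year_mode, " (", 100 * x$level, "% CI ",
      x$peak$year_ci[1], "-", x$peak$year_ci[2], ")\n", sep = "")
  invisible(x)
}

#' Write a projection table as CSV
#'
#' Columns: year, median, credible interval, prediction interval for ages
#' 20-89, plus the all-ages rescaled series (both series are labelled
#' explicitly).
#'
#' @param projection a `meso_projection`.
#' @param path output CSV path.
#' @return the projection, invisibly.
#' @export
write_projection <- function(projection, path) {
  utils::write.csv(projection$table, path, row.names = FALSE)
  invisible(projection)
}

#' Deviance-versus-lag sensitivity sweep
#'
#' Refits the model at each candidate lag (identical priors otherwise) and
#' tabulates the deviance at the posterior-median parameters together with
#' the projected peak.  The minimum-deviance lag is flagged.
#'
#' The sweep is a local sensitivity analysis: by default each lag is refit
#' starting from `init` (typically the posterior median of a reference fit
#' of the same data), with identical priors throughout, rather than from an
#' independent global search per lag.
#'
#' @param data a [mortality_surface()] with deaths.
#' @param pop person-years surface covering the projection horizon.
#' @param lags integer candidate lags (years).
#' @param fitter function `(data, fixed, seed)` returning a `meso_fit`;
#'   default wraps [fit_mortality_model()] with `control` and `init`.
#' @param control [meso_control()] used by the default fitter (lag sweeps
#'   use a shorter chain per lag; peak-year profiling is off when an `init`
#'   is supplied since the sweep explores locally around it).
#' @param init named starting vector for the default fitter (see
#'   [fit_mortality_model()]); usually `fit_init()` of a reference fit.
#' @param horizon projection years for the peak summary.
#' @param seed base seed; lag `i` uses `seed + i`.
#' @return data.frame with columns `lag`, `deviance`, `peak_year`,
#'   `peak_deaths`, `best` (logical, minimum deviance).
#' @export
lag_sensitivity <- function(data, pop = NULL, lags = 0:15, fitter = NULL,
                            control = NULL, init = NULL,
                            horizon = c(1968L, 2050L), seed = 1L) {
  if (is.null(pop)) pop <- data
  if (is.null(control))
    control <- meso_control(n_adapt_rounds = 6, adapt_sweeps = 50,
                            n_burn = 300, n_keep = 400, n_chains = 1,
                            profile_peakyears = if (is.null(init))
                              seq(1950L, 2000L, by = 5L))
  if (is.null(fitter))
    fitter <- function(data, fixed, seed)
      fit_mortality_model(data, fixed = fixed, control = control,
                          init = init, seed = seed)
  rows <- lapply(seq_along(lags), function(i) {
    fit <- fitter(data, fixed = list(H = 1e6, L = lags[i]), seed = seed + i)
    dev <- poisson_deviance(data, fitted_median_surface(fit))
    proj <- fitted_median_surface(fit, years = horizon, pop = pop)
    tot <- colSums(proj$lambda)
    data.frame(lag = lags[i], deviance = dev,
               peak_year = as.integer(names(tot)[which.max(tot)]),
               peak_deaths = max(tot))
  })
  out <- do.call(rbind, rows)
  out$best <- out$deviance == min(out$deviance)
  out
}
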