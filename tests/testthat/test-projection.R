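## a tiny single-draw "fit" built directly from the generating truth, so
## projection behaviour can be tested without MCMC
one_draw_fit <- function(sim = fx_sim()) {
  th <- mesoproj:::params_to_vector(fx_truth())
  chain <- structure(list(draws = matrix(th, 1, length(th),
                                         dimnames = list(NULL, names(th))),
                          lp = 0, acceptance = NULL, n_burn = 0,
                          n_keep = 1, thin = 1, seed = 1),
                     class = "meso_chain")
  structure(list(chain = chain, data = sim, fixed = list(H = 1e6, L = 10),
                 diagnostic_trend = FALSE, scenario = "decline", seed = 1),
            class = "meso_fit")
}

test_that("a one-draw chain yields a zero-width CI and a Poisson PI", {
  proj <- project_mortality(one_draw_fit(), fx_pop(), seed = 2)
  tab <- proj$table
  expect_equal(tab$ci_lower, tab$median)
  expect_equal(tab$ci_upper, tab$median)
  ## the prediction interval approximates the Poisson quantile interval of
  ## the (single) expected total; check a large-count year against qpois
  y <- which(tab$year == 2005)
  lam <- tab$median[y]
  expect_equal(tab$pi_lower[y], qpois(0.05, lam), tolerance = 0.005)
  expect_equal(tab$pi_upper[y], qpois(0.95, lam), tolerance = 0.005)
  ## central 90% Poisson interval of a total of 2038 (quantile oracle)
  expect_equal(qpois(c(0.05, 0.95), 2038), c(1964, 2113))
})

test_that("prediction intervals contain credible intervals each year", {
  fit <- fx_fit()
  proj <- project_mortality(fit, fx_pop(), n_draws = 400, seed = 3)
  expect_true(all(proj$table$pi_lower <= proj$table$ci_lower + 1e-9))
  expect_true(all(proj$table$pi_upper >= proj$table$ci_upper - 1e-9))
})

test_that("doubling future person-years doubles expected deaths", {
  pop <- fx_pop()
  pop2 <- pop
  pop2$person_years <- pop$person_years * 2
  f <- one_draw_fit()
  ## same normalisation data; only the projection population changes
  p1 <- project_mortality(f, pop, horizon = c(2007, 2050), seed = 4)
  ## doubled population needs the fit window intact for normalisation, so
  ## splice: double only years > 2006
  pop2$person_years[, pop$years <= 2006] <- pop$person_years[,
    pop$years <= 2006]
  p2 <- project_mortality(f, pop2, horizon = c(2007, 2050), seed = 4)
  expect_equal(p2$table$median, 2 * p1$table$median, tolerance = 1e-10)
})

test_that("peak finding takes the first maximum and discrete-year intervals", {
  m <- matrix(c(1, 3, 3, 2), 1)                 # tie at positions 2 and 3
  pk <- mesoproj:::peak_per_draw(m, 2001:2004)
  expect_equal(pk$year, 2002)
  expect_equal(pk$value, 3)
  draws <- c(rep(2015, 5), rep(2016, 90), rep(2017, 5))
  expect_equal(discrete_interval(draws, 0.90), c(2015, 2017))
  expect_equal(discrete_interval(draws, 0.98), c(2015, 2017))
  ## monotone series flagged, not an error
  mm <- matrix(rep(1:5, 2), 2, 5, byrow = TRUE)
  expect_true(mesoproj:::peak_per_draw(mm, 2001:2005)$monotone)
})

test_that("projection peak is internally consistent with find_peak", {
  proj <- project_mortality(fx_fit(), fx_pop(), n_draws = 200, seed = 5)
  pk <- find_peak(proj)
  expect_equal(pk$year_mode, proj$peak$year_mode)
  expect_equal(pk$deaths_median, proj$peak$deaths_median)
  ## peak lies inside the horizon and its CI brackets the mode
  expect_gte(pk$year_mode, pk$year_ci[1])
  expect_lte(pk$year_mode, pk$year_ci[2])
})

test_that("all-ages rescaling is a guarded multiplicative map", {
  expect_equal(rescale_all_ages(100, 1), 100)
  expect_equal(rescale_all_ages(1990, 2038 / 1990), 2038)
  expect_error(rescale_all_ages(100, 0.9), ">= 1")
  ## applied per draw it commutes with percentile summarisation
  x <- rpois(500, 100)
  f <- 1 / 0.99
  expect_equal(quantile(rescale_all_ages(x, f), 0.95),
               rescale_all_ages(quantile(x, 0.95), f))
})

test_that("cumulative totals are per-draw sums, reported with the 2007+ share", {
  proj <- project_mortality(fx_fit(), fx_pop(), n_draws = 100, seed = 6)
  expect_lt(proj$cumulative$from_2007[["median"]],
            proj$cumulative$horizon[["median"]])
  ## consistency: median of row sums equals the reported median
  expect_equal(proj$cumulative$horizon[["median"]],
               median(rowSums(proj$draws_total)))
})

test_that("projection tables are written in the standard CSV layout", {
  proj <- project_mortality(one_draw_fit(), fx_pop(), seed = 7)
  f <- withr::local_tempfile(fileext = ".csv")
  write_projection(proj, f)
  df <- read.csv(f)
  expect_true(all(c("year", "median", "ci_lower", "ci_upper", "pi_lower",
                    "pi_upper", "all_median") %in% names(df)))
  expect_equal(df$year, 1968:2050)
})

test_that("missing future population years are an error", {
  f <- one_draw_fit()
  short_pop <- fx_sim()                          # only covers 1968-2006
  expect_error(project_mortality(f, short_pop, horizon = c(1968, 2050)),
               "cover")
})

test_that("lag sweep refits locally and flags the minimum-deviance lag", {
  ## local sweep around the generating truth with short chains: exercises
  ## the machinery (the full-strength self-consistency study lives in the
  ## acceptance suite)
  sim <- fx_sim()
  tab <- lag_sensitivity(sim, fx_pop(), lags = c(0, 10, 15),
                         control = meso_control(n_adapt_rounds = 4,
                                                adapt_sweeps = 40,
                                                n_burn = 150, n_keep = 200,
                                                profile_peakyears = NULL),
                         init = mesoproj:::params_to_vector(fx_truth()),
                         seed = 2)
  expect_equal(nrow(tab), 3)
  expect_equal(sum(tab$best), 1)
  expect_equal(tab$deviance[tab$best], min(tab$deviance))
  expect_true(all(tab$peak_year %in% 1968:2050))
  ## single lag: one row
  one <- lag_sensitivity(sim, fx_pop(), lags = 10,
                         control = meso_control(n_adapt_rounds = 2,
                                                adapt_sweeps = 20,
                                                n_burn = 50, n_keep = 80,
                                                profile_peakyears = NULL),
                         init = mesoproj:::params_to_vector(fx_truth()),
                         seed = 3)
  expect_equal(nrow(one), 1)
  expect_true(one$best)
})
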