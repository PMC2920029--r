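test_that("risk weight follows the lagged power of time since exposure", {
  expect_equal(risk_weight(10, L = 10, k = 2.42), 0)
  expect_equal(risk_weight(11, L = 10, k = 7.3), 1)
  expect_equal(risk_weight(30, L = 10, k = 2.42), 20^2.42)
  expect_equal(risk_weight(0:9, L = 10, k = 2), rep(0, 10))
})

test_that("clearance factor is 2^(-l/H) and vanishes slowly for huge H", {
  expect_equal(clearance_factor(0, 50), 1)
  expect_equal(clearance_factor(50, 50), 0.5)
  ## H = 1e6: virtually no clearance over a lifetime; differs from the
  ## no-clearance limit by < 1e-4 relative for l <= 100
  l <- 0:100
  expect_true(all(abs(clearance_factor(l, 1e6) - 1) < 1e-4))
})

test_that("age weights are a piecewise-constant band lookup", {
  W <- default_parameters()$W
  expect_equal(age_weight(25, W), 1)
  expect_equal(age_weight(35, W), 1.79)
  expect_equal(age_weight(c(0, 4, 5, 15, 16, 19, 89), W),
               unname(W[c(1, 1, 2, 2, 3, 3, 9)]))
  W0 <- W; W0["0-4"] <- 0
  expect_equal(age_weight(3, W0), 0)
  expect_error(age_weight(-1, W), "negative age")
})

test_that("diagnostic proportion is anchored at 98% from 1997", {
  expect_equal(diagnostic_proportion(1950:2010, alpha = 0),
               rep(0.98, 61))
  expect_equal(diagnostic_proportion(1997, alpha = 5), 0.98)
  expect_equal(diagnostic_proportion(2005, alpha = 5), 0.98)
  expect_equal(diagnostic_proportion(1987, alpha = 5),
               1 - 0.02 * 1.05^10)
  ## no diagnostic trend: everything recorded
  expect_equal(diagnostic_proportion(1970:1975, alpha = NULL), rep(1, 6))
  ## missed cases compound above 100% far enough back in time
  expect_error(diagnostic_proportion(1900, alpha = 5), "p_T")
})

test_that("vectorised asbestos surface equals the brute-force loop oracle", {
  params <- default_parameters()
  curve <- build_exposure_curve(params$knots, params$peakyear)
  for (n in c(5, 10)) {
    toy <- fx_toy_surface(n, n, seed = n)
    u <- asbestos_surface(params, curve, toy)
    u0 <- oracle_asbestos(params, curve, toy)
    expect_equal(u, u0, tolerance = 1e-10)
  }
})

test_that("zero exposure gives a zero asbestos surface", {
  params <- default_parameters()
  curve <- build_exposure_curve(params$knots, params$peakyear)
  curve$D[] <- 0
  toy <- fx_toy_surface()
  expect_true(all(asbestos_surface(params, curve, toy) == 0))
})

test_that("an exposure impulse propagates as (l - L)^k along a cohort", {
  ## D = 1 in a single year y0, 0 elsewhere: a person aged a0 in y0 has,
  ## at death l years later, risk P * W(a0) * 2^(-l/H) * (l - L)^k
  params <- default_parameters()
  curve <- build_exposure_curve(params$knots, params$peakyear)
  y0 <- 1950
  curve$D[] <- 0; curve$D[curve$years == y0] <- 1
  pop <- mortality_surface(20:89, 1968:2006,
                          person_years = matrix(1, 70, 39))
  u <- asbestos_surface(params, curve, pop)
  a0 <- 30                               # age at the impulse
  for (Td in c(1968, 1980, 2006)) {
    l <- Td - y0
    A <- a0 + l
    expect_equal(u[as.character(A), as.character(Td)],
                 age_weight(a0, params$W) * 2^(-l / params$H) *
                   risk_weight(l, params$L, params$k))
  }
})

test_that("exposure before birth contributes nothing", {
  params <- default_parameters()
  curve <- build_exposure_curve(params$knots, params$peakyear)
  ## impulse before this cohort's birth year
  curve$D[] <- 0
  curve$D[curve$years == 1930] <- 1
  pop <- mortality_surface(20:89, 1968:2006,
                          person_years = matrix(1, 70, 39))
  u <- asbestos_surface(params, curve, pop)
  ## someone aged 30 in 1968 was born in 1938: no 1930 exposure
  expect_equal(u["30", "1968"], 0)
  ## someone aged 50 in 1968 was 12 in 1930: exposed
  expect_gt(u["50", "1968"], 0)
})

test_that("background cases scale with rate and person-years", {
  toy <- fx_toy_surface()
  expect_true(all(background_surface(0, toy, k = 2.42, L = 10) == 0))
  B <- background_surface(1.08, toy, k = 2.42, L = 10)
  ## yearly totals: rate per million person-years
  expect_equal(colSums(B),
               1.08 * colSums(toy$person_years) / 1e6,
               ignore_attr = TRUE)
  ## 1.08 per million on 21.3 million person-years is ~23 cases
  expect_equal(1.08 * 21.3e6 / 1e6, 23, tolerance = 0.02)
  ## age distribution proportional to (A - L)^k: increasing in A for k > 0
  expect_true(all(diff(B[, 1]) > 0))
  props <- B[, 1] / sum(B[, 1])
  expect_equal(props,
               pmax(toy$ages - 10, 0)^2.42 / sum(pmax(toy$ages - 10, 0)^2.42),
               ignore_attr = TRUE)
})

test_that("fitted surface matches a hand-computed toy case", {
  ## 3 ages x 3 years, flat exposure, W = 1 everywhere, k = 1, no lag
  ## truncation issues: hand-compute u = P * sum_{l>L}^{A} (l - L) on D = 1
  W <- setNames(rep(1, 9), names(default_parameters()$W))
  params <- parameter_set(k = 1, H = 1e6, L = 10, rate = 0, peakyear = 1963,
                          knots = default_knot_rates(), W = W)
  curve <- build_exposure_curve(params$knots, 1963)
  curve$D[] <- 1
  py <- matrix(2, 3, 3)
  deaths <- matrix(5, 3, 3)
  pop <- mortality_surface(40:42, 2000:2002, deaths, py)
  fs <- fitted_surface(params, curve, pop, normalise = FALSE, c_scale = 1)
  for (i in 1:3) {
    A <- 39 + i
    hand <- 2 * sum(2^(-(0:A) / 1e6) * pmax((0:A) - 10, 0))
    expect_equal(unname(fs$lambda[i, 1]), hand, tolerance = 1e-12)
  }
})

test_that("normalisation makes the fitted total equal the observed total", {
  sim <- fx_sim()
  params <- default_parameters()
  curve <- build_exposure_curve(params$knots, params$peakyear)
  fs <- fitted_surface(params, curve, sim, fit_window = c(1968, 2006))
  expect_equal(sum(fs$lambda), total_deaths(sim))
  expect_gt(fs$c, 0)
  ## background-only limit: zero exposure, background matching the total
  curve0 <- curve; curve0$D[] <- 0
  rate0 <- total_deaths(sim) / (sum(sim$person_years) / 1e6)
  p0 <- parameter_set(k = 2.42, rate = rate0, peakyear = 1963,
                      knots = default_knot_rates(), W = params$W)
  fs0 <- fitted_surface(p0, curve0, sim, fit_window = c(1968, 2006))
  expect_equal(sum(fs0$lambda), total_deaths(sim))
  expect_equal(fs0$lambda, fs0$background, ignore_attr = TRUE)
})

test_that("lambda is monotone in rate and in each W component", {
  toy <- fx_toy_surface()
  params <- default_parameters()
  curve <- build_exposure_curve(params$knots, params$peakyear)
  f1 <- fitted_surface(params, curve, toy, c_scale = 1e-9)
  p2 <- params; p2$rate <- params$rate * 2
  f2 <- fitted_surface(p2, curve, toy, c_scale = 1e-9)
  expect_true(all(f2$lambda >= f1$lambda))
  p3 <- params; p3$W["40-49"] <- params$W[["40-49"]] * 2
  f3 <- fitted_surface(p3, curve, toy, c_scale = 1e-9)
  expect_true(all(f3$lambda >= f1$lambda))
  expect_gt(sum(f3$lambda), sum(f1$lambda))
})

test_that("surfaces round-trip through CSV bit-identically", {
  sim <- fx_sim()
  d <- withr::local_tempfile(fileext = ".csv")
  p <- withr::local_tempfile(fileext = ".csv")
  write_mortality_surface(sim, p, d)
  back <- read_mortality_surface(p, d)
  expect_identical(back$deaths, sim$deaths)
  expect_identical(back$person_years, sim$person_years)
  expect_identical(back$ages, sim$ages)
})
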