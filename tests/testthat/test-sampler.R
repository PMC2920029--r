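## small helpers for toy targets
toy_prior <- function(lo, hi, int = FALSE)
  list(lower = lo, upper = hi, integer = int)

test_that("proposals outside the prior support are always rejected", {
  lp <- function(theta) 0                       # flat target
  priors <- list(x = toy_prior(0, 1))
  set.seed(1)
  theta <- c(x = 0.999)
  ## huge scale: nearly every proposal leaves [0, 1]
  out <- replicate(200, mh_step(theta, "x", lp, priors, c(x = 100))$theta)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("a flat target inside the support accepts almost everything", {
  lp <- function(theta) 0
  priors <- list(x = toy_prior(-1e6, 1e6))
  ch <- run_chain(lp, c(x = 0), priors, c(x = 1), n_burn = 0,
                  n_keep = 2000, seed = 4)
  expect_gt(ch$acceptance[["x"]], 0.999)
})

test_that("chain matches the closed-form conjugate Poisson-Gamma posterior", {
  ## y_i ~ Poisson(lambda), lambda ~ Gamma(a, b): posterior
  ## Gamma(a + sum(y), b + n)
  a <- 3; b <- 1
  set.seed(11)
  y <- rpois(10, 5)
  ap <- a + sum(y); bp <- b + length(y)
  lp <- function(theta) {
    lam <- theta[["lambda"]]
    sum(dpois(y, lam, log = TRUE)) + dgamma(lam, a, b, log = TRUE)
  }
  priors <- list(lambda = toy_prior(0, Inf))
  ch <- run_chain(lp, c(lambda = 5), priors, c(lambda = 1),
                  n_burn = 1000, n_keep = 20000, seed = 5)
  x <- ch$draws[, "lambda"]
  se <- batch_se(x)
  expect_lt(abs(mean(x) - ap / bp), 3 * se)
  ## quantiles: MC error of an empirical quantile is p(1-p)/(n_eff f(q)^2);
  ## estimate n_eff from the batch-means variance inflation
  n_eff <- stats::var(x) / se^2
  for (p in c(0.05, 0.5, 0.95)) {
    q_true <- qgamma(p, ap, bp)
    se_q <- sqrt(p * (1 - p) / n_eff) / dgamma(q_true, ap, bp)
    expect_lt(abs(quantile(x, p, names = FALSE) - q_true), 3 * se_q)
  }
})

test_that("empirical stationary distribution matches a 3-state toy target", {
  ## discrete target on {1, 2, 3} with probabilities 0.2, 0.3, 0.5,
  ## sampled via the integer random-walk machinery
  pr <- c(0.2, 0.3, 0.5)
  lp <- function(theta) log(pr[theta[["s"]]])
  priors <- list(s = toy_prior(1, 3, int = TRUE))
  ch <- run_chain(lp, c(s = 2), priors, c(s = 1), n_burn = 500,
                  n_keep = 30000, seed = 6)
  freq <- tabulate(ch$draws[, "s"], 3) / 30000
  expect_equal(freq, pr, tolerance = 0.05)
})

test_that("tuning moves oversized proposal scales into the acceptance band", {
  lp <- function(theta) dnorm(theta[["x"]], log = TRUE)
  priors <- list(x = toy_prior(-50, 50))
  set.seed(7)
  tuned <- tune_proposals(lp, c(x = 0), priors, c(x = 200),
                          rounds = 12, sweeps_per_round = 200)
  expect_gte(tuned$acceptance[["x"]], 0.20)
  expect_lte(tuned$acceptance[["x"]], 0.45)
  expect_lt(tuned$proposals[["x"]], 200)
  ## a well-scaled start (acceptance comfortably inside the band) is kept
  set.seed(8)
  tuned2 <- tune_proposals(lp, c(x = 0), priors, c(x = 4),
                           rounds = 5, sweeps_per_round = 400)
  expect_equal(tuned2$proposals[["x"]], 4)
  ## integer steps never tune below 1
  lpi <- function(theta) dnorm(theta[["i"]], sd = 0.3, log = TRUE)
  set.seed(9)
  t3 <- tune_proposals(lpi, c(i = 0), list(i = toy_prior(-100, 100, TRUE)),
                       c(i = 8), rounds = 8, sweeps_per_round = 100)
  expect_gte(t3$proposals[["i"]], 1)
})

test_that("chains are reproducible and bookkeeping survives n_keep = 0", {
  lp <- function(theta) dnorm(theta[["x"]], log = TRUE)
  priors <- list(x = toy_prior(-10, 10))
  c1 <- run_chain(lp, c(x = 0), priors, c(x = 2), 100, 500, seed = 42)
  c2 <- run_chain(lp, c(x = 0), priors, c(x = 2), 100, 500, seed = 42)
  expect_identical(c1$draws, c2$draws)
  c3 <- run_chain(lp, c(x = 0), priors, c(x = 2), 100, 500, seed = 43)
  expect_false(identical(c1$draws, c3$draws))
  empty <- run_chain(lp, c(x = 0), priors, c(x = 2), 0, 0, seed = 1)
  expect_equal(nrow(empty$draws), 0)
  expect_error(summarise_chain(empty), "empty")
})

test_that("summaries use linear-interpolation percentiles and are invariant", {
  ch <- structure(list(draws = matrix(1:100, 100, 1,
                                      dimnames = list(NULL, "x"))),
                  class = "meso_chain")
  s <- summarise_chain(ch)
  expect_equal(s$median, 50.5)
  expect_equal(s$lower, 5.95)
  expect_equal(s$upper, 95.05)
  ## permutation invariance
  ch2 <- ch; ch2$draws[, 1] <- sample(100)
  expect_equal(summarise_chain(ch2)[, -1], s[, -1])
  ## constant chain: zero-width interval
  ch3 <- ch; ch3$draws[, 1] <- 7
  s3 <- summarise_chain(ch3)
  expect_equal(c(s3$median, s3$lower, s3$upper), c(7, 7, 7))
  ## integer parameter summarised by its mode
  chp <- structure(list(draws = matrix(c(rep(1963, 80), rep(1964, 20)),
                                       ncol = 1,
                                       dimnames = list(NULL, "peakyear"))),
                   class = "meso_chain")
  expect_equal(summarise_chain(chp)$mode, 1963)
})

test_that("chains persist through CSV + manifest round trip", {
  lp <- function(theta) dnorm(theta[["x"]], log = TRUE)
  ch <- run_chain(lp, c(x = 0), list(x = toy_prior(-10, 10)), c(x = 2),
                  50, 200, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_chain(ch, f)
  back <- read_chain(f)
  expect_equal(back$draws, ch$draws, tolerance = 1e-12)
  expect_equal(back$acceptance, ch$acceptance)
  expect_equal(back$seed, ch$seed)
})
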