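## Poisson likelihood, deviance and deviance-residual diagnostics.

## extract aligned (Y, lambda) matrices from surface/fitted pairs
align_obs_fit <- function(observed, fitted) {
  Y <- if (inherits(observed, "meso_surface")) observed$deaths else
    as.matrix(observed)
  lam <- if (inherits(fitted, "meso_fitted")) fitted$lambda else
    as.matrix(fitted)
  if (inherits(observed, "meso_surface") && inherits(fitted, "meso_fitted")) {
    ia <- match(observed$ages, fitted$ages)
    it <- match(observed$years, fitted$years)
    if (anyNA(ia) || anyNA(it))
      stop("fitted surface does not cover the observed grid")
    lam <- lam[ia, it, drop = FALSE]
  }
  if (!all(dim(Y) == dim(lam))) stop("observed/fitted shapes disagree")
  list(Y = Y, lam = lam)
}

#' Poisson log-likelihood of a fitted surface
#'
#' `sum over cells of [Y * log(lambda) - lambda - log(Y!)]`.  Returns
#' `-Inf` when any cell has `lambda <= 0` with `Y > 0` (an impossible
#' observation); such parameter values are rejected by the sampler.
#'
#' @param observed a [mortality_surface()] with deaths (or a bare matrix).
#' @param fitted a [fitted_surface()] result (or a bare matrix of the same
#'   shape).
#' @return scalar log-likelihood.
#' @export
poisson_log_likelihood <- function(observed, fitted) {
  a <- align_obs_fit(observed, fitted)
  if (any(a$lam < 0)) return(-Inf)
  if (any(a$lam == 0 & a$Y > 0)) return(-Inf)
  ok <- a$lam > 0
  sum(a$Y[ok] * log(a$lam[ok])) - sum(a$lam) - sum(lfactorial(a$Y))
}

#' Poisson deviance of a fitted surface
#'
#' Saturated-versus-fitted Poisson deviance
#' `2 * sum [Y * log(Y / lambda) - (Y - lambda)]`, with the convention
#' `Y * log(Y / lambda) = 0` when `Y = 0`.  Equals
#' `2 * (loglik_saturated - loglik_fitted)`.
#'
#' @inheritParams poisson_log_likelihood
#' @return scalar deviance (nonnegative for a valid fit).
#' @export
poisson_deviance <- function(observed, fitted) {
  a <- align_obs_fit(observed, fitted)
  sum(deviance_cells(a$Y, a$lam))
}

## per-cell deviance contributions
deviance_cells <- function(Y, lam) {
  term <- ifelse(Y > 0, Y * log(Y / lam), 0)
  2 * (term - (Y - lam))
}

#' Deviance residual diagnostics on aggregated cells
#'
#' Aggregates the observed and fitted surfaces over age bands and calendar
#' periods, then computes the signed deviance residual of each aggregated
#' cell, `r = sign(Y - lambda) * sqrt(deviance contribution)`.  Residuals
#' are approximately standard normal under a good fit, so about 95% should
#' lie in `[-2, 2]`.
#'
#' The default banding -- five-year age bands 20-24..85-89 crossed with nine
#' calendar periods (1968-71, eight 4-year bands, 2000-06) -- yields 126
#' cells on the standard 20-89 x 1968-2006 grid.  It is a package
#' convention, not a registry standard, and is configurable.
#'
#' @inheritParams poisson_log_likelihood
#' @param age_breaks,year_breaks left-closed break points (the last value is
#'   the exclusive upper edge) partitioning ages and years.
#' @return object of class `meso_deviance`: list with `residuals` (matrix,
#'   age band x period), `observed` and `fitted` aggregated matrices, total
#'   `deviance` (unaggregated), `in_range_fraction` (share of residuals in
#'   `[-2, 2]`) and `n_cells`.
#' @export
deviance_residuals <- function(observed, fitted,
                               age_breaks = seq(20L, 90L, 5L),
                               year_breaks = c(1968L, seq(1972L, 2000L, 4L),
                                               2007L)) {
  a <- align_obs_fit(observed, fitted)
  ages <- if (inherits(observed, "meso_surface")) observed$ages else
    seq_len(nrow(a$Y))
  yrs <- if (inherits(observed, "meso_surface")) observed$years else
    seq_len(ncol(a$Y))
  ab <- cut(ages, age_breaks, right = FALSE, include.lowest = FALSE,
            dig.lab = 4)
  yb <- cut(yrs, year_breaks, right = FALSE, dig.lab = 4)
  if (anyNA(ab) || anyNA(yb))
    stop("age/year breaks do not cover the surface")
  if (any(table(ab) == 0) || any(table(yb) == 0))
    stop("empty aggregation band")
  Yagg <- rowsum(t(rowsum(a$Y, ab)), yb)          # period x ageband
  Lagg <- rowsum(t(rowsum(a$lam, ab)), yb)
  r <- sign(Yagg - Lagg) * sqrt(deviance_cells(Yagg, Lagg))
  r <- t(r)                                        # ageband x period
  labs_a <- paste(age_breaks[-length(age_breaks)], age_breaks[-1] - 1,
                  sep = "-")
  labs_y <- paste(year_breaks[-length(year_breaks)], year_breaks[-1] - 1,
                  sep = "-")
  dimnames(r) <- list(labs_a, labs_y)
  structure(list(residuals = r,
                 observed = t(Yagg), fitted = t(Lagg),
                 deviance = sum(deviance_cells(a$Y, a$lam)),
                 in_range_fraction = mean(abs(r) <= 2),
                 n_cells = length(r)),
            class = "meso_deviance")
}

#' @export
print.meso_deviance <- function(x, ...) {
  cat("<meso_deviance> ", x$n_cells, " aggregated cells, ",
      round(100 * x$in_range_fraction, 1), "% of residuals in [-2, 2], ",
      "total deviance ", format(round(x$deviance, 1)), "\n", sep = "")
  invisible(x)
}

#' Write a deviance report as CSV
#'
#' One row per aggregated cell: age band, period, observed, fitted,
#' residual, and whether the residual lies in `[-2, 2]`.
#'
#' @param report a [deviance_residuals()] result.
#' @param path output CSV path.
#' @return the report, invisibly.
#' @export
write_deviance_report <- function(report, path) {
  df <- data.frame(age_band = rep(rownames(report$residuals),
                                  ncol(report$residuals)),
                   period = rep(colnames(report$residuals),
                                each = nrow(report$residuals)),
                   observed = as.vector(report$observed),
                   fitted = as.vector(report$fitted),
                   residual = as.vector(report$residuals),
                   in_range = as.vector(abs(report$residuals) <= 2))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(report)
}
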