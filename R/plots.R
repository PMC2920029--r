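## Simple base-graphics diagnostics: trace plots, fitted-versus-observed
## yearly totals, the exposure index, and the projection fan chart.

#' @export
plot.meso_exposure <- function(x, ...) {
  graphics::plot(x$years, x$D, type = "l", xlab = "year",
                 ylab = "relative exposure index",
                 main = "Derived population exposure", ...)
  graphics::abline(v = x$peakyear, lty = 3)
  invisible(x)
}

#' @export
plot.meso_chain <- function(x, pars = colnames(x$draws), ...) {
  pars <- intersect(pars, colnames(x$draws))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(pars)),
                       mar = c(2, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in pars)
    graphics::plot(x$draws[, p], type = "l", ylab = p, xlab = "", ...)
  invisible(x)
}

#' @export
plot.meso_projection <- function(x, observed = NULL, ...) {
  tab <- x$table
  graphics::plot(tab$year, tab$median, type = "n",
                 ylim = range(tab$pi_lower, tab$pi_upper,
                              if (!is.null(observed))
                                colSums(observed$deaths)),
                 xlab = "year", ylab = "male deaths (ages 20-89)",
                 main = "Projected annual mesothelioma deaths", ...)
  graphics::polygon(c(tab$year, rev(tab$year)),
                    c(tab$pi_lower, rev(tab$pi_upper)),
                    col = "grey85", border = NA)
  graphics::lines(tab$year, tab$median, lwd = 2)
  if (!is.null(observed))
    graphics::points(observed$years, colSums(observed$deaths), pch = 1,
                     cex = 0.6)
  invisible(x)
}

#' Fitted-versus-observed yearly totals
#'
#' @param observed a [mortality_surface()] with deaths.
#' @param fitted a [fitted_surface()] result on the same years.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, a data.frame of yearly observed and fitted totals.
#' @export
plot_fit_by_year <- function(observed, fitted, ...) {
  obs <- colSums(observed$deaths)
  fit <- colSums(fitted$lambda[, match(observed$years, fitted$years),
                               drop = FALSE])
  graphics::plot(observed$years, obs, pch = 1, xlab = "year",
                 ylab = "male deaths", main = "Observed and fitted deaths",
                 ...)
  graphics::lines(observed$years, fit, lwd = 2)
  invisible(data.frame(year = observed$years, observed = obs, fitted = fit))
}
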