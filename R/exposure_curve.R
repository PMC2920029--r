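## Reconstruction of the relative population asbestos-exposure history D_T.
##
## The curve is parameterised by annual growth/decline rates (percent per
## year) at knot years placed in multiples of ten around the peak exposure
## year; rates at intermediate years come from linear interpolation and the
## curve itself evolves multiplicatively, anchored at D(peakyear) = 1.
## Outside the estimated range the curve follows fixed assumptions: a linear
## decline from the last estimated year to 4% of the peak in 2000, then
## linear interpolation through 2% in 2010 and 0.75% in 2050.

KNOT_OFFSETS <- c(-65L, -55L, -45L, -35L, -25L, -15L, -5L, 5L, 15L)
FIXED_KNOTS <- c(`-65` = 0, `-55` = 1000, `-45` = 100000)

#' Growth-rate knots of the exposure curve
#'
#' The exposure history is defined by percent-per-year rates of change at
#' offsets `-65, -55, ..., -5, +5, +15` years from the peak exposure year
#' (`peakyear`); the rate at the peak itself is 0 by definition.  The three
#' earliest knots are conventionally fixed (0, 1000 and 100000 percent per
#' year) to force a negligible exposure level in the distant past rising
#' steeply towards the 1930s; the remaining six are estimated.
#'
#' @param rates named numeric vector of percent-per-year rates; names are the
#'   offsets as characters (`"-35"`, `"5"`, ...).  Missing estimated knots are
#'   an error; the fixed knots may be omitted and default to their
#'   conventional values.
#' @param fixed named numeric vector giving the fixed early knots (default
#'   `c("-65" = 0, "-55" = 1000, "-45" = 1e5)`).  Override here if a
#'   different transcription of the steepest fixed rate is wanted.
#' @return object of class `meso_knots`: list with `offsets`, `rates` and
#'   logical `fixed_mask` (all in offset order).
#' @export
#' @examples
#' growth_rate_knots(default_knot_rates())
growth_rate_knots <- function(rates, fixed = FIXED_KNOTS) {
  rates <- c(rates, fixed[setdiff(names(fixed), names(rates))])
  rates[names(fixed)] <- fixed            # fixed values take precedence
  missing <- setdiff(as.character(KNOT_OFFSETS), names(rates))
  if (length(missing))
    stop("missing growth-rate knot(s) at offset(s): ",
         paste(missing, collapse = ", "))
  rates <- rates[as.character(KNOT_OFFSETS)]
  if (any(!is.finite(rates)) || any(rates <= -100))
    stop("knot rates must be finite and > -100 (exposure stays positive)")
  structure(list(offsets = KNOT_OFFSETS,
                 rates = unname(rates),
                 fixed_mask = KNOT_OFFSETS %in%
                   as.integer(names(fixed))),
            class = "meso_knots")
}

#' Reference growth-rate knots
#'
#' Posterior-median growth rates for British male mesothelioma mortality
#' (peak exposure year 1963), used as package defaults and as generating
#' truth for synthetic data.
#'
#' @return named numeric vector of percent-per-year rates by offset.
#' @export
default_knot_rates <- function() {
  c(`-65` = 0, `-55` = 1000, `-45` = 100000,
    `-35` = -91.3, `-25` = 104.6, `-15` = -25.5, `-5` = 36.6,
    `5` = -7.5, `15` = -18.6)
}

#' Interpolate yearly growth rates between knots
#'
#' Linear interpolation of the knot rates onto every calendar year of the
#' estimated range `peakyear - 65 .. peakyear + 15`, with the rate at the
#' peak year itself fixed at 0.
#'
#' @param knots a [growth_rate_knots()] object.
#' @param peakyear integer peak exposure year.
#' @return data.frame with columns `year` and `rate` (percent per year).
#' @export
interpolate_rates <- function(knots, peakyear) {
  if (!inherits(knots, "meso_knots")) knots <- growth_rate_knots(knots)
  yrs <- (peakyear - 65L):(peakyear + 15L)
  data.frame(year = yrs,
             rate = rate_per_year(knots$rates, peakyear, yrs))
}

## bare per-year rate lookup; years before peakyear-65 take the first knot's
## rate (0 under the defaults)
rate_per_year <- function(rates, peakyear, years) {
  kx <- peakyear + c(KNOT_OFFSETS, 0L)
  ky <- c(rates, 0)
  o <- order(kx)
  stats::approx(kx[o], ky[o], xout = years, rule = 2)$y
}

#' Build the relative population exposure curve
#'
#' Starting from `D(peakyear) = 1`, the curve evolves multiplicatively year
#' on year by `1 + rate(T)/100` (forwards and backwards) across the
#' estimated range `peakyear - 65 .. peakyear + 15`, using the rate at the
#' source year of each step.  Beyond the estimated range the default
#' `"decline"` scenario bridges linearly (in D) to the fixed post-2000
#' assumptions: 4% of the peak in 2000, 2% in 2010 and 0.75% in 2050, with
#' linear interpolation between anchors.  The `"levelled-1978"` scenario
#' instead holds exposure constant at its last estimated value, a
#' sensitivity variant for long-term projections.
#'
#' @inheritParams interpolate_rates
#' @param years `c(first, last)` calendar range of the curve.  The default
#'   `c(1860, 2050)` covers the lifetime exposure of every cohort on the
#'   standard 20-89 x 1968+ grid; exposure is vanishingly small before the
#'   steep fixed-rate rise anyway.
#' @param anchors named numeric vector of post-estimation exposure levels as
#'   fractions of the peak, by calendar year.
#' @param scenario `"decline"` (default) or `"levelled-1978"`.
#' @return object of class `meso_exposure`: list with `years` (integer
#'   vector), `D` (nonnegative numeric, `D[peakyear] == 1`), `peakyear`,
#'   `knots`, `scenario`.
#' @export
#' @examples
#' curve <- build_exposure_curve(growth_rate_knots(default_knot_rates()), 1963)
#' exposure_at(curve, c(1963, 2000, 2010, 2050))
build_exposure_curve <- function(knots, peakyear,
                                 years = c(1860L, 2050L),
                                 anchors = c(`2000` = 0.04, `2010` = 0.02,
                                             `2050` = 0.0075),
                                 scenario = c("decline", "levelled-1978")) {
  if (!inherits(knots, "meso_knots")) knots <- growth_rate_knots(knots)
  scenario <- match.arg(scenario)
  y0 <- as.integer(years[1]); y1 <- as.integer(years[2])
  if (y0 >= peakyear || y1 <= peakyear)
    stop("year range must bracket the peak year")
  D <- curve_values(knots$rates, peakyear, y0, y1, anchors, scenario)
  if (is.null(D)) stop("invalid growth rates: yearly multiplier <= 0 ",
                       "(a rate at or below -100 percent)")
  if (any(!is.finite(D)))
    stop("exposure curve overflowed; growth rates are too extreme")
  structure(list(years = y0:y1, D = D, peakyear = as.integer(peakyear),
                 knots = knots, scenario = scenario),
            class = "meso_exposure")
}

## fast core shared with the sampler: returns bare numeric vector over
## y0:y1, or NULL when a multiplier is non-positive (invalid parameters)
curve_values <- function(rates, peakyear, y0, y1, anchors, scenario) {
  E <- peakyear + 15L                    # last estimated year
  n <- y1 - y0 + 1L
  yrs <- y0:y1
  r <- rate_per_year(rates, peakyear, yrs)
  mult <- 1 + r / 100
  if (any(mult <= 0)) return(NULL)
  D <- numeric(n)
  ip <- peakyear - y0 + 1L               # index of peakyear
  D[ip] <- 1
  iE <- min(E, y1) - y0 + 1L
  if (iE > ip)                            # forward, source-year rates
    D[(ip + 1L):iE] <- cumprod(mult[ip:(iE - 1L)])
  if (ip > 1L)                            # backward
    D[(ip - 1L):1L] <- 1 / cumprod(rev(mult[1L:(ip - 1L)]))
  if (scenario == "levelled-1978") {
    if (y1 > E) D[(iE + 1L):n] <- D[iE]
    return(D)
  }
  ay <- as.integer(names(anchors))
  o <- order(ay)
  ay <- ay[o]; av <- unname(anchors)[o]
  a0 <- ay[1]                             # first anchor year (2000)
  if (y1 > E) {
    if (E < a0) {                         # linear bridge E -> first anchor
      j <- (E:min(a0, y1)) - y0 + 1L
      D[j] <- D[iE] + (av[1] - D[iE]) * (seq_along(j) - 1L) / (a0 - E)
      j <- which(yrs > a0)                # piecewise-linear between anchors
    } else {
      j <- which(yrs >= a0)               # assumptions override from 2000 on
    }
    if (length(j))
      D[j] <- stats::approx(ay, av, xout = yrs[j], rule = 2)$y
    ## anchor years carry the assumed values exactly, no rounding residue
    ia <- match(ay, yrs)
    ok <- !is.na(ia)
    D[ia[ok]] <- av[ok]
  }
  D
}

#' Look up exposure at given years
#'
#' @param curve a `meso_exposure`.
#' @param years integer years within the curve range.
#' @return numeric exposure levels (relative to the peak).
#' @export
exposure_at <- function(curve, years) {
  i <- match(as.integer(years), curve$years)
  if (anyNA(i))
    stop("curve does not cover year(s): ",
         paste(years[is.na(i)], collapse = ", "))
  curve$D[i]
}

#' @export
print.meso_exposure <- function(x, ...) {
  cat("<meso_exposure> years ", min(x$years), "-", max(x$years),
      ", peak year ", x$peakyear, ", scenario '", x$scenario, "'\n", sep = "")
  invisible(x)
}

#' Read / write an exposure curve as two-column CSV
#'
#' @param curve a `meso_exposure`.
#' @param path CSV path (columns `year`, `D`).
#' @param peakyear peak year recorded on reading (the year of maximal D by
#'   default).
#' @return the curve (invisibly for the writer).
#' @export
write_exposure_curve <- function(curve, path) {
  utils::write.csv(data.frame(year = curve$years,
                              D = format(curve$D, digits = 17, trim = TRUE)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(curve)
}

#' @rdname write_exposure_curve
#' @export
read_exposure_curve <- function(path, peakyear = NULL) {
  df <- utils::read.csv(path)
  if (is.null(peakyear)) peakyear <- df$year[which.max(df$D)]
  structure(list(years = as.integer(df$year), D = df$D,
                 peakyear = as.integer(peakyear), knots = NULL,
                 scenario = "imported"),
            class = "meso_exposure")
}
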