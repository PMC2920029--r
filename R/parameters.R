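## Model parameter container.  One point in parameter space: the power of
## time since exposure k, clearance half-life H, lag L, background rate,
## optional diagnostic trend alpha, the peak exposure year with its
## growth-rate knots, and the nine age-band exposure-potential weights W.

AGE_BANDS <- c("0-4", "5-15", "16-19", "20-29", "30-39", "40-49",
               "50-59", "60-64", "65+")
AGE_BAND_STARTS <- c(0L, 5L, 16L, 20L, 30L, 40L, 50L, 60L, 65L)
BASELINE_BAND <- "20-29"

#' Model parameter set
#'
#' @param k power of time since (lagged) exposure; risk grows as
#'   `(l - L)^k` with `l` years since exposure.  Dimensionless, `k >= 0`.
#' @param H clearance half-life of asbestos fibres in the lungs, years;
#'   exposure `l` years back is attenuated by `2^(-l/H)`.  The default
#'   `1e6` corresponds to virtually no clearance.
#' @param L lag in years between exposure and any contribution to risk
#'   (default 10).
#' @param rate background mesothelioma rate, cases per million person-years,
#'   for cases not attributable to asbestos.
#' @param alpha diagnostic-trend parameter: annual percent decrease in
#'   missed cases working backwards from 1997, or `NULL` (default) for a
#'   model without a diagnostic trend (all cases recorded).
#' @param peakyear integer calendar year of maximal population exposure.
#' @param knots a [growth_rate_knots()] object (or a named rate vector).
#' @param W nine nonnegative exposure-potential weights for the age bands
#'   0-4, 5-15, 16-19, 20-29, 30-39, 40-49, 50-59, 60-64, 65+, relative to
#'   the 20-29 baseline (which must equal 1).  Named or positional in band
#'   order.
#'
#' @return object of class `meso_params`.
#' @export
#' @examples
#' p <- default_parameters()
#' p$k
parameter_set <- function(k, H = 1e6, L = 10, rate, alpha = NULL,
                          peakyear, knots, W) {
  if (!inherits(knots, "meso_knots")) knots <- growth_rate_knots(knots)
  if (!is.null(names(W))) {
    miss <- setdiff(AGE_BANDS, names(W))
    if (length(miss)) stop("missing W band(s): ", paste(miss, collapse = ", "))
    W <- W[AGE_BANDS]
  }
  if (length(W) != 9) stop("W must have 9 age-band weights")
  W <- unname(as.numeric(W))
  if (any(W < 0)) stop("W weights must be nonnegative")
  if (abs(W[match(BASELINE_BAND, AGE_BANDS)] - 1) > 1e-12)
    stop("W for the baseline band ", BASELINE_BAND, " must be fixed at 1")
  if (k < 0) stop("k must be nonnegative")
  if (H <= 0) stop("H must be positive")
  if (rate < 0) stop("background rate must be nonnegative")
  structure(list(k = k, H = H, L = L, rate = rate, alpha = alpha,
                 peakyear = as.integer(peakyear), knots = knots,
                 W = stats::setNames(W, AGE_BANDS)),
            class = "meso_params")
}

#' Reference parameter values
#'
#' Posterior-median estimates for British male mesothelioma mortality
#' (1968-2006 register fit): `k = 2.42`, background rate 1.08 per million,
#' peak exposure year 1963, no clearance (`H = 1e6`), lag 10, no diagnostic
#' trend, with the matching growth-rate knots and age-band weights.  Used
#' as package defaults and as the generating truth for synthetic data.
#'
#' @return a `meso_params` object.
#' @export
default_parameters <- function() {
  parameter_set(
    k = 2.42, H = 1e6, L = 10, rate = 1.08, alpha = NULL, peakyear = 1963,
    knots = growth_rate_knots(default_knot_rates()),
    W = c(`0-4` = 0.0019, `5-15` = 0.0023, `16-19` = 0.25, `20-29` = 1,
          `30-39` = 1.79, `40-49` = 1.59, `50-59` = 0.13, `60-64` = 0.56,
          `65+` = 0.42))
}

#' @export
print.meso_params <- function(x, ...) {
  cat("<meso_params> k=", x$k, " H=", format(x$H), " L=", x$L,
      " rate=", x$rate, " peakyear=", x$peakyear,
      if (is.null(x$alpha)) " (no diagnostic trend)" else
        paste0(" alpha=", x$alpha), "\n W: ", sep = "")
  cat(paste0(names(x$W), "=", signif(x$W, 3), collapse = " "), "\n")
  invisible(x)
}

## ---- flat-vector view used by the sampler --------------------------------

FREE_W_BANDS <- setdiff(AGE_BANDS, BASELINE_BAND)
FREE_KNOT_OFFSETS <- c(-35L, -25L, -15L, -5L, 5L, 15L)

free_param_names <- function(diagnostic_trend = FALSE) {
  c("k", "rate", "peakyear",
    paste0("W.", FREE_W_BANDS),
    paste0("D.", FREE_KNOT_OFFSETS),
    if (diagnostic_trend) "alpha")
}

params_to_vector <- function(params) {
  v <- c(k = params$k, rate = params$rate, peakyear = params$peakyear,
         stats::setNames(unname(params$W[FREE_W_BANDS]),
                         paste0("W.", FREE_W_BANDS)),
         stats::setNames(
           params$knots$rates[match(FREE_KNOT_OFFSETS, params$knots$offsets)],
           paste0("D.", FREE_KNOT_OFFSETS)))
  if (!is.null(params$alpha)) v <- c(v, alpha = params$alpha)
  v
}

vector_to_params <- function(theta, template) {
  W <- template$W
  W[FREE_W_BANDS] <- theta[paste0("W.", FREE_W_BANDS)]
  rates <- template$knots$rates
  rates[match(FREE_KNOT_OFFSETS, template$knots$offsets)] <-
    theta[paste0("D.", FREE_KNOT_OFFSETS)]
  parameter_set(k = theta[["k"]], H = template$H, L = template$L,
                rate = theta[["rate"]],
                alpha = if ("alpha" %in% names(theta)) theta[["alpha"]],
                peakyear = theta[["peakyear"]],
                knots = growth_rate_knots(
                  stats::setNames(rates, template$knots$offsets)),
                W = W)
}
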