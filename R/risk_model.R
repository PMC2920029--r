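## Expected death surface lambda[A, T].
##
## A cohort dying at age A in year T accumulated exposure over its lifetime:
## l years before death it was aged A - l and received dose
## W(A - l) * D(T - l), attenuated by fibre clearance 2^(-l/H) and weighted
## by the power-of-time risk kernel (l - L)^k (zero within the lag L).
## Summing these contributions over l = 0..A and multiplying by person-years
## gives the asbestos component; a background component distributes
## rate-per-million cases over ages proportionally to (A - L)^k; the
## diagnostic proportion p_T thins both to recorded deaths.

#' Power-of-time risk weight
#'
#' Contribution weight of exposure `l` years before death: `(l - L)^k` for
#' `l > L`, zero otherwise (exposure within the lag contributes nothing).
#'
#' @param l integer years since exposure (may be a vector).
#' @param L lag in years.
#' @param k power of time since exposure.
#' @return nonnegative weights.
#' @export
#' @examples
#' risk_weight(0:15, L = 10, k = 2.42)
risk_weight <- function(l, L, k) {
  ifelse(l > L, pmax(l - L, 0)^k, 0)
}

#' Clearance attenuation factor
#'
#' Fraction of fibres from an exposure `l` years ago still retained in the
#' lungs: `2^(-l/H)` for half-life `H`.
#'
#' @param l years since exposure.
#' @param H clearance half-life in years (`H = 1e6` means virtually no
#'   clearance).
#' @return factors in (0, 1].
#' @export
clearance_factor <- function(l, H) {
  stopifnot(H > 0, all(l >= 0))
  2^(-l / H)
}

#' Age-specific exposure-potential weight
#'
#' Piecewise-constant lookup of the nine-band weight vector `W` at single
#' ages.
#'
#' @param A integer age(s), `0 <= A <= 120`.
#' @param W nine-band weight vector (see [parameter_set()]).
#' @return weights.
#' @export
age_weight <- function(A, W) {
  if (any(A < 0)) stop("negative age")
  if (!is.null(names(W))) W <- W[AGE_BANDS]
  unname(W[findInterval(A, AGE_BAND_STARTS)])
}

#' Diagnostic completeness proportion
#'
#' Proportion `p_T` of true mesothelioma deaths recorded in year `T`.
#' Diagnosis is assumed essentially complete (98%) from 1997 onwards; going
#' backwards the fraction of missed cases grows by `alpha` percent per year:
#' `missed(T) = 0.02 * (1 + alpha/100)^(1997 - T)` for `T < 1997`.
#'
#' @param T calendar year(s).
#' @param alpha annual percent decrease in missed cases (forward in time),
#'   or `NULL` for a model without a diagnostic trend (`p_T = 1`).
#' @param floor lower bound applied to `p_T` (an error if reached with
#'   `floor <= 0` disallowed states).
#' @return proportions in (0, 1].
#' @export
#' @examples
#' diagnostic_proportion(1987, alpha = 5)
diagnostic_proportion <- function(T, alpha, floor = 1e-6) {
  if (is.null(alpha)) return(rep(1, length(T)))
  p <- ifelse(T >= 1997, 0.98,
              1 - 0.02 * (1 + alpha / 100)^(1997 - T))
  if (any(p <= 0)) stop("diagnostic proportion p_T <= 0 for alpha = ", alpha)
  pmax(p, floor)
}

## ---- vectorised surface core ---------------------------------------------

## Precomputed index structures for repeated lambda evaluations on a fixed
## age/year grid against a fixed exposure-curve year range.
risk_context <- function(pop, years = NULL, curve_years) {
  cols <- surface_year_cols(pop, years)
  ages <- pop$ages
  yrs <- pop$years[cols]
  lmax <- max(ages)
  l <- 0:lmax
  AmL <- outer(ages, l, "-")            # age at exposure (may be < 0)
  valid <- which(AmL >= 0)
  if (min(yrs) - lmax < curve_years[1])
    stop("exposure curve must start at or before year ", min(yrs) - lmax)
  if (max(yrs) > curve_years[2])
    stop("exposure curve must extend to year ", max(yrs))
  list(ages = ages, years = yrs, P = pop$person_years[, cols, drop = FALSE],
       l = l, valid = valid, age_at_exposure = AmL[valid] + 1L,
       band_of_age = findInterval(0:lmax, AGE_BAND_STARTS),
       ## idxD[l+1, t]: position of year T - l in the curve vector
       idxD = outer(-l, yrs, "+") - curve_years[1] + 1L,
       nA = length(ages), nL = lmax + 1L, nT = length(yrs))
}

## unnormalised asbestos surface u[A, T] given bare inputs; D is the curve
## value vector aligned with ctx$idxD
asbestos_core <- function(ctx, W9, k, H, L, D) {
  g <- 2^(-ctx$l / H) * risk_weight(ctx$l, L, k)
  Wfull <- W9[ctx$band_of_age]
  Wmat <- matrix(0, ctx$nA, ctx$nL)
  Wmat[ctx$valid] <- Wfull[ctx$age_at_exposure]
  Dmat <- matrix(D[ctx$idxD], ctx$nL, ctx$nT)
  ctx$P * (Wmat %*% (Dmat * g))
}

## background surface B[A, T] given bare inputs
background_core <- function(ctx, rate, k, L) {
  bprop <- pmax(ctx$ages - L, 0)^k
  s <- sum(bprop)
  if (s == 0) return(matrix(0, ctx$nA, ctx$nT))
  outer(bprop / s, rate * colSums(ctx$P) / 1e6)
}

#' Unnormalised asbestos-attributable surface
#'
#' Computes `u[A, T] = P[A, T] * sum_{l=0}^{A} W(A - l) * D(T - l) *
#' 2^(-l/H) * risk_weight(l, L, k)`: the relative expected asbestos-related
#' deaths before scaling by the normalisation constant.  Exposure before
#' birth contributes nothing (the sum stops at `l = A`).
#'
#' @param params a [parameter_set()].
#' @param curve a [build_exposure_curve()] result covering
#'   `min(years) - max(ages) .. max(years)`.
#' @param pop a [mortality_surface()] providing person-years.
#' @param years optional `c(first, last)` restriction of the output years.
#' @return matrix over `ages x years` (with dimnames).
#' @export
asbestos_surface <- function(params, curve, pop, years = NULL) {
  ctx <- risk_context(pop, years, range(curve$years))
  u <- asbestos_core(ctx, unname(params$W), params$k, params$H, params$L,
                     curve$D)
  dimnames(u) <- list(ctx$ages, ctx$years)
  u
}

#' Background-case surface
#'
#' Cases not attributable to asbestos: `rate` per million person-years
#' overall each year, distributed over ages proportionally to
#' `max(A - L, 0)^k` (normalised within year).
#'
#' @param rate background rate, cases per million person-years.
#' @param pop a [mortality_surface()] providing person-years.
#' @param k,L power of time and lag, shaping the age distribution.
#' @param years optional year-range restriction.
#' @return matrix `B[A, T]`.
#' @export
background_surface <- function(rate, pop, k, L, years = NULL) {
  stopifnot(rate >= 0)
  ctx <- risk_context(pop, years, c(-Inf, Inf))
  B <- background_core(ctx, rate, k, L)
  dimnames(B) <- list(ctx$ages, ctx$years)
  B
}

#' Expected recorded-death surface
#'
#' Assembles `lambda[A, T] = p_T * (c * u[A, T] + B[A, T])` from the
#' asbestos component `u`, the background component `B` and the diagnostic
#' proportion `p_T`.  With `normalise = TRUE` (the default) the
#' normalisation constant is chosen so the fitted total over the fit window
#' equals the observed total `M`:
#' `c = (M - sum(p * B)) / sum(p * u)`; with an explicit `c_scale` the
#' surface is evaluated at that absolute scale instead (as the synthetic
#' generator does).
#'
#' @inheritParams asbestos_surface
#' @param normalise scale the asbestos component so the fitted total equals
#'   the observed total over `fit_window` (requires deaths on `pop`).
#' @param c_scale explicit normalisation constant, overriding `normalise`.
#' @param fit_window `c(first, last)` years over which the observed total is
#'   matched; default the full extent of `pop`'s deaths.
#' @param years years on which to evaluate the surface (may extend beyond
#'   the fit window for projection; the constant from the fit window is
#'   carried forward unchanged).
#' @return object of class `meso_fitted`: list with matrices `lambda`,
#'   `asbestos` (`u`), `background` (`B`), vector `p` (by year), scalar `c`,
#'   plus the grid (`ages`, `years`).
#' @export
fitted_surface <- function(params, curve, pop, normalise = TRUE,
                           c_scale = NULL, fit_window = NULL, years = NULL) {
  ctx <- risk_context(pop, years, range(curve$years))
  u <- asbestos_core(ctx, unname(params$W), params$k, params$H, params$L,
                     curve$D)
  B <- background_core(ctx, params$rate, params$k, params$L)
  p <- diagnostic_proportion(ctx$years, params$alpha)
  if (is.null(c_scale)) {
    if (!normalise) {
      c_scale <- 1
    } else {
      if (is.null(pop$deaths))
        stop("normalisation requires observed deaths on 'pop'")
      if (is.null(fit_window)) fit_window <- range(pop$years)
      fc <- which(ctx$years >= fit_window[1] & ctx$years <= fit_window[2])
      if (length(fc) != fit_window[2] - fit_window[1] + 1)
        stop("evaluation years do not cover the fit window")
      M <- total_deaths(pop, fit_window)
      pu <- sum(t(u[, fc, drop = FALSE]) * p[fc])
      pB <- sum(t(B[, fc, drop = FALSE]) * p[fc])
      if (pu <= 0 && M > pB)
        stop("normalisation impossible: asbestos component is zero but ",
             "observed deaths exceed background")
      c_scale <- if (pu > 0) (M - pB) / pu else 0
    }
  }
  lambda <- t(t(c_scale * u + B) * p)
  dn <- list(ctx$ages, ctx$years)
  dimnames(lambda) <- dimnames(u) <- dimnames(B) <- dn
  structure(list(lambda = lambda, asbestos = u, background = B,
                 p = p, c = c_scale, ages = ctx$ages, years = ctx$years),
            class = "meso_fitted")
}

#' @export
print.meso_fitted <- function(x, ...) {
  cat("<meso_fitted> ", nrow(x$lambda), " ages x ", ncol(x$lambda),
      " years, total fitted ", format(round(sum(x$lambda), 1)),
      ", c = ", format(x$c, digits = 4), "\n", sep = "")
  invisible(x)
}
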