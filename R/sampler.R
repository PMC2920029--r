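## Component-wise random-walk Metropolis-Hastings.
##
## The sampler is generic: it walks a named parameter vector under box
## (uniform-support) constraints against any log-posterior function, one
## parameter at a time in a fixed sweep order.  Integer-valued parameters
## (the peak exposure year) take symmetric integer steps.  Proposal scales
## are tuned in a pilot phase towards an acceptance band of 20-45% and then
## frozen before burn-in; adaptation never overlaps retained samples.

#' Prior specification
#'
#' Uniform box priors for the free model parameters: `k ~ U(0, 10)`, each
#' age weight `W ~ U(0, 10)`, each growth-rate knot `~ U(-100, 200)`,
#' background rate `~ U(0, 20)` (cases per million), `peakyear` discrete
#' uniform on integers 1950-2000, and (when the diagnostic trend is on)
#' `alpha ~ U(-7, 9)` percent per year.
#'
#' @param diagnostic_trend include the diagnostic-trend parameter `alpha`.
#' @return named list, one element per free parameter:
#'   `list(lower, upper, integer)`.
#' @export
default_priors <- function(diagnostic_trend = FALSE) {
  pr <- function(lo, hi, int = FALSE) list(lower = lo, upper = hi,
                                           integer = int)
  p <- c(list(k = pr(0, 10), rate = pr(0, 20),
              peakyear = pr(1950, 2000, int = TRUE)),
         stats::setNames(rep(list(pr(0, 10)), length(FREE_W_BANDS)),
                         paste0("W.", FREE_W_BANDS)),
         stats::setNames(rep(list(pr(-100, 200)),
                             length(FREE_KNOT_OFFSETS)),
                         paste0("D.", FREE_KNOT_OFFSETS)))
  if (diagnostic_trend) p$alpha <- pr(-7, 9)
  p
}

#' Initial random-walk proposal scales
#'
#' Starting standard deviations for the per-parameter normal random-walk
#' proposals (integer step size for `peakyear`); [tune_proposals()] adapts
#' them to the 20-45% acceptance band.
#'
#' @inheritParams default_priors
#' @return named numeric vector of proposal scales.
#' @export
default_proposals <- function(diagnostic_trend = FALSE) {
  s <- c(k = 0.1, rate = 0.3, peakyear = 2,
         stats::setNames(rep(0.3, length(FREE_W_BANDS)),
                         paste0("W.", FREE_W_BANDS)),
         stats::setNames(rep(5, length(FREE_KNOT_OFFSETS)),
                         paste0("D.", FREE_KNOT_OFFSETS)))
  if (diagnostic_trend) s <- c(s, alpha = 0.5)
  s
}

in_support <- function(theta, priors) {
  all(vapply(names(priors), function(nm) {
    v <- theta[[nm]]
    v >= priors[[nm]]$lower && v <= priors[[nm]]$upper
  }, logical(1)))
}

propose_component <- function(value, prior, scale) {
  if (isTRUE(prior$integer)) {
    s <- max(1L, as.integer(round(scale)))
    value + sample(c(-s:-1, 1:s), 1L)      # symmetric integer step
  } else {
    value + stats::rnorm(1L, 0, scale)
  }
}

#' One component-wise Metropolis-Hastings update
#'
#' Proposes a symmetric random-walk move of a single named component of
#' `theta` and accepts it with probability `min(1, posterior ratio)`.
#' Proposals outside the prior support are rejected outright.
#'
#' @param theta named numeric vector, the current state (must be inside the
#'   prior support with finite log-posterior).
#' @param block name of the component to update.
#' @param log_post function of the full `theta` returning the unnormalised
#'   log-posterior (for uniform priors, the log-likelihood).
#' @param priors named list as from [default_priors()] (the support).
#' @param proposals named numeric vector of proposal scales.
#' @param lp_current log-posterior at `theta`, if already known (avoids one
#'   evaluation).
#' @return list with `theta`, `lp` (its log-posterior) and logical
#'   `accepted`.
#' @export
mh_step <- function(theta, block, log_post, priors, proposals,
                    lp_current = NULL) {
  if (is.null(lp_current)) lp_current <- log_post(theta)
  if (!is.finite(lp_current))
    stop("non-finite log-posterior at the current state (block '", block,
         "')")
  cand <- theta
  cand[[block]] <- propose_component(theta[[block]], priors[[block]],
                                     proposals[[block]])
  pr <- priors[[block]]
  if (cand[[block]] < pr$lower || cand[[block]] > pr$upper)
    return(list(theta = theta, lp = lp_current, accepted = FALSE))
  lp_cand <- log_post(cand)
  if (is.finite(lp_cand) &&
      log(stats::runif(1L)) < (lp_cand - lp_current)) {
    list(theta = cand, lp = lp_cand, accepted = TRUE)
  } else {
    list(theta = theta, lp = lp_current, accepted = FALSE)
  }
}

## one full sweep over all blocks; acc is an environment-free counter vector
mh_sweep <- function(theta, lp, log_post, priors, proposals, blocks) {
  acc <- logical(length(blocks))
  for (i in seq_along(blocks)) {
    st <- mh_step(theta, blocks[i], log_post, priors, proposals, lp)
    theta <- st$theta; lp <- st$lp; acc[i] <- st$accepted
  }
  list(theta = theta, lp = lp, accepted = acc)
}

#' Tune proposal scales to the target acceptance band
#'
#' Pilot adaptation: runs short pilot sweeps, measures per-parameter
#' acceptance, and doubles/halves each scale outside the 20-45% band,
#' repeating up to `rounds` times.  The pilot chain state is returned so a
#' subsequent run can start from where adaptation left off; tuned scales are
#' frozen thereafter.  Integer steps never tune below 1.
#'
#' @inheritParams mh_step
#' @param init named numeric starting state.
#' @param target acceptance band `c(lower, upper)`.
#' @param rounds maximum adaptation rounds.
#' @param sweeps_per_round pilot sweeps per round.
#' @return list with `proposals` (tuned scales), `state` (last pilot state),
#'   `lp`, and `acceptance` (per-parameter rates of the last round).
#' @export
tune_proposals <- function(log_post, init, priors, proposals,
                           target = c(0.20, 0.45), rounds = 10,
                           sweeps_per_round = 100) {
  blocks <- names(priors)
  proposals <- proposals[blocks]
  theta <- init; lp <- log_post(theta)
  if (!is.finite(lp)) stop("non-finite log-posterior at the initial state")
  rates <- stats::setNames(rep(NA_real_, length(blocks)), blocks)
  for (r in seq_len(rounds)) {
    nacc <- stats::setNames(integer(length(blocks)), blocks)
    for (s in seq_len(sweeps_per_round)) {
      sw <- mh_sweep(theta, lp, log_post, priors, proposals, blocks)
      theta <- sw$theta; lp <- sw$lp
      nacc <- nacc + sw$accepted
    }
    rates <- nacc / sweeps_per_round
    lo <- rates < target[1]; hi <- rates > target[2]
    if (!any(lo | hi)) break
    proposals[lo] <- proposals[lo] / 2
    proposals[hi] <- proposals[hi] * 2
    for (b in blocks[priors_integer(priors)])
      proposals[b] <- max(1, proposals[b])
    proposals <- pmax(proposals, 1e-9)
  }
  stuck <- names(rates)[rates == 0 & proposals <= 1e-8]
  if (length(stuck))
    stop("proposal tuning failed: zero acceptance for ",
         paste(stuck, collapse = ", "))
  list(proposals = proposals, state = theta, lp = lp, acceptance = rates)
}

priors_integer <- function(priors) {
  vapply(priors, function(p) isTRUE(p$integer), logical(1))
}

#' Run a Metropolis-Hastings chain
#'
#' Component-wise random-walk sampling with fixed proposal scales: `n_burn`
#' burn-in sweeps followed by `n_keep` retained sweeps (optionally thinned).
#' Fully deterministic given `seed`.
#'
#' @inheritParams tune_proposals
#' @param n_burn burn-in sweeps (discarded).
#' @param n_keep retained draws.
#' @param thin keep every `thin`-th sweep after burn-in (default 1, no
#'   thinning).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return object of class `meso_chain`: list with `draws` (matrix,
#'   `n_keep` rows, one column per parameter), `lp` (log-posterior per
#'   retained draw), `acceptance` (per-parameter rates over the whole run),
#'   `n_burn`, `n_keep`, `thin`, `seed`.
#' @export
run_chain <- function(log_post, init, priors, proposals, n_burn, n_keep,
                      thin = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- names(priors)
  if (!all(blocks %in% names(init)))
    stop("init is missing parameter(s): ",
         paste(setdiff(blocks, names(init)), collapse = ", "))
  theta <- init[blocks]
  if (!in_support(theta, priors)) stop("initial state outside prior support")
  lp <- log_post(theta)
  if (!is.finite(lp)) stop("non-finite log-posterior at the initial state")
  draws <- matrix(NA_real_, n_keep, length(blocks),
                  dimnames = list(NULL, blocks))
  lps <- numeric(n_keep)
  nacc <- stats::setNames(integer(length(blocks)), blocks)
  nsweep <- n_burn + n_keep * thin
  for (s in seq_len(nsweep)) {
    sw <- mh_sweep(theta, lp, log_post, priors, proposals, blocks)
    theta <- sw$theta; lp <- sw$lp
    nacc <- nacc + sw$accepted
    if (s > n_burn && (s - n_burn) %% thin == 0) {
      i <- (s - n_burn) %/% thin
      draws[i, ] <- theta
      lps[i] <- lp
    }
  }
  structure(list(draws = draws, lp = lps,
                 acceptance = if (nsweep > 0) nacc / nsweep else
                   nacc * NA_real_,
                 n_burn = n_burn, n_keep = n_keep, thin = thin,
                 seed = seed),
            class = "meso_chain")
}

#' @export
print.meso_chain <- function(x, ...) {
  cat("<meso_chain> ", nrow(x$draws), " retained draws of ",
      ncol(x$draws), " parameters (burn-in ", x$n_burn, ", thin ",
      x$thin, ")\n", sep = "")
  cat("acceptance: ",
      paste0(colnames(x$draws), " ",
             round(100 * x$acceptance[colnames(x$draws)]), "%",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.meso_chain <- function(x, ...) as.data.frame(x$draws)

#' Posterior summaries of a chain
#'
#' Per-parameter posterior median and equal-tailed credible interval
#' (linear-interpolation percentiles).  Integer parameters (the peak
#' exposure year) are additionally summarised by their posterior mode.
#'
#' @param chain a [run_chain()] result.
#' @param level credible level (default 0.90).
#' @param integer_params names of integer-valued parameters (for the mode).
#' @return data.frame with columns `parameter`, `median`, `lower`, `upper`,
#'   `mode` (NA for continuous parameters).
#' @export
summarise_chain <- function(chain, level = 0.90,
                            integer_params = "peakyear") {
  if (nrow(chain$draws) == 0) stop("empty chain")
  a <- (1 - level) / 2
  q <- apply(chain$draws, 2, stats::quantile, probs = c(a, 0.5, 1 - a),
             names = FALSE)
  mode <- rep(NA_real_, ncol(chain$draws))
  for (nm in intersect(integer_params, colnames(chain$draws))) {
    tab <- table(chain$draws[, nm])
    mode[match(nm, colnames(chain$draws))] <-
      as.numeric(names(tab)[which.max(tab)])
  }
  data.frame(parameter = colnames(chain$draws),
             median = q[2, ], lower = q[1, ], upper = q[3, ], mode = mode,
             row.names = NULL)
}

#' @export
summary.meso_chain <- function(object, level = 0.90, ...) {
  summarise_chain(object, level = level)
}

#' Persist / restore a chain as CSV plus JSON manifest
#'
#' The draws go to CSV (one row per retained draw, one column per
#' parameter, plus `lp`); seed, burn-in, thinning and acceptance rates go to
#' a JSON manifest next to it.
#'
#' @param chain a `meso_chain`.
#' @param path CSV path; the manifest is written at `<path>.manifest.json`.
#' @return the chain, invisibly (reader: the restored `meso_chain`).
#' @export
write_chain <- function(chain, path) {
  utils::write.csv(data.frame(chain$draws, lp = chain$lp,
                              check.names = FALSE),
                   path, row.names = FALSE)
  manifest <- list(seed = chain$seed, n_burn = chain$n_burn,
                   n_keep = chain$n_keep, thin = chain$thin,
                   acceptance = as.list(chain$acceptance))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(chain)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  man <- jsonlite::read_json(paste0(path, ".manifest.json"),
                             simplifyVector = TRUE)
  draws <- as.matrix(df[, setdiff(names(df), "lp"), drop = FALSE])
  structure(list(draws = draws, lp = df$lp,
                 acceptance = unlist(man$acceptance),
                 n_burn = man$n_burn, n_keep = man$n_keep,
                 thin = man$thin, seed = man$seed),
            class = "meso_chain")
}
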