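## JSON run configuration for the simulate -> fit -> diagnose -> project
## pipeline, with cross-field validation that reports every problem found,
## not just the first.

#' Default run configuration
#'
#' A nested list mirroring the JSON configuration understood by
#' [meso_cli()]: model switches (clearance half-life `H`, lag `L`,
#' diagnostic trend, all-ages rescale factor, exposure scenario), prior
#' bounds, initial proposal scales, MCMC lengths and seed, fit window and
#' projection horizon.
#'
#' @return nested list of class `meso_config`.
#' @export
default_config <- function() {
  structure(list(
    model = list(H = 1e6, L = 10, diagnostic_trend = FALSE,
                 rescale_factor = 1 / 0.99,
                 scenario = "decline"),
    priors = lapply(default_priors(), function(p)
      list(lower = p$lower, upper = p$upper, integer = p$integer)),
    proposals = as.list(default_proposals()),
    mcmc = list(n_adapt_rounds = 12, adapt_sweeps = 100,
                n_burn = 2000, n_keep = 5000, thin = 1, seed = 1,
                n_chains = 4, profile_rounds = 2, profile_sweeps = 120),
    fit_window = c(1968L, 2006L),
    projection = list(horizon = c(1968L, 2050L), n_draws = 1000,
                      level = 0.9),
    simulate = list(target_deaths = 34000, seed = 1)),
    class = "meso_config")
}

#' Read a configuration from JSON
#'
#' Values present in the file override the defaults; unknown keys are
#' reported by [validate_config()].
#'
#' @param path JSON file.
#' @return `meso_config` list (merged over [default_config()]).
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- merge_config(unclass(default_config()), user)
  attr(cfg, "unknown_keys") <- unknown_keys(default_config(), user)
  class(cfg) <- "meso_config"
  cfg
}

merge_config <- function(base, user) {
  for (nm in intersect(names(user), names(base))) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

unknown_keys <- function(base, user, prefix = "") {
  out <- character()
  for (nm in names(user)) {
    if (!nm %in% names(base)) {
      out <- c(out, paste0(prefix, nm))
    } else if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
               !is.null(names(user[[nm]]))) {
      out <- c(out, unknown_keys(base[[nm]], user[[nm]],
                                 paste0(prefix, nm, ".")))
    }
  }
  out
}

#' Validate a run configuration
#'
#' Cross-checks the configuration and returns every error found: unknown
#' keys, unordered prior bounds, a peak-year support outside 1950-2000,
#' non-positive proposal scales or chain lengths, and (when data years are
#' known) a fit window not covered by the data.
#'
#' @param config a `meso_config` (or plain list).
#' @param data_years optional integer range of the available data years,
#'   for the fit-window check.
#' @return list with `valid` (logical) and `errors` (character vector,
#'   empty when valid).
#' @export
validate_config <- function(config, data_years = NULL) {
  errors <- character()
  unk <- attr(config, "unknown_keys")
  if (length(unk))
    errors <- c(errors, paste0("unknown config key: ", unk))
  for (nm in names(config$priors)) {
    p <- config$priors[[nm]]
    if (!is.numeric(p$lower) || !is.numeric(p$upper) ||
        p$lower >= p$upper)
      errors <- c(errors, paste0("priors.", nm,
                                 ": lower bound must be < upper bound"))
  }
  py <- config$priors$peakyear
  if (!is.null(py) && (py$lower < 1950 || py$upper > 2000))
    errors <- c(errors,
                "priors.peakyear: support must lie within 1950-2000")
  bad_sc <- names(config$proposals)[unlist(config$proposals) <= 0]
  if (length(bad_sc))
    errors <- c(errors, paste0("proposals.", bad_sc,
                               ": scale must be positive"))
  mc <- config$mcmc
  for (nm in c("n_burn", "n_keep", "thin"))
    if (!is.numeric(mc[[nm]]) || mc[[nm]] < (nm == "thin"))
      errors <- c(errors, paste0("mcmc.", nm, ": invalid value"))
  fw <- config$fit_window
  if (length(fw) != 2 || fw[1] > fw[2])
    errors <- c(errors, "fit_window: must be c(first, last) with first <= last")
  if (!is.null(data_years) && length(fw) == 2 &&
      (fw[1] < min(data_years) || fw[2] > max(data_years)))
    errors <- c(errors, paste0(
      "fit_window: ", fw[1], "-", fw[2], " not covered by data years ",
      min(data_years), "-", max(data_years)))
  hz <- config$projection$horizon
  if (length(hz) != 2 || hz[1] > hz[2])
    errors <- c(errors, "projection.horizon: must be c(first, last)")
  list(valid = length(errors) == 0, errors = errors)
}

#' Write a configuration to JSON
#'
#' @param config a `meso_config`.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
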