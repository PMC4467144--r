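#' Default run configuration
#'
#' Thresholds and settings of the published filtering procedure: ETS-specific
#' and ETS-shared target rules at |FC| >= 1.5 (shared in at least 3 of the 4
#' silencing models), phenotype include/exclude rules at |FC| > 1.2 or > 1.5
#' depending on the rule, panel percentile cuts {10, 25, 50} with minimum
#' flagged-gene counts {1, 2, 4}, and alpha = 0.05.
#'
#' @param seed integer random seed recorded in the configuration.
#' @return named list of class `"run_config"`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    specific_fc          = 1.5,
    shared_fc            = 1.5,
    shared_min_models    = 3L,
    inv_aig_include_fc   = 1.2,
    inv_aig_exclude_fc   = 1.2,
    aig_include_fc       = 1.5,
    aig_exclude_fc       = 1.2,
    invasion_include_fc  = 1.5,
    invasion_exclude_fc  = 1.2,
    panel_percentiles    = c(10, 25, 50),
    panel_k              = c(1L, 2L, 4L),
    alpha                = 0.05,
    fc_average           = "arithmetic",
    seed                 = as.integer(seed)
  ), class = "run_config")
}

#' Validate and normalize a run configuration
#'
#' Unset fields are filled with the defaults of [default_config()]; every
#' deviation from a default threshold is reported as a "non-default setting"
#' warning so parameter drift is always visible in logs. Contradictory
#' settings are aggregated into a single error.
#'
#' @param config named list of overrides (possibly empty or NULL).
#' @param quiet logical; suppress non-default warnings.
#' @return normalized `"run_config"` list.
#' @export
validate_config <- function(config = NULL, quiet = FALSE) {
  defaults <- default_config()
  if (is.null(config)) config <- list()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(config)] <- config
  errors <- character()
  fc_fields <- grep("_fc$", names(cfg), value = TRUE)
  for (f in fc_fields)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1)
      errors <- c(errors, sprintf("%s must be a fold-change >= 1", f))
  if (any(cfg$panel_percentiles <= 0 | cfg$panel_percentiles >= 100))
    errors <- c(errors, "panel_percentiles must lie strictly between 0 and 100")
  if (any(cfg$panel_k < 1))
    errors <- c(errors, "panel_k must be >= 1")
  if (length(cfg$panel_k) != length(cfg$panel_percentiles))
    errors <- c(errors, "panel_k and panel_percentiles must have equal length")
  if (cfg$shared_min_models < 1)
    errors <- c(errors, "shared_min_models must be >= 1")
  if (!cfg$fc_average %in% c("arithmetic", "geometric"))
    errors <- c(errors, "fc_average must be 'arithmetic' or 'geometric'")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    errors <- c(errors, "alpha must lie in (0, 1)")
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  if (!quiet) {
    for (f in setdiff(names(config), "seed"))
      if (!isTRUE(all.equal(cfg[[f]], defaults[[f]])))
        warning("non-default setting: ", f, call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}
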