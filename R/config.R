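#' Run configuration defaults
#'
#' The solver and campaign settings with their default values: time step
#' `dt = 0.25` days, mechanics refreshed every `mech_every = 4` steps,
#' influence threshold `eps_s = 0.1`, `n_boot = 1000` bootstrap resamples,
#' and the scenario/regimen/sampling settings of the shipped pipeline.
#' @keywords internal
config_defaults <- function() {
  list(
    scenario = list(
      shape = c(16L, 16L, 16L),
      spacing_mm = c(2, 2, 2),
      tumor_radius_mm = 8,
      peak_density_fraction = 0.6,
      perfusion = "well",
      smooth_mm = 2,
      seed = 1L
    ),
    regimen = "dox_cyc",
    solver = list(dt = 0.25, mech_every = 4L),
    sa = list(n_s = 128L, seed = 1L, eps_s = 0.1, n_boot = 1000L),
    output = list(dir = "nacdyn_out")
  )
}

merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) {
    stop("config entry '", path, "' must be a mapping", call. = FALSE)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key: '",
         paste0(sub("^\\.", "", paste0(path, ".", unknown[1]))),
         "'", call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, ".", nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills in defaults, rejects unknown keys by
#' name, and validates the numeric settings.
#'
#' @param path Path to a YAML file; an empty or missing document yields the
#'   full defaults.
#' @return A validated configuration list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- merge_config(config_defaults(), user)
  if (!is.numeric(cfg$solver$dt) || cfg$solver$dt <= 0) {
    stop("config error: solver.dt must be positive", call. = FALSE)
  }
  if (cfg$solver$mech_every < 1) {
    stop("config error: solver.mech_every must be at least 1", call. = FALSE)
  }
  if (cfg$sa$eps_s <= 0 || cfg$sa$eps_s >= 1) {
    stop("config error: sa.eps_s must lie in (0, 1)", call. = FALSE)
  }
  if (!cfg$regimen %in% c("dox_cyc", "ptx_cpt")) {
    stop("config error: regimen must be 'dox_cyc' or 'ptx_cpt'", call. = FALSE)
  }
  if (!cfg$scenario$perfusion %in% c("well", "poor")) {
    stop("config error: scenario.perfusion must be 'well' or 'poor'",
         call. = FALSE)
  }
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

#' Build the scenario described by a configuration
#'
#' @param cfg A [load_config()] result.
#' @return An `nac_scenario`.
#' @export
scenario_from_config <- function(cfg) {
  sc <- cfg$scenario
  synth_scenario(
    make_grid(sc$shape, sc$spacing_mm),
    tumor_radius_mm = sc$tumor_radius_mm,
    peak_density_fraction = sc$peak_density_fraction,
    perfusion = sc$perfusion,
    smooth_mm = sc$smooth_mm,
    seed = sc$seed
  )
}

#' Persist the resolved configuration beside run outputs
#'
#' @param cfg A configuration list.
#' @param dir Output directory.
#' @return The written path, invisibly.
#' @export
write_config <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
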