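# interface: YAML run configuration with fail-fast validation.

config_defaults <- function() {
  list(
    version = 1L,
    seed = 1L,
    output_dir = ".",
    topology = list(
      bond_k = 100, bond_r0 = 1.5, angle_k = 2, bead_radius = 1.7,
      drug_radius = 2.5, epsilon = 2, ch2_mass = 14, drug_mass = 200,
      attach_k = 4.0, attach_r0 = 0.5),
    environment = list(
      pocket_fixture = "clash_pocket_A", anchor_well_depth = 8,
      anchor_well_width = 1.0, slab_half_width = 8, slab_strength = 2,
      solvation_bonus = 0.8),
    protocol = list(
      timestep = 0.002, friction = 10, temperature = 298.15,
      ti_steps = 100000L, us_steps = 60000L, sample_stride = 10L),
    schedule = list(
      n_lambda = 9L, k_exponent = 4L, d_min = 0.5, d_max = 5.0,
      spacing = 0.5, force_constant = 4.0),
    scan = list(
      linkers = 2:8, references = c("water", "lipid"), anchor_linker = 6L)
  )
}

check_unknown_keys <- function(user, defaults, path = character(0)) {
  if (!is.list(user)) return(invisible(NULL))
  for (nm in names(user)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(defaults)) {
      stop_plafep(sprintf("unknown configuration key '%s'", here),
                  "plafep_config_error")
    }
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      check_unknown_keys(user[[nm]], defaults[[nm]], c(path, nm))
    }
  }
  invisible(NULL)
}

validate_config <- function(cfg) {
  need_pos <- list(
    "topology.bond_k" = cfg$topology$bond_k,
    "topology.bond_r0" = cfg$topology$bond_r0,
    "topology.bead_radius" = cfg$topology$bead_radius,
    "topology.drug_radius" = cfg$topology$drug_radius,
    "topology.attach_k" = cfg$topology$attach_k,
    "protocol.timestep" = cfg$protocol$timestep,
    "protocol.friction" = cfg$protocol$friction,
    "protocol.temperature" = cfg$protocol$temperature,
    "protocol.ti_steps" = cfg$protocol$ti_steps,
    "protocol.us_steps" = cfg$protocol$us_steps,
    "protocol.sample_stride" = cfg$protocol$sample_stride,
    "schedule.d_min" = cfg$schedule$d_min,
    "schedule.spacing" = cfg$schedule$spacing,
    "schedule.force_constant" = cfg$schedule$force_constant,
    "environment.anchor_well_depth" = cfg$environment$anchor_well_depth,
    "environment.slab_half_width" = cfg$environment$slab_half_width)
  for (nm in names(need_pos)) {
    v <- need_pos[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop_plafep(sprintf("invalid value for %s: must be a positive number",
                          nm), "plafep_config_error")
    }
  }
  if (cfg$schedule$d_max < cfg$schedule$d_min) {
    stop_plafep("invalid value for schedule.d_max: must be >= schedule.d_min",
                "plafep_config_error")
  }
  if (cfg$schedule$n_lambda < 2 || cfg$schedule$n_lambda > 64) {
    stop_plafep("invalid value for schedule.n_lambda: must be in [2, 64]",
                "plafep_config_error")
  }
  if (cfg$schedule$k_exponent < 1) {
    stop_plafep("invalid value for schedule.k_exponent: must be >= 1",
                "plafep_config_error")
  }
  lk <- sort(unique(as.integer(cfg$scan$linkers)))
  if (length(lk) < 2 || any(diff(lk) != 1) || min(lk) < 1 || max(lk) > 12) {
    stop_plafep(
      "invalid value for scan.linkers: need consecutive integers within [1, 12]",
      "plafep_config_error")
  }
  if (!cfg$scan$anchor_linker %in% lk) {
    stop_plafep(
      "invalid value for scan.anchor_linker: must be one of scan.linkers",
      "plafep_config_error")
  }
  if (!all(cfg$scan$references %in% c("water", "lipid"))) {
    stop_plafep(
      "invalid value for scan.references: subset of c('water', 'lipid')",
      "plafep_config_error")
  }
  invisible(cfg)
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, fills defaults explicitly (the published protocol:
#' k = 4, 9 lambda nodes, 4.0 kcal/mol/A^2 umbrella bias on a 0.5-5.0 A
#' grid), validates every physical parameter fail-fast with its field
#' path, and rejects unknown keys by name.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `run_config` list with all defaults recorded.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_plafep(sprintf("configuration file not found: %s", path),
                "plafep_config_error")
  }
  user <- yaml::read_yaml(path) %||% list()
  defaults <- config_defaults()
  check_unknown_keys(user, defaults)
  cfg <- merge_config(defaults, user)
  cfg <- validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' Write a configuration to YAML
#'
#' `load_config(write_config(cfg, path))` reproduces an identical
#' configuration.
#'
#' @param config A `run_config` (or compatible list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Turn a run configuration into a scan configuration
#'
#' @param config A `run_config` from [load_config()].
#' @param cache_dir Optional per-leg cache directory.
#' @return A [scan_config()].
#' @export
as_scan_config <- function(config, cache_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t <- config$topology
  scan_config(
    linkers = config$scan$linkers,
    references = config$scan$references,
    pocket = config$environment$pocket_fixture,
    anchor_linker = config$scan$anchor_linker,
    params = builder_params(
      bond_k = t$bond_k, bond_r0 = t$bond_r0, angle_k = t$angle_k,
      bead_radius = t$bead_radius, drug_radius = t$drug_radius,
      epsilon = t$epsilon, ch2_mass = t$ch2_mass, drug_mass = t$drug_mass,
      attach_k = t$attach_k, attach_r0 = t$attach_r0),
    schedule = mixing_schedule(config$schedule$n_lambda,
                               config$schedule$k_exponent),
    windows = window_schedule(config$schedule$d_min, config$schedule$d_max,
                              config$schedule$spacing,
                              config$schedule$force_constant),
    ti_steps = config$protocol$ti_steps,
    us_steps = config$protocol$us_steps,
    timestep = config$protocol$timestep,
    friction = config$protocol$friction,
    temperature = config$protocol$temperature,
    sample_stride = config$protocol$sample_stride,
    seed = config$seed, cache_dir = cache_dir)
}
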