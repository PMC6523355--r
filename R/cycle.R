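# cycle_assembler: thermodynamic cycles, relative rates, linker scan.

#' Combine the TI and attachment legs of one linker-modification step
#'
#' `delta_G_mod = delta_A_TI + delta_G_attach` with errors combined in
#' quadrature (TI block error and US hysteresis treated as independent).
#' The window-ensemble attachment reading is used by default because the
#' TI end state coincides with the detach window ensemble, which makes
#' telescoped and direct cycles consistent (see the methods vignette).
#'
#' @param ti A `fep_ti` result.
#' @param attach A `fep_attachment` result produced in the same environment
#'   on the same linker pair.
#' @param state One of `"initial_water"`, `"initial_lipid"`,
#'   `"final_ts_complex"`.
#' @param pair Optional integer pair `c(N, N-1)`; defaults to the TI
#'   metadata.
#' @param attach_estimate `"windows"` (default) or `"profile"`.
#' @return A `fep_state` object with `delta_G_mod`, `error`, and the
#'   components.
#' @export
state_free_energy <- function(ti, attach,
                              state = c("initial_water", "initial_lipid",
                                        "final_ts_complex"),
                              pair = NULL,
                              attach_estimate = c("windows", "profile")) {
  state <- match.arg(state)
  attach_estimate <- match.arg(attach_estimate)
  stopifnot(inherits(ti, "fep_ti"), inherits(attach, "fep_attachment"))
  pair <- pair %||% ti$meta$linker_pair
  if (!is.null(ti$meta$linker_pair) && !is.null(pair) &&
      !identical(as.integer(pair), as.integer(ti$meta$linker_pair))) {
    stop_plafep("incompatible inputs: linker pair mismatch",
                "plafep_mismatch_error")
  }
  env_expect <- switch(state, initial_water = "water_reference",
                       initial_lipid = "lipid_reference",
                       final_ts_complex = "ts_pocket")
  if (!is.na(ti$meta$environment) && ti$meta$environment != env_expect) {
    stop_plafep(sprintf(
      "incompatible inputs: TI leg was run in '%s' but state '%s' expects '%s'",
      ti$meta$environment, state, env_expect), "plafep_mismatch_error")
  }
  env_attach <- attr(attach, "environment")
  if (!is.null(env_attach) && env_attach != env_expect) {
    stop_plafep(sprintf(
      "incompatible inputs: attachment leg was run in '%s' but state '%s' expects '%s'",
      env_attach, state, env_expect), "plafep_mismatch_error")
  }
  us <- if (attach_estimate == "windows") attach$delta_G_attach_windows
        else attach$delta_G_attach
  us_err <- if (attach_estimate == "windows") attach$hysteresis_error_windows
            else attach$hysteresis_error
  structure(
    list(state = state, linker_pair = as.integer(pair),
         delta_G_mod = ti$delta_A + us,
         error = sqrt(ti$delta_A_error^2 + us_err^2),
         components = c(ti_delta_A = ti$delta_A, us_delta_G_attach = us),
         component_errors = c(ti = ti$delta_A_error, us = us_err)),
    class = "fep_state")
}

#' @export
print.fep_state <- function(x, ...) {
  cat(sprintf("<fep_state> %s, pair (%d, %d): delta_G_mod = %.4f +/- %.4f kcal/mol\n",
              x$state, x$linker_pair[1], x$linker_pair[2], x$delta_G_mod,
              x$error))
  invisible(x)
}

#' Compose a thermodynamic cycle from initial- and final-state legs
#'
#' `delta_delta_G_tr = delta_G_mod(final) - delta_G_mod(initial)`: the
#' change in transition-state binding free energy associated with the
#' linker step, with errors in quadrature.
#'
#' @param initial A `fep_state` with state `initial_water` or
#'   `initial_lipid`.
#' @param final A `fep_state` with state `final_ts_complex`.
#' @return A `fep_cycle` object.
#' @export
compose_cycle <- function(initial, final) {
  stopifnot(inherits(initial, "fep_state"), inherits(final, "fep_state"))
  if (!initial$state %in% c("initial_water", "initial_lipid")) {
    stop_plafep("initial leg must be a water or lipid reference state",
                "plafep_mismatch_error")
  }
  if (final$state != "final_ts_complex") {
    stop_plafep("final leg must be the transition-state complex",
                "plafep_mismatch_error")
  }
  if (!identical(initial$linker_pair, final$linker_pair)) {
    stop_plafep("incompatible inputs: linker pair mismatch",
                "plafep_mismatch_error")
  }
  structure(
    list(linker_pair = initial$linker_pair,
         reference = sub("initial_", "", initial$state),
         delta_delta_G_tr = final$delta_G_mod - initial$delta_G_mod,
         error = sqrt(final$error^2 + initial$error^2)),
    class = "fep_cycle")
}

#' @export
print.fep_cycle <- function(x, ...) {
  cat(sprintf(
    "<fep_cycle> pair (%d, %d), %s reference: ddG_tr = %.4f +/- %.4f kcal/mol\n",
    x$linker_pair[1], x$linker_pair[2], x$reference, x$delta_delta_G_tr,
    x$error))
  invisible(x)
}

#' Relative hydrolysis rate from a binding free-energy difference
#'
#' `exp(-dG / (R T))`: higher transition-state binding free energy maps to
#' a strictly lower relative hydrolysis rate.
#'
#' @param delta_G_difference Free-energy difference, kcal/mol.
#' @param temperature Temperature, K (> 0).
#' @return Dimensionless rate ratio.
#' @export
#' @examples
#' relative_rate(0)                       # 1
#' relative_rate(-1.3643, 298.15)         # ~10
relative_rate <- function(delta_G_difference, temperature = 298.15) {
  if (!all(is.finite(temperature)) || any(temperature <= 0)) {
    stop_plafep("temperature must be > 0", "plafep_value_error")
  }
  exp(-delta_G_difference / (GAS_CONSTANT_KCAL * temperature))
}

#' Run one linker-modification leg (TI + umbrella/WHAM) in one environment
#'
#' Builds the N-linker conjugate in the requested environment, decouples
#' `n_remove` terminal CH2 beads by TI on the mixing Hamiltonian, then runs
#' the umbrella sweep re-attaching the drug to the new linker end, solves
#' WHAM for the forward, backward, and pooled sweeps, and combines the two
#' steps into `delta_G_mod`.
#'
#' @param n_linker Linker length N of the full end state.
#' @param environment An [environment_model()].
#' @param params [builder_params()] for the conjugate.
#' @param schedule A [mixing_schedule()].
#' @param windows A [window_schedule()] tibble.
#' @param protocol_ti,protocol_us Per-node / per-window protocols; their
#'   `seed` fields are the stage roots.
#' @param n_remove Terminal beads to remove (1 or 2).
#' @param ti_detach Distance (A) at which the drug is held to the new
#'   linker end during TI; must lie on the window grid so the TI end state
#'   is one of the umbrella ensembles.  The default is the drug's natural
#'   distance to the new end before removal (`attach_r0 + n_remove *
#'   bond_r0`, snapped to the grid): the drug stays put while the CH2
#'   units vanish, keeping the alchemical perturbation small, and the
#'   umbrella step does the moving.
#' @param bin_width,wham_tolerance WHAM settings.
#' @return A `fep_leg` object: `ti`, `umbrella`, `wham` (fwd/bwd/pooled),
#'   `attach` (the full-span attachment result, attach vs detached
#'   plateau), `attach_composed` (attach vs the TI hand-over window, the
#'   component `delta_G_mod` uses), `delta_G_mod`, `error`, metadata.
#' @export
linker_leg <- function(n_linker, environment, params = builder_params(),
                       schedule = mixing_schedule(),
                       windows = window_schedule(),
                       protocol_ti, protocol_us, n_remove = 1,
                       ti_detach = NULL, bin_width = 0.1,
                       wham_tolerance = 1e-6) {
  top <- build_conjugate(n_linker, params)
  sys <- build_environment(top, environment = environment)
  detach_d <- max(windows$d0)
  attach_d <- min(windows$d0)
  if (is.null(ti_detach)) {
    natural <- params$attach_r0 + n_remove * params$bond_r0
    ti_detach <- windows$d0[which.min(abs(windows$d0 - natural))]
  }
  if (!any(abs(windows$d0 - ti_detach) < 1e-9)) {
    stop_plafep("ti_detach must coincide with an umbrella window distance",
                "plafep_config_error")
  }
  cmp <- shorten_companion(sys, n_remove = n_remove,
                           detach_distance = ti_detach)
  ti <- run_ti(sys, cmp, schedule, protocol_ti)
  us <- run_umbrella_sweep(cmp, windows, protocol_us, coords = sys$coords)
  pooled <- solve_wham(us, bin_width = bin_width, tolerance = wham_tolerance)
  fwd <- solve_wham(sweep_direction(us, "forward"), bin_width = bin_width,
                    tolerance = wham_tolerance)
  bwd <- solve_wham(sweep_direction(us, "backward"), bin_width = bin_width,
                    tolerance = wham_tolerance)
  attach <- attachment_free_energy(fwd, bwd, pooled, attach_d = attach_d,
                                   detach_d = detach_d)
  composed <- attachment_free_energy(fwd, bwd, pooled, attach_d = attach_d,
                                     detach_d = ti_detach)
  attr(attach, "environment") <- environment$kind
  attr(composed, "environment") <- environment$kind
  structure(
    list(ti = ti, umbrella = us,
         wham = list(forward = fwd, backward = bwd, pooled = pooled),
         attach = attach, attach_composed = composed,
         delta_G_mod = ti$delta_A + composed$delta_G_attach_windows,
         error = sqrt(ti$delta_A_error^2 +
                      composed$hysteresis_error_windows^2),
         meta = list(environment = environment$kind,
                     linker_pair = c(n_linker, n_linker - n_remove))),
    class = "fep_leg")
}

#' @export
print.fep_leg <- function(x, ...) {
  cat(sprintf(
    "<fep_leg> pair (%d, %d) in %s: delta_G_mod = %.4f +/- %.4f kcal/mol\n",
    x$meta$linker_pair[1], x$meta$linker_pair[2], x$meta$environment,
    x$delta_G_mod, x$error))
  invisible(x)
}

leg_state <- function(leg, state) {
  state_free_energy(leg$ti, leg$attach_composed, state = state)
}

#' Scan configuration
#'
#' Defaults are the study conditions: linker lengths 2..8, water and lipid
#' reference states, the packaged clash pocket, gauge anchor at N = 6,
#' 9-node mixing schedule with k = 4, and the 0.5-5 A umbrella grid at
#' 4.0 kcal/mol/A^2.
#'
#' @param linkers Integer vector of linker lengths (consecutive).
#' @param references Subset of `c("water", "lipid")`.
#' @param pocket A `ts_pocket` [environment_model()] or a clash-pocket
#'   fixture name (`"clash_pocket_A"`, `"clash_pocket_B"`).
#' @param anchor_linker Gauge zero of the relative profile (must be in
#'   `linkers`).
#' @param params [builder_params()].
#' @param schedule [mixing_schedule()].
#' @param windows [window_schedule()] tibble.
#' @param ti_steps,us_steps Integration steps per lambda node / per window.
#' @param timestep,friction,temperature,sample_stride Protocol settings.
#' @param seed Root seed; every stage seed derives from it.
#' @param bin_width WHAM bin width, A.
#' @param cache_dir Optional directory for resumable per-leg caches (RDS).
#' @return A `scan_config` list.
#' @export
scan_config <- function(linkers = 2:8, references = c("water", "lipid"),
                        pocket = "clash_pocket_A", anchor_linker = 6,
                        params = builder_params(),
                        schedule = mixing_schedule(),
                        windows = window_schedule(),
                        ti_steps = 100000, us_steps = 60000,
                        timestep = 0.002, friction = 10,
                        temperature = 298.15, sample_stride = 10,
                        seed = 1L, bin_width = 0.1, cache_dir = NULL) {
  linkers <- sort(unique(as.integer(linkers)))
  if (length(linkers) < 2 || any(diff(linkers) != 1)) {
    stop_plafep("scan.linkers must be at least two consecutive integers",
                "plafep_config_error")
  }
  if (!all(references %in% c("water", "lipid")) || length(references) < 1) {
    stop_plafep("scan.references must be a subset of c('water', 'lipid')",
                "plafep_config_error")
  }
  if (!(anchor_linker %in% linkers)) {
    stop_plafep("scan.anchor_linker must be one of the scanned linker lengths",
                "plafep_config_error")
  }
  if (is.character(pocket)) pocket <- make_fixture(pocket)
  stopifnot(inherits(pocket, "environment_model"), pocket$kind == "ts_pocket")
  structure(list(linkers = linkers, references = references, pocket = pocket,
                 anchor_linker = as.integer(anchor_linker), params = params,
                 schedule = schedule, windows = windows,
                 ti_steps = as.integer(ti_steps),
                 us_steps = as.integer(us_steps), timestep = timestep,
                 friction = friction, temperature = temperature,
                 sample_stride = as.integer(sample_stride),
                 seed = as.integer(seed), bin_width = bin_width,
                 cache_dir = cache_dir),
            class = "scan_config")
}

scan_environments <- function(config) {
  envs <- list(pocket = config$pocket)
  if ("water" %in% config$references) {
    envs$water <- environment_model("water_reference")
  }
  if ("lipid" %in% config$references) {
    envs$lipid <- environment_model("lipid_reference")
  }
  envs
}

run_scan_leg <- function(config, env_name, env, n_linker) {
  prot <- function(stage, steps) {
    simulation_protocol(
      steps, timestep = config$timestep, friction = config$friction,
      temperature = config$temperature, sample_stride = config$sample_stride,
      seed = derive_seed(config$seed, env_name, n_linker, stage))
  }
  cache_file <- NULL
  if (!is.null(config$cache_dir)) {
    key <- sprintf("leg_%s_N%d_seed%d_%d_%d.rds", env_name, n_linker,
                   config$seed, config$ti_steps, config$us_steps)
    cache_file <- file.path(config$cache_dir, key)
    if (file.exists(cache_file)) return(readRDS(cache_file))
  }
  leg <- linker_leg(
    n_linker, env, params = config$params, schedule = config$schedule,
    windows = config$windows, protocol_ti = prot("ti", config$ti_steps),
    protocol_us = prot("us", config$us_steps),
    bin_width = config$bin_width)
  if (!is.null(cache_file)) {
    dir.create(dirname(cache_file), showWarnings = FALSE, recursive = TRUE)
    saveRDS(leg, cache_file)
  }
  leg
}

#' Scan linker lengths and assemble relative binding free energies
#'
#' For every adjacent pair (N, N-1) in the configured range, runs the
#' two-step leg (TI removal + umbrella re-attachment) in the
#' transition-state pocket and in each reference phase, composes the
#' thermodynamic cycles, telescopes the pairwise `ddG_tr` values into a
#' relative transition-state binding free-energy profile anchored at the
#' gauge linker length, and maps the profile to relative hydrolysis rates.
#' Stage failures are recorded with their stage identity; the scan
#' continues and flags partial results.
#'
#' @param config A [scan_config()].
#' @return A `fep_scan` object whose `results` tibble has columns
#'   `reference`, `N`, `rel_G_tr` (kcal/mol), `error`, `rel_rate`.
#' @export
run_linker_scan <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  envs <- scan_environments(config)
  pair_Ns <- rev(setdiff(config$linkers, min(config$linkers)))  # N of (N, N-1)
  legs <- list()
  failures <- list()
  for (env_name in names(envs)) {
    for (N in pair_Ns) {
      key <- paste(env_name, N, sep = ":")
      legs[[key]] <- tryCatch(
        run_scan_leg(config, env_name, envs[[env_name]], N),
        error = function(e) {
          failures[[key]] <<- tibble(stage = key,
                                     message = conditionMessage(e))
          NULL
        })
    }
  }

  cycles <- list()
  results <- list()
  RT <- GAS_CONSTANT_KCAL * config$temperature
  for (ref in config$references) {
    state_i <- paste0("initial_", ref)
    ddG <- setNames(rep(NA_real_, length(pair_Ns)), pair_Ns)
    dd_err <- ddG
    for (N in pair_Ns) {
      leg_f <- legs[[paste("pocket", N, sep = ":")]]
      leg_i <- legs[[paste(ref, N, sep = ":")]]
      if (is.null(leg_f) || is.null(leg_i)) next
      cy <- compose_cycle(leg_state(leg_i, state_i),
                          leg_state(leg_f, "final_ts_complex"))
      ddG[as.character(N)] <- cy$delta_delta_G_tr
      dd_err[as.character(N)] <- cy$error
      cycles[[paste(ref, N)]] <- tibble(
        reference = ref, N = N, N_minus_1 = N - 1L,
        delta_delta_G_tr = cy$delta_delta_G_tr, error = cy$error)
    }
    # telescope: ddG(N) = G_tr(N-1) - G_tr(N), anchored at the gauge linker
    Ns <- config$linkers
    G <- setNames(rep(NA_real_, length(Ns)), Ns)
    E2 <- setNames(rep(0, length(Ns)), Ns)
    N0 <- config$anchor_linker
    G[as.character(N0)] <- 0
    for (N in sort(Ns[Ns < N0], decreasing = TRUE)) {       # downward
      up <- as.character(N + 1)
      G[as.character(N)] <- G[up] + ddG[up]
      E2[as.character(N)] <- E2[up] + dd_err[up]^2
    }
    for (N in Ns[Ns > N0]) {                                # upward
      dn <- as.character(N - 1)
      G[as.character(N)] <- G[dn] - ddG[as.character(N)]
      E2[as.character(N)] <- E2[dn] + dd_err[as.character(N)]^2
    }
    results[[ref]] <- tibble(
      reference = ref, N = Ns, rel_G_tr = unname(G),
      error = sqrt(unname(E2)),
      rel_rate = exp(-(unname(G) - 0) / RT))
  }
  out <- structure(
    list(results = dplyr::bind_rows(results),
         cycles = dplyr::bind_rows(cycles), legs = legs, config = config,
         anchor_linker = config$anchor_linker,
         temperature = config$temperature,
         gas_constant = GAS_CONSTANT_KCAL,
         incomplete = length(failures) > 0,
         failures = if (length(failures)) dplyr::bind_rows(failures)
                    else tibble(stage = character(0), message = character(0))),
    class = "fep_scan")
  out
}

#' @export
print.fep_scan <- function(x, ...) {
  cat(sprintf("<fep_scan> linkers %d..%d, references: %s%s\n",
              min(x$config$linkers), max(x$config$linkers),
              paste(x$config$references, collapse = ", "),
              if (x$incomplete) " [INCOMPLETE]" else ""))
  print(x$results)
  invisible(x)
}
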