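# umbrella_wham: biased sampling along the drug-to-linker-end distance.

#' Umbrella window schedule, forward sweep then backward sweep
#'
#' The published grid runs the bias equilibrium distance from 0.5 A to 5 A
#' and back in 0.5 A steps at 4.0 kcal/mol/A^2; each window is seeded from
#' the final frame of its predecessor (sweep continuity), which is what
#' makes forward/backward hysteresis meaningful.
#'
#' @param d_min,d_max Grid endpoints, A; `0 < d_min <= d_max`.
#' @param spacing Grid interval, A.
#' @param force_constant Bias force constant, kcal/mol/A^2.
#' @return A tibble: `window_id`, `direction` (forward/backward), `d0`,
#'   `force_constant`.  Non-divisible spans are snapped to the nearest grid
#'   with a warning.
#' @export
#' @examples
#' window_schedule()  # 10 forward + 10 backward windows
window_schedule <- function(d_min = 0.5, d_max = 5.0, spacing = 0.5,
                            force_constant = 4.0) {
  if (!(d_min > 0) || d_max < d_min) {
    stop_plafep("window grid requires 0 < d_min <= d_max",
                "plafep_range_error")
  }
  if (!(spacing > 0)) {
    stop_plafep("window spacing must be > 0", "plafep_range_error")
  }
  if (!(force_constant > 0)) {
    stop_plafep("window force_constant must be > 0", "plafep_range_error")
  }
  if (d_min == d_max) {
    return(tibble(window_id = 1L, direction = "forward", d0 = d_min,
                  force_constant = force_constant))
  }
  span <- d_max - d_min
  if (spacing > span) {
    warn("window spacing exceeds the span; emitting endpoint-only schedule",
         class = "plafep_grid_warning")
    grid <- c(d_min, d_max)
  } else {
    n_int <- round(span / spacing)
    if (abs(n_int * spacing - span) > 1e-9) {
      warn(sprintf(
        "window span is not divisible by spacing; snapping to %d intervals",
        n_int), class = "plafep_grid_warning")
    }
    grid <- d_min + (span / n_int) * (0:n_int)
  }
  fwd <- tibble(direction = "forward", d0 = grid)
  bwd <- tibble(direction = "backward", d0 = rev(grid))
  out <- dplyr::bind_rows(fwd, bwd)
  out$window_id <- seq_len(nrow(out))
  out$force_constant <- force_constant
  out[, c("window_id", "direction", "d0", "force_constant")]
}

#' Run an umbrella-sampling sweep
#'
#' For each window the bias equilibrium distance is set, the system is
#' propagated, and the biased reaction coordinate (the drug-to-linker-end
#' distance, or the fixture's designated coordinate) is recorded after the
#' equilibration discard.  Windows run in schedule order, each starting
#' from its predecessor's final frame; RNG seeds are derived per window
#' from the protocol seed.
#'
#' @param system A `fep_system` carrying an umbrella bias handle (conjugate
#'   systems bias the drug attachment bond).
#' @param schedule A [window_schedule()] tibble.
#' @param protocol Per-window [simulation_protocol()]; its `seed` is the
#'   stage root.
#' @param coords Optional starting coordinates for the first window.
#' @return A `fep_umbrella` object: windows tibble with a `samples`
#'   list-column, protocol and temperature.
#' @export
run_umbrella_sweep <- function(system, schedule = window_schedule(),
                               protocol = NULL, coords = NULL) {
  stopifnot(inherits(system, "fep_system"))
  if (is.null(protocol)) {
    stop_plafep("run_umbrella_sweep requires a simulation_protocol",
                "plafep_value_error")
  }
  n_samp <- (protocol$n_steps - protocol$equilibration_steps) %/%
    protocol$sample_stride
  if (n_samp < 1) {
    stop_plafep("insufficient data: protocol yields zero samples per window",
                "plafep_data_error")
  }
  if (is.null(system$umbrella)) {
    stop_plafep("system has no umbrella bias handle", "plafep_value_error")
  }
  coords <- coords %||% system$coords
  obs <- list(rc = bias_observable(system))
  out <- vector("list", nrow(schedule))
  for (w in seq_len(nrow(schedule))) {
    sys_w <- set_bias_distance(system, schedule$d0[w],
                               schedule$force_constant[w])
    prot_w <- protocol
    prot_w$seed <- derive_seed(protocol$seed, "us", schedule$direction[w],
                               format(schedule$d0[w], digits = 10))
    tr <- tryCatch(
      run_simulation(sys_w, prot_w, observables = obs, coords = coords),
      error = function(e) {
        stop_plafep(sprintf("window %d (d0 = %.2f A): %s", w,
                            schedule$d0[w], conditionMessage(e)),
                    "plafep_window_error")
      })
    coords <- tr$final_coords
    out[[w]] <- tr$scalars$rc
  }
  windows <- schedule
  windows$samples <- out
  windows$n_samples <- vapply(out, length, integer(1))
  structure(list(windows = windows, protocol = protocol,
                 temperature = protocol$temperature),
            class = "fep_umbrella")
}

#' @export
print.fep_umbrella <- function(x, ...) {
  cat(sprintf("<fep_umbrella> %d windows (%s), %d samples each\n",
              nrow(x$windows),
              paste(unique(x$windows$direction), collapse = "+"),
              x$windows$n_samples[1]))
  invisible(x)
}

#' Subset an umbrella sweep by direction
#'
#' @param umbrella A `fep_umbrella`.
#' @param direction `"forward"` or `"backward"`.
#' @return A `fep_umbrella` containing only the requested sweep.
#' @export
sweep_direction <- function(umbrella, direction) {
  stopifnot(inherits(umbrella, "fep_umbrella"))
  out <- umbrella
  out$windows <- umbrella$windows[umbrella$windows$direction == direction, ]
  out
}
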