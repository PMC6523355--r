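# dynamics_engine: energies, forces, Langevin sampling, error estimation.

#' Potential energy of a system at given coordinates
#'
#' @param system A `fep_system`.
#' @param coords Optional n x 3 coordinate matrix (A); defaults to the
#'   system's stored coordinates.
#' @return Total potential energy, kcal/mol.
#' @export
potential_energy <- function(system, coords = NULL) {
  stopifnot(inherits(system, "fep_system"))
  cpp_energy(system$termset, coords %||% system$coords)$total
}

#' Potential energy broken down by term type
#'
#' @inheritParams potential_energy
#' @return A one-row tibble with columns `bond`, `angle`, `pair`, `wall`,
#'   `anchor`, `slab`, `restraint`, `external`, `total` (kcal/mol).
#' @export
energy_components <- function(system, coords = NULL) {
  stopifnot(inherits(system, "fep_system"))
  e <- cpp_energy(system$termset, coords %||% system$coords)
  dplyr::bind_cols(as_tibble(as.list(e$components)), tibble(total = e$total))
}

#' Forces on all beads
#'
#' Analytic negative gradient of [potential_energy()].
#'
#' @inheritParams potential_energy
#' @return An n x 3 matrix, kcal/mol/A.
#' @export
forces <- function(system, coords = NULL) {
  stopifnot(inherits(system, "fep_system"))
  cpp_forces(system$termset, coords %||% system$coords)
}

#' Sampling protocol for Langevin dynamics
#'
#' BAOAB-discretised Langevin dynamics; defaults are 2 fs steps, friction
#' 1/ps, 298.15 K, with the first 20% of steps discarded as equilibration.
#' `temperature = 0` is accepted as the quench limit.
#'
#' @param n_steps Total integration steps.
#' @param timestep Timestep, ps.
#' @param friction Langevin friction, 1/ps.
#' @param temperature Temperature, K.
#' @param equilibration_steps Steps discarded before sampling
#'   (default `floor(0.2 * n_steps)`).
#' @param sample_stride Record every `sample_stride`-th step.
#' @param seed Integer RNG seed; identical seed and inputs reproduce the
#'   scalar series bit-exactly.
#' @return A `simulation_protocol` list.
#' @export
#' @examples
#' simulation_protocol(1000, seed = 7)
simulation_protocol <- function(n_steps, timestep = 0.002, friction = 1.0,
                                temperature = 298.15,
                                equilibration_steps = NULL,
                                sample_stride = 10, seed = 1L) {
  equilibration_steps <- equilibration_steps %||% floor(0.2 * n_steps)
  p <- list(n_steps = as.integer(n_steps), timestep = timestep,
            friction = friction, temperature = temperature,
            equilibration_steps = as.integer(equilibration_steps),
            sample_stride = as.integer(sample_stride),
            seed = as.integer(seed))
  if (!is.finite(p$timestep) || p$timestep <= 0) {
    stop_plafep("protocol.timestep must be > 0", "plafep_value_error")
  }
  if (!is.finite(p$friction) || p$friction <= 0) {
    stop_plafep("protocol.friction must be > 0", "plafep_value_error")
  }
  if (!is.finite(p$temperature) || p$temperature < 0) {
    stop_plafep("protocol.temperature must be >= 0", "plafep_value_error")
  }
  if (p$n_steps < 1) {
    stop_plafep("protocol.n_steps must be >= 1", "plafep_value_error")
  }
  if (p$equilibration_steps >= p$n_steps) {
    stop_plafep("protocol.equilibration_steps must be < n_steps",
                "plafep_value_error")
  }
  if (p$sample_stride < 1) {
    stop_plafep("protocol.sample_stride must be >= 1", "plafep_value_error")
  }
  structure(p, class = "simulation_protocol")
}

resolve_observables <- function(system, observables) {
  if (is.null(observables) || length(observables) == 0) {
    return(list(mat = matrix(0, 0, 6), names = character(0)))
  }
  rows <- lapply(observables, function(o) {
    switch(o$type,
      pair = c(0, o$i - 1, o$j - 1, 0, 0, 0),
      point = c(1, o$i - 1, 0, o$point),
      axis = c(2, o$i - 1, o$axis - 1, 0, 0, 0),
      stop_plafep("unknown observable type", "plafep_value_error"))
  })
  list(mat = do.call(rbind, rows),
       names = names(observables) %||% paste0("obs", seq_along(observables)))
}

#' Run Langevin dynamics and collect a trajectory
#'
#' BAOAB splitting at the protocol temperature; optional holonomic pair
#' distance constraints are enforced each step to within 1e-6 A.  With
#' `mixed_with`, forces are the weighted mix `wA * F_A + wB * F_B` of the
#' two term sets (the alchemical Hamiltonian) and both potential energies
#' are recorded per sample.
#'
#' @param system A `fep_system`.
#' @param protocol A [simulation_protocol()].
#' @param observables Named list of observable specs: `list(type = "pair",
#'   i, j)`, `list(type = "point", i, point)`, or
#'   `list(type = "axis", i, axis)`.
#' @param record_frames Store sampled coordinate frames.
#' @param coords,velocities Optional starting coordinates/velocities;
#'   velocities default to a Maxwell-Boltzmann draw with zero net momentum.
#' @param mixed_with Optional companion `fep_system` sharing the bead count.
#' @param weights Length-2 mixing weights `c(wA, wB)` when `mixed_with` is
#'   given.
#' @return A `fep_trajectory`: tibble of sampled scalars (`step`, `time_ps`,
#'   `potential`, `kinetic`, `total`, observables, and `potential_B` for
#'   mixed runs), optional frames array, final coordinates/velocities, and
#'   the protocol.
#' @export
#' @examples
#' fx <- make_fixture("harmonic_1d")
#' tr <- run_simulation(fx$system, simulation_protocol(2000, seed = 1))
#' head(tr$scalars)
run_simulation <- function(system, protocol, observables = NULL,
                           record_frames = FALSE, coords = NULL,
                           velocities = NULL, mixed_with = NULL,
                           weights = c(1, 0)) {
  stopifnot(inherits(system, "fep_system"),
            inherits(protocol, "simulation_protocol"))
  coords <- coords %||% system$coords
  e0 <- potential_energy(system, coords)
  if (!is.finite(e0)) {
    stop_plafep("starting energy is not finite", "plafep_value_error")
  }
  obs <- resolve_observables(system, observables)
  tsB <- if (!is.null(mixed_with)) mixed_with$termset else NULL

  set.seed(protocol$seed)
  res <- cpp_run_langevin(
    system$termset, tsB, weights[1], weights[2], coords, system$masses,
    protocol$timestep, protocol$friction, protocol$temperature,
    protocol$n_steps, protocol$equilibration_steps, protocol$sample_stride,
    system$constraints, obs$mat, record_frames, velocities)

  ns <- length(res$energy_A)
  steps <- protocol$equilibration_steps + protocol$sample_stride * seq_len(ns)
  scalars <- tibble(step = steps, time_ps = steps * protocol$timestep,
                    potential = res$energy_A, kinetic = res$kinetic,
                    total = res$energy_A + res$kinetic)
  if (!is.null(tsB)) scalars$potential_B <- res$energy_B
  if (length(obs$names) > 0) {
    om <- res$obs
    colnames(om) <- obs$names
    scalars <- dplyr::bind_cols(scalars, as_tibble(om))
  }
  structure(
    list(scalars = scalars, frames = if (record_frames) res$frames else NULL,
         final_coords = res$final_coords,
         final_velocities = res$final_velocities, protocol = protocol),
    class = "fep_trajectory")
}

#' @export
print.fep_trajectory <- function(x, ...) {
  cat(sprintf("<fep_trajectory> %d sampled frames, %.1f ps at %g K\n",
              nrow(x$scalars), x$protocol$n_steps * x$protocol$timestep,
              x$protocol$temperature))
  invisible(x)
}

#' Draw Maxwell-Boltzmann velocities with zero net momentum
#'
#' @param system A `fep_system`.
#' @param temperature Temperature, K.
#' @param seed Optional integer seed.
#' @return An n x 3 velocity matrix, A/ps.
#' @export
init_velocities <- function(system, temperature = 298.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cpp_init_velocities(system$masses, temperature)
}

#' Mean and block-averaged standard error of a correlated series
#'
#' Blocks are doubled until the standard error estimate plateaus (changes
#' by less than 10% over two successive doublings) or fewer than 8 blocks
#' remain; the plateau value is returned.  This corrects the naive
#' `sd/sqrt(n)` for serial correlation.
#'
#' @param series Numeric vector, length >= 16.
#' @return One-row tibble: `mean`, `se`, `n`, `block_size`.
#' @export
#' @examples
#' mean_and_error(rnorm(1024))
mean_and_error <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 16) {
    stop_plafep("insufficient data: series must have length >= 16",
                "plafep_data_error")
  }
  m <- mean(series)
  if (sd(series) == 0) {
    return(tibble(mean = m, se = 0, n = n, block_size = 1L))
  }
  ses <- numeric(0)
  sizes <- integer(0)
  bs <- 1L
  repeat {
    nb <- n %/% bs
    if (nb < 8) break
    bm <- colMeans(matrix(series[seq_len(nb * bs)], nrow = bs))
    ses <- c(ses, sd(bm) / sqrt(nb))
    sizes <- c(sizes, bs)
    k <- length(ses)
    if (k >= 3) {
      r1 <- abs(ses[k] - ses[k - 1]) / max(ses[k - 1], .Machine$double.eps)
      r2 <- abs(ses[k - 1] - ses[k - 2]) / max(ses[k - 2], .Machine$double.eps)
      if (r1 <= 0.1 && r2 <= 0.1) {
        return(tibble(mean = m, se = ses[k], n = n, block_size = sizes[k]))
      }
    }
    bs <- bs * 2L
  }
  k <- length(ses)
  tibble(mean = m, se = ses[k], n = n, block_size = sizes[k])
}

#' Write a trajectory in XYZ format
#'
#' Element column is the bead label; the comment line carries the frame
#' index and total energy.
#'
#' @param trajectory A `fep_trajectory` recorded with `record_frames = TRUE`.
#' @param system The `fep_system` it was sampled from (for labels).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(trajectory, system, path) {
  stopifnot(inherits(trajectory, "fep_trajectory"))
  fr <- trajectory$frames
  if (is.null(fr)) {
    stop_plafep("trajectory was recorded without frames", "plafep_value_error")
  }
  dm <- dim(fr)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seq_len(dm[1])) {
    writeLines(as.character(dm[2]), con)
    writeLines(sprintf("frame %d energy %.6f kcal/mol", s,
                       trajectory$scalars$total[s]), con)
    for (i in seq_len(dm[2])) {
      writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", system$labels[i],
                         fr[s, i, 1], fr[s, i, 2], fr[s, i, 3]), con)
    }
  }
  invisible(path)
}
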