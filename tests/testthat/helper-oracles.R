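# Shared oracle helpers and small fixture builders (all built in code).

RT_298 <- plafep::gas_constant_kcal() * 298.15

# central finite-difference forces, the independent oracle for forces()
fd_forces <- function(system, coords, h = 1e-5) {
  n <- nrow(coords)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (d in 1:3) {
      xp <- coords; xp[i, d] <- xp[i, d] + h
      xm <- coords; xm[i, d] <- xm[i, d] - h
      out[i, d] <- -(potential_energy(system, xp) -
                       potential_energy(system, xm)) / (2 * h)
    }
  }
  out
}

# two beads joined by one harmonic bond, at a given separation
two_bead_bond <- function(k = 10, r0 = 1.5, distance = r0) {
  plafep:::fixture_system(
    masses = c(14, 14),
    coords = rbind(c(0, 0, 0), c(distance, 0, 0)),
    termset_patch = list(bonds = matrix(c(0, 1, k, r0), 1)))
}

# a small conjugate system with randomised coordinates for gradient checks
jiggled_system <- function(seed = 1) {
  set.seed(seed)
  sys <- build_environment(build_conjugate(3),
                           environment = make_fixture("clash_pocket_A"))
  sys$coords <- sys$coords + matrix(rnorm(length(sys$coords), sd = 0.15),
                                    ncol = 3)
  sys
}

# i.i.d.-sampled umbrella object on a flat landscape (exact Gaussian
# window samples), bypassing the dynamics engine
synthetic_flat_umbrella <- function(n_per_window = 4000, k = 4,
                                    d0s = seq(0.5, 5, 0.5), seed = 1,
                                    temperature = 298.15) {
  set.seed(seed)
  sigma <- sqrt(plafep::gas_constant_kcal() * temperature / k)
  win <- tibble::tibble(
    window_id = seq_along(d0s), direction = "forward", d0 = d0s,
    force_constant = k,
    samples = lapply(d0s, function(d) stats::rnorm(n_per_window, d, sigma)),
    n_samples = n_per_window)
  structure(list(windows = win, protocol = NULL, temperature = temperature),
            class = "fep_umbrella")
}
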