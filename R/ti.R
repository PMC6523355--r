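# alchemical_ti: polynomial mixing Hamiltonian and thermodynamic
# integration for removal of terminal CH2 linker units.
#
# V(lambda) = (1 - lambda)^k V_N + [1 - (1 - lambda)^k] V_{N-1}, k = 4 by
# default; dA = integral_0^1 <dV/dlambda> dlambda evaluated by
# Gauss-Legendre quadrature over 9 interior nodes.

#' Gauss-Legendre nodes and weights on the unit interval
#'
#' Nodes/weights mapped from \[-1, 1\] to \[0, 1\]; exact for polynomials of
#' degree up to `2 * n_nodes - 1`.
#'
#' @param n_nodes Number of nodes, 2..64.
#' @return A tibble with columns `node` and `weight` (weights sum to 1).
#' @export
#' @examples
#' gauss_quadrature_01(9)
gauss_quadrature_01 <- function(n_nodes) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1 ||
      n_nodes != round(n_nodes) || n_nodes < 2 || n_nodes > 64) {
    stop_plafep("n_nodes out of range: must be an integer in [2, 64]",
                "plafep_range_error")
  }
  g <- pracma::gaussLegendre(as.integer(n_nodes), 0, 1)
  tibble(node = g$x, weight = g$w)
}

#' Mixing schedule for the alchemical Hamiltonian
#'
#' @param n_nodes Number of lambda nodes (9 matches the published protocol).
#' @param k_exponent Positive integer exponent of the mixing polynomial
#'   (4 matches the published protocol).
#' @return A `mixing_schedule` object with fields `lambda_nodes`,
#'   `quadrature_weights`, `k_exponent`, `n_nodes`.
#' @export
#' @examples
#' mixing_schedule()
mixing_schedule <- function(n_nodes = 9, k_exponent = 4) {
  if (!is.numeric(k_exponent) || k_exponent != round(k_exponent) ||
      k_exponent < 1) {
    stop_plafep("k_exponent must be a positive integer", "plafep_range_error")
  }
  q <- gauss_quadrature_01(n_nodes)
  stopifnot(abs(sum(q$weight) - 1) < 1e-12,
            all(diff(q$node) > 0),
            max(abs(q$node + rev(q$node) - 1)) < 1e-12)
  structure(list(lambda_nodes = q$node, quadrature_weights = q$weight,
                 k_exponent = as.integer(k_exponent),
                 n_nodes = as.integer(n_nodes)),
            class = "mixing_schedule")
}

#' @export
print.mixing_schedule <- function(x, ...) {
  cat(sprintf("<mixing_schedule> %d Gauss-Legendre nodes, k = %d\n",
              x$n_nodes, x$k_exponent))
  invisible(x)
}

#' Alchemically mixed potential
#'
#' `(1 - lambda)^k * V_N + (1 - (1 - lambda)^k) * V_{N-1}`.
#'
#' @param lambda Coupling parameter in \[0, 1\] (vectorised).
#' @param k Positive integer exponent.
#' @param V_N,V_Nminus1 End-state potential energies, kcal/mol.
#' @return Mixed energy, kcal/mol.
#' @export
#' @examples
#' mixed_potential(0.5, 4, 10, 2)  # 2.5
mixed_potential <- function(lambda, k, V_N, V_Nminus1) {
  if (any(lambda < 0 | lambda > 1)) {
    stop_plafep("lambda out of range [0, 1]", "plafep_range_error")
  }
  if (any(k < 1)) stop_plafep("k must be >= 1", "plafep_range_error")
  w <- (1 - lambda)^k
  w * V_N + (1 - w) * V_Nminus1
}

#' Derivative of the mixed potential with respect to lambda
#'
#' `-k (1 - lambda)^(k-1) (V_N - V_{N-1})`; the quantity whose ensemble
#' average is integrated by [run_ti()].
#'
#' @inheritParams mixed_potential
#' @return dV/dlambda, kcal/mol per unit lambda.
#' @export
#' @examples
#' dV_dlambda(0, 4, 10, 2)  # -32
dV_dlambda <- function(lambda, k, V_N, V_Nminus1) {
  if (any(lambda < 0 | lambda > 1)) {
    stop_plafep("lambda out of range [0, 1]", "plafep_range_error")
  }
  if (any(k < 1)) stop_plafep("k must be >= 1", "plafep_range_error")
  -k * (1 - lambda)^(k - 1) * (V_N - V_Nminus1)
}

#' Thermodynamic integration between two end states
#'
#' For each lambda node, samples the mixed Hamiltonian with BAOAB Langevin
#' dynamics and records the block-averaged `<dV/dlambda>`; the free energy
#' difference is the quadrature-weighted sum.  Node trajectories use
#' seed-derived independent RNG streams and their own equilibration; each
#' node starts from the previous node's final frame for faster relaxation.
#'
#' @param system_N Full end state (`fep_system`).
#' @param companion Decoupled end state sharing the bead count, normally
#'   from [shorten_companion()]; for generic fixtures any same-dimension
#'   `fep_system`.
#' @param schedule A [mixing_schedule()].
#' @param protocol A [simulation_protocol()] applied per node; its `seed`
#'   is the stage root seed.
#' @return A `fep_ti` object: `per_node` tibble (`lambda`, `weight`,
#'   `mean_dVdl`, `se`, `n_samples`), `delta_A`, `delta_A_error` (both
#'   kcal/mol), protocol, and metadata.
#' @export
#' @examples
#' a <- make_fixture("harmonic_1d", k = 1)$system
#' b <- make_fixture("harmonic_1d", k = 4)$system
#' ti <- run_ti(a, b, mixing_schedule(),
#'              simulation_protocol(4000, sample_stride = 5, seed = 1))
#' glance(ti)
run_ti <- function(system_N, companion, schedule = mixing_schedule(),
                   protocol = NULL) {
  stopifnot(inherits(schedule, "mixing_schedule"))
  if (is.null(protocol)) {
    stop_plafep("run_ti requires a simulation_protocol", "plafep_value_error")
  }
  n_removed <- check_ti_endpoints(system_N, companion)
  k <- schedule$k_exponent
  coords <- system_N$coords
  rows <- vector("list", schedule$n_nodes)
  for (i in seq_len(schedule$n_nodes)) {
    lam <- schedule$lambda_nodes[i]
    wA <- (1 - lam)^k
    prot_i <- protocol
    prot_i$seed <- derive_seed(protocol$seed, "ti", i)
    tr <- run_simulation(system_N, prot_i, coords = coords,
                         mixed_with = companion, weights = c(wA, 1 - wA))
    coords <- tr$final_coords
    dvdl <- dV_dlambda(lam, k, tr$scalars$potential, tr$scalars$potential_B)
    me <- mean_and_error(dvdl)
    rows[[i]] <- tibble(lambda = lam, weight = schedule$quadrature_weights[i],
                        mean_dVdl = me$mean, se = me$se, n_samples = me$n)
  }
  per_node <- dplyr::bind_rows(rows)
  delta_A <- sum(per_node$weight * per_node$mean_dVdl)
  delta_A_error <- sqrt(sum((per_node$weight * per_node$se)^2))
  env_kind <- if (!is.null(system_N$environment)) system_N$environment$kind else NA_character_
  pair <- if (!is.null(system_N$topology)) {
    c(system_N$topology$n_linker, system_N$topology$n_linker - n_removed)
  } else NULL
  structure(
    list(per_node = per_node, delta_A = delta_A,
         delta_A_error = delta_A_error, protocol = protocol,
         schedule = schedule,
         meta = list(environment = env_kind, linker_pair = pair,
                     n_removed = n_removed)),
    class = "fep_ti")
}

#' @export
print.fep_ti <- function(x, ...) {
  cat(sprintf("<fep_ti> delta_A = %.4f +/- %.4f kcal/mol over %d nodes\n",
              x$delta_A, x$delta_A_error, nrow(x$per_node)))
  invisible(x)
}
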