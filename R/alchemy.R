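# alchemical_ti support: companion end states sharing one coordinate array.
#
# The (N - n_remove) end state is represented on the N-topology coordinates:
# removed terminal linker beads become dummies that keep only their chain
# bond (an environment-independent tether whose free-energy contribution is
# a constant, identical for every leg, and cancels in all cycle
# differences), while losing angles and every nonbonded term.  The drug
# attachment bond is retargeted to the new linker end with its equilibrium
# distance at the detach plateau, which makes the TI end state coincide with
# the umbrella window at that distance.

#' Build the alchemical companion of a conjugate system
#'
#' @param system A `fep_system` built from a conjugate topology.
#' @param n_remove Number of terminal CH2 beads to decouple (1 for the
#'   standard leg; 2 for the direct cycle-closure check).
#' @param detach_distance Equilibrium distance (A) of the drug attachment
#'   bond to the new linker end in the companion state.  The default, 2 A,
#'   is roughly where the drug already sits relative to the new end while
#'   still attached to the old one, which keeps the alchemical perturbation
#'   small; it must lie on the umbrella grid so the TI end state coincides
#'   with that window's ensemble.
#' @return A `fep_system` whose term set is the decoupled end state; the
#'   shared bead count and masses are unchanged.
#' @export
#' @examples
#' sysN <- build_environment(build_conjugate(4), "water_reference")
#' cmp <- shorten_companion(sysN)
shorten_companion <- function(system, n_remove = 1, detach_distance = 2.0) {
  stopifnot(inherits(system, "fep_system"))
  top <- system$topology
  if (is.null(top)) {
    stop_plafep("shorten_companion needs a conjugate-topology system",
                "plafep_value_error")
  }
  if (n_remove < 1 || n_remove > top$n_linker - 1) {
    stop_plafep(
      "n_remove out of range: must leave at least one linker bead",
      "plafep_range_error")
  }
  vanish <- top$linker[(top$n_linker - n_remove + 1):top$n_linker]
  new_end <- top$linker[top$n_linker - n_remove]

  bonds <- top$bonds
  bonds$r0[top$attach_bond] <- detach_distance
  bonds$i[top$attach_bond] <- new_end          # retarget drug to new end
  angles <- top$angles
  angles <- angles[!(angles$i %in% vanish | angles$j %in% vanish |
                     angles$l %in% vanish), , drop = FALSE]

  # exclusions follow the companion's own bond graph (dummies keep their
  # tether bonds, so the vanished beads stay graph-connected)
  ts <- compile_termset(top, system$environment, bonds = bonds,
                        angles = angles, exclusion_bonds = bonds)
  # dummies lose every nonbonded term
  keep <- !(ts$pairs[, 1] %in% (vanish - 1) | ts$pairs[, 2] %in% (vanish - 1))
  ts$pairs <- ts$pairs[keep, , drop = FALSE]
  ts$wall_scale[vanish] <- 0
  ts$anchor_q[vanish] <- 0
  ts$slab_mask[vanish] <- 0

  out <- system
  out$termset <- ts
  out$umbrella <- list(type = "bond", row = top$attach_bond)
  out$meta$vanished <- vanish
  out$meta$linker_end <- new_end
  out$meta$companion_of <- top$n_linker
  out
}

# validate a TI endpoint pair; returns number of decoupled beads (0 for
# generic same-dimension fixtures)
check_ti_endpoints <- function(system_N, companion) {
  if (!inherits(system_N, "fep_system") || !inherits(companion, "fep_system")) {
    stop_plafep("run_ti expects two fep_system objects", "plafep_value_error")
  }
  if (system_N$termset$n != companion$termset$n) {
    stop_plafep(
      "incompatible endpoints: systems must share one coordinate array (build the shortened state with shorten_companion())",
      "plafep_endpoint_error")
  }
  if (!isTRUE(all.equal(system_N$masses, companion$masses))) {
    stop_plafep("incompatible endpoints: bead masses differ",
                "plafep_endpoint_error")
  }
  nv <- length(companion$meta$vanished)
  if (!is.null(system_N$topology)) {
    if (nv < 1 || nv > 2) {
      stop_plafep(
        "incompatible endpoints: companion must decouple one or two terminal linker beads",
        "plafep_endpoint_error")
    }
    if (!identical(companion$meta$companion_of, system_N$topology$n_linker)) {
      stop_plafep(
        "incompatible endpoints: companion was built from a different linker length",
        "plafep_endpoint_error")
    }
  }
  nv
}
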