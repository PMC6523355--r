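# model_builder: thermodynamic environments and system assembly.
#
# Three environment kinds stand in for the paper's three thermodynamic
# states: the PLA2 transition-state pocket (calcium-like anchor well plus
# repulsive wall spheres), free solution in water (no external terms), and
# the lipid phase (flat-bottom slab confinement plus a per-bead hydrophobic
# solvation bonus for tail/linker beads inside the slab).

#' Construct an environment model
#'
#' @param kind One of `"ts_pocket"`, `"water_reference"`, `"lipid_reference"`.
#' @param anchor_position 3-vector, A; calcium-like site (ts_pocket only).
#' @param anchor_well_depth Gaussian well depth, kcal/mol (> 0, ts_pocket).
#' @param anchor_well_width Gaussian well width, A (ts_pocket).
#' @param wall_spheres Tibble/data frame with columns `x`, `y`, `z`,
#'   `radius` (A): repulsive obstacles (ts_pocket only, at least one).
#' @param wall_strength Cap height of the wall repulsion, kcal/mol.
#' @param ts_restraint_k Harmonic restraint tying the carbonyl bead to the
#'   anchor (transition-state geometry surrogate), kcal/mol/A^2.
#' @param slab_half_width Lipid slab half width, A (lipid_reference only).
#' @param slab_strength Flat-bottom confinement constant, kcal/mol/A^2.
#' @param solvation_bonus Hydrophobic stabilisation per tail/linker bead
#'   inside the slab, kcal/mol (lipid_reference only).
#' @param implicit_friction Langevin friction the environment implies, 1/ps.
#' @return An `environment_model` object.
#' @export
#' @examples
#' environment_model("water_reference")
environment_model <- function(kind = c("ts_pocket", "water_reference",
                                       "lipid_reference"),
                              anchor_position = c(0, 0, 0),
                              anchor_well_depth = 8, anchor_well_width = 1.0,
                              wall_spheres = NULL, wall_strength = 4.0,
                              ts_restraint_k = 10,
                              slab_half_width = 8, slab_strength = 2,
                              solvation_bonus = 0.8,
                              implicit_friction = 1.0) {
  kind <- match.arg(kind)
  env <- list(kind = kind, implicit_friction = implicit_friction)
  if (kind == "ts_pocket") {
    if (is.null(wall_spheres) || nrow(wall_spheres) < 1) {
      stop_plafep("configuration error: ts_pocket requires 'wall_spheres' (>= 1)",
                  "plafep_config_error")
    }
    if (!all(c("x", "y", "z", "radius") %in% names(wall_spheres))) {
      stop_plafep("configuration error: wall_spheres needs columns x, y, z, radius",
                  "plafep_config_error")
    }
    if (!is.finite(anchor_well_depth) || anchor_well_depth <= 0) {
      stop_plafep("configuration error: anchor_well_depth must be finite and > 0",
                  "plafep_config_error")
    }
    env$anchor_position <- anchor_position
    env$anchor_well_depth <- anchor_well_depth
    env$anchor_well_width <- anchor_well_width
    env$wall_spheres <- as_tibble(wall_spheres)
    env$wall_strength <- wall_strength
    env$ts_restraint_k <- ts_restraint_k
  } else if (kind == "lipid_reference") {
    if (!is.finite(slab_half_width) || slab_half_width <= 0) {
      stop_plafep("configuration error: slab_half_width must be > 0",
                  "plafep_config_error")
    }
    env$slab_half_width <- slab_half_width
    env$slab_strength <- slab_strength
    env$solvation_bonus <- solvation_bonus
  }
  structure(env, class = "environment_model")
}

#' @export
print.environment_model <- function(x, ...) {
  extra <- switch(x$kind,
    ts_pocket = sprintf("%d wall spheres, anchor depth %.1f kcal/mol",
                        nrow(x$wall_spheres), x$anchor_well_depth),
    lipid_reference = sprintf("slab half width %.1f A", x$slab_half_width),
    "implicit solvent, no external terms")
  cat(sprintf("<environment_model> %s: %s\n", x$kind, extra))
  invisible(x)
}

# deterministic initial placement: carbonyl at the pocket anchor (or the
# origin), linker extended along +x (the channel axis), headgroup and tail
# extended along -x, everything in the z = 0 plane (inside the lipid slab).
place_conjugate <- function(topology, origin = c(0, 0, 0)) {
  n <- nrow(topology$beads)
  r0 <- topology$params$bond_r0
  xyz <- matrix(0, n, 3)
  lab <- topology$beads$label
  at <- function(label) which(lab == label)
  xyz[at("CO"), ] <- origin
  xyz[at("GLY"), ] <- origin + c(-r0, 0, 0)
  xyz[at("PHO"), ] <- origin + c(-2 * r0, 0.8, 0)
  xyz[at("CHO"), ] <- origin + c(-3 * r0, 0.8, 0)
  for (i in 1:4) {
    xyz[at(paste0("T", i)), ] <- origin + c(-r0 * (1 + i * 0.9), -1.2, 0)
  }
  for (i in seq_len(topology$n_linker)) {
    xyz[at(paste0("L", i)), ] <- origin + c(r0 * i, 0, 0)
  }
  xyz[at("DRG"), ] <- origin +
    c(r0 * topology$n_linker + topology$params$attach_r0, 0, 0)
  xyz
}

# Compile a topology + environment into the flat term-set list consumed by
# the C++ engine (0-based indices).  Nonbonded pairs exclude beads within
# three bonds of each other on the bond graph.
compile_termset <- function(topology, env, bonds = NULL, angles = NULL,
                            exclusion_bonds = NULL) {
  beads <- topology$beads
  n <- nrow(beads)
  bonds <- bonds %||% topology$bonds
  angles <- angles %||% topology$angles
  exclusion_bonds <- exclusion_bonds %||% bonds

  d <- bond_graph_distances(n, exclusion_bonds, max_d = 3L)
  pairs <- NULL
  if (n >= 2) {
    cmb <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- d[cmb] > 3
    cmb <- cmb[keep, , drop = FALSE]
    if (nrow(cmb) > 0) {
      i <- cmb[, 1]; j <- cmb[, 2]
      pairs <- cbind(i - 1, j - 1,
                     sqrt(beads$epsilon[i] * beads$epsilon[j]),
                     beads$radius[i] + beads$radius[j])
      pairs <- pairs[pairs[, 3] > 0, , drop = FALSE]
    }
  }
  empty <- function(k) matrix(0, 0, k)

  ts <- list(
    n = as.integer(n),
    bonds = cbind(bonds$i - 1, bonds$j - 1, bonds$k, bonds$r0),
    angles = if (nrow(angles)) {
      cbind(angles$i - 1, angles$j - 1, angles$l - 1, angles$k, angles$theta0)
    } else empty(5),
    pairs = pairs %||% empty(4),
    point_restraints = empty(6),
    dist_restraints = empty(4),
    axis_restraints = empty(4),
    walls = empty(5),
    wall_scale = rep(1, n),
    radii = beads$radius,
    anchor = c(0, 0, 0, 0, 0, 1),
    anchor_q = rep(0, n),
    slab = c(0, 1, 0, 0),
    slab_mask = rep(0, n),
    dwell = empty(5)
  )

  if (env$kind == "ts_pocket") {
    ws <- env$wall_spheres
    ts$walls <- cbind(ws$x, ws$y, ws$z, ws$radius, env$wall_strength)
    ts$anchor <- c(1, env$anchor_position, env$anchor_well_depth,
                   env$anchor_well_width)
    ts$anchor_q <- beads$charge_like
    # transition-state geometry surrogate: carbonyl tied to the anchor
    ts$point_restraints <- matrix(
      c(topology$carbonyl - 1, env$ts_restraint_k, 0, env$anchor_position),
      nrow = 1)
  } else if (env$kind == "lipid_reference") {
    mask <- as.numeric(beads$role %in% c("tail", "linker"))
    ts$slab <- c(1, env$slab_half_width, env$slab_strength,
                 env$solvation_bonus)
    ts$slab_mask <- mask
  }
  ts
}

#' Build a simulation system from a topology and an environment
#'
#' Places initial coordinates by a deterministic rule (linker extended along
#' the pocket channel axis for `ts_pocket`; extended chain at the origin
#' otherwise), compiles all potential terms, and installs the
#' carbonyl-to-anchor restraint for transition-state pocket systems.
#'
#' @param topology A [build_conjugate()] topology.
#' @param kind Environment kind, or an [environment_model()] object via
#'   `environment`.
#' @param params Named list of [environment_model()] arguments used when
#'   `kind` is a string.
#' @param environment Optional pre-built [environment_model()].
#' @return A `fep_system` object.
#' @export
#' @examples
#' sys <- build_environment(build_conjugate(4), "water_reference")
#' potential_energy(sys)
build_environment <- function(topology, kind = c("ts_pocket",
                                                 "water_reference",
                                                 "lipid_reference"),
                              params = list(), environment = NULL) {
  stopifnot(inherits(topology, "conjugate_topology"))
  env <- environment %||%
    do.call(environment_model, c(list(kind = match.arg(kind)), params))
  stopifnot(inherits(env, "environment_model"))

  origin <- if (env$kind == "ts_pocket") env$anchor_position else c(0, 0, 0)
  coords <- place_conjugate(topology, origin)
  ts <- compile_termset(topology, env)

  sys <- structure(
    list(topology = topology, environment = env, coords = coords,
         termset = ts, masses = topology$beads$mass,
         labels = topology$beads$label,
         constraints = matrix(0, 0, 3),
         umbrella = list(type = "bond", row = topology$attach_bond),
         meta = list(carbonyl = topology$carbonyl, drug = topology$drug,
                     linker_end = topology$linker[topology$n_linker],
                     vanished = integer(0))),
    class = "fep_system")
  e <- potential_energy(sys)
  if (!is.finite(e)) {
    stop_plafep("built system has non-finite initial energy",
                "plafep_value_error")
  }
  sys
}

#' @export
print.fep_system <- function(x, ...) {
  cat(sprintf("<fep_system> %d beads in %s; initial energy %.3f kcal/mol\n",
              x$termset$n,
              if (is.null(x$environment)) "custom environment"
              else x$environment$kind,
              potential_energy(x)))
  invisible(x)
}

# a bare system for fixtures: beads + explicit terms, no conjugate topology
fixture_system <- function(masses, coords, labels = NULL, radii = NULL,
                           termset_patch = list(), umbrella = NULL) {
  n <- length(masses)
  empty <- function(k) matrix(0, 0, k)
  ts <- list(n = as.integer(n), bonds = empty(4), angles = empty(5),
             pairs = empty(4), point_restraints = empty(6),
             dist_restraints = empty(4), axis_restraints = empty(4),
             walls = empty(5), wall_scale = rep(1, n),
             radii = radii %||% rep(1.7, n), anchor = c(0, 0, 0, 0, 0, 1),
             anchor_q = rep(0, n), slab = c(0, 1, 0, 0),
             slab_mask = rep(0, n), dwell = empty(5))
  ts[names(termset_patch)] <- termset_patch
  structure(
    list(topology = NULL, environment = NULL, coords = coords, termset = ts,
         masses = masses, labels = labels %||% paste0("B", seq_len(n)),
         constraints = matrix(0, 0, 3), umbrella = umbrella,
         meta = list(vanished = integer(0))),
    class = "fep_system")
}

# set the umbrella bias equilibrium distance (and optionally k) in place
set_bias_distance <- function(system, d0, force_constant = NULL) {
  u <- system$umbrella
  if (is.null(u)) {
    stop_plafep("system has no umbrella bias handle", "plafep_value_error")
  }
  if (u$type == "bond") {
    system$termset$bonds[u$row, 4] <- d0
    if (!is.null(force_constant)) system$termset$bonds[u$row, 3] <- force_constant
  } else if (u$type == "point") {
    system$termset$point_restraints[u$row, 3] <- d0
    if (!is.null(force_constant)) {
      system$termset$point_restraints[u$row, 2] <- force_constant
    }
  } else {
    stop_plafep("unknown umbrella bias type", "plafep_value_error")
  }
  system
}

# observable spec for the biased reaction coordinate
bias_observable <- function(system) {
  u <- system$umbrella
  if (is.null(u)) {
    stop_plafep("system has no umbrella bias handle", "plafep_value_error")
  }
  if (u$type == "bond") {
    b <- system$termset$bonds[u$row, ]
    list(type = "pair", i = b[1] + 1, j = b[2] + 1)
  } else {
    p <- system$termset$point_restraints[u$row, ]
    list(type = "point", i = p[1] + 1, point = p[4:6])
  }
}
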