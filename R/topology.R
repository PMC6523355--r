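# model_builder: coarse-grained conjugate topologies.
#
# One bead per CH2 linker unit, one bead for the drug moiety, three beads
# for the phosphocholine headgroup, four per sn-1 acyl tail, one for the
# sn-2 carbonyl.  The drug is joined to the linker end by a soft harmonic
# "attachment bond" (k = 4 kcal/mol/A^2) whose equilibrium distance is the
# umbrella-sampling variable; 0.5 A is the attached state.

#' Bead specification
#'
#' @param label Short unique label within a topology.
#' @param mass Mass in amu; must be positive.
#' @param radius Soft-sphere radius in Angstrom; must be positive.
#' @param epsilon Pair-repulsion cap height in kcal/mol (energy of full
#'   overlap between two beads of this epsilon); must be non-negative.
#' @param charge_like Dimensionless scalar used only by the calcium-anchor
#'   attraction term; 0 for beads the anchor ignores.
#' @return A one-row tibble with class information carried by the topology.
#' @export
#' @examples
#' bead_spec("L1", mass = 14, radius = 1.7)
bead_spec <- function(label, mass, radius, epsilon = 2, charge_like = 0) {
  if (!is.character(label) || length(label) != 1 || !nzchar(label)) {
    stop_plafep("bead label must be a non-empty string", "plafep_value_error")
  }
  if (!is.finite(mass) || mass <= 0) {
    stop_plafep("bead mass must be > 0", "plafep_value_error")
  }
  if (!is.finite(radius) || radius <= 0) {
    stop_plafep("bead radius must be > 0", "plafep_value_error")
  }
  if (!is.finite(epsilon) || epsilon < 0) {
    stop_plafep("bead epsilon must be >= 0", "plafep_value_error")
  }
  tibble(label = label, mass = mass, radius = radius,
         epsilon = epsilon, charge_like = charge_like)
}

#' Builder parameter set for conjugate topologies
#'
#' Defaults: bond equilibrium distance 1.5 A, bead radius 1.7 A, bond force
#' constant 100 kcal/mol/A^2, chain angle force constant 2 kcal/mol/rad^2
#' (equilibrium straight), attachment bond 4.0 kcal/mol/A^2 at 0.5 A.
#'
#' @param bond_k Chain bond force constant, kcal/mol/A^2.
#' @param bond_r0 Chain bond equilibrium distance, A.
#' @param angle_k Chain angle force constant, kcal/mol/rad^2.
#' @param angle_theta0 Chain angle equilibrium, rad.
#' @param bead_radius Default bead radius, A.
#' @param drug_radius Drug bead radius, A (bulky moiety).
#' @param epsilon Pair-repulsion cap height, kcal/mol.
#' @param ch2_mass Linker bead mass, amu.
#' @param drug_mass Drug bead mass, amu.
#' @param attach_k Drug attachment bond force constant, kcal/mol/A^2.
#' @param attach_r0 Drug attachment equilibrium distance, A (attached state).
#' @return A named list of parameters.
#' @export
builder_params <- function(bond_k = 100, bond_r0 = 1.5, angle_k = 2,
                           angle_theta0 = pi, bead_radius = 1.7,
                           drug_radius = 2.5, epsilon = 2, ch2_mass = 14,
                           drug_mass = 200, attach_k = 4.0, attach_r0 = 0.5) {
  p <- list(bond_k = bond_k, bond_r0 = bond_r0, angle_k = angle_k,
            angle_theta0 = angle_theta0, bead_radius = bead_radius,
            drug_radius = drug_radius, epsilon = epsilon,
            ch2_mass = ch2_mass, drug_mass = drug_mass,
            attach_k = attach_k, attach_r0 = attach_r0)
  for (nm in c("bond_k", "bond_r0", "angle_k", "bead_radius", "drug_radius",
               "ch2_mass", "drug_mass", "attach_k", "attach_r0")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop_plafep(sprintf("builder parameter '%s' must be > 0", nm),
                  "plafep_value_error")
    }
  }
  if (!is.finite(epsilon) || epsilon < 0) {
    stop_plafep("builder parameter 'epsilon' must be >= 0",
                "plafep_value_error")
  }
  p
}

#' Build a coarse-grained PL-prodrug conjugate topology
#'
#' Beads: 3 headgroup (choline `CHO`, phosphate `PHO`, glycerol `GLY`),
#' 4 sn-1 tail (`T1`..`T4`), the sn-2 carbonyl surrogate `CO`, `n_linker`
#' CH2 beads (`L1`..), and the drug bead `DRG`.  The bond graph is a tree;
#' the drug is attached to the last linker bead by the soft attachment bond.
#'
#' @param n_linker Number of CH2 linker beads, integer in 1..12 (the scan
#'   uses 2..8).
#' @param params A [builder_params()] list.
#' @return A `conjugate_topology` object: beads tibble, bonds tibble
#'   (`i`, `j`, `k`, `r0`), angles tibble (`i`, `j`, `l`, `k`, `theta0`),
#'   `n_linker`, and the parameter set.
#' @export
#' @examples
#' top <- build_conjugate(6)
#' nrow(top$beads)  # 16
build_conjugate <- function(n_linker, params = builder_params()) {
  if (!is.numeric(n_linker) || length(n_linker) != 1 ||
      n_linker != round(n_linker)) {
    stop_plafep("n_linker must be a single integer", "plafep_range_error")
  }
  if (n_linker < 1) {
    stop_plafep("n_linker out of range: must be >= 1", "plafep_range_error")
  }
  if (n_linker > 12) {
    stop_plafep("n_linker out of range: must be <= 12", "plafep_range_error")
  }
  p <- params
  head <- dplyr::bind_rows(
    bead_spec("CHO", mass = 87, radius = p$bead_radius, epsilon = p$epsilon),
    bead_spec("PHO", mass = 95, radius = p$bead_radius, epsilon = p$epsilon),
    bead_spec("GLY", mass = 74, radius = p$bead_radius, epsilon = p$epsilon)
  )
  head$role <- "head"
  tail_b <- dplyr::bind_rows(lapply(1:4, function(i) {
    bead_spec(paste0("T", i), mass = 42, radius = p$bead_radius,
              epsilon = p$epsilon)
  }))
  tail_b$role <- "tail"
  co <- bead_spec("CO", mass = 28, radius = p$bead_radius,
                  epsilon = p$epsilon, charge_like = 1)
  co$role <- "carbonyl"
  link <- dplyr::bind_rows(lapply(seq_len(n_linker), function(i) {
    bead_spec(paste0("L", i), mass = p$ch2_mass, radius = p$bead_radius,
              epsilon = p$epsilon)
  }))
  link$role <- "linker"
  drug <- bead_spec("DRG", mass = p$drug_mass, radius = p$drug_radius,
                    epsilon = p$epsilon)
  drug$role <- "drug"

  beads <- dplyr::bind_rows(head, tail_b, co, link, drug)
  if (anyDuplicated(beads$label)) {
    stop_plafep("bead labels must be unique within a topology",
                "plafep_value_error")
  }
  idx <- setNames(seq_len(nrow(beads)), beads$label)
  co_i <- idx[["CO"]]
  drug_i <- idx[["DRG"]]
  l <- function(i) idx[[paste0("L", i)]]

  chain_bond <- function(i, j) tibble(i = i, j = j, k = p$bond_k, r0 = p$bond_r0)
  bonds <- dplyr::bind_rows(
    chain_bond(co_i, idx[["GLY"]]),
    chain_bond(idx[["GLY"]], idx[["PHO"]]),
    chain_bond(idx[["PHO"]], idx[["CHO"]]),
    chain_bond(idx[["GLY"]], idx[["T1"]]),
    chain_bond(idx[["T1"]], idx[["T2"]]),
    chain_bond(idx[["T2"]], idx[["T3"]]),
    chain_bond(idx[["T3"]], idx[["T4"]]),
    chain_bond(co_i, l(1))
  )
  if (n_linker >= 2) {
    for (i in 2:n_linker) bonds <- dplyr::bind_rows(bonds, chain_bond(l(i - 1), l(i)))
  }
  # attachment bond: the umbrella-sampling variable
  bonds <- dplyr::bind_rows(bonds, tibble(i = l(n_linker), j = drug_i,
                                          k = p$attach_k, r0 = p$attach_r0))
  attach_idx <- nrow(bonds)

  ang <- function(i, j, l_) tibble(i = i, j = j, l = l_, k = p$angle_k,
                                   theta0 = p$angle_theta0)
  angles <- dplyr::bind_rows(
    ang(co_i, idx[["GLY"]], idx[["PHO"]]),
    ang(idx[["GLY"]], idx[["PHO"]], idx[["CHO"]]),
    ang(idx[["PHO"]], idx[["GLY"]], idx[["T1"]]),
    ang(idx[["GLY"]], idx[["T1"]], idx[["T2"]]),
    ang(idx[["T1"]], idx[["T2"]], idx[["T3"]]),
    ang(idx[["T2"]], idx[["T3"]], idx[["T4"]]),
    ang(idx[["GLY"]], co_i, l(1))
  )
  if (n_linker >= 2) angles <- dplyr::bind_rows(angles, ang(co_i, l(1), l(2)))
  if (n_linker >= 3) {
    for (i in 3:n_linker) {
      angles <- dplyr::bind_rows(angles, ang(l(i - 2), l(i - 1), l(i)))
    }
  }

  structure(
    list(beads = beads, bonds = bonds, angles = angles,
         n_linker = as.integer(n_linker), params = p,
         attach_bond = attach_idx,
         carbonyl = unname(co_i), drug = unname(drug_i),
         linker = unname(vapply(seq_len(n_linker), l, integer(1)))),
    class = "conjugate_topology"
  )
}

#' Remove the terminal CH2 unit from a conjugate topology
#'
#' Returns the (N-1)-linker companion topology used as the alchemical end
#' state: all beads other than the removed terminal linker bead retain
#' labels and parameters, and the drug is attached to the new linker end by
#' the attachment bond with a controllable equilibrium distance.
#'
#' @param topology A `conjugate_topology` with at least 2 linker beads.
#' @param attach_r0 Equilibrium distance of the drug attachment bond in the
#'   shortened topology (default: the builder's attached distance).
#' @return A `conjugate_topology` with one fewer linker bead.
#' @export
#' @examples
#' top7 <- build_conjugate(7)
#' top6 <- shorten_linker(top7)
#' top6$n_linker
shorten_linker <- function(topology, attach_r0 = NULL) {
  stopifnot(inherits(topology, "conjugate_topology"))
  if (topology$n_linker < 2) {
    stop_plafep("cannot shorten: topology must have >= 2 linker beads",
                "plafep_range_error")
  }
  p <- topology$params
  if (!is.null(attach_r0)) p$attach_r0 <- attach_r0
  build_conjugate(topology$n_linker - 1L, p)
}

#' @export
print.conjugate_topology <- function(x, ...) {
  cat(sprintf(
    "<conjugate_topology> %d beads (%d CH2 linker units), %d bonds, %d angles\n",
    nrow(x$beads), x$n_linker, nrow(x$bonds), nrow(x$angles)))
  invisible(x)
}

# graph distance matrix over the bond list (small n; BFS per bead)
bond_graph_distances <- function(n, bonds, max_d = 3L) {
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0L
    while (length(frontier) > 0 && depth < max_d) {
      depth <- depth + 1L
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# TRUE if the bond graph is connected and acyclic (a tree)
topology_is_tree <- function(topology) {
  n <- nrow(topology$beads)
  if (nrow(topology$bonds) != n - 1) return(FALSE)
  d <- bond_graph_distances(n, topology$bonds, max_d = n)
  all(is.finite(d))
}
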