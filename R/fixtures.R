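# interface: deterministic synthetic fixtures.
#
# The clash pockets encode the designed steric mechanism: rings of
# repulsive wall spheres form a channel that narrows toward the
# calcium-like anchor, so a drug bead attached at the end of a short
# linker overlaps the walls while a 6-unit linker places it in open
# space.  Pocket B is a slightly wider variant standing in for a second
# enzyme; neither claims structural fidelity to a real PLA2.

clash_pocket_walls <- function(offsets, xs, wall_radius = 2.0) {
  ang <- seq(0, 5) * pi / 3
  rings <- mapply(function(x0, rho) {
    cbind(x = x0, y = rho * cos(ang), z = rho * sin(ang))
  }, xs, offsets, SIMPLIFY = FALSE)
  ws <- as_tibble(do.call(rbind, rings))
  ws$radius <- wall_radius
  ws
}

#' Packaged synthetic fixtures
#'
#' * `harmonic_1d`: one bead in a harmonic well along x (`k`, default
#'   2 kcal/mol/A^2); analytic position variance `RT/k`.
#' * `double_well`: one bead on a tilted quartic double-well along x
#'   (minima near 1.5 and 3.5 A), y/z confined; the analytic potential is
#'   returned for oracle tests, and the umbrella bias is the distance to
#'   the origin.
#' * `flat_landscape`: as `double_well` but with no landscape along x.
#' * `clash_pocket_A`, `clash_pocket_B`: transition-state pocket
#'   environments with narrowing wall rings (two enzyme variants).
#' * `mini_pdb`: writes a small synthetic 3-residue PDB file with a
#'   calcium HETATM and returns its path.
#'
#' @param name Fixture name.
#' @param ... Fixture-specific overrides (`k` and `mass` for
#'   `harmonic_1d`; `h`, `a`, `c`, `tilt` for `double_well`; `path` for
#'   `mini_pdb`).
#' @return A list with a `system` (and `analytic` description) for the toy
#'   landscapes, an `environment_model` for the pockets, or a file path for
#'   `mini_pdb`.
#' @export
#' @examples
#' fx <- make_fixture("double_well")
#' fx$analytic$potential(2.5)
make_fixture <- function(name, ...) {
  args <- list(...)
  known <- c("harmonic_1d", "double_well", "flat_landscape",
             "clash_pocket_A", "clash_pocket_B", "mini_pdb")
  if (!name %in% known) {
    stop_plafep(sprintf("unknown fixture '%s'; available: %s", name,
                        paste(known, collapse = ", ")),
                "plafep_value_error")
  }
  switch(name,
    harmonic_1d = {
      k <- args$k %||% 2
      mass <- args$mass %||% 14
      sys <- fixture_system(
        masses = mass, coords = matrix(0, 1, 3),
        termset_patch = list(axis_restraints = matrix(c(0, 0, k, 0), 1)))
      list(system = sys,
           analytic = list(k = k,
                           variance = function(temperature = 298.15) {
                             GAS_CONSTANT_KCAL * temperature / k
                           }))
    },
    double_well = ,
    flat_landscape = {
      # two tilted basins on [0.5, 5] separated by a capped barrier at
      # x = c0; barrier height and tilt are a few kcal/mol so the
      # 4 kcal/mol/A^2 umbrella bias can drag the bead across the range
      h <- args$h %||% 1.8          # barrier height, kcal/mol
      a <- args$a %||% 0.8          # barrier half width, A
      c0 <- args$c %||% 2.5         # barrier position, A
      tilt <- args$tilt %||% 0.3    # linear slope, kcal/mol/A
      k_conf <- args$k_conf %||% 200
      flat <- name == "flat_landscape"
      patch <- list(
        axis_restraints = rbind(c(0, 1, k_conf, 0), c(0, 2, k_conf, 0)),
        point_restraints = matrix(c(0, 4, 0.5, 0, 0, 0), 1))
      if (!flat) patch$dwell <- matrix(c(0, h, a, c0, tilt), 1)
      sys <- fixture_system(
        masses = args$mass %||% 14,
        coords = matrix(c(if (flat) 0.5 else c0 - a - 0.5, 0, 0), 1, 3),
        termset_patch = patch,
        umbrella = list(type = "point", row = 1))
      pot <- if (flat) function(x) 0 * x else {
        function(x) {
          u <- (abs(x) - c0) / a
          ifelse(abs(u) < 1, h * (1 - u^2)^2, 0) + tilt * (abs(x) - c0)
        }
      }
      list(system = sys,
           analytic = list(potential = pot, h = h, a = a, c = c0,
                           tilt = tilt))
    },
    clash_pocket_A = environment_model(
      "ts_pocket",
      wall_spheres = clash_pocket_walls(
        offsets = c(3.8, 3.1, 3.2, 3.9, 3.9, 4.3),
        xs = c(0.8, 2.0, 3.5, 5.0, 6.5, 8.0)),
      wall_strength = args$wall_strength %||% 4.0),
    clash_pocket_B = environment_model(
      "ts_pocket",
      wall_spheres = clash_pocket_walls(
        offsets = c(4.1, 3.4, 3.5, 4.2, 4.2, 4.6),
        xs = c(0.8, 2.0, 3.6, 5.2, 6.8, 8.4)),
      wall_strength = args$wall_strength %||% 3.0),
    mini_pdb = {
      path <- args$path %||% tempfile(fileext = ".pdb")
      lines <- c(
        "REMARK synthetic three-residue pocket fixture",
        sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                1L, 1L, 3.0, 4.0, 0.0),
        sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                2L, 2L, 3.0, -4.0, 0.0),
        sprintf("ATOM  %5d  CA  SER A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                3L, 3L, 5.0, 0.0, 4.0),
        sprintf("HETATM%5d CA    CA A%4d    %8.3f%8.3f%8.3f  1.00  0.00          CA",
                4L, 4L, 0.0, 0.0, 0.0),
        "END")
      writeLines(lines, path)
      path
    })
}
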