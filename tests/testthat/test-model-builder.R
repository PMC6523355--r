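# Conjugate topologies, environments, and the packaged pocket fixtures.

test_that("build_conjugate constructs a connected acyclic topology", {
  top <- build_conjugate(6)
  expect_equal(top$n_linker, 6L)
  expect_equal(nrow(top$bonds), nrow(top$beads) - 1)   # tree
  expect_true(plafep:::topology_is_tree(top))
  expect_false(anyDuplicated(top$beads$label) > 0)
  expect_equal(sum(top$beads$role == "carbonyl"), 1)
  expect_equal(sum(top$beads$role == "drug"), 1)

  # adding one linker unit adds exactly one bead and one bond, for every N
  for (N in 2:12) {
    expect_equal(nrow(build_conjugate(N)$beads),
                 nrow(build_conjugate(N - 1)$beads) + 1)
    expect_equal(nrow(build_conjugate(N)$bonds),
                 nrow(build_conjugate(N - 1)$bonds) + 1)
  }
})

test_that("build_conjugate rejects out-of-range linker counts", {
  expect_error(build_conjugate(0), ">= 1", class = "plafep_range_error")
  expect_error(build_conjugate(13), "<= 12", class = "plafep_range_error")
  expect_error(build_conjugate(2.5), class = "plafep_range_error")
})

test_that("shorten_linker yields the isomorphic N-1 companion", {
  top7 <- build_conjugate(7)
  top6 <- shorten_linker(top7)
  expect_equal(top6$n_linker, 6L)
  expect_equal(nrow(top6$beads), nrow(top7$beads) - 1)
  ref <- build_conjugate(6)
  # same labelled bond multiset = isomorphic bond graphs
  key <- function(t) {
    li <- t$beads$label[t$bonds$i]
    lj <- t$beads$label[t$bonds$j]
    sort(mapply(function(a, b) paste(sort(c(a, b)), collapse = "-"), li, lj))
  }
  expect_identical(key(top6), key(ref))
  expect_error(shorten_linker(build_conjugate(1)),
               class = "plafep_range_error")
})

test_that("bead_spec validates physical fields", {
  expect_error(bead_spec("A", mass = -1, radius = 1), "mass")
  expect_error(bead_spec("A", mass = 1, radius = 0), "radius")
  expect_error(bead_spec("A", mass = 1, radius = 1, epsilon = -2), "epsilon")
})

test_that("environment invariants hold for the three kinds", {
  expect_error(environment_model("ts_pocket"), "wall_spheres",
               class = "plafep_config_error")
  w <- environment_model("water_reference")
  expect_null(w$wall_spheres)
  expect_null(w$anchor_position)
  l <- environment_model("lipid_reference", slab_half_width = 8)
  expect_equal(l$slab_half_width, 8)
  expect_error(environment_model("lipid_reference", slab_half_width = -1),
               "slab_half_width", class = "plafep_config_error")
})

test_that("built systems have finite energy and sensible placement", {
  top <- build_conjugate(4)

  sys_w <- build_environment(top, "water_reference")
  expect_true(is.finite(potential_energy(sys_w)))
  ec <- energy_components(sys_w)
  expect_equal(ec$wall, 0)
  expect_equal(ec$anchor, 0)

  sys_p <- build_environment(top, environment = make_fixture("clash_pocket_A"))
  expect_true(is.finite(potential_energy(sys_p)))
  co <- sys_p$coords[sys_p$meta$carbonyl, ]
  expect_lt(sqrt(sum((co - sys_p$environment$anchor_position)^2)), 2)
  expect_equal(nrow(sys_p$termset$point_restraints), 1)  # TS restraint

  sys_l <- build_environment(top, "lipid_reference",
                             params = list(slab_half_width = 8))
  conf <- top$beads$role %in% c("tail", "linker")
  expect_true(all(abs(sys_l$coords[conf, 3]) <= 8))
})

test_that("velocity initialisation has zero net linear momentum", {
  sys <- build_environment(build_conjugate(5), "water_reference")
  v <- init_velocities(sys, 298.15, seed = 4)
  p <- colSums(v * sys$masses)
  expect_lt(max(abs(p)), 1e-9)
})

test_that("clash pocket penalises short linkers at the TS pose", {
  for (pocket in c("clash_pocket_A", "clash_pocket_B")) {
    env <- make_fixture(pocket)
    wall_at <- function(N) {
      sys <- build_environment(build_conjugate(N), environment = env)
      energy_components(sys)$wall
    }
    expect_gte(wall_at(2) - wall_at(6), 2)     # designed steric clash
    expect_gt(wall_at(2), wall_at(4))
  }
})

test_that("pocket_from_pdb coarse-grains the synthetic PDB fixture", {
  path <- make_fixture("mini_pdb")
  env <- pocket_from_pdb(path)
  expect_s3_class(env, "environment_model")
  expect_equal(nrow(env$wall_spheres), 3)      # one sphere per C-alpha
  expect_equal(env$anchor_position, c(0, 0, 0))  # the calcium HETATM

  # residue selection and empty-selection error
  env2 <- pocket_from_pdb(path, selection = c(1, 2))
  expect_equal(nrow(env2$wall_spheres), 2)
  expect_error(pocket_from_pdb(path, selection = 99),
               class = "plafep_selection_error")

  empty <- tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", empty)
  expect_error(pocket_from_pdb(empty), class = "plafep_selection_error")

  bad <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1      bad coords here"), bad)
  expect_error(pocket_from_pdb(bad), "line 1",
               class = "plafep_parse_error")
})
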