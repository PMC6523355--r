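# Energies, forces, the Langevin sampler, and block-error estimation.

test_that("potential_energy matches closed forms for elementary terms", {
  expect_equal(potential_energy(two_bead_bond(k = 10, r0 = 1.5,
                                              distance = 1.5)), 0)
  expect_equal(potential_energy(two_bead_bond(k = 10, r0 = 1.5,
                                              distance = 2.5)), 5)  # k/2 dr^2
  # isolated bead at the bottom of the anchor well
  sys <- plafep:::fixture_system(
    masses = 14, coords = matrix(0, 1, 3),
    termset_patch = list(anchor = c(1, 0, 0, 0, 8, 1), anchor_q = 1))
  expect_equal(potential_energy(sys), -8)
  expect_error(potential_energy(sys, matrix(NaN, 1, 3)), "non-finite")
})

test_that("analytic forces match the finite-difference oracle", {
  sys <- jiggled_system(seed = 2)
  f <- forces(sys)
  expect_lt(max(abs(f - fd_forces(sys, sys$coords))), 1e-4)
  # harmonic bond at its minimum: zero force
  expect_equal(max(abs(forces(two_bead_bond()))), 0)
})

test_that("internal forces obey Newton's third law", {
  sys <- jiggled_system(seed = 3)
  # strip external terms so only pair-additive internal forces remain
  sys$termset$walls <- matrix(0, 0, 5)
  sys$termset$anchor <- c(0, 0, 0, 0, 0, 1)
  sys$termset$point_restraints <- matrix(0, 0, 6)
  expect_lt(max(abs(colSums(forces(sys)))), 1e-8)
})

test_that("simulation_protocol validates its invariants", {
  expect_error(simulation_protocol(1000, timestep = -1), "timestep")
  expect_error(simulation_protocol(1000, friction = 0), "friction")
  expect_error(simulation_protocol(1000, equilibration_steps = 1000),
               "equilibration")
  expect_error(simulation_protocol(1000, sample_stride = 0), "stride")
})

test_that("trajectories are deterministic under a fixed seed", {
  fx <- make_fixture("harmonic_1d")
  pr <- simulation_protocol(4000, seed = 99)
  t1 <- run_simulation(fx$system, pr)
  t2 <- run_simulation(fx$system, pr)
  expect_identical(t1$scalars$potential, t2$scalars$potential)
  expect_equal(nrow(t1$scalars),
               (pr$n_steps - pr$equilibration_steps) %/% pr$sample_stride)
  pr2 <- simulation_protocol(4000, seed = 100)
  expect_false(identical(run_simulation(fx$system, pr2)$scalars$potential,
                         t1$scalars$potential))
})

test_that("sampled harmonic position variance matches equipartition", {
  fx <- make_fixture("harmonic_1d", k = 2)
  pr <- simulation_protocol(4e5, friction = 8, sample_stride = 25, seed = 11)
  tr <- run_simulation(fx$system, pr,
                       observables = list(x = list(type = "axis", i = 1,
                                                   axis = 1)))
  expect_lt(abs(var(tr$scalars$x) / fx$analytic$variance() - 1), 0.05)
})

test_that("overdamped zero-temperature dynamics quench monotonically", {
  sys <- two_bead_bond(k = 10, r0 = 1.5, distance = 2.8)
  pr <- simulation_protocol(2000, friction = 50, temperature = 0,
                            equilibration_steps = 0, sample_stride = 20,
                            seed = 1)
  tr <- run_simulation(sys, pr)
  expect_true(all(diff(tr$scalars$potential) <= 1e-9))
  expect_lt(tail(tr$scalars$potential, 1), 1e-4)
})

test_that("zero-friction integration conserves energy", {
  sys <- two_bead_bond(k = 10, r0 = 1.5, distance = 1.9)
  # gamma -> 0 turns BAOAB into velocity Verlet; drift < 1e-3 kcal/mol/ps
  pr <- simulation_protocol(5000, timestep = 0.002, friction = 1e-12,
                            temperature = 298.15, equilibration_steps = 0,
                            sample_stride = 10, seed = 2)
  tr <- run_simulation(sys, pr)
  drift <- abs(tail(tr$scalars$total, 1) - tr$scalars$total[1]) /
    (pr$n_steps * pr$timestep)
  expect_lt(drift, 1e-3)
})

test_that("holonomic distance constraints hold to tolerance", {
  sys <- two_bead_bond(k = 0.001, r0 = 2, distance = 2)
  sys$constraints <- matrix(c(0, 1, 2), 1)
  pr <- simulation_protocol(3000, equilibration_steps = 0,
                            sample_stride = 10, seed = 5)
  tr <- run_simulation(sys, pr, record_frames = TRUE,
                       observables = list(d = list(type = "pair", i = 1,
                                                   j = 2)))
  expect_lt(max(abs(tr$scalars$d - 2)), 1e-5)
})

test_that("instability raises an actionable error", {
  sys <- two_bead_bond(k = 1e6, r0 = 1.5, distance = 8)
  pr <- simulation_protocol(2000, timestep = 0.05, equilibration_steps = 0,
                            sample_stride = 1, seed = 1)
  expect_error(run_simulation(sys, pr), "timestep")
})

test_that("mean_and_error recovers closed-form standard errors", {
  expect_error(mean_and_error(rnorm(10)), class = "plafep_data_error")
  expect_equal(mean_and_error(rep(3.2, 64))$se, 0)

  set.seed(8)
  x <- rnorm(2^14)
  me <- mean_and_error(x)
  expect_equal(me$mean, mean(x))
  expect_lt(me$se / (1 / sqrt(2^14)), 1.3)
  expect_gt(me$se / (1 / sqrt(2^14)), 1 / 1.3)

  # AR(1): block SE inflates the naive SE by ~ sqrt((1+phi)/(1-phi))
  set.seed(9)
  phi <- 0.9
  ar <- as.numeric(arima.sim(list(ar = phi), 2^15))
  me <- mean_and_error(ar)
  naive <- sd(ar) / sqrt(length(ar))
  target <- sqrt((1 + phi) / (1 - phi))
  expect_lt(abs(me$se / naive - target) / target, 0.35)
})

test_that("sampled configurational distribution is Boltzmann", {
  fx <- make_fixture("harmonic_1d", k = 2)
  pr <- simulation_protocol(3e5, friction = 8, sample_stride = 30, seed = 21)
  tr <- run_simulation(fx$system, pr,
                       observables = list(x = list(type = "axis", i = 1,
                                                   axis = 1)))
  ks <- suppressWarnings(
    ks.test(tr$scalars$x, "pnorm", 0, sqrt(fx$analytic$variance())))
  expect_gt(ks$p.value, 0.01)
})

test_that("XYZ trajectories round-trip bead counts and labels", {
  sys <- two_bead_bond()
  pr <- simulation_protocol(200, equilibration_steps = 0, sample_stride = 50,
                            seed = 1)
  tr <- run_simulation(sys, pr, record_frames = TRUE)
  path <- tempfile(fileext = ".xyz")
  write_xyz(tr, sys, path)
  lines <- readLines(path)
  expect_equal(lines[1], "2")
  expect_match(lines[2], "frame 1 energy")
  expect_equal(length(lines), 4 * nrow(tr$scalars))
})
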