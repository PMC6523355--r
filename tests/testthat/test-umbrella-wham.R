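# Window schedules, umbrella sweeps, WHAM unbiasing, attachment energies.

test_that("window_schedule reproduces the published grid", {
  ws <- window_schedule()
  expect_equal(nrow(ws), 20)                      # 10 forward + 10 backward
  expect_equal(sum(ws$direction == "forward"), 10)
  expect_equal(ws$d0[ws$direction == "forward"], seq(0.5, 5, 0.5))
  expect_equal(ws$d0[ws$direction == "backward"], seq(5, 0.5, -0.5))
  expect_true(all(ws$force_constant == 4))

  expect_equal(nrow(window_schedule(2, 2)), 1)    # degenerate single window
  expect_warning(w2 <- window_schedule(1, 2, spacing = 5),
                 class = "plafep_grid_warning")
  expect_equal(w2$d0[w2$direction == "forward"], c(1, 2))
  expect_warning(window_schedule(0.5, 5, spacing = 0.7),
                 class = "plafep_grid_warning")
  expect_error(window_schedule(0, 5), class = "plafep_range_error")
})

test_that("a restrained free pair samples the analytic radial mean", {
  # one free bead biased to a fixed point: p(r) ~ r^2 exp(-beta k (r-d0)^2/2)
  sys <- plafep:::fixture_system(
    masses = 14, coords = matrix(c(2, 0, 0), 1, 3),
    termset_patch = list(point_restraints = matrix(c(0, 4, 2, 0, 0, 0), 1)),
    umbrella = list(type = "point", row = 1))
  pr <- simulation_protocol(48000, friction = 8, sample_stride = 5, seed = 13)
  ws <- window_schedule(2, 2, force_constant = 4)
  us <- run_umbrella_sweep(sys, ws, pr)
  samp <- us$windows$samples[[1]]
  beta <- 1 / RT_298
  num <- integrate(function(r) r^3 * exp(-beta * 2 * (r - 2)^2), 0, 10)$value
  den <- integrate(function(r) r^2 * exp(-beta * 2 * (r - 2)^2), 0, 10)$value
  me <- mean_and_error(samp)
  expect_lt(abs(me$mean - num / den), 3 * me$se)
})

test_that("umbrella sweeps are deterministic and validate their inputs", {
  fx <- make_fixture("flat_landscape")
  pr <- simulation_protocol(2000, sample_stride = 5, seed = 17)
  ws <- window_schedule(1, 3, 1)
  u1 <- run_umbrella_sweep(fx$system, ws, pr)
  u2 <- run_umbrella_sweep(fx$system, ws, pr)
  expect_identical(u1$windows$samples, u2$windows$samples)
  expect_error(
    run_umbrella_sweep(fx$system, ws,
                       simulation_protocol(10, equilibration_steps = 9,
                                           sample_stride = 5, seed = 1)),
    class = "plafep_data_error")
  sys <- two_bead_bond()
  sys$umbrella <- NULL
  expect_error(run_umbrella_sweep(sys, ws, pr), "umbrella")
})

test_that("WHAM recovers a flat landscape as flat", {
  # exact i.i.d. window samples isolate the solver from the sampler
  um <- synthetic_flat_umbrella(seed = 2)
  sol <- solve_wham(um)
  b <- sol$bins[sol$bins$counts >= 500, ]
  expect_lt(diff(range(b$free_energy)), 0.1)
  expect_lt(sol$final_residual, 1e-6)
  # probabilities are normalised
  expect_equal(sum(sol$bins$prob), 1, tolerance = 1e-8)

  # dynamics-sampled flat landscape
  fx <- make_fixture("flat_landscape")
  us <- run_umbrella_sweep(fx$system, window_schedule(),
                           simulation_protocol(48000, friction = 20,
                                               sample_stride = 5, seed = 19))
  solf <- solve_wham(us)
  bf <- solf$bins[solf$bins$counts >= 1000, ]
  # RMS flatness: the range statistic over ~50 correlated-sample bins
  # grows with bin count even for an unbiased solver
  expect_lt(sqrt(mean((bf$free_energy - mean(bf$free_energy))^2)), 0.1)
})

test_that("a single biased window on a flat landscape unbiases to flat", {
  um <- synthetic_flat_umbrella(d0s = 2, n_per_window = 20000, seed = 3)
  sol <- solve_wham(um)
  b <- sol$bins[sol$bins$counts >= 500, ]
  expect_lt(diff(range(b$free_energy)), 0.1)
})

test_that("disconnected windows raise an overlap error naming the gap", {
  um <- synthetic_flat_umbrella(d0s = c(0.5, 5), seed = 4)
  expect_error(solve_wham(um), "overlap",
               class = "plafep_overlap_error")
})

test_that("WHAM recovers the double-well landscape", {
  fx <- make_fixture("double_well")
  us <- run_umbrella_sweep(fx$system, window_schedule(),
                           simulation_protocol(48000, friction = 10,
                                               sample_stride = 5, seed = 23))
  pooled <- solve_wham(us)
  fwd <- solve_wham(sweep_direction(us, "forward"))
  bwd <- solve_wham(sweep_direction(us, "backward"))

  b <- pooled$bins[pooled$bins$counts >= 100 &
                     pooled$bins$center >= 0.5 & pooled$bins$center <= 5, ]
  U <- fx$analytic$potential(b$center)
  dev <- b$free_energy - (U - min(U))
  rms <- sqrt(mean((dev - mean(dev))^2))
  expect_lt(rms, 0.15)

  # bin-width halving leaves the attachment estimate nearly unchanged
  half <- solve_wham(us, bin_width = 0.05)
  att1 <- attachment_free_energy(fwd, bwd, pooled)
  att2 <- attachment_free_energy(solve_wham(sweep_direction(us, "forward"),
                                            bin_width = 0.05),
                                 solve_wham(sweep_direction(us, "backward"),
                                            bin_width = 0.05), half)
  expect_lt(abs(att1$delta_G_attach - att2$delta_G_attach), 0.05)

  # attachment free energy against the Boltzmann quadrature oracle
  beta <- 1 / RT_298
  zc <- function(lo, hi) {
    integrate(function(x) exp(-beta * fx$analytic$potential(x)), lo, hi)$value
  }
  dG_wells <- -log(zc(0.5, 2.5) / zc(2.5, 5)) / beta
  well_means <- function(sol) {
    b <- sol$bins[sol$bins$counts > 0 & sol$bins$center >= 0.5 &
                    sol$bins$center <= 5, ]
    pl <- sum(b$prob[b$center <= 2.5]); pr <- sum(b$prob[b$center > 2.5])
    -log(pl / pr) / beta
  }
  hyst_wells <- abs(well_means(fwd) - well_means(bwd)) / 2
  expect_lt(abs(well_means(pooled) - dG_wells),
            3 * max(hyst_wells, att1$hysteresis_error, 0.05))

  # pooled endpoint estimate lies between the sweeps (or within noise)
  lo <- min(att1$forward_value, att1$backward_value)
  hi <- max(att1$forward_value, att1$backward_value)
  expect_gte(att1$delta_G_attach, lo - 0.05)
  expect_lte(att1$delta_G_attach, hi + 0.05)

  # endpoint reading matches the analytic tilt within 3x hysteresis
  dG_an <- fx$analytic$potential(0.5) - fx$analytic$potential(5)
  expect_lt(abs(att1$delta_G_attach - dG_an), 3 * att1$hysteresis_error + 0.1)
})

test_that("attachment free energy is gauge invariant with zero hysteresis
           for identical sweeps", {
  um <- synthetic_flat_umbrella(seed = 5)
  sol <- solve_wham(um)
  att <- attachment_free_energy(sol, sol, sol)
  expect_equal(att$hysteresis_error, 0)
  expect_equal(att$hysteresis_error_windows, 0)
  shifted <- sol
  shifted$bins$free_energy <- shifted$bins$free_energy + 12.34
  att2 <- attachment_free_energy(shifted, shifted, shifted)
  expect_equal(att2$delta_G_attach, att$delta_G_attach, tolerance = 1e-12)
  expect_error(attachment_free_energy(sol, sol, sol, attach_d = 9),
               class = "plafep_coverage_error")
})

test_that("window CSV round-trips through the documented format", {
  um <- synthetic_flat_umbrella(d0s = c(1, 2, 3), n_per_window = 50, seed = 6)
  path <- tempfile(fileext = ".csv")
  write_windows_csv(um, path)
  back <- read_windows_csv(path, temperature = 298.15)
  expect_equal(back$windows$d0, um$windows$d0)
  expect_equal(back$windows$samples, um$windows$samples)
  sol1 <- solve_wham(um)
  sol2 <- solve_wham(back)
  expect_equal(sol1$bins$free_energy, sol2$bins$free_energy)
})
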