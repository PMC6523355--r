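# Configuration loading, fixtures, seed derivation, tabular outputs.

test_that("a minimal config is filled with the published defaults", {
  path <- tempfile(fileext = ".yaml")
  writeLines("scan:\n  linkers: [3, 4, 5]\n  anchor_linker: 4", path)
  cfg <- load_config(path)
  expect_equal(cfg$schedule$k_exponent, 4L)
  expect_equal(cfg$schedule$n_lambda, 9L)
  expect_equal(cfg$schedule$force_constant, 4.0)
  expect_equal(c(cfg$schedule$d_min, cfg$schedule$d_max,
                 cfg$schedule$spacing), c(0.5, 5.0, 0.5))
  expect_equal(cfg$scan$linkers, 3:5)
  sc <- as_scan_config(cfg)
  expect_s3_class(sc, "scan_config")
  expect_equal(sc$schedule$k_exponent, 4L)
})

test_that("config validation fails fast with field paths", {
  bad <- tempfile(fileext = ".yaml")
  writeLines("protocol:\n  timestep: -1", bad)
  expect_error(load_config(bad), "protocol.timestep",
               class = "plafep_config_error")
  unk <- tempfile(fileext = ".yaml")
  writeLines("protocoll:\n  timestep: 1", unk)
  expect_error(load_config(unk), "protocoll",
               class = "plafep_config_error")
  unk2 <- tempfile(fileext = ".yaml")
  writeLines("protocol:\n  timestepp: 1", unk2)
  expect_error(load_config(unk2), "protocol.timestepp",
               class = "plafep_config_error")
})

test_that("configs round-trip through YAML unchanged", {
  path <- tempfile(fileext = ".yaml")
  writeLines("seed: 31\nschedule:\n  n_lambda: 17", path)
  cfg <- load_config(path)
  out <- tempfile(fileext = ".yaml")
  write_config(cfg, out)
  cfg2 <- load_config(out)
  expect_equal(unclass(cfg2), unclass(cfg))
})

test_that("make_fixture knows its catalogue and rejects strangers", {
  expect_error(make_fixture("nope"), "available",
               class = "plafep_value_error")
  dw <- make_fixture("double_well")
  expect_s3_class(dw$system, "fep_system")
  expect_true(is.function(dw$analytic$potential))
  # the emitted analytic parameters describe the packaged system exactly
  s <- dw$system
  s$termset$point_restraints[1, 2] <- 0   # switch off the bias
  for (x in c(0.7, 1.5, 2.5, 4.4)) {
    expect_equal(potential_energy(s, matrix(c(x, 0, 0), 1, 3)),
                 dw$analytic$potential(x), tolerance = 1e-10)
  }
  expect_s3_class(make_fixture("clash_pocket_A"), "environment_model")
  expect_s3_class(make_fixture("clash_pocket_B"), "environment_model")
})

test_that("fixtures and schedules are deterministic constructions", {
  a <- make_fixture("clash_pocket_A")
  b <- make_fixture("clash_pocket_A")
  expect_identical(a$wall_spheres, b$wall_spheres)
  expect_identical(mixing_schedule(), mixing_schedule())
})

test_that("seed derivation is deterministic, label-sensitive and in range", {
  expect_identical(derive_seed(1, "ti", 3), derive_seed(1, "ti", 3))
  expect_false(derive_seed(1, "ti", 3) == derive_seed(1, "ti", 4))
  expect_false(derive_seed(1, "ti", 3) == derive_seed(2, "ti", 3))
  expect_false(derive_seed(1, "us", "forward", 1) ==
                 derive_seed(1, "us", "backward", 1))
  s <- vapply(1:200, function(i) derive_seed(i, "stage"), integer(1))
  expect_true(all(s >= 1 & s < 2^31))
})

test_that("TI and PMF reports are written in the documented shapes", {
  a <- make_fixture("harmonic_1d", k = 1)$system
  b <- make_fixture("harmonic_1d", k = 4)$system
  ti <- run_ti(a, b, mixing_schedule(3),
               simulation_protocol(800, sample_stride = 4, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_ti_csv(ti, path)
  df <- read.csv(path)
  expect_equal(df$record, c(rep("node", 3), "delta_A", "delta_A_error"))
  expect_equal(df$mean_dVdl[df$record == "delta_A"], ti$delta_A)
  js <- jsonlite::read_json(sub("\\.csv$", ".json", path))
  expect_equal(js$delta_A, ti$delta_A, tolerance = 1e-12)

  um <- synthetic_flat_umbrella(d0s = c(1, 2), n_per_window = 500, seed = 1)
  sol <- solve_wham(um)
  pmf <- tempfile(fileext = ".csv")
  write_pmf_csv(sol, pmf)
  expect_equal(names(read.csv(pmf)),
               c("bin_center_A", "free_energy_kcal_mol", "counts"))
})

test_that("tidiers and autoplot methods return the documented types", {
  a <- make_fixture("harmonic_1d", k = 1)$system
  b <- make_fixture("harmonic_1d", k = 4)$system
  ti <- run_ti(a, b, mixing_schedule(3),
               simulation_protocol(800, sample_stride = 4, seed = 2))
  expect_s3_class(tidy(ti), "tbl_df")
  expect_named(glance(ti),
               c("delta_A", "delta_A_error", "n_nodes", "n_samples"))
  expect_s3_class(autoplot(ti), "ggplot")
  um <- synthetic_flat_umbrella(d0s = c(1, 2), n_per_window = 500, seed = 1)
  sol <- solve_wham(um)
  expect_s3_class(tidy(sol), "tbl_df")
  expect_s3_class(autoplot(sol), "ggplot")
  expect_s3_class(tidy(um), "tbl_df")
  expect_equal(nrow(tidy(um)), 1000)
})

test_that("the command-line entry point exposes the documented subcommands", {
  cli <- system.file("cli", "plafep.R", package = "plafep")
  expect_true(nzchar(cli))
  src <- readLines(cli)
  for (sub in c("build", "ti", "umbrella", "wham", "cycle", "scan",
                "validate", "fixtures")) {
    expect_true(any(grepl(paste0('"', sub, '"'), src)), info = sub)
  }
})
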