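# Thermodynamic cycle assembly, rate mapping, scan bookkeeping.

fake_ti <- function(dA, err, env = "water_reference", pair = c(4L, 3L)) {
  structure(list(per_node = tibble::tibble(), delta_A = dA,
                 delta_A_error = err, protocol = NULL, schedule = NULL,
                 meta = list(environment = env, linker_pair = pair,
                             n_removed = 1L)),
            class = "fep_ti")
}

fake_attach <- function(dG, hyst, env = "water_reference") {
  out <- structure(
    list(delta_G_attach = dG, hysteresis_error = hyst,
         delta_G_attach_windows = dG, hysteresis_error_windows = hyst,
         forward_value = dG, backward_value = dG,
         attach_d = 0.5, detach_d = 5), class = "fep_attachment")
  attr(out, "environment") <- env
  out
}

test_that("state_free_energy sums components with quadrature errors", {
  st <- state_free_energy(fake_ti(1.2, 0.1), fake_attach(-0.4, 0.1),
                          "initial_water")
  expect_equal(st$delta_G_mod, 0.8)
  expect_equal(st$error, sqrt(0.02), tolerance = 1e-12)
  expect_equal(unname(st$components["ti_delta_A"] +
                        st$components["us_delta_G_attach"]),
               st$delta_G_mod, tolerance = 1e-12)

  zero <- state_free_energy(fake_ti(1.2, 0.1), fake_attach(0, 0),
                            "initial_water")
  expect_equal(zero$delta_G_mod, 1.2)

  # environment mismatch between legs and requested state
  expect_error(state_free_energy(fake_ti(1, 0.1), fake_attach(0, 0),
                                 "final_ts_complex"),
               class = "plafep_mismatch_error")
  expect_error(
    state_free_energy(fake_ti(1, 0.1, env = "ts_pocket"),
                      fake_attach(0, 0), "initial_water"),
    class = "plafep_mismatch_error")
})

test_that("compose_cycle implements the cycle difference with antisymmetry", {
  ini <- state_free_energy(fake_ti(0.5, 0.05), fake_attach(0, 0),
                           "initial_water")
  fin <- state_free_energy(fake_ti(2.0, 0.05, env = "ts_pocket"),
                           fake_attach(0, 0, env = "ts_pocket"),
                           "final_ts_complex")
  cy <- compose_cycle(ini, fin)
  expect_equal(cy$delta_delta_G_tr, 1.5)
  expect_equal(cy$reference, "water")

  same <- compose_cycle(ini, state_free_energy(
    fake_ti(0.5, 0.05, env = "ts_pocket"),
    fake_attach(0, 0, env = "ts_pocket"), "final_ts_complex"))
  expect_equal(same$delta_delta_G_tr, 0)

  expect_error(compose_cycle(fin, fin), class = "plafep_mismatch_error")
  ini5 <- state_free_energy(fake_ti(0.5, 0.05, pair = c(5L, 4L)),
                            fake_attach(0, 0), "initial_water")
  expect_error(compose_cycle(ini5, fin), class = "plafep_mismatch_error")
  # swapping roles is rejected rather than silently sign-flipped
  expect_error(compose_cycle(fin, ini), class = "plafep_mismatch_error")
})

test_that("relative_rate implements the Boltzmann rate map", {
  expect_equal(relative_rate(0), 1)
  expect_equal(relative_rate(-1.3643, 298.15), 10, tolerance = 1e-3)
  RT <- gas_constant_kcal() * 298.15
  expect_equal(relative_rate(RT), exp(-1))
  expect_error(relative_rate(1, temperature = -5))

  # order-reversing: higher binding free energy, strictly lower rate
  g <- sort(runif(10, -3, 3))
  expect_true(all(diff(relative_rate(g)) < 0))
  # gauge invariance: only differences matter
  expect_equal(relative_rate(g - 1.7) / relative_rate(0 - 1.7),
               relative_rate(g) / relative_rate(0), tolerance = 1e-12)
})

test_that("a minimal scan produces consistent bookkeeping", {
  cfg <- scan_config(linkers = 2:3, references = "water", anchor_linker = 3,
                     ti_steps = 3000, us_steps = 2500, sample_stride = 5,
                     seed = 7)
  scan <- run_linker_scan(cfg)
  r <- scan$results
  expect_equal(nrow(r), 2)                      # anchor and one partner
  expect_equal(r$rel_G_tr[r$N == 3], 0)
  expect_equal(r$rel_rate[r$N == 3], 1)
  RT <- gas_constant_kcal() * cfg$temperature
  expect_equal(r$rel_rate, exp(-r$rel_G_tr / RT), tolerance = 1e-12)
  expect_equal(nrow(scan$cycles), 1)
  expect_false(scan$incomplete)
  expect_s3_class(glance(scan), "tbl_df")

  # provenance manifest and CSV output
  path <- tempfile(fileext = ".csv")
  write_scan_csv(scan, path)
  expect_true(file.exists(path))
  man <- jsonlite::read_json(sub("\\.csv$", "_manifest.json", path))
  expect_equal(man$root_seed, 7L)
  expect_false(man$incomplete)
})

test_that("scan caching makes stages resumable", {
  cache <- file.path(tempdir(), "plafep-cache-test")
  unlink(cache, recursive = TRUE)
  cfg <- scan_config(linkers = 2:3, references = "water", anchor_linker = 3,
                     ti_steps = 2000, us_steps = 2000, sample_stride = 5,
                     seed = 9, cache_dir = cache)
  s1 <- run_linker_scan(cfg)
  expect_gt(length(list.files(cache)), 0)
  t0 <- Sys.time()
  s2 <- run_linker_scan(cfg)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
  expect_equal(s1$results$rel_G_tr, s2$results$rel_G_tr)
  unlink(cache, recursive = TRUE)
})
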