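# interface: tabular output formats (tidy CSV, JSON mirrors).

#' Write umbrella window time series as tidy CSV
#'
#' Columns: `window_id`, `direction`, `d0_A`, `k_kcal_mol_A2`, `step`,
#' `distance_A` — the interchange format that lets external samplers feed
#' the WHAM estimator.
#'
#' @param umbrella A `fep_umbrella`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_csv <- function(umbrella, path) {
  stopifnot(inherits(umbrella, "fep_umbrella"))
  df <- tidyr::unnest(
    dplyr::mutate(umbrella$windows,
                  step = purrr::map(.data$samples, seq_along)),
    c("samples", "step"))
  out <- tibble(window_id = df$window_id, direction = df$direction,
                d0_A = df$d0, k_kcal_mol_A2 = df$force_constant,
                step = df$step, distance_A = df$samples)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read umbrella window time series from tidy CSV
#'
#' @param path CSV written by [write_windows_csv()] (or an external
#'   sampler using the same columns).
#' @param temperature Sampling temperature, K (not stored in the CSV).
#' @return A `fep_umbrella` suitable for [solve_wham()].
#' @export
read_windows_csv <- function(path, temperature = 298.15) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("window_id", "direction", "d0_A", "k_kcal_mol_A2", "distance_A")
  if (!all(need %in% names(df))) {
    stop_plafep(sprintf("window CSV must contain columns: %s",
                        paste(need, collapse = ", ")),
                "plafep_parse_error")
  }
  grp <- dplyr::group_by(df, .data$window_id, .data$direction, .data$d0_A,
                         .data$k_kcal_mol_A2)
  win <- dplyr::summarise(grp, samples = list(.data$distance_A),
                          .groups = "drop")
  win <- dplyr::arrange(win, .data$window_id)
  windows <- tibble(window_id = win$window_id, direction = win$direction,
                    d0 = win$d0_A, force_constant = win$k_kcal_mol_A2,
                    samples = win$samples,
                    n_samples = vapply(win$samples, length, integer(1)))
  structure(list(windows = windows, protocol = NULL,
                 temperature = temperature),
            class = "fep_umbrella")
}

#' Write a TI report as CSV (with JSON mirror)
#'
#' Node rows carry (`lambda`, `mean_dVdl`, `se`, `n_samples`); footer rows
#' (`record` = `delta_A`, `delta_A_error`) carry the integrated result.
#'
#' @param ti A `fep_ti`.
#' @param path Output CSV path; a `.json` mirror is written alongside.
#' @return `path`, invisibly.
#' @export
write_ti_csv <- function(ti, path) {
  stopifnot(inherits(ti, "fep_ti"))
  body <- dplyr::mutate(ti$per_node, record = "node")
  footer <- tibble(lambda = NA_real_, weight = NA_real_,
                   mean_dVdl = c(ti$delta_A, ti$delta_A_error),
                   se = NA_real_, n_samples = NA_integer_,
                   record = c("delta_A", "delta_A_error"))
  write.csv(dplyr::bind_rows(body, footer), path, row.names = FALSE)
  jsonlite::write_json(
    list(per_node = ti$per_node, delta_A = ti$delta_A,
         delta_A_error = ti$delta_A_error),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a potential of mean force as CSV
#'
#' Columns: `bin_center_A`, `free_energy_kcal_mol`, `counts`.
#'
#' @param wham A `fep_wham`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pmf_csv <- function(wham, path) {
  stopifnot(inherits(wham, "fep_wham"))
  out <- tibble(bin_center_A = wham$bins$center,
                free_energy_kcal_mol = wham$bins$free_energy,
                counts = wham$bins$counts)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

config_hash <- function(x) {
  derive_seed(0, paste(deparse(x), collapse = ""))
}

#' Write linker-scan results as CSV plus a provenance manifest
#'
#' The CSV carries (`reference`, `N`, `rel_G_tr_kcal_mol`, `error`,
#' `rel_rate`); the JSON manifest records the root seed, per-stage derived
#' seeds, protocol sizes, and a fixture hash.
#'
#' @param scan A `fep_scan`.
#' @param path Output CSV path.
#' @param manifest_path Output JSON path (defaults next to `path`).
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path,
                           manifest_path = sub("\\.csv$", "_manifest.json",
                                               path)) {
  stopifnot(inherits(scan, "fep_scan"))
  out <- tibble(reference = scan$results$reference, N = scan$results$N,
                rel_G_tr_kcal_mol = scan$results$rel_G_tr,
                error = scan$results$error, rel_rate = scan$results$rel_rate)
  write.csv(out, path, row.names = FALSE)
  cfg <- scan$config
  stage_seeds <- list()
  for (env_name in c("pocket", cfg$references)) {
    for (N in rev(setdiff(cfg$linkers, min(cfg$linkers)))) {
      stage_seeds[[sprintf("%s_N%d", env_name, N)]] <- list(
        ti = derive_seed(cfg$seed, env_name, N, "ti"),
        us = derive_seed(cfg$seed, env_name, N, "us"))
    }
  }
  jsonlite::write_json(
    list(root_seed = cfg$seed, stage_seeds = stage_seeds,
         ti_steps = cfg$ti_steps, us_steps = cfg$us_steps,
         timestep = cfg$timestep, friction = cfg$friction,
         temperature = cfg$temperature,
         anchor_linker = cfg$anchor_linker,
         pocket_hash = config_hash(cfg$pocket),
         incomplete = scan$incomplete),
    manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
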