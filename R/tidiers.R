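# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and summarise TI results
#'
#' `tidy()` returns the per-node table; `glance()` the integrated free
#' energy difference with its quadrature-propagated error.
#'
#' @param x A `fep_ti`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy fep_ti
#' @export
tidy.fep_ti <- function(x, ...) x$per_node

#' @rdname tidy.fep_ti
#' @method glance fep_ti
#' @export
glance.fep_ti <- function(x, ...) {
  tibble(delta_A = x$delta_A, delta_A_error = x$delta_A_error,
         n_nodes = nrow(x$per_node),
         n_samples = sum(x$per_node$n_samples))
}

#' Tidy and summarise WHAM solutions
#'
#' `tidy()` returns the binned profile; `glance()` convergence facts.
#'
#' @param x A `fep_wham`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy fep_wham
#' @export
tidy.fep_wham <- function(x, ...) x$bins

#' @rdname tidy.fep_wham
#' @method glance fep_wham
#' @export
glance.fep_wham <- function(x, ...) {
  tibble(n_bins = nrow(x$bins), bin_width = x$bin_width,
         n_iterations = x$n_iterations, final_residual = x$final_residual,
         temperature = x$temperature)
}

#' Tidy an umbrella sweep into long format
#'
#' @param x A `fep_umbrella`.
#' @param ... Unused.
#' @return A tibble with one row per recorded sample.
#' @method tidy fep_umbrella
#' @export
tidy.fep_umbrella <- function(x, ...) {
  df <- dplyr::mutate(x$windows,
                      step = purrr::map(.data$samples, seq_along))
  out <- tidyr::unnest(df, c("samples", "step"))
  dplyr::select(out, "window_id", "direction", "d0", "force_constant",
                "step", distance = "samples")
}

#' Tidy and summarise a linker scan
#'
#' `tidy()` returns the relative free-energy/rate table; `glance()` the
#' rate-optimal linker length per reference state.
#'
#' @param x A `fep_scan`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy fep_scan
#' @export
tidy.fep_scan <- function(x, ...) x$results

#' @rdname tidy.fep_scan
#' @method glance fep_scan
#' @export
glance.fep_scan <- function(x, ...) {
  grp <- dplyr::group_by(x$results, .data$reference)
  dplyr::summarise(grp,
                   optimal_linker = .data$N[which.max(.data$rel_rate)],
                   spread_kcal_mol = max(.data$rel_G_tr) - min(.data$rel_G_tr),
                   incomplete = x$incomplete, .groups = "drop")
}

#' Plot the per-node TI integrand
#'
#' @param object A `fep_ti`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fep_ti
#' @export
autoplot.fep_ti <- function(object, ...) {
  ggplot2::ggplot(object$per_node, ggplot2::aes(x = .data$lambda,
                                                y = .data$mean_dVdl)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_dVdl - .data$se,
                                          ymax = .data$mean_dVdl + .data$se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(lambda),
                  y = expression(paste("<", partialdiff * V /
                                         partialdiff * lambda, "> (kcal/mol)")),
                  title = sprintf("dA = %.3f +/- %.3f kcal/mol",
                                  object$delta_A, object$delta_A_error))
}

#' Plot a potential of mean force
#'
#' @param object A `fep_wham`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fep_wham
#' @export
autoplot.fep_wham <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$center,
                                            y = .data$free_energy)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "reaction coordinate (Å)",
                  y = "free energy (kcal/mol)")
}

#' Plot a linker scan profile
#'
#' Relative transition-state binding free energy against linker length,
#' one line per reference state, with error bars.
#'
#' @param object A `fep_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fep_scan
#' @export
autoplot.fep_scan <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$N, y = .data$rel_G_tr,
                               colour = .data$reference)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$rel_G_tr - .data$error,
                                          ymax = .data$rel_G_tr + .data$error)) +
    ggplot2::labs(x = "linker length (CH2 units)",
                  y = expression(paste(Delta * G[tr], " relative to anchor (kcal/mol)")))
}

#' @rdname autoplot.fep_wham
#' @param wham A `fep_wham`.
#' @export
plot_pmf <- function(wham, ...) autoplot(wham, ...)

#' @rdname autoplot.fep_scan
#' @param scan A `fep_scan`.
#' @export
plot_linker_scan <- function(scan, ...) autoplot(scan, ...)
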