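# umbrella_wham: self-consistent WHAM unbiasing and the attachment free
# energy with forward/backward hysteresis.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Solve WHAM for a set of umbrella windows
#'
#' Standard self-consistent iteration over binned counts with per-window
#' bias `w_j(x) = k_j/2 (x - d0_j)^2`, performed in log space.  Bins with
#' zero total counts are excluded from the profile.  The unbiased profile
#' (potential of mean force) is gauge-fixed to zero at its minimum; window
#' free energies use the `f_1 = 0` gauge.
#'
#' @param windows A `fep_umbrella` (all windows share one temperature).
#' @param bin_width Histogram bin width, A.
#' @param tolerance Convergence threshold on `max |delta f_j|`, kcal/mol.
#' @param max_iterations Iteration cap.
#' @return A `fep_wham` object: `bins` tibble (`center`, `free_energy`,
#'   `counts`, `prob`), `window_f` tibble (`window_id`, `direction`, `d0`,
#'   `f`), `n_iterations`, `final_residual`, `bin_width`, `temperature`.
#' @export
solve_wham <- function(windows, bin_width = 0.1, tolerance = 1e-6,
                       max_iterations = 1e5) {
  stopifnot(inherits(windows, "fep_umbrella"))
  wtab <- windows$windows
  if (nrow(wtab) < 1 || any(wtab$n_samples < 1)) {
    stop_plafep("insufficient data: empty umbrella windows",
                "plafep_data_error")
  }
  RT <- GAS_CONSTANT_KCAL * windows$temperature
  all_s <- unlist(wtab$samples)
  lo <- floor(min(all_s) / bin_width) * bin_width
  hi <- ceiling(max(all_s) / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (length(edges) < 2) edges <- c(lo, lo + bin_width)
  centers <- head(edges, -1) + bin_width / 2
  L <- length(centers)
  J <- nrow(wtab)

  counts <- matrix(0, J, L)
  for (j in seq_len(J)) {
    idx <- pmin(pmax(floor((wtab$samples[[j]] - lo) / bin_width) + 1, 1), L)
    tb <- tabulate(idx, nbins = L)
    counts[j, ] <- tb
  }
  n_l <- colSums(counts)
  occupied <- n_l > 0

  # connectivity: windows sharing occupied bins must chain across the range
  occ_rng <- t(vapply(seq_len(J), function(j) {
    o <- which(counts[j, ] > 0)
    c(min(o), max(o))
  }, numeric(2)))
  ord <- order(wtab$d0)
  rng_sorted <- occ_rng[ord, , drop = FALSE]
  reach <- rng_sorted[1, 2]
  for (j in seq_len(J)[-1]) {
    if (rng_sorted[j, 1] > reach) {
      stop_plafep(sprintf(
        "disconnected histograms: no sampled overlap between d0 = %.3f and d0 = %.3f A",
        wtab$d0[ord[j - 1]], wtab$d0[ord[j]]), "plafep_overlap_error")
    }
    reach <- max(reach, rng_sorted[j, 2])
  }

  N_j <- wtab$n_samples
  bias <- outer(seq_len(J), seq_len(L), function(j, l) {
    0.5 * wtab$force_constant[j] * (centers[l] - wtab$d0[j])^2
  })
  bb <- bias / RT                     # beta * b_jl
  logN <- log(N_j)
  f <- rep(0, J)                      # in units of RT
  iter <- 0L
  resid <- Inf
  log_nl <- ifelse(occupied, log(n_l), -Inf)
  while (iter < max_iterations) {
    iter <- iter + 1L
    # log denominator per bin: logsumexp_j( log N_j + f_j - bb_jl )
    M <- logN + f - bb                # J x L via recycling (f, logN length J)
    mmax <- apply(M, 2, max)
    logden <- mmax + log(colSums(exp(sweep(M, 2, mmax))))
    logp <- log_nl - logden
    # f_j = -log sum_l exp(logp_l - bb_jl)
    P <- matrix(logp, J, L, byrow = TRUE) - bb
    pmax_ <- apply(P, 1, max)
    f_new <- -(pmax_ + log(rowSums(exp(P - pmax_))))
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f)) * RT
    f <- f_new
    if (resid < tolerance) break
  }
  if (resid >= tolerance) {
    stop_plafep(sprintf(
      "WHAM failed to converge in %d iterations (final residual %.3g kcal/mol)",
      as.integer(max_iterations), resid), "plafep_convergence_error")
  }
  M <- logN + f - bb
  mmax <- apply(M, 2, max)
  logden <- mmax + log(colSums(exp(sweep(M, 2, mmax))))
  logp <- log_nl - logden
  lz <- logsumexp(logp[occupied])
  logp <- logp - lz                   # probabilities sum to 1 over bins
  G <- -RT * logp
  G <- G - min(G[occupied])

  bins <- tibble(center = centers, free_energy = G, counts = n_l,
                 prob = exp(logp))[occupied, ]
  window_f <- tibble(window_id = wtab$window_id, direction = wtab$direction,
                     d0 = wtab$d0, f = f * RT)
  structure(list(bins = bins, window_f = window_f,
                 n_iterations = iter, final_residual = resid,
                 bin_width = bin_width, temperature = windows$temperature),
            class = "fep_wham")
}

#' @export
print.fep_wham <- function(x, ...) {
  cat(sprintf(
    "<fep_wham> %d occupied bins (%.2f A wide), converged in %d iterations (residual %.2g)\n",
    nrow(x$bins), x$bin_width, x$n_iterations, x$final_residual))
  invisible(x)
}

# profile value at a distance, linear interpolation over occupied bins
profile_value <- function(wham, d) {
  b <- wham$bins
  if (d < min(b$center) - wham$bin_width / 2 ||
      d > max(b$center) + wham$bin_width / 2) {
    stop_plafep(sprintf(
      "coverage error: %.3f A is outside the sampled profile [%.3f, %.3f]",
      d, min(b$center), max(b$center)), "plafep_coverage_error")
  }
  approx(b$center, b$free_energy, xout = d, rule = 2)$y
}

# window free-energy value at a bias distance (mean over directions present)
window_value <- function(wham, d) {
  wf <- wham$window_f
  hit <- abs(wf$d0 - d) < 1e-9
  if (!any(hit)) {
    stop_plafep(sprintf(
      "coverage error: no umbrella window at d0 = %.3f A", d),
      "plafep_coverage_error")
  }
  mean(wf$f[hit])
}

#' Attachment free energy with hysteresis error
#'
#' The headline `delta_G_attach` follows the profile endpoint-difference
#' convention: pooled PMF at the attach distance minus pooled PMF at the
#' detach plateau.  The hysteresis error is half the difference between the
#' forward-only and backward-only estimates.  `delta_G_attach_windows` is
#' the Boltzmann-integrated alternative, read from the WHAM window free
#' energies `f(d0 = attach) - f(d0 = detach)`: it is the free energy
#' difference between the two restrained window ensembles, which is the
#' quantity a thermodynamic cycle built from restrained states needs (see
#' the methods vignette), and is what [state_free_energy()] uses by default.
#'
#' @param forward,backward,pooled `fep_wham` solutions for the forward
#'   sweep, the backward sweep, and both pooled.
#' @param attach_d Attached-state distance, A (grid minimum by default).
#' @param detach_d Detached plateau distance, A (grid maximum by default).
#' @return A `fep_attachment` object.
#' @export
attachment_free_energy <- function(forward, backward, pooled,
                                   attach_d = 0.5, detach_d = 5.0) {
  stopifnot(inherits(forward, "fep_wham"), inherits(backward, "fep_wham"),
            inherits(pooled, "fep_wham"))
  has_win <- function(sol, d) any(abs(sol$window_f$d0 - d) < 1e-9)
  dg <- function(sol) {
    tryCatch(
      profile_value(sol, attach_d) - profile_value(sol, detach_d),
      plafep_coverage_error = function(e) {
        # a strongly repulsive landscape can leave the grid minimum
        # unsampled; fall back to NA if the window reading still exists,
        # otherwise the requested distance is genuinely uncovered
        if (has_win(sol, attach_d) && has_win(sol, detach_d)) NA_real_
        else stop(e)
      })
  }
  dgw <- function(sol) {
    tryCatch(window_value(sol, attach_d) - window_value(sol, detach_d),
             plafep_coverage_error = function(e) dg(sol))
  }
  fwd <- dg(forward); bwd <- dg(backward); pool <- dg(pooled)
  fwd_w <- dgw(forward); bwd_w <- dgw(backward); pool_w <- dgw(pooled)
  structure(
    list(delta_G_attach = pool,
         hysteresis_error = abs(fwd - bwd) / 2,
         delta_G_attach_windows = pool_w,
         hysteresis_error_windows = abs(fwd_w - bwd_w) / 2,
         forward_value = fwd, backward_value = bwd,
         attach_d = attach_d, detach_d = detach_d,
         forward_profile = forward, backward_profile = backward,
         pooled_profile = pooled),
    class = "fep_attachment")
}

#' @export
print.fep_attachment <- function(x, ...) {
  cat(sprintf(
    "<fep_attachment> dG(%.1f <- %.1f A) = %.4f kcal/mol (hysteresis %.4f); window-ensemble %.4f (hysteresis %.4f)\n",
    x$attach_d, x$detach_d, x$delta_G_attach, x$hysteresis_error,
    x$delta_G_attach_windows, x$hysteresis_error_windows))
  invisible(x)
}
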