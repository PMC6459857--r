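#' Conformational state of a labelled molecule
#'
#' One conformational state as seen by the dyes: a (Gaussian-distributed)
#' inter-dye distance, the donor fluorescence lifetime in that state, and the
#' rotational mobility of the label.
#'
#' @param label Short name.
#' @param R_DA Mean inter-dye distance, Å.  `Inf` marks a donor-only species
#'   (single-label anisotropy experiments).
#' @param sigma_DA Half-width (Gaussian sd) of the distance distribution, Å.
#' @param tau_D Donor fluorescence lifetime in this state, ns (already
#'   including FRET quenching where applicable; see [donor_lifetime()]).
#' @param rho Rotational correlation time of the label, ns.
#' @param r0 Fundamental anisotropy (0 < r0 <= 0.4).
#' @return A `dye_state` list.
#' @export
dye_state <- function(label, R_DA, sigma_DA = 0, tau_D = 4, rho = 10,
                      r0 = 0.38) {
  stopifnot(R_DA > 0, sigma_DA >= 0, tau_D > 0, rho > 0, r0 > 0, r0 <= 0.4)
  structure(list(label = label, R_DA = R_DA, sigma_DA = sigma_DA,
                 tau_D = tau_D, rho = rho, r0 = r0),
            class = "dye_state")
}

#' Donor lifetime consistent with a FRET distance
#'
#' `tau_D(A) = tau0 * (1 - E(R))`: the lifetime a donor with unquenched
#' lifetime `tau0` has when quenched by FRET at distance `R`.
#' @param R Distance, Å.
#' @param R0 Förster radius, Å.
#' @param tau0 Unquenched donor lifetime, ns.
#' @export
donor_lifetime <- function(R, R0, tau0) {
  tau0 * (1 - efficiency_from_distance(R, R0))
}

#' k-state conformational exchange model
#'
#' States plus a first-order rate matrix.  Off-diagonal entry `[i, j]` is the
#' i -> j interconversion rate in 1/s; the diagonal is set so each row sums
#' to zero.  The chain must be ergodic (a single communicating class) when
#' more than one state is present.
#'
#' @param states List of [dye_state] objects.
#' @param rates k x k matrix of rates (diagonal ignored/overwritten), or
#'   NULL for a single state.
#' @param R0 Förster radius, Å.
#' @return An `exchange_model` with the generator `Q`, its spectral
#'   decomposition, and the stationary distribution `pi`.
#' @export
exchange_model <- function(states, rates = NULL, R0 = 53.0) {
  if (inherits(states, "dye_state")) states <- list(states)
  stopifnot(length(states) >= 1, R0 > 0)
  k <- length(states)
  if (is.null(rates)) rates <- matrix(0, k, k)
  rates <- as.matrix(rates)
  stopifnot(nrow(rates) == k, ncol(rates) == k)
  off <- rates; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be >= 0")
  Q <- off
  diag(Q) <- -rowSums(off)
  if (k > 1) {
    # ergodicity: the embedded graph must be strongly connected
    reach <- (off > 0) | diag(TRUE, k)
    for (i in seq_len(k)) reach <- (reach %*% reach) > 0
    if (!all(reach))
      stop("rate matrix is not ergodic: some states are unreachable")
  }
  pi0 <- if (k == 1) 1 else {
    # stationary distribution: left null vector of Q
    e <- eigen(t(Q))
    i0 <- which.min(abs(e$values))
    v <- Re(e$vectors[, i0])
    v / sum(v)
  }
  if (any(pi0 < -1e-8)) stop("invalid stationary distribution")
  pi0 <- pmax(pi0, 0); pi0 <- pi0 / sum(pi0)
  ed <- eigen(Q)
  structure(list(states = states, Q = Q, R0 = R0, pi = pi0,
                 V = Re(ed$vectors), lambda = Re(ed$values),
                 Vinv = Re(solve(ed$vectors))),
            class = "exchange_model")
}

#' @export
print.exchange_model <- function(x, ...) {
  cat(sprintf("<exchange_model> %d state(s), R0 = %.1f A\n",
              length(x$states), x$R0))
  for (i in seq_along(x$states)) {
    s <- x$states[[i]]
    cat(sprintf("  [%d] %-8s R_DA = %5.1f A (hw %.1f), tau_D = %.2f ns, rho = %.2f ns, pi = %.3f\n",
                i, s$label, s$R_DA, s$sigma_DA, s$tau_D, s$rho, x$pi[i]))
  }
  invisible(x)
}

#' Confocal detection model
#'
#' Parameters of the detection volume and registration electronics used by
#' the photon-stream simulator.  Defaults emulate a dilute single-molecule
#' measurement producing on the order of one usable burst per second with a
#' diffusion time of 1.7 ms.
#'
#' @param t_diff Diffusion time through the detection volume, ms.
#' @param mean_occupancy Mean number of molecules in the volume (a warning is
#'   issued above 0.1, where bursts start to overlap routinely).
#' @param brightness Peak detected photon rate per molecule, kHz.
#' @param background Per-channel Poisson background rates, kHz, length 4 in
#'   channel order (G par, G perp, R par, R perp).
#' @param g_factor Polarisation detection-efficiency ratio eta_par/eta_perp.
#' @param det_ratio_gr Green/red detection-efficiency ratio.
#' @param excitation_period Laser excitation period, ns (64 MHz -> 15.625).
#' @param irf_sigma,irf_t0 Gaussian instrument-response width and offset, ns.
#' @export
confocal_model <- function(t_diff = 1.7, mean_occupancy = 0.005,
                           brightness = 60, background = rep(0.3, 4),
                           g_factor = 1, det_ratio_gr = 1,
                           excitation_period = 15.625,
                           irf_sigma = 0.25, irf_t0 = 2.0) {
  stopifnot(t_diff > 0, mean_occupancy > 0, brightness >= 0,
            length(background) == 4, all(background >= 0),
            g_factor > 0, det_ratio_gr > 0, excitation_period > 0,
            irf_sigma >= 0, irf_t0 >= 0)
  if (mean_occupancy > 0.1)
    warning("mean_occupancy > 0.1: bursts will frequently overlap")
  structure(list(t_diff = t_diff, mean_occupancy = mean_occupancy,
                 brightness = brightness, background = background,
                 g_factor = g_factor, det_ratio_gr = det_ratio_gr,
                 excitation_period = excitation_period,
                 irf_sigma = irf_sigma, irf_t0 = irf_t0),
            class = "confocal_model")
}

#' Channel labels used throughout the package
#' @return Character vector of the four detection channels.
#' @export
channel_levels <- function() c("Gp", "Gs", "Rp", "Rs")
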