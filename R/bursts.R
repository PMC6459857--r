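#' Calibration parameters for MFD observables
#'
#' Correction factors applied when converting raw channel counts into
#' fluorescence observables.
#'
#' @param g_factor Polarisation detection-efficiency ratio eta_par/eta_perp.
#' @param gamma Detection-efficiency/quantum-yield ratio entering the
#'   proximity-ratio denominator `F_A / (F_A + gamma F_D)`.
#' @param crosstalk Fraction of donor signal leaking into the red channels.
#' @param direct_excitation Fraction of total signal attributed to directly
#'   excited acceptor, subtracted from the acceptor signal.
#' @param bg_rates Background rates per channel (Gp, Gs, Rp, Rs), kHz.
#' @param R0 Förster radius, Å.
#' @param l1,l2 Polarisation mixing factors of the objective (default 0).
#' @param censor_R Distance (Å) at which zero-acceptor segments are
#'   right-censored.
#' @return A `calibration` list.
#' @export
calibration <- function(g_factor = 1, gamma = 1, crosstalk = 0,
                        direct_excitation = 0, bg_rates = rep(0.3, 4),
                        R0 = 53.0, l1 = 0, l2 = 0, censor_R = 150) {
  stopifnot(g_factor > 0, gamma > 0, crosstalk >= 0, direct_excitation >= 0,
            length(bg_rates) == 4, all(bg_rates >= 0), R0 > 0, censor_R > 0)
  structure(list(g_factor = g_factor, gamma = gamma, crosstalk = crosstalk,
                 direct_excitation = direct_excitation, bg_rates = bg_rates,
                 R0 = R0, l1 = l1, l2 = l2, censor_R = censor_R),
            class = "calibration")
}

#' Calibration matching a simulation setup
#'
#' Builds the [calibration] implied by the parameters of a
#' [confocal_model] used to simulate a stream.
#' @param confocal A [confocal_model].
#' @param R0 Förster radius, Å.
#' @export
calibration_from_confocal <- function(confocal, R0 = 53.0) {
  calibration(g_factor = confocal$g_factor, gamma = 1,
              bg_rates = confocal$background, R0 = R0)
}

#' All-photon sliding-window burst search
#'
#' Lee-filter style burst search: the interphoton time series is smoothed
#' with a centred running mean over `smoothing_window` photons; runs of
#' photons whose smoothed interphoton time stays below `max_interphoton`
#' form candidate bursts, which are kept when their photon count exceeds
#' `min_photons` after subtracting the expected background contribution.
#'
#' @param stream A `photon_stream`.
#' @param min_photons Minimum background-corrected photons per burst.
#' @param max_interphoton Smoothed interphoton-time threshold, ms.
#' @param smoothing_window Running-mean window length, photons.
#' @param bg_rate_khz Total background rate used for the count correction,
#'   kHz; defaults to the stream metadata when present, else 0.
#' @return A tibble of disjoint, time-ordered bursts: `burst`, `start_idx`,
#'   `stop_idx` (photon indices into the stream), `t_start` (s),
#'   `duration_ms`, `n_photons`, and per-channel counts `n_Gp` ... `n_Rs`.
#' @export
find_bursts <- function(stream, min_photons = 60, max_interphoton = 0.1,
                        smoothing_window = 30, bg_rate_khz = NULL) {
  stopifnot(min_photons > 0, max_interphoton > 0, smoothing_window > 0)
  n <- nrow(stream)
  if (is.null(bg_rate_khz)) {
    meta <- attr(stream, "metadata")
    bg_rate_khz <- if (!is.null(meta$background_khz))
      sum(meta$background_khz) else 0
  }
  empty <- tibble::tibble(
    burst = integer(), start_idx = integer(), stop_idx = integer(),
    t_start = numeric(), duration_ms = numeric(), n_photons = integer(),
    n_Gp = integer(), n_Gs = integer(), n_Rp = integer(), n_Rs = integer())
  if (n < max(smoothing_window + 1, min_photons)) return(empty)

  ipt <- diff(stream$macro_time) * 1e3          # ms
  k <- min(smoothing_window, length(ipt))
  sm <- stats::filter(ipt, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- ipt[is.na(sm)]
  inburst <- sm < max_interphoton               # gap i joins photons i, i+1
  r <- rle(as.vector(inburst))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (!length(keep)) return(empty)

  out <- purrr::map_dfr(keep, function(j) {
    i0 <- starts[j]; i1 <- ends[j] + 1L          # photon index range
    dur <- (stream$macro_time[i1] - stream$macro_time[i0]) * 1e3
    nph <- i1 - i0 + 1L
    tibble::tibble(start_idx = i0, stop_idx = i1, t_start = stream$macro_time[i0],
                   duration_ms = dur, n_photons = nph)
  })
  bg_expected <- bg_rate_khz * out$duration_ms
  out <- out[out$n_photons - bg_expected >= min_photons, , drop = FALSE]
  if (!nrow(out)) return(empty)
  ch <- as.integer(stream$channel)
  counts <- t(vapply(seq_len(nrow(out)), function(i) {
    tabulate(ch[out$start_idx[i]:out$stop_idx[i]], nbins = 4)
  }, integer(4)))
  out$n_Gp <- counts[, 1]; out$n_Gs <- counts[, 2]
  out$n_Rp <- counts[, 3]; out$n_Rs <- counts[, 4]
  out$burst <- seq_len(nrow(out))
  dplyr::relocate(out, "burst")
}

#' Tile bursts into fixed time windows
#'
#' Cuts each burst into consecutive, non-overlapping windows of length
#' `delta_t`, dropping the trailing remainder.  Bursts shorter than
#' `delta_t` contribute no windows.
#'
#' @param stream The `photon_stream` the bursts refer to.
#' @param bursts Burst table from [find_bursts()].
#' @param delta_t Window length, ms.
#' @return A tibble with `burst`, `window`, `delta_t`, `start_idx`,
#'   `stop_idx`, `t_start`, `duration_ms`, `n_photons` and per-channel
#'   counts.  Window boundaries are clock-based: a window covers photons in
#'   `[t_start, t_start + delta_t)`.
#' @export
time_windows <- function(stream, bursts, delta_t) {
  stopifnot(delta_t > 0)
  ch <- as.integer(stream$channel)
  tt <- stream$macro_time
  purrr::map_dfr(seq_len(nrow(bursts)), function(i) {
    b <- bursts[i, ]
    nw <- floor(b$duration_ms / delta_t)
    if (nw < 1) return(NULL)
    idx <- b$start_idx:b$stop_idx
    rel <- (tt[idx] - b$t_start) * 1e3        # ms from burst start
    # the final photon defines the burst duration; when that duration is an
    # exact multiple of delta_t the photon belongs to the last full window
    w <- floor(pmin(rel, b$duration_ms - 1e-9) / delta_t)
    keep <- w < nw
    idxk <- idx[keep]; wk <- w[keep]
    purrr::map_dfr(0:(nw - 1), function(wi) {
      ii <- idxk[wk == wi]
      if (!length(ii)) return(NULL)
      cnt <- tabulate(ch[ii], nbins = 4)
      tibble::tibble(
        burst = b$burst, window = wi + 1L, delta_t = delta_t,
        start_idx = min(ii), stop_idx = max(ii),
        t_start = b$t_start + wi * delta_t * 1e-3,
        duration_ms = delta_t, n_photons = length(ii),
        n_Gp = cnt[1], n_Gs = cnt[2], n_Rp = cnt[3], n_Rs = cnt[4])
    })
  })
}

# Maximum-likelihood mono-exponential lifetime with Gaussian IRF and a
# uniform background floor.  micro: ns; returns NA with < min_photons.
.tau_mle <- function(micro, irf_sigma, irf_t0, period, bg_frac = 0,
                     min_photons = 20, tau_range = c(0.05, 10)) {
  if (length(micro) < min_photons) return(NA_real_)
  bg_frac <- min(max(bg_frac, 0), 0.95)
  s <- irf_sigma
  nll <- function(tau) {
    if (s > 0) {
      z <- (micro - irf_t0) / s - s / tau
      dens <- exp(s^2 / (2 * tau^2) - (micro - irf_t0) / tau) *
        stats::pnorm(z) / tau
    } else {
      dt <- micro - irf_t0
      dens <- ifelse(dt >= 0, exp(-dt / tau) / tau, 0)
    }
    dens <- (1 - bg_frac) * dens + bg_frac / period
    -sum(log(pmax(dens, 1e-300)))
  }
  stats::optimize(nll, tau_range)$minimum
}

#' Burst-wise / window-wise MFD observables
#'
#' Converts raw channel counts of each segment into the standard MFD
#' observables: background- and crosstalk-corrected donor/acceptor signal
#' ratio `FD_FA`, the FRET-averaged distance `RDA_E` obtained by inverting
#' the Förster relation on the intensity-derived efficiency, the
#' fluorescence-weighted average donor lifetime `tau_DA_f` from a
#' maximum-likelihood mono-exponential fit (Gaussian IRF convolution,
#' uniform micro-time background floor), and the scatter-corrected
#' anisotropy `r_D` from the polarisation-resolved green counts,
#' `r_D = (F_p - g F_s) / ((1 - 3 l2) F_p + (2 - 3 l1) g F_s)`.
#'
#' Segments whose corrected acceptor signal vanishes are right-censored at
#' `calib$censor_R`; segments with too few green photons for the lifetime
#' fit carry `tau_DA_f = NA`.
#'
#' @param stream The `photon_stream`.
#' @param segments Burst or window table ([find_bursts()], [time_windows()]).
#' @param calib A [calibration].
#' @param irf List with `sigma`, `t0` (ns); defaults to stream metadata.
#' @param lifetime Compute the lifetime MLE (set FALSE to skip, it is the
#'   slow part).
#' @param min_lifetime_photons Minimum green photons for the lifetime fit.
#' @return The segment table augmented with `FD_FA`, `E_prox`, `RDA_E`,
#'   `censored`, `tau_DA_f`, `r_D`, `N_fret` (raw green+red counts entering
#'   the proximity ratio).
#' @export
mfd_observables <- function(stream, segments, calib = calibration(),
                            irf = NULL, lifetime = TRUE,
                            min_lifetime_photons = 20) {
  stopifnot(inherits(calib, "calibration"))
  if (!nrow(segments)) stop("no segments supplied")
  meta <- attr(stream, "metadata")
  if (is.null(irf))
    irf <- list(sigma = meta$irf_sigma %||% 0.25, t0 = meta$irf_t0 %||% 2.0)
  period <- meta$excitation_period %||% 15.625
  seg <- tibble::as_tibble(segments)
  dur <- seg$duration_ms
  bg <- calib$bg_rates                           # kHz * ms = counts
  FGp <- seg$n_Gp - bg[1] * dur
  FGs <- seg$n_Gs - bg[2] * dur
  FG <- FGp + calib$g_factor * FGs
  FRraw <- (seg$n_Rp - bg[3] * dur) + (seg$n_Rs - bg[4] * dur)
  FA <- FRraw - calib$crosstalk * FG -
    calib$direct_excitation * (FG + FRraw)
  E <- FA / (FA + calib$gamma * FG)
  censored <- !is.finite(E) | E <= 0
  E_valid <- pmin(E, 1 - 1e-12)
  RDA <- ifelse(censored, calib$censor_R,
                distance_from_efficiency(pmax(E_valid, 1e-12), calib$R0))
  RDA <- pmin(RDA, calib$censor_R)
  r_D <- (FGp - calib$g_factor * FGs) /
    ((1 - 3 * calib$l2) * FGp + (2 - 3 * calib$l1) * calib$g_factor * FGs)

  tau <- rep(NA_real_, nrow(seg))
  if (lifetime) {
    chan <- as.integer(stream$channel)
    micro <- stream$micro_time
    bg_green_rate <- (bg[1] + bg[2])             # kHz
    tau <- vapply(seq_len(nrow(seg)), function(i) {
      ii <- seg$start_idx[i]:seg$stop_idx[i]
      mi <- micro[ii][chan[ii] <= 2L]
      bgf <- if (length(mi)) bg_green_rate * dur[i] / length(mi) else 0
      .tau_mle(mi, irf$sigma, irf$t0, period, bg_frac = bgf,
               min_photons = min_lifetime_photons)
    }, numeric(1))
  }
  seg$FD_FA <- FG / FA
  seg$E_prox <- E
  seg$RDA_E <- RDA
  seg$censored <- censored
  seg$tau_DA_f <- tau
  seg$r_D <- r_D
  seg$N_fret <- seg$n_Gp + seg$n_Gs + seg$n_Rp + seg$n_Rs
  seg
}

#' Two-dimensional MFD frequency histogram
#'
#' Bins two observables jointly; the marginals equal the row/column sums of
#' the 2D table by construction.
#'
#' @param observables Table from [mfd_observables()].
#' @param x,y Observable column names (e.g. `"tau_DA_f"`, `"RDA_E"`).
#' @param bins Number of bins per axis, or a list with numeric break
#'   vectors `x` and `y`.
#' @return An `mfd_hist2d` object: `table` (tibble x_mid, y_mid, n),
#'   `marginal_x`, `marginal_y`, and the break vectors.
#' @export
mfd_histogram2d <- function(observables, x, y, bins = 41) {
  if (!nrow(observables)) stop("no observable records")
  vx <- observables[[x]]; vy <- observables[[y]]
  if (is.null(vx) || is.null(vy)) stop("unknown observable column")
  ok <- is.finite(vx) & is.finite(vy)
  if (!any(ok)) stop("all values missing for observable ", x, " or ", y)
  vx <- vx[ok]; vy <- vy[ok]
  brk <- function(v, n) {
    r <- range(v)
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = n + 1)
  }
  if (is.list(bins)) { bx <- bins$x; by <- bins$y }
  else { bx <- brk(vx, bins); by <- brk(vy, bins) }
  ix <- cut(vx, bx, include.lowest = TRUE, labels = FALSE)
  iy <- cut(vy, by, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(ix) & !is.na(iy)
  tab <- table(factor(ix[keep], seq_len(length(bx) - 1)),
               factor(iy[keep], seq_len(length(by) - 1)))
  xm <- (bx[-1] + bx[-length(bx)]) / 2
  ym <- (by[-1] + by[-length(by)]) / 2
  grid <- tidyr::expand_grid(xi = seq_along(xm), yi = seq_along(ym))
  tbl <- tibble::tibble(x_mid = xm[grid$xi], y_mid = ym[grid$yi],
                        n = as.vector(tab)[(grid$yi - 1) * length(xm) + grid$xi])
  structure(list(
    table = tbl,
    marginal_x = tibble::tibble(mid = xm, n = as.vector(unname(rowSums(tab)))),
    marginal_y = tibble::tibble(mid = ym, n = as.vector(unname(colSums(tab)))),
    breaks_x = bx, breaks_y = by, x = x, y = y,
    n_total = sum(tab), n_dropped = sum(!ok)),
    class = "mfd_hist2d")
}

#' @export
print.mfd_hist2d <- function(x, ...) {
  cat(sprintf("<mfd_hist2d> %s vs %s, %d records (%d dropped), %d x %d bins\n",
              x$x, x$y, x$n_total, x$n_dropped,
              length(x$breaks_x) - 1, length(x$breaks_y) - 1))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
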