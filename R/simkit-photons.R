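#' Simulate a single-molecule photon stream
#'
#' Generates a time-tagged, polarisation- and colour-resolved photon stream
#' of freely diffusing labelled molecules undergoing k-state conformational
#' exchange, with known ground truth.  Two diffusion modes are offered:
#'
#' * `"tophat"` (default): molecule transits arrive as a Poisson process and
#'   last an exponentially distributed dwell time with mean `t_diff`, with
#'   constant emission rate inside the volume.  This preserves the
#'   burst-duration statistics that burst search, time-window analysis and
#'   PDA rely on, at a fraction of the cost of full Brownian paths.
#' * `"brownian"`: molecules random-walk through a periodic box with a
#'   3D-Gaussian detection profile (axial ratio `kappa`), so the intensity
#'   autocorrelation follows the closed-form 3D-Gaussian diffusion model
#'   with diffusion time `t_diff`.  Use this mode for FCS-facing analyses.
#'
#' The conformational trajectory is a continuous-time Markov chain over the
#' model's states, evaluated exactly at photon arrival times through the
#' spectral form of `exp(Q dt)`.  A fresh inter-dye distance is drawn from
#' the state's Gaussian each time the state changes or a new molecule
#' (transit) begins, so distances are quasi-static within bursts for slow
#' exchange, as PDA assumes.  Per state the photon colour split obeys
#' `E = 1/(1 + (R/R0)^6)` and the polarisation split follows the
#' Perrin-decayed steady-state anisotropy `r0/(1 + tau/rho)`.  Background
#' photons are Poisson in every channel with uniform micro times.
#'
#' @param model An [exchange_model].
#' @param confocal A [confocal_model].
#' @param duration Trace length, s.
#' @param seed Integer seed; required, the stream is fully reproducible.
#' @param mode `"tophat"` or `"brownian"`.
#' @param crosstalk Probability that a donor photon is detected in a red
#'   channel (default 0).
#' @param direct_excitation Probability that an excitation directly excites
#'   the acceptor (default 0).
#' @param tau_acceptor Acceptor fluorescence lifetime, ns.
#' @param r_acceptor Effective steady-state anisotropy of acceptor emission.
#' @param kappa Axial ratio of the Gaussian detection volume (brownian mode).
#' @param dt_frac Brownian time step as a fraction of `t_diff`.
#' @return A `photon_stream`: tibble with columns `macro_time` (s),
#'   `micro_time` (ns), `channel` (factor Gp/Gs/Rp/Rs), plus ground-truth
#'   columns `molecule` and `state` (0 = background photon).  Attributes:
#'   `metadata` (acquisition parameters) and `transits` (top-hat mode ground
#'   truth table).
#' @export
simulate_photon_stream <- function(model, confocal, duration, seed,
                                   mode = c("tophat", "brownian"),
                                   crosstalk = 0, direct_excitation = 0,
                                   tau_acceptor = 1.2, r_acceptor = 0.2,
                                   kappa = 3, dt_frac = 1 / 60) {
  stopifnot(inherits(model, "exchange_model"),
            inherits(confocal, "confocal_model"),
            duration > 0)
  if (missing(seed)) stop("seed is required")
  mode <- match.arg(mode)
  set.seed(as.integer(seed))

  st <- model$states
  raw <- sim_photons_cpp(
    duration = duration, mode = match(mode, c("tophat", "brownian")) - 1L,
    R_DA = vapply(st, `[[`, 0, "R_DA"),
    sigma_DA = vapply(st, `[[`, 0, "sigma_DA"),
    tau_D = vapply(st, `[[`, 0, "tau_D"),
    rho = vapply(st, `[[`, 0, "rho"),
    r0_state = vapply(st, `[[`, 0, "r0"),
    R0 = model$R0, V = model$V, lambda = model$lambda, Vinv = model$Vinv,
    pi0 = model$pi,
    t_diff = confocal$t_diff * 1e-3,
    occupancy = confocal$mean_occupancy,
    brightness = confocal$brightness * 1e3,
    g_factor = confocal$g_factor, det_ratio_gr = confocal$det_ratio_gr,
    crosstalk = crosstalk, direct_exc = direct_excitation,
    tau_A = tau_acceptor, r_acceptor = r_acceptor,
    irf_sigma = confocal$irf_sigma, irf_t0 = confocal$irf_t0,
    period = confocal$excitation_period, kappa = kappa, dt_frac = dt_frac)

  df <- tibble::tibble(
    macro_time = raw$t, micro_time = raw$micro,
    channel = raw$channel, molecule = raw$molecule, state = raw$state)

  # Poisson background, uniform in time and micro time
  bg_rates <- confocal$background * 1e3
  bg <- purrr::map_dfr(seq_len(4), function(ch) {
    n <- stats::rpois(1, bg_rates[ch] * duration)
    tibble::tibble(
      macro_time = stats::runif(n, 0, duration),
      micro_time = stats::runif(n, 0, confocal$excitation_period),
      channel = rep(ch, n), molecule = rep(0L, n), state = rep(0L, n))
  })
  df <- dplyr::bind_rows(df, bg)
  df <- df[order(df$macro_time), , drop = FALSE]
  df$channel <- factor(channel_levels()[df$channel], levels = channel_levels())

  transits <- tibble::tibble(
    transit = raw$transit_id, t_start = raw$transit_start,
    t_stop = raw$transit_stop, n_photons = raw$transit_n)

  meta <- list(duration = duration, seed = as.integer(seed), mode = mode,
               R0 = model$R0, t_diff_ms = confocal$t_diff,
               excitation_period = confocal$excitation_period,
               background_khz = confocal$background,
               g_factor = confocal$g_factor,
               irf_sigma = confocal$irf_sigma, irf_t0 = confocal$irf_t0,
               n_states = length(st))
  new_photon_stream(df, metadata = meta, transits = transits)
}

#' Construct a photon stream object from a photon table
#'
#' @param df Data frame with `macro_time` (s, nondecreasing), `micro_time`
#'   (ns, within the excitation period) and `channel` (factor or character
#'   Gp/Gs/Rp/Rs).
#' @param metadata Named list of acquisition parameters; must include
#'   `duration` and `excitation_period`.
#' @param transits Optional ground-truth transit table.
#' @return A `photon_stream` tibble.
#' @export
new_photon_stream <- function(df, metadata = list(), transits = NULL) {
  df <- tibble::as_tibble(df)
  need <- c("macro_time", "micro_time", "channel")
  if (!all(need %in% names(df)))
    stop("photon stream needs columns: ", paste(need, collapse = ", "))
  if (is.unsorted(df$macro_time))
    stop("macro_time must be nondecreasing")
  if (!is.factor(df$channel))
    df$channel <- factor(as.character(df$channel), levels = channel_levels())
  if (anyNA(df$channel)) stop("unknown channel labels")
  if (is.null(metadata$duration))
    metadata$duration <- if (nrow(df)) max(df$macro_time) else 0
  if (is.null(metadata$excitation_period))
    metadata$excitation_period <- 15.625
  per <- metadata$excitation_period
  if (nrow(df) && any(df$micro_time < 0 | df$micro_time > per))
    stop("micro times must lie within the excitation period")
  structure(df, metadata = metadata, transits = transits,
            class = c("photon_stream", class(df)))
}

#' @export
print.photon_stream <- function(x, ...) {
  meta <- attr(x, "metadata")
  cat(sprintf("<photon_stream> %d photons over %.3g s (%.2f kHz)\n",
              nrow(x), meta$duration,
              if (meta$duration > 0) nrow(x) / meta$duration / 1e3 else 0))
  NextMethod()
}

#' Channel photon counts of a stream
#' @param stream A `photon_stream`.
#' @return Named integer vector over the four channels.
#' @export
channel_counts <- function(stream) {
  table(factor(stream$channel, levels = channel_levels()))
}
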