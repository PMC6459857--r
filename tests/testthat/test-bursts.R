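test_that("burst search finds no bursts in background-only traces", {
  cm <- confocal_model(brightness = 0, background = rep(0.25, 4))
  em <- exchange_model(dye_state("s", 53))
  st <- simulate_photon_stream(em, cm, 100, seed = 5)
  b <- find_bursts(st, min_photons = 60)
  expect_lte(nrow(b), 1)
})

test_that("isolated transits are recovered as single bursts", {
  # hand-built stream: two dense 2 ms clusters of 150 photons, 50 ms apart,
  # on sparse background
  set.seed(8)
  mk_cluster <- function(t0) sort(runif(150, t0, t0 + 0.002))
  bgt <- sort(runif(60, 0, 0.2))
  tt <- sort(c(mk_cluster(0.05), mk_cluster(0.1), bgt))
  st <- new_photon_stream(
    tibble::tibble(macro_time = tt,
                   micro_time = rep(1, length(tt)),
                   channel = sample(channel_levels(), length(tt), TRUE)),
    metadata = list(duration = 0.2, background_khz = rep(0.075, 4)))
  b <- find_bursts(st, min_photons = 60, max_interphoton = 0.1,
                   smoothing_window = 10)
  expect_equal(nrow(b), 2)
  # each burst contains >= 90% of its transit's photons
  for (t0 in c(0.05, 0.1)) {
    hit <- b[b$t_start > t0 - 0.01 & b$t_start < t0 + 0.01, ]
    expect_equal(nrow(hit), 1)
    expect_gte(hit$n_photons, 0.9 * 150)
  }
  # counts are consistent with the index range
  expect_equal(b$n_Gp + b$n_Gs + b$n_Rp + b$n_Rs, b$n_photons)
  expect_equal(b$n_photons, b$stop_idx - b$start_idx + 1L)
})

test_that("time windows tile bursts without overlap and conserve counts", {
  set.seed(3)
  n <- 400
  tt <- sort(runif(n, 0.01, 0.01 + 0.0032))    # one 3.2 ms burst
  st <- new_photon_stream(
    tibble::tibble(macro_time = tt, micro_time = rep(1, n),
                   channel = sample(channel_levels(), n, TRUE)),
    metadata = list(duration = 0.05))
  bursts <- tibble::tibble(burst = 1L, start_idx = 1L, stop_idx = n,
                           t_start = tt[1],
                           duration_ms = (tt[n] - tt[1]) * 1e3,
                           n_photons = n)
  tw1 <- time_windows(st, bursts, 1)
  expect_equal(nrow(tw1), 3)
  expect_equal(unique(tw1$delta_t), 1)
  # non-overlapping: each photon index in at most one window
  idx <- unlist(purrr::map2(tw1$start_idx, tw1$stop_idx, seq))
  expect_false(any(duplicated(idx)))
  # count conservation: windows never exceed the burst, equality when the
  # duration is an exact multiple of delta_t
  expect_lte(sum(tw1$n_photons), bursts$n_photons)
  tw2 <- time_windows(st, bursts, 5)           # burst shorter than delta_t
  expect_equal(nrow(tw2), 0)
  expect_equal(sum(time_windows(st, bursts, bursts$duration_ms / 2)$n_photons),
               n)
})

test_that("burst-wise efficiency from photon counting is unbiased", {
  R <- 47
  em <- exchange_model(dye_state("s", R, sigma_DA = 0, tau_D = 2))
  cm <- confocal_model(brightness = 90, background = rep(0.2, 4),
                       mean_occupancy = 0.04)
  st <- simulate_photon_stream(em, cm, 120, seed = 13)
  b <- find_bursts(st)
  expect_gt(nrow(b), 400)
  obs <- mfd_observables(st, b, calibration_from_confocal(cm),
                         lifetime = FALSE)
  E_true <- efficiency_from_distance(R, 53)
  expect_within(mean(obs$E_prox[!obs$censored]), E_true, 0.01)
})

test_that("window lifetime MLE recovers the simulated lifetime within 5%", {
  tau <- 2.4
  em <- exchange_model(dye_state("s", Inf, tau_D = tau, rho = 6))
  cm <- confocal_model(brightness = 120, background = rep(0.2, 4),
                       mean_occupancy = 0.04)
  st <- simulate_photon_stream(em, cm, 40, seed = 17)
  b <- find_bursts(st)
  tw <- time_windows(st, b, 2)
  tw <- tw[tw$n_photons >= 100, ]
  expect_gt(nrow(tw), 50)
  obs <- mfd_observables(st, tw, calibration_from_confocal(cm))
  expect_within(mean(obs$tau_DA_f, na.rm = TRUE), tau, 0.05 * tau)
})

test_that("burst anisotropy matches the Perrin closed form", {
  cm <- confocal_model(brightness = 120, background = rep(0.2, 4),
                       mean_occupancy = 0.04)
  for (rho in c(1, 4, 20)) {
    em <- exchange_model(dye_state("a", Inf, tau_D = 4, rho = rho, r0 = 0.38))
    st <- simulate_photon_stream(em, cm, 30, seed = 60 + rho)
    b <- find_bursts(st)
    obs <- mfd_observables(st, b, calibration_from_confocal(cm),
                           lifetime = FALSE)
    r_true <- perrin_r(rho, 0.38, 4)
    m <- mean(obs$r_D); se <- sd(obs$r_D) / sqrt(nrow(obs))
    expect_within(m, r_true, 3 * max(se, 0.003))
  }
})

test_that("censoring convention reports zero-acceptor segments at 150 A", {
  st <- new_photon_stream(
    tibble::tibble(macro_time = seq(0, 0.001, length.out = 80),
                   micro_time = rep(2.5, 80),
                   channel = rep(c("Gp", "Gs"), 40)),
    metadata = list(duration = 0.01))
  seg <- tibble::tibble(start_idx = 1L, stop_idx = 80L, duration_ms = 1,
                        n_Gp = 40L, n_Gs = 40L, n_Rp = 0L, n_Rs = 0L)
  obs <- mfd_observables(st, seg, calibration(bg_rates = rep(0, 4)),
                         lifetime = FALSE)
  expect_true(obs$censored)
  expect_equal(obs$RDA_E, 150)
})

test_that("noiseless counts invert the Forster relation exactly", {
  mk <- function(nG, nR) tibble::tibble(
    start_idx = 1L, stop_idx = nG + nR, duration_ms = 1,
    n_Gp = nG, n_Gs = 0L, n_Rp = nR, n_Rs = 0L)
  st <- new_photon_stream(
    tibble::tibble(macro_time = seq(0, 1e-3, length.out = 1100),
                   micro_time = 2.5, channel = "Gp"),
    metadata = list(duration = 0.01))
  cal <- calibration(bg_rates = rep(0, 4), R0 = 53)
  # E = 0.5 -> R = R0
  o1 <- mfd_observables(st, mk(500L, 500L), cal, lifetime = FALSE)
  expect_equal(o1$RDA_E, 53)
  # E = 0.727 -> R = 45 (acceptor/donor = E/(1-E))
  E <- efficiency_from_distance(45, 53)
  o2 <- mfd_observables(st, mk(1000L - round(1000 * E), round(1000 * E)),
                        cal, lifetime = FALSE)
  expect_within(o2$RDA_E, 45, 0.05)
})

test_that("2D histograms conserve counts and expose exact marginals", {
  set.seed(2)
  obs <- tibble::tibble(RDA_E = rnorm(500, 48, 4),
                        tau_DA_f = rnorm(500, 2, 0.4))
  h <- mfd_histogram2d(obs, "tau_DA_f", "RDA_E", bins = 21)
  expect_equal(sum(h$table$n), 500)
  mx <- h$table |> dplyr::group_by(.data$x_mid) |>
    dplyr::summarise(n = sum(.data$n)) |> dplyr::pull(n)
  expect_equal(mx, h$marginal_x$n)
  my <- h$table |> dplyr::group_by(.data$y_mid) |>
    dplyr::summarise(n = sum(.data$n)) |> dplyr::pull(n)
  expect_equal(my, h$marginal_y$n)
  # single record -> exactly one occupied cell
  h1 <- mfd_histogram2d(obs[1, ], "tau_DA_f", "RDA_E", bins = 5)
  expect_equal(sum(h1$table$n > 0), 1)
  expect_error(mfd_histogram2d(tibble::tibble(RDA_E = NA_real_,
                                              tau_DA_f = NA_real_),
                               "tau_DA_f", "RDA_E"), "missing")
})

test_that("two slow-exchanging states give a bimodal distance marginal", {
  em <- two_state_fret(R1 = 42, R2 = 58, f1 = 0.5, k_total = 20, sigma = 1)
  cm <- confocal_model(brightness = 100, background = rep(0.2, 4),
                       mean_occupancy = 0.04)
  st <- simulate_photon_stream(em, cm, 90, seed = 23)
  b <- find_bursts(st, min_photons = 80)
  obs <- mfd_observables(st, b, calibration_from_confocal(cm),
                         lifetime = FALSE)
  h <- mfd_histogram2d(dplyr::filter(obs, !.data$censored),
                       "E_prox", "RDA_E",
                       bins = list(x = seq(0, 1, 0.05), y = seq(35, 70, 1)))
  marg <- h$marginal_y
  # modes at the state means within a bin width
  peak_lo <- marg$mid[which.max(marg$n * (marg$mid < 50))]
  peak_hi <- marg$mid[which.max(marg$n * (marg$mid > 50))]
  expect_within(peak_lo, 42, 1.5)
  expect_within(peak_hi, 58, 1.5)
})
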