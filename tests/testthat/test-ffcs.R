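test_that("orthogonal single-bin patterns give indicator filters", {
  pat <- list(A = c(10, 0, 0, 0), B = c(0, 0, 20, 0))
  fl <- build_filters(pat)
  expect_equal(unname(fl$weights["A", ]), c(1, 0, 0, 0))
  expect_equal(unname(fl$weights["B", ]), c(0, 0, 1, 0))
})

test_that("filters satisfy the unbiasedness constraint by construction", {
  set.seed(6)
  p1 <- dexp(seq(0.5, 15, 0.5), 1 / 1.0)
  p2 <- dexp(seq(0.5, 15, 0.5), 1 / 3.8)
  fl <- build_filters(list(fast = p1, slow = p2))
  P <- cbind(p1 / sum(p1), p2 / sum(p2))
  expect_equal(unname(fl$weights %*% P), diag(2), tolerance = 1e-6)
  # collinear patterns are rejected with a condition-number report
  expect_error(build_filters(list(a = p1, b = p1 * 2)), "condition number")
})

test_that("photon-weighted filter sums recover mixture fractions", {
  # two lifetime patterns, multinomial photon sample of a 30/70 mixture
  set.seed(7)
  grid <- seq(0.25, 15, 0.25)
  p1 <- dexp(grid, 1 / 1.0); p1 <- p1 / sum(p1)
  p2 <- dexp(grid, 1 / 3.8); p2 <- p2 / sum(p2)
  fl <- build_filters(list(fast = p1, slow = p2),
                      mix_weights = c(0.3, 0.7))
  n <- 2e5
  counts <- rmultinom(1, n, 0.3 * p1 + 0.7 * p2)[, 1]
  frac <- as.vector(fl$weights %*% counts) / n
  expect_within(frac[1], 0.3, 0.02 * 0.3 + 3 * sqrt(0.3 * 0.7 / n) * 3)
  expect_within(frac[2], 0.7, 0.02)
  expect_equal(sum(frac), 1, tolerance = 1e-3)
})

test_that("correlation of Poisson background is flat at one", {
  cm <- confocal_model(brightness = 0, background = rep(2, 4))
  em <- exchange_model(dye_state("s", 53))
  st <- simulate_photon_stream(em, cm, 30, seed = 1)
  cv <- correlate(st, lag_min = 1e-6)
  expect_lt(abs(mean(cv$G) - 1), 0.01)
  expect_lt(max(abs(cv$G - 1)), 0.15)
})

test_that("uniform filters reduce to the ordinary intensity ACF", {
  cm <- confocal_model(brightness = 100, background = rep(0.3, 4),
                       mean_occupancy = 0.08)
  em <- exchange_model(dye_state("s", 45, tau_D = 2))
  st <- simulate_photon_stream(em, cm, 20, seed = 4)
  acf0 <- correlate(st, lag_min = 1e-6)
  ufl <- structure(list(weights = matrix(1, 1, 64,
                                         dimnames = list("all", NULL)),
                        species = "all", micro_bins = 16, period = NULL),
                   class = "filter_set")
  acf1 <- correlate(st, ufl, lag_min = 1e-6)
  expect_equal(acf1$G, acf0$G, tolerance = 1e-12)
})

test_that("diffusion-only curves are fit without relaxation terms", {
  cm <- confocal_model(brightness = 150, background = rep(0.3, 4),
                       mean_occupancy = 0.1, t_diff = 1.7)
  em <- exchange_model(dye_state("s", 53, tau_D = 2))
  st <- simulate_photon_stream(em, cm, 60, seed = 2, mode = "brownian")
  cv <- correlate(st, lag_min = 2e-6)
  f <- fit_relaxations(cv, 0)
  expect_within(f$t_diff * 1e3, 1.7, 0.17)
  expect_lt(f$chi2_r, 3)
  # residuals show no systematic lag trend
  expect_lt(abs(cor(f$residuals / f$sd, log(f$lag_s))), 0.4)
})

test_that("a single relaxation term is recovered and overfitting collapses", {
  tau0 <- 3.8
  sH <- dye_state("HF", 40, 0, donor_lifetime(40, 53, tau0), 2)
  sL <- dye_state("LF", 60, 0, donor_lifetime(60, 53, tau0), 2)
  cm <- confocal_model(brightness = 150, background = rep(0.3, 4),
                       mean_occupancy = 0.1, t_diff = 1.7)
  ref <- lapply(list(HF = exchange_model(sH), LF = exchange_model(sL)),
                function(e) simulate_photon_stream(e, cm, 10, seed = 99))
  fl <- build_filters(ref)
  k <- 1 / 20e-6 / 2
  em <- exchange_model(list(sH, sL),
                       matrix(c(0, k, k, 0), 2, 2, byrow = TRUE))
  st <- simulate_photon_stream(em, cm, 60, seed = 41, mode = "brownian")
  cv <- correlate(st, fl, lag_min = 2e-7)
  ccf <- dplyr::filter(cv, .data$species1 == "HF", .data$species2 == "LF")
  f1 <- fit_relaxations(ccf, 1)
  expect_within(f1$components$relaxation_time_s, 20e-6, 0.15 * 20e-6)
  expect_true(f1$components$anticorrelated)
  # global fit across sACFs + sCCFs shares the exchange time; auto terms are
  # correlated (positive amplitude), the cross term anticorrelated
  fg <- fit_relaxations_global(cv, 1, n_starts = 10)
  expect_within(fg$relaxation_times_s, 20e-6, 0.2 * 20e-6)
  expect_gt(fg$amplitudes[1, "HF x HF"], 0)
  expect_gt(fg$amplitudes[1, "LF x LF"], 0)
  expect_lt(fg$amplitudes[1, "HF x LF"], 0)
  # overfit guard: with 2 components on 1-term data the extra component
  # degenerates (collapses to the lag-grid edge, merges, or loses amplitude)
  f2 <- fit_relaxations(ccf, 2)
  t1 <- f1$components$relaxation_time_s
  comp <- f2$components
  spurious <- vapply(seq_len(2), function(i) {
    comp$relaxation_time_s[i] < 3 * min(ccf$lag_s) ||
      comp$relaxation_time_s[i] > max(ccf$lag_s) / 3 &&
        abs(comp$amplitude[i]) < 0.1 ||
      abs(log(comp$relaxation_time_s[i] / t1)) < log(1.5) ||
      abs(comp$amplitude[i]) < 0.1
  }, logical(1))
  expect_true(any(spurious))
})

test_that("fitted exchange rates track the simulated flux monotonically", {
  tau0 <- 3.8
  sH <- dye_state("HF", 40, 0, donor_lifetime(40, 53, tau0), 2)
  sL <- dye_state("LF", 60, 0, donor_lifetime(60, 53, tau0), 2)
  cm <- confocal_model(brightness = 150, background = rep(0.3, 4),
                       mean_occupancy = 0.1, t_diff = 1.7)
  ref <- lapply(list(HF = exchange_model(sH), LF = exchange_model(sL)),
                function(e) simulate_photon_stream(e, cm, 10, seed = 99))
  fl <- build_filters(ref)
  fits <- lapply(c(2e3, 8e3, 32e3), function(k) {
    em <- exchange_model(list(sH, sL),
                         matrix(c(0, k, k, 0), 2, 2, byrow = TRUE))
    st <- simulate_photon_stream(em, cm, 30, seed = 51, mode = "brownian")
    cv <- correlate(st, fl, lag_min = 5e-7)
    ccf <- dplyr::filter(cv, .data$species1 == "HF", .data$species2 == "LF")
    fit_relaxations(ccf, 1, n_starts = 10)
  })
  rates <- vapply(fits, function(f) 1 / f$components$relaxation_time_s, 0)
  expect_true(all(diff(rates) > 0))
  expect_true(all(vapply(fits, function(f) f$components$anticorrelated,
                         logical(1))))
})

test_that("short streams warn about noise", {
  cm <- confocal_model(brightness = 0, background = rep(0.5, 4))
  em <- exchange_model(dye_state("s", 53))
  st <- simulate_photon_stream(em, cm, 2, seed = 1)
  expect_warning(correlate(st, lag_min = 1e-5, lag_max = 1e-3), "1e4|noisy")
})
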