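test_that("single-state zero-width prediction is the pure binomial", {
  # E = 0.5 at R = R0, all windows N = 100: the predicted proximity-ratio
  # histogram must equal Binomial(100, 0.5) pushed through the estimator.
  m <- pda_model(data.frame(mean = 53, half_width = 0, fraction = 1))
  bins <- seq(30, 110, length.out = 161)
  cd <- tibble::tibble(N = 100L, n_windows = 1000)
  pred <- pda_predict(m, cd, bins)
  # independent construction: map each red count to a distance, histogram
  s <- 1:100
  R_of_s <- 53 * ((100 - s) / s)^(1 / 6)
  w <- dbinom(s, 100, 0.5) * 1000
  oracle <- vapply(seq_len(length(bins) - 1), function(b)
    sum(w[R_of_s >= bins[b] & R_of_s < bins[b + 1] & s < 100]), numeric(1))
  expect_equal(pred$expected, oracle, tolerance = 1e-9)
  # censored mass = P(s = 0)
  expect_equal(attr(pred, "censored"), 1000 * dbinom(0, 100, 0.5),
               tolerance = 1e-9)
})

test_that("predicted mass is normalised to the number of windows", {
  m <- pda_model(data.frame(mean = c(0.08, 0.25), half_width = c(0.01, 0.02),
                            fraction = c(0.4, 0.6)), kind = "anisotropy")
  cd <- tibble::tibble(N = c(40L, 80L, 120L), n_windows = c(300, 500, 200))
  bins <- seq(-0.55, 1.05, length.out = 101)   # covers the full estimator range
  pred <- pda_predict(m, cd, bins)
  total <- sum(pred$expected) + attr(pred, "censored") +
    attr(pred, "lost_low") + attr(pred, "lost_high")
  expect_equal(total, 1000, tolerance = 1e-9)
  expect_equal(attr(pred, "lost_low") + attr(pred, "lost_high"), 0,
               tolerance = 1e-9)
})

test_that("two-state mixture mass matches the fractions", {
  m <- pda_model(data.frame(mean = c(45, 52), half_width = c(1, 1),
                            fraction = c(0.83, 0.17)))
  cd <- tibble::tibble(N = 400L, n_windows = 1000)   # high counts: basins separate
  bins <- seq(35, 70, length.out = 201)
  pred <- pda_predict(m, cd, bins)
  valley <- 48.5                                      # midpoint between states
  m_lo <- sum(pred$expected[pred$mid < valley])
  m_hi <- sum(pred$expected[pred$mid >= valley])
  expect_within(m_lo / (m_lo + m_hi), 0.83, 0.01)
})

test_that("bins not covering the support raise an error listing lost mass", {
  m <- pda_model(data.frame(mean = 45, half_width = 0, fraction = 1))
  expect_error(pda_predict(m, tibble::tibble(N = 100L, n_windows = 10),
                           bins = seq(60, 80, 1)), "lost")
})

test_that("prediction agrees with brute-force Monte-Carlo draws", {
  # total-variation distance < 0.01 for 1- and 2-state models, with and
  # without background
  bins <- seq(30, 90, length.out = 62)
  cd <- tibble::tibble(N = c(60L, 90L, 130L), n_windows = c(3, 5, 2))
  models <- list(
    pda_model(data.frame(mean = 47, half_width = 3, fraction = 1)),
    pda_model(data.frame(mean = c(45, 52), half_width = c(2, 2),
                         fraction = c(0.83, 0.17))))
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    for (bg in c(0, 1.2)) {
      pred <- pda_predict(m, cd, bins, bg_success = bg, bg_fail = bg)
      draws <- pda_sample_windows(m, cd, 1e6, seed = 100 + mi,
                                  bg_success = bg, bg_fail = bg)
      h <- hist(draws[!is.na(draws) & draws >= 30 & draws < 90],
                breaks = bins, plot = FALSE)
      p_pred <- pred$expected / sum(cd$n_windows)
      p_mc <- h$counts / 1e6
      tv <- sum(abs(p_pred - p_mc)) / 2
      expect_lt(tv, 0.01)
    }
  }
})

test_that("PDA fitting recovers a single static state", {
  m_true <- pda_model(data.frame(mean = 47, half_width = 2, fraction = 1))
  obs <- synthetic_windows(m_true, 2000, delta_t = c(1, 2), seed = 21)
  prep <- pda_prepare(obs, "RDA_E", calib = calib0())
  fit <- pda_fit(prep, 1, seed = 2)
  expect_within(fit$states$mean, 47, 1)
  expect_lt(fit$chi2_r, 1.8)
  expect_equal(sum(tidy(fit)$fraction), 1, tolerance = 1e-9)
  expect_true(all(is.finite(tidy(fit)$mean_se)))
})

test_that("nested PDA models improve monotonically and compare correctly", {
  m_true <- pda_model(data.frame(mean = c(44, 54), half_width = c(2, 2),
                                 fraction = c(0.6, 0.4)))
  obs <- synthetic_windows(m_true, 2500, delta_t = c(1, 2), seed = 31)
  prep <- pda_prepare(obs, "RDA_E", calib = calib0())
  f1 <- pda_fit(prep, 1, seed = 3)
  f2 <- pda_fit(prep, 2, seed = 3)
  expect_lt(f2$chi2_r, f1$chi2_r)
  cmp <- model_compare(list(f1, f2))
  expect_equal(cmp$k_states[cmp$selected], 2)
  # 1-state truth: parsimony keeps the simpler model
  m1 <- pda_model(data.frame(mean = 48, half_width = 2.5, fraction = 1))
  obs1 <- synthetic_windows(m1, 2500, delta_t = c(1, 2), seed = 32)
  prep1 <- pda_prepare(obs1, "RDA_E", calib = calib0())
  g1 <- pda_fit(prep1, 1, seed = 3)
  g2 <- pda_fit(prep1, 2, seed = 3)
  cmp1 <- model_compare(list(g1, g2))
  expect_equal(cmp1$k_states[cmp1$selected], 1)
  # ties break toward fewer states
  g2_tie <- g2; g2_tie$chi2_r <- g1$chi2_r
  cmp2 <- model_compare(list(g1, g2_tie))
  expect_equal(cmp2$k_states[cmp2$selected], 1)
  expect_error(model_compare(list(f1, g1)), "same data")
})

test_that("static species give time-window-independent fractions", {
  m_true <- pda_model(data.frame(mean = c(45, 52), half_width = c(2, 2),
                                 fraction = c(0.7, 0.3)))
  obs <- synthetic_windows(m_true, 2500, delta_t = c(1, 2, 3),
                           mean_counts = 80, seed = 41)
  prep <- pda_prepare(obs, "RDA_E", calib = calib0())
  fit <- pda_fit(prep, 2, fractions_shared = FALSE, seed = 4)
  pw <- tidy(fit, per_window = TRUE)
  f_lo <- pw$fraction[pw$state == 1]
  expect_lt(max(f_lo) - min(f_lo), 0.1)
  expect_within(mean(f_lo), 0.7, 0.05)
})

test_that("model construction validates fractions and state parameters", {
  expect_error(pda_model(data.frame(mean = c(45, 52), half_width = c(1, 1),
                                    fraction = c(0.6, 0.6))), "sum to 1")
  expect_error(pda_model(data.frame(mean = -3, half_width = 1,
                                    fraction = 1)), "positive")
  expect_error(pda_model(data.frame(mean = 45, half_width = -1,
                                    fraction = 1)), "nonnegative")
})
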