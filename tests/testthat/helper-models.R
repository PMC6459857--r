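# Shared builders for simulated fixtures (everything generated in code).

# Two-state FRET exchange model with lifetimes consistent with a donor of
# unquenched lifetime tau0 (states then sit on the ideal static FRET line).
two_state_fret <- function(R1 = 45, R2 = 52, f1 = 0.83, k_total = 20,
                           sigma = 2, tau0 = 3.8, R0 = 53, rho = 10) {
  k12 <- k_total * (1 - f1)
  k21 <- k_total * f1
  Q <- matrix(c(0, k12, k21, 0), 2, 2, byrow = TRUE)
  exchange_model(list(
    dye_state("HF", R1, sigma, donor_lifetime(R1, R0, tau0), rho),
    dye_state("LF", R2, sigma, donor_lifetime(R2, R0, tau0), rho)),
    Q, R0 = R0)
}

# Synthetic window-observable table drawn directly from the PDA generative
# process (no photon simulation): N windows at fixed per-window totals.
synthetic_windows <- function(model, n, delta_t, mean_counts = 90, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(delta_t, function(dt) {
    N <- pmax(15L, stats::rpois(n, mean_counts * dt))
    st <- sample.int(nrow(model$states), n, TRUE, model$states$fraction)
    x <- stats::rnorm(n, model$states$mean[st], model$states$half_width[st])
    if (model$kind == "fret") x <- pmax(x, 1)
    p <- smdyn:::.pda_success_prob(x, model)
    s <- stats::rbinom(n, N, p)
    if (model$kind == "fret") {
      tibble::tibble(delta_t = dt, duration_ms = dt,
                     n_Gp = N - s, n_Gs = 0L, n_Rp = s, n_Rs = 0L,
                     RDA_E = ifelse(s == 0, 150,
                                    model$R0 * (pmax(N - s, 0) / pmax(s, 1))^(1 / 6)),
                     censored = s == 0)
    } else {
      tibble::tibble(delta_t = dt, duration_ms = dt,
                     n_Gp = s, n_Gs = N - s, n_Rp = 0L, n_Rs = 0L,
                     r_D = (s - (N - s)) / (s + 2 * (N - s)),
                     censored = FALSE)
    }
  })
}

# calibration with zero background (matches synthetic_windows)
calib0 <- function(R0 = 53) calibration(bg_rates = rep(0, 4), R0 = R0)

expect_within <- function(object, target, tol) {
  expect_true(abs(object - target) <= tol,
              label = sprintf("%.6g within %.3g of %.6g", object, tol, target))
}
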