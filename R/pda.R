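#' Shot-noise PDA model
#'
#' A probability-distribution-analysis model: a set of conformational states,
#' each a Gaussian-distributed observable (inter-dye distance for FRET,
#' anisotropy for smFA) with a population fraction, plus the nuisance
#' parameters needed to turn an observable into a photon-splitting
#' probability.
#'
#' @param states Data frame with columns `mean`, `half_width`, `fraction`
#'   (fractions must sum to 1 within 1e-6).
#' @param kind `"fret"` (means in Å) or `"anisotropy"` (dimensionless).
#' @param R0 Förster radius, Å (FRET).
#' @param gamma Detection/quantum-yield ratio (FRET).
#' @param g_factor Polarisation detection ratio (anisotropy).
#' @param acceptor_brightness_sd Multiplicative Gaussian variation of the
#'   red detection efficiency (default 0 = off).
#' @return A `pda_model`.
#' @export
pda_model <- function(states, kind = c("fret", "anisotropy"), R0 = 53.0,
                      gamma = 1, g_factor = 1, acceptor_brightness_sd = 0) {
  kind <- match.arg(kind)
  states <- tibble::as_tibble(states)
  need <- c("mean", "half_width", "fraction")
  if (!all(need %in% names(states)))
    stop("states must have columns: ", paste(need, collapse = ", "))
  if (abs(sum(states$fraction) - 1) > 1e-6)
    stop("state fractions must sum to 1")
  if (any(states$fraction < 0) || any(states$half_width < 0))
    stop("fractions and half-widths must be nonnegative")
  if (kind == "fret" && any(states$mean <= 0))
    stop("FRET state means must be positive distances")
  structure(list(states = states, kind = kind, R0 = R0, gamma = gamma,
                 g_factor = g_factor,
                 acceptor_brightness_sd = acceptor_brightness_sd),
            class = "pda_model")
}

#' @export
print.pda_model <- function(x, ...) {
  cat(sprintf("<pda_model> %s, %d state(s)\n", x$kind, nrow(x$states)))
  print(x$states)
  invisible(x)
}

# Gauss-Hermite nodes for one state: values + weights of the Gaussian
# observable distribution, truncated at physical bounds.
.pda_nodes <- function(mean, half_width, kind, n_nodes = 16) {
  if (half_width <= 0) return(list(x = mean, w = 1))
  gh <- pracma::gaussHermite(n_nodes)
  x <- mean + sqrt(2) * half_width * gh$x
  w <- gh$w / sqrt(pi)
  if (kind == "fret") {
    keep <- x > 1
  } else {
    keep <- x > -0.199 & x < 0.999
  }
  x <- x[keep]; w <- w[keep]; w <- w / sum(w)
  list(x = x, w = w)
}

# observable value -> success-channel probability
.pda_success_prob <- function(x, model) {
  if (model$kind == "fret") {
    E <- efficiency_from_distance(pmax(x, 1), model$R0)
    model$gamma * E / (1 - E + model$gamma * E)
  } else {
    g <- model$g_factor
    g * (1 + 2 * x) / (g * (1 + 2 * x) + (1 - x))
  }
}

# normalise a count-distribution argument to tibble(N, n_windows)
.pda_count_dist <- function(count_dist) {
  if (is.data.frame(count_dist)) {
    stopifnot(all(c("N", "n_windows") %in% names(count_dist)))
    df <- tibble::as_tibble(count_dist)
  } else {
    tab <- table(count_dist)
    df <- tibble::tibble(N = as.integer(names(tab)),
                         n_windows = as.numeric(tab))
  }
  df <- df[df$N > 0, , drop = FALSE]
  if (!nrow(df)) stop("empty photon-count distribution")
  df
}

#' Predict a shot-noise-limited observable histogram
#'
#' For each window photon total `N` the model mixes over states, integrates
#' each state's Gaussian observable on Gauss-Hermite nodes, converts the
#' observable to a green/red (or parallel/perpendicular) splitting
#' probability, convolves with binomial counting statistics and with
#' Poisson background in both channels, and maps the resulting counts back
#' through the same estimator the burst analysis uses.  The output is
#' normalised to the number of windows.
#'
#' @param model A [pda_model].
#' @param count_dist Window photon totals: either a vector of per-window
#'   totals or a tibble `(N, n_windows)`.
#' @param bins Histogram break points on the observable (increasing).
#' @param bg_success,bg_fail Mean Poisson background counts per window in
#'   the success (red / parallel) and fail (green / perpendicular) channel.
#' @param n_nodes Gauss-Hermite nodes per state.
#' @return A tibble `bin_lo, bin_hi, mid, expected`; attributes `censored`,
#'   `lost_low`, `lost_high` hold the predicted mass falling outside the
#'   bins (censored = windows whose estimator is undefined, e.g. zero
#'   corrected acceptor signal).  An error is raised when more than 1% of
#'   the mass misses the bins.
#' @export
pda_predict <- function(model, count_dist, bins, bg_success = 0,
                        bg_fail = 0, n_nodes = 16, max_lost = 0.01) {
  stopifnot(inherits(model, "pda_model"))
  if (is.unsorted(bins, strictly = TRUE)) stop("bins must be increasing")
  cd <- .pda_count_dist(count_dist)
  k <- nrow(model$states)
  nodes <- lapply(seq_len(k), function(i)
    .pda_nodes(model$states$mean[i], model$states$half_width[i],
               model$kind, n_nodes))
  nn <- max(vapply(nodes, function(nd) length(nd$x), 0L))
  p_nodes <- matrix(0, nn, k); w_nodes <- matrix(0, nn, k)
  for (i in seq_len(k)) {
    ni <- length(nodes[[i]]$x)
    p_nodes[seq_len(ni), i] <- .pda_success_prob(nodes[[i]]$x, model)
    w_nodes[seq_len(ni), i] <- nodes[[i]]$w
  }
  res <- pda_predict_cpp(
    Ns = as.integer(cd$N), wN = cd$n_windows,
    p_nodes = p_nodes, w_nodes = w_nodes,
    fractions = model$states$fraction, obs_edges = bins,
    kind = if (model$kind == "fret") 0L else 1L,
    gammaf = model$gamma, R0 = model$R0, gfac = model$g_factor,
    bg_success = bg_success, bg_fail = bg_fail)
  total <- sum(cd$n_windows)
  lost <- res$lost_low + res$lost_high
  if (lost > max_lost * total)
    stop(sprintf(
      "bins do not cover the predicted support: %.3g of %g windows lost below, %.3g above",
      res$lost_low, total, res$lost_high))
  nb <- length(bins) - 1
  out <- tibble::tibble(
    bin_lo = bins[-length(bins)], bin_hi = bins[-1],
    mid = (bins[-1] + bins[-length(bins)]) / 2,
    expected = res$hist)
  attr(out, "censored") <- res$censored
  attr(out, "lost_low") <- res$lost_low
  attr(out, "lost_high") <- res$lost_high
  attr(out, "n_windows") <- total
  out
}

#' Monte-Carlo draws from a PDA generative model
#'
#' Samples per-window observables directly from the generative process
#' (state -> Gaussian observable -> binomial counts -> estimator).  This is
#' the brute-force counterpart of [pda_predict()] used to validate it.
#'
#' @inheritParams pda_predict
#' @param n_draws Number of windows to draw.
#' @param seed Integer seed.
#' @return Numeric vector of observable values (NA = censored windows).
#' @export
pda_sample_windows <- function(model, count_dist, n_draws, seed,
                               bg_success = 0, bg_fail = 0) {
  stopifnot(inherits(model, "pda_model"))
  set.seed(as.integer(seed))
  cd <- .pda_count_dist(count_dist)
  N <- sample(cd$N, n_draws, replace = TRUE, prob = cd$n_windows)
  st <- sample.int(nrow(model$states), n_draws, replace = TRUE,
                   prob = model$states$fraction)
  x <- stats::rnorm(n_draws, model$states$mean[st],
                    model$states$half_width[st])
  if (model$kind == "fret") x <- pmax(x, 1) else x <- pmin(pmax(x, -0.199), 0.999)
  p <- .pda_success_prob(x, model)
  bs <- if (bg_success > 0) stats::rpois(n_draws, bg_success) else 0
  bf <- if (bg_fail > 0) stats::rpois(n_draws, bg_fail) else 0
  Fl <- pmax(N - bs - bf, 0)
  s_obs <- stats::rbinom(n_draws, Fl, p) + bs
  Fsucc <- s_obs - bg_success
  Ffail <- (N - s_obs) - bg_fail
  if (model$kind == "fret") {
    E <- ifelse(Fsucc <= 0, NA_real_,
                Fsucc / (Fsucc + model$gamma * pmax(Ffail, 0)))
    ifelse(is.na(E), NA_real_,
           ifelse(E >= 1, 0, model$R0 * (1 / E - 1)^(1 / 6)))
  } else {
    den <- Fsucc + 2 * model$g_factor * Ffail
    ifelse(den <= 0, NA_real_, (Fsucc - model$g_factor * Ffail) / den)
  }
}

#' Prepare windowed observables for PDA fitting
#'
#' Groups a window-observable table by time-window length and builds, per
#' group, the observable histogram and the window photon-count
#' distribution.
#'
#' @param observables Output of [mfd_observables()] on [time_windows()]
#'   tables (may be the row-bound result over several `delta_t`).
#' @param observable `"RDA_E"` or `"r_D"`.
#' @param bins Histogram breaks on the observable (default: 61 bins over
#'   35-150 Å for FRET, -0.2-0.45 for anisotropy).
#' @param calib The [calibration] used to compute the observables.
#' @return A `pda_data` object (list of per-`delta_t` groups with
#'   histogram, count distribution and background means).
#' @export
pda_prepare <- function(observables, observable = c("RDA_E", "r_D"),
                        bins = NULL, calib = calibration()) {
  observable <- match.arg(observable)
  kind <- if (observable == "RDA_E") "fret" else "anisotropy"
  obs <- tibble::as_tibble(observables)
  if (!"delta_t" %in% names(obs)) obs$delta_t <- obs$duration_ms
  if (is.null(bins)) {
    bins <- if (kind == "fret") seq(30, 90, length.out = 62)
            else seq(-0.2, 0.45, length.out = 62)
  }
  groups <- split(obs, obs$delta_t)
  data <- purrr::map(groups, function(g) {
    dt <- g$delta_t[1]
    if (kind == "fret") {
      N <- g$n_Gp + g$n_Gs + g$n_Rp + g$n_Rs
      val <- g$RDA_E
      cens <- g$censored | !is.finite(val)
      bg_succ <- (calib$bg_rates[3] + calib$bg_rates[4]) * dt
      bg_fail <- (calib$bg_rates[1] + calib$bg_rates[2]) * dt
    } else {
      N <- g$n_Gp + g$n_Gs
      val <- g$r_D
      cens <- !is.finite(val)
      bg_succ <- calib$bg_rates[1] * dt
      bg_fail <- calib$bg_rates[2] * dt
    }
    h <- graphics::hist(val[!cens & val >= min(bins) & val <= max(bins)],
                        breaks = bins, plot = FALSE)
    list(delta_t = dt,
         bins = bins, counts = h$counts,
         count_dist = .pda_count_dist(N),
         bg_success = bg_succ, bg_fail = bg_fail,
         n_windows = length(N), n_censored = sum(cens))
  })
  structure(list(groups = data, kind = kind, observable = observable,
                 bins = bins, calib = calib),
            class = "pda_data")
}

#' @export
print.pda_data <- function(x, ...) {
  cat(sprintf("<pda_data> %s, %d time-window group(s)\n", x$kind,
              length(x$groups)))
  for (g in x$groups)
    cat(sprintf("  dt = %g ms: %d windows (%d censored)\n",
                g$delta_t, g$n_windows, g$n_censored))
  invisible(x)
}

# stick-breaking softmax for fractions
.logits_to_fractions <- function(l) {
  e <- exp(c(l, 0))
  e / sum(e)
}

#' Fit a k-state PDA model globally across time windows
#'
#' State means and half-widths are shared across all time-window groups;
#' fractions are either shared too (default) or free per group.  The fit
#' minimises Poisson-weighted least squares between observed and predicted
#' histograms using bounded Levenberg-Marquardt with a seeded multi-start
#' (the best of `n_starts` runs wins; ties break toward lower chi2_r).
#'
#' @param data A `pda_data` from [pda_prepare()].
#' @param k_states Number of states.
#' @param fractions_shared Share fractions across groups (default TRUE).
#' @param n_starts Number of multi-start runs.
#' @param seed Seed for start dispersion (fit is deterministic given data,
#'   bounds and this seed).
#' @param n_nodes Gauss-Hermite nodes per state.
#' @param hw_max Upper bound for half-widths (default: observable range/4).
#' @return A `pda_fit` object; see [tidy.pda_fit()].
#' @export
pda_fit <- function(data, k_states, fractions_shared = TRUE, n_starts = 8,
                    seed = 1, n_nodes = 12, hw_max = NULL) {
  stopifnot(inherits(data, "pda_data"), k_states >= 1)
  kind <- data$kind
  bins <- data$bins
  rng <- range(bins)
  if (is.null(hw_max)) hw_max <- diff(rng) / 4
  ngrp <- length(data$groups)
  nfr <- if (k_states == 1) 0 else (k_states - 1) * (if (fractions_shared) 1 else ngrp)

  # parameter packing: means (k), half-widths (k), fraction logits
  unpack <- function(p) {
    means <- p[seq_len(k_states)]
    hw <- p[k_states + seq_len(k_states)]
    fr <- if (k_states == 1) {
      matrix(1, 1, ngrp)
    } else if (fractions_shared) {
      matrix(.logits_to_fractions(p[2 * k_states + seq_len(k_states - 1)]),
             k_states, ngrp)
    } else {
      sapply(seq_len(ngrp), function(g)
        .logits_to_fractions(
          p[2 * k_states + (g - 1) * (k_states - 1) + seq_len(k_states - 1)]))
    }
    list(means = means, hw = hw, fr = fr)
  }

  predict_group <- function(g, means, hw, fracs) {
    m <- pda_model(tibble::tibble(mean = means, half_width = hw,
                                  fraction = fracs),
                   kind = kind, R0 = data$calib$R0, gamma = data$calib$gamma,
                   g_factor = data$calib$g_factor)
    pda_predict(m, g$count_dist, g$bins, bg_success = g$bg_success,
                bg_fail = g$bg_fail, n_nodes = n_nodes,
                max_lost = 1)$expected
  }

  resid_fn <- function(p) {
    u <- unpack(p)
    # order penalty: keep means sorted to remove label switching
    unlist(lapply(seq_len(ngrp), function(gi) {
      g <- data$groups[[gi]]
      pred <- predict_group(g, u$means, u$hw, u$fr[, gi])
      (g$counts - pred) / sqrt(pmax(pred, 1))
    }))
  }

  # seeded multi-start
  set.seed(as.integer(seed))
  obs_mids <- lapply(data$groups, function(g) {
    mids <- (g$bins[-1] + g$bins[-length(g$bins)]) / 2
    rep(mids, g$counts)
  })
  allv <- unlist(obs_mids)
  qs <- stats::quantile(allv, probs = seq(0.15, 0.85,
                                          length.out = k_states))
  hw0 <- diff(rng) / 30
  lower <- c(rep(rng[1], k_states), rep(0, k_states), rep(-6, nfr))
  upper <- c(rep(rng[2], k_states), rep(hw_max, k_states), rep(6, nfr))
  starts <- lapply(seq_len(n_starts), function(i) {
    m0 <- sort(as.numeric(qs) +
                 if (i == 1) 0 else stats::rnorm(k_states, 0, diff(rng) / 10))
    m0 <- pmin(pmax(m0, rng[1]), rng[2])
    c(m0, rep(hw0, k_states), rep(0, nfr))
  })

  nbins_all <- sum(vapply(data$groups, function(g) length(g$counts), 0L))
  runs <- list()
  for (p0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = p0, fn = resid_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    runs[[length(runs) + 1]] <- fit
    # a start that already reaches chi2_r ~ 1 cannot be improved meaningfully
    if (sum(fit$fvec^2) / max(nbins_all - length(p0), 1) < 1.15) break
  }
  if (!length(runs)) stop("all PDA fit starts failed")
  dev <- vapply(runs, function(f) sum(f$fvec^2), 0)
  best <- runs[[which.min(dev)]]
  u <- unpack(best$par)
  ord <- order(u$means)
  u$means <- u$means[ord]; u$hw <- u$hw[ord]
  u$fr <- u$fr[ord, , drop = FALSE]

  # goodness of fit
  nbins_tot <- sum(vapply(data$groups, function(g) length(g$counts), 0L))
  npar <- length(best$par)
  chi2 <- sum(best$fvec^2)
  chi2_r <- chi2 / max(nbins_tot - npar, 1)

  # parameter uncertainties from the jacobian (delta method for fractions)
  se <- rep(NA_real_, length(best$par))
  vc <- try(vcov(best), silent = TRUE)
  if (!inherits(vc, "try-error") && all(is.finite(diag(vc))))
    se <- sqrt(pmax(diag(vc), 0))
  se_means <- se[seq_len(k_states)][ord]
  se_hw <- se[k_states + seq_len(k_states)][ord]
  se_fr <- if (k_states > 1) {
    # linearised through the softmax at the optimum
    J <- .softmax_jacobian(best$par[2 * k_states + seq_len(nfr)],
                           k_states, if (fractions_shared) 1 else ngrp)
    idx <- 2 * k_states + seq_len(nfr)
    V <- vc[idx, idx, drop = FALSE]
    fr_se <- sqrt(pmax(diag(J %*% V %*% t(J)), 0))
    matrix(fr_se, k_states)[ord, , drop = FALSE]
  } else matrix(0, 1, 1)

  per_window <- purrr::map_dfr(seq_len(ngrp), function(gi) {
    tibble::tibble(delta_t = data$groups[[gi]]$delta_t,
                   state = seq_len(k_states),
                   mean = u$means, half_width = u$hw,
                   fraction = u$fr[, gi],
                   fraction_se = se_fr[, min(gi, ncol(se_fr))])
  })

  conv_warn <- NULL
  if (k_states > 1 && !inherits(vc, "try-error")) {
    cm <- stats::cov2cor(vc + diag(1e-12, nrow(vc)))
    maxcor <- max(abs(cm[upper.tri(cm)]))
    if (maxcor > 0.999) {
      conv_warn <- sprintf(
        "parameter correlations reach %.4f: model complexity may exceed what the data identify",
        maxcor)
      warning(conv_warn)
    }
  }

  structure(list(
    states = tibble::tibble(mean = u$means, mean_se = se_means,
                            half_width = u$hw, half_width_se = se_hw,
                            fraction = rowMeans(u$fr),
                            fraction_se = rowMeans(se_fr)),
    per_window = per_window,
    chi2_r = chi2_r, chi2 = chi2, df = max(nbins_tot - npar, 1),
    k_states = k_states, kind = kind,
    fractions_shared = fractions_shared,
    convergence = best$info, message = best$message,
    conv_warning = conv_warn,
    data = data, n_nodes = n_nodes, seed = seed),
    class = "pda_fit")
}

.softmax_jacobian <- function(logits, k, ngrp) {
  # block-diagonal jacobian d fractions / d logits, stacked over groups
  blocks <- lapply(seq_len(ngrp), function(g) {
    l <- logits[(g - 1) * (k - 1) + seq_len(k - 1)]
    f <- .logits_to_fractions(l)
    J <- matrix(0, k, k - 1)
    for (i in seq_len(k)) for (j in seq_len(k - 1))
      J[i, j] <- f[i] * ((i == j) - f[j])
    J
  })
  out <- matrix(0, k * ngrp, (k - 1) * ngrp)
  for (g in seq_len(ngrp)) {
    out[(g - 1) * k + seq_len(k), (g - 1) * (k - 1) + seq_len(k - 1)] <-
      blocks[[g]]
  }
  out
}

#' @export
print.pda_fit <- function(x, ...) {
  cat(sprintf("<pda_fit> %d-state %s PDA, chi2_r = %.3f (df %d)\n",
              x$k_states, x$kind, x$chi2_r, x$df))
  print(x$states)
  invisible(x)
}

#' Tidy a PDA fit
#' @param x A `pda_fit`.
#' @param per_window Return per-time-window fractions instead of the
#'   state-level summary.
#' @param ... Unused.
#' @export
tidy.pda_fit <- function(x, per_window = FALSE, ...) {
  if (per_window) x$per_window else x$states
}

#' @rdname tidy.pda_fit
#' @export
glance.pda_fit <- function(x, ...) {
  tibble::tibble(k_states = x$k_states, kind = x$kind, chi2_r = x$chi2_r,
                 chi2 = x$chi2, df = x$df,
                 fractions_shared = x$fractions_shared,
                 converged = x$convergence %in% 1:4)
}

#' Predicted histograms of a fitted PDA model
#' @param object A `pda_fit`.
#' @param ... Unused.
#' @return Tibble of per-group observed and predicted bin counts.
#' @export
predict.pda_fit <- function(object, ...) {
  x <- object
  purrr::map_dfr(seq_along(x$data$groups), function(gi) {
    g <- x$data$groups[[gi]]
    fr <- x$per_window$fraction[x$per_window$delta_t == g$delta_t]
    m <- pda_model(tibble::tibble(mean = x$states$mean,
                                  half_width = x$states$half_width,
                                  fraction = fr),
                   kind = x$kind, R0 = x$data$calib$R0,
                   gamma = x$data$calib$gamma,
                   g_factor = x$data$calib$g_factor)
    pr <- pda_predict(m, g$count_dist, g$bins, bg_success = g$bg_success,
                      bg_fail = g$bg_fail, n_nodes = x$n_nodes,
                      max_lost = 1)
    tibble::tibble(delta_t = g$delta_t, mid = pr$mid,
                   observed = g$counts, expected = pr$expected)
  })
}

#' Rank PDA fits of the same data by parsimony
#'
#' Ranks fits by their reduced chi-square with a parsimony rule: a model
#' with more states is preferred only when it improves chi2_r by more than
#' `threshold` (relative).  Ties go to the model with fewer states.
#'
#' @param fits List of `pda_fit` objects of the same prepared data.
#' @param threshold Relative chi2_r improvement required to justify an
#'   extra state (default 0.1).
#' @return A tibble ranked by preference with the selected model first.
#' @export
model_compare <- function(fits, threshold = 0.1) {
  stopifnot(length(fits) >= 2)
  sig <- function(f) unlist(lapply(f$data$groups, function(g) g$counts))
  s0 <- sig(fits[[1]])
  for (f in fits[-1])
    if (!isTRUE(all.equal(sig(f), s0)))
      stop("model_compare requires fits of the same data")
  tab <- purrr::map_dfr(fits, function(f)
    tibble::tibble(k_states = f$k_states, chi2_r = f$chi2_r))
  tab <- dplyr::arrange(tab, .data$k_states)
  sel <- 1
  for (i in seq_len(nrow(tab))[-1]) {
    if (tab$chi2_r[i] < tab$chi2_r[sel] * (1 - threshold)) sel <- i
  }
  tab$selected <- seq_len(nrow(tab)) == sel
  dplyr::arrange(tab, dplyr::desc(.data$selected), .data$chi2_r,
                 .data$k_states)
}
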