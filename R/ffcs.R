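#' Species reference decay pattern of a photon stream
#'
#' Histograms photons over (channel, micro-time bin): the fingerprint used
#' to build species filters.  In simulation work the references come from
#' pure single-state simulated streams; with measured data they come from
#' subpopulation-gated bursts (gate the burst table, then subset the stream
#' to the gated photon indices before calling this).
#'
#' @param stream A `photon_stream`.
#' @param micro_bins Number of micro-time bins per channel.
#' @return Numeric vector of length `4 * micro_bins` (channel-major).
#' @export
decay_pattern <- function(stream, micro_bins = 16) {
  meta <- attr(stream, "metadata")
  period <- meta$excitation_period %||% 15.625
  idx <- .pattern_bin(as.integer(stream$channel), stream$micro_time,
                      micro_bins, period)
  tabulate(idx, nbins = 4 * micro_bins)
}

.pattern_bin <- function(channel, micro, micro_bins, period) {
  mb <- pmin(pmax(ceiling(micro / period * micro_bins), 1L), micro_bins)
  (channel - 1L) * micro_bins + mb
}

#' Build species filters from reference decay patterns
#'
#' Solves the standard least-squares unmixing problem: filter weights over
#' (channel, micro-time) bins such that, applied to a pure-species decay
#' pattern, the photon-weighted sum returns 1 for that species and 0 for
#' every other (the unbiasedness constraint, verified post hoc to 1e-6).
#' Weighting uses the expected mixed pattern, so the filters are also
#' minimum-variance for the assumed mixture.
#'
#' @param reference_decays Named list of per-species patterns (vectors from
#'   [decay_pattern()], equal length) or of pure-species `photon_stream`s.
#' @param mix_weights Assumed species weights in the mixed measurement
#'   (default equal).  Only efficiency, not unbiasedness, depends on this.
#' @param micro_bins Micro-time bins per channel (when streams are given).
#' @return A `filter_set`: matrix `weights` (species x bins), species
#'   labels, and the micro-binning used.
#' @export
build_filters <- function(reference_decays, mix_weights = NULL,
                          micro_bins = 16) {
  if (length(reference_decays) < 2)
    stop("need at least 2 reference decay patterns")
  if (inherits(reference_decays[[1]], "photon_stream")) {
    period <- attr(reference_decays[[1]], "metadata")$excitation_period
    reference_decays <- lapply(reference_decays, decay_pattern,
                               micro_bins = micro_bins)
  } else {
    period <- NULL
  }
  P <- do.call(cbind, reference_decays)
  if (is.null(colnames(P)))
    colnames(P) <- paste0("S", seq_len(ncol(P)))
  P <- sweep(P, 2, colSums(P), "/")            # normalised patterns
  ns <- ncol(P)
  if (is.null(mix_weights)) mix_weights <- rep(1 / ns, ns)
  s <- as.vector(P %*% mix_weights)
  d <- ifelse(s > 0, 1 / s, 0)
  M <- t(P) %*% (P * d)
  kap <- kappa(M, exact = TRUE)
  if (!is.finite(kap) || kap > 1e10)
    stop(sprintf(
      "reference patterns are degenerate (condition number %.3g): filters cannot be built", kap))
  Fmat <- solve(M, t(P * d))                  # species x bins
  resid <- Fmat %*% P - diag(ns)
  if (max(abs(resid)) > 1e-6)
    stop("filter unbiasedness constraint violated; patterns may be collinear")
  rownames(Fmat) <- colnames(P)
  structure(list(weights = Fmat, species = colnames(P),
                 micro_bins = if (is.matrix(P)) nrow(P) / 4 else micro_bins,
                 period = period),
            class = "filter_set")
}

#' @export
print.filter_set <- function(x, ...) {
  cat(sprintf("<filter_set> %d species (%s), %d bins\n",
              length(x$species), paste(x$species, collapse = ", "),
              ncol(x$weights)))
  invisible(x)
}

#' Per-photon species filter weights
#'
#' @param stream A `photon_stream`.
#' @param filters A `filter_set`.
#' @return Matrix (photons x species).
#' @export
filter_photons <- function(stream, filters) {
  meta <- attr(stream, "metadata")
  period <- meta$excitation_period %||% 15.625
  mb <- filters$micro_bins
  idx <- .pattern_bin(as.integer(stream$channel), stream$micro_time, mb,
                      period)
  t(filters$weights[, idx, drop = FALSE])
}

#' Species-filtered correlation functions
#'
#' Computes weighted photon-pair correlations on a quasi-logarithmic
#' multi-tau lag grid: the species autocorrelation (sACF) for every species
#' and the species cross-correlation (sCCF) for every ordered species pair.
#' With `filters = NULL` all weights are 1 and the ordinary intensity ACF is
#' returned.  Uncertainties come from splitting the trace into
#' `n_segments` equal segments and taking the standard error over segments.
#'
#' @param stream A `photon_stream` (warns below 1e4 photons).
#' @param filters Optional `filter_set`.
#' @param lag_min Smallest lag, s.
#' @param lag_max Largest lag, s (must be well below the segment length).
#' @param m Points per cascade (lag doubling after the first `2 m` lags).
#' @param n_segments Segments for the variance estimate.
#' @return A `corr_curve` tibble: `species1`, `species2`, `kind`
#'   (ACF/sACF/sCCF), `lag_s`, `G`, `sd`.
#' @export
correlate <- function(stream, filters = NULL, lag_min = 2e-7,
                      lag_max = NULL, m = 16, n_segments = 8) {
  meta <- attr(stream, "metadata")
  duration <- meta$duration
  if (is.null(lag_max)) lag_max <- duration / n_segments / 10
  if (duration <= 10 * lag_max)
    stop("stream duration must be much longer than the largest lag")
  if (nrow(stream) < 1e4)
    warning("fewer than 1e4 photons: correlation curves will be noisy")
  n_casc <- max(1, ceiling(log2(lag_max / (lag_min * 2 * m))) + 1)

  if (is.null(filters)) {
    W <- matrix(1, nrow(stream), 1)
    species <- "all"
  } else {
    W <- filter_photons(stream, filters)
    species <- filters$species
  }
  ns <- length(species)
  pairs <- tidyr::expand_grid(i = seq_len(ns), j = seq_len(ns))

  seg_len <- duration / n_segments
  seg_id <- pmin(floor(stream$macro_time / seg_len), n_segments - 1)
  tt <- stream$macro_time

  purrr::map_dfr(seq_len(nrow(pairs)), function(pp) {
    i <- pairs$i[pp]; j <- pairs$j[pp]
    per_seg <- lapply(seq_len(n_segments) - 1, function(sg) {
      sel <- seg_id == sg
      res <- correlate_cpp(tt[sel] - sg * seg_len, W[sel, i], W[sel, j],
                           seg_len, lag_min, m, n_casc)
      res$G
    })
    lag <- correlate_cpp(tt[seg_id == 0], W[seg_id == 0, i],
                         W[seg_id == 0, j], seg_len, lag_min, m,
                         n_casc)$lag
    Gm <- do.call(cbind, per_seg)
    keep <- lag <= lag_max
    kind <- if (is.null(filters)) "ACF" else if (i == j) "sACF" else "sCCF"
    tibble::tibble(
      species1 = species[i], species2 = species[j], kind = kind,
      lag_s = lag[keep],
      G = rowMeans(Gm, na.rm = TRUE)[keep],
      sd = apply(Gm, 1, stats::sd, na.rm = TRUE)[keep] / sqrt(n_segments))
  }) |>
    (\(d) structure(d, class = c("corr_curve", class(d))))()
}

#' Fit a diffusion x relaxation model to a correlation curve
#'
#' Model: `G(tau) = 1 + G0 * Gdiff(tau) * (1 + sum_i A_i exp(-tau/t_i))`
#' with the 3D-Gaussian diffusion factor
#' `Gdiff = (1 + tau/td)^-1 (1 + tau/(kappa^2 td))^-1/2`.  Negative
#' amplitudes capture the anticorrelation terms of species
#' cross-correlations.  Bounded Levenberg-Marquardt with a seeded
#' multi-start over log-spaced relaxation times; deterministic given data,
#' bounds and seed.
#'
#' @param curve One correlation curve: tibble with `lag_s`, `G` and
#'   (optionally) `sd` columns, e.g. one species pair filtered from
#'   [correlate()] output.
#' @param n_components Number of exponential relaxation terms (>= 0).
#' @param kappa Axial ratio of the detection volume.
#' @param t_diff_init Optional initial diffusion time, s.
#' @param n_starts Multi-start runs.
#' @param seed Seed for start dispersion.
#' @return A `relaxation_fit` with diffusion time (s), relaxation times,
#'   amplitudes, anticorrelation flags, chi2_r and residuals.
#' @export
fit_relaxations <- function(curve, n_components, kappa = 3,
                            t_diff_init = NULL, n_starts = 8, seed = 1) {
  stopifnot(n_components >= 0)
  if ("kind" %in% names(curve) &&
      length(unique(paste(curve$species1, curve$species2))) > 1)
    stop("pass a single correlation curve (one species pair)")
  lag <- curve$lag_s
  G <- curve$G
  ok <- is.finite(lag) & is.finite(G)
  sd <- if ("sd" %in% names(curve)) curve$sd else rep(NA_real_, length(G))
  lag <- lag[ok]; G <- G[ok]; sd <- sd[ok]
  sd[!is.finite(sd) | sd <= 0] <- stats::median(sd[is.finite(sd) & sd > 0],
                                                na.rm = TRUE)
  if (!any(is.finite(sd))) sd <- rep(1, length(G))
  w <- 1 / pmax(sd, 1e-6)

  if (is.null(t_diff_init)) {
    # lag where the amplitude has dropped to half its small-lag plateau
    g0 <- stats::median(head(G - 1, 8))
    idx <- which(G - 1 < g0 / 2)[1]
    t_diff_init <- if (is.na(idx)) stats::median(lag) else lag[idx]
  }
  gdiff <- function(tau, td) 1 / ((1 + tau / td) * sqrt(1 + tau / (kappa^2 * td)))

  nc <- n_components
  model_fn <- function(p) {
    G0 <- exp(p[1]); td <- exp(p[2])
    rel <- rep(1, length(lag))
    if (nc > 0) {
      A <- p[2 + seq_len(nc)]
      ti <- exp(p[2 + nc + seq_len(nc)])
      rel <- 1 + rowSums(sapply(seq_len(nc),
                                function(i) A[i] * exp(-lag / ti[i])))
    }
    1 + G0 * gdiff(lag, td) * rel
  }
  resid_fn <- function(p) (G - model_fn(p)) * w

  set.seed(as.integer(seed))
  lag_rng <- range(lag)
  g0_init <- max(stats::median(head(G, 5)) - 1, 1e-3)
  starts <- lapply(seq_len(max(n_starts, 1)), function(i) {
    ti0 <- exp(seq(log(lag_rng[1] * 3), log(lag_rng[2] / 3),
                   length.out = max(nc, 1)))
    if (i > 1 && nc > 0)
      ti0 <- exp(log(ti0) + stats::rnorm(nc, 0, 0.8))
    # alternate between the data-driven diffusion-time guess and log-uniform
    # draws over the lag range (the guess fails for strongly anticorrelated
    # cross-correlations whose small-lag plateau is suppressed)
    td0 <- if (i <= 2) t_diff_init
           else exp(stats::runif(1, log(lag_rng[1] * 10), log(lag_rng[2])))
    c(log(g0_init), log(td0),
      if (nc > 0) rep(if (i %% 2 == 0) -0.2 else 0.2, nc),
      if (nc > 0) log(ti0))
  })
  lower <- c(log(1e-6), log(lag_rng[1]),
             rep(-1.5, nc), rep(log(lag_rng[1] / 2), nc))
  upper <- c(log(1e4), log(lag_rng[2] * 10),
             rep(50, nc), rep(log(lag_rng[2] * 2), nc))
  runs <- lapply(starts, function(p0) {
    tryCatch(minpack.lm::nls.lm(
      par = p0, fn = resid_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) stop("relaxation fit failed from every start")
  dev <- vapply(runs, function(f) sum(f$fvec^2), 0)
  best <- runs[[which.min(dev)]]
  p <- best$par
  G0 <- exp(p[1]); td <- exp(p[2])
  A <- if (nc > 0) p[2 + seq_len(nc)] else numeric(0)
  ti <- if (nc > 0) exp(p[2 + nc + seq_len(nc)]) else numeric(0)
  ordc <- order(ti)
  A <- A[ordc]; ti <- ti[ordc]
  chi2 <- sum(best$fvec^2)
  dfree <- max(length(G) - length(p), 1)
  fitted <- model_fn(best$par)
  converged <- best$info %in% 1:4
  if (!converged)
    warning("relaxation fit did not converge: ", best$message)
  structure(list(
    G0 = G0, t_diff = td,
    components = tibble::tibble(
      relaxation_time_s = ti, amplitude = A, anticorrelated = A < 0),
    chi2_r = chi2 / dfree, converged = converged,
    residuals = G - fitted, fitted = fitted, lag_s = lag, G = G, sd = sd,
    kappa = kappa, n_components = nc),
    class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf("<relaxation_fit> t_diff = %.3g s, G0 = %.3g, chi2_r = %.2f\n",
              x$t_diff, x$G0, x$chi2_r))
  if (nrow(x$components)) print(x$components)
  invisible(x)
}

#' Tidy a relaxation fit
#' @param x A `relaxation_fit`.
#' @param ... Unused.
#' @export
tidy.relaxation_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "t_diff", estimate = x$t_diff),
    tibble::tibble(term = paste0("t_relax_", seq_len(nrow(x$components))),
                   estimate = x$components$relaxation_time_s),
    tibble::tibble(term = paste0("amplitude_", seq_len(nrow(x$components))),
                   estimate = x$components$amplitude))
}

#' @rdname tidy.relaxation_fit
#' @export
glance.relaxation_fit <- function(x, ...) {
  tibble::tibble(t_diff = x$t_diff, G0 = x$G0, chi2_r = x$chi2_r,
                 n_components = x$n_components, converged = x$converged)
}

#' Write a correlation curve to CSV (lag_s, G, sd)
#' @param curve Tibble from [correlate()].
#' @param path Output path.
#' @export
write_corr_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Global relaxation fit across several correlation curves
#'
#' Fits the species auto- and cross-correlation curves of one measurement
#' jointly: the diffusion time and the relaxation times are shared across
#' curves while each curve keeps its own amplitude `G0` and relaxation
#' amplitudes `A_i` (positive in sACFs, negative in sCCFs for two-state
#' exchange).  Sharing the time axis across curves removes the
#' diffusion/relaxation trade-off that limits single-curve fits when a
#' relaxation time approaches the diffusion time.
#'
#' @param curves A `corr_curve` tibble from [correlate()] containing two or
#'   more species pairs.
#' @param n_components Number of shared exponential relaxation terms.
#' @param kappa Axial ratio of the detection volume.
#' @param n_starts,seed Seeded multi-start (deterministic).
#' @return A `relaxation_fit_global`: shared `t_diff` and relaxation times,
#'   per-curve amplitudes, chi2_r.
#' @export
fit_relaxations_global <- function(curves, n_components, kappa = 3,
                                   n_starts = 8, seed = 1) {
  stopifnot(n_components >= 0)
  key <- paste(curves$species1, curves$species2, sep = " x ")
  groups <- split(tibble::as_tibble(curves), key)
  ng <- length(groups)
  if (ng < 2) stop("global fit needs at least two curves; use fit_relaxations()")
  nc <- n_components
  prep <- lapply(groups, function(g) {
    ok <- is.finite(g$lag_s) & is.finite(g$G)
    sd <- if ("sd" %in% names(g)) g$sd else rep(NA_real_, nrow(g))
    lag <- g$lag_s[ok]; G <- g$G[ok]; sd <- sd[ok]
    sd[!is.finite(sd) | sd <= 0] <-
      stats::median(sd[is.finite(sd) & sd > 0], na.rm = TRUE)
    if (!any(is.finite(sd))) sd <- rep(1, length(G))
    list(lag = lag, G = G, w = 1 / pmax(sd, 1e-6), sd = sd)
  })
  lag_rng <- range(unlist(lapply(prep, `[[`, "lag")))
  gdiff <- function(tau, td) 1 / ((1 + tau / td) * sqrt(1 + tau / (kappa^2 * td)))

  # packing: [log G0 (ng)] [log td] [A (ng x nc)] [log t_i (nc)]
  model_g <- function(p, g) {
    G0 <- exp(p[g]); td <- exp(p[ng + 1])
    lag <- prep[[g]]$lag
    rel <- rep(1, length(lag))
    if (nc > 0) {
      A <- p[ng + 1 + (g - 1) * nc + seq_len(nc)]
      ti <- exp(p[ng + 1 + ng * nc + seq_len(nc)])
      rel <- 1 + rowSums(sapply(seq_len(nc),
                                function(i) A[i] * exp(-lag / ti[i])))
    }
    1 + G0 * gdiff(lag, td) * rel
  }
  resid_fn <- function(p)
    unlist(lapply(seq_len(ng), function(g)
      (prep[[g]]$G - model_g(p, g)) * prep[[g]]$w))

  set.seed(as.integer(seed))
  g0s <- vapply(prep, function(pg) max(stats::median(utils::head(pg$G, 5)) - 1,
                                       1e-3), 0)
  td0 <- stats::median(lag_rng)
  starts <- lapply(seq_len(max(n_starts, 1)), function(i) {
    ti0 <- exp(seq(log(lag_rng[1] * 3), log(lag_rng[2] / 3),
                   length.out = max(nc, 1)))
    if (i > 1 && nc > 0) ti0 <- exp(log(ti0) + stats::rnorm(nc, 0, 0.8))
    tds <- if (i <= 2) td0
           else exp(stats::runif(1, log(lag_rng[1] * 10), log(lag_rng[2])))
    c(log(g0s), log(tds),
      if (nc > 0) rep(c(-0.2, 0.2), length.out = ng * nc),
      if (nc > 0) log(ti0))
  })
  lower <- c(rep(log(1e-6), ng), log(lag_rng[1]),
             rep(-1.5, ng * nc), rep(log(lag_rng[1] / 2), nc))
  upper <- c(rep(log(1e4), ng), log(lag_rng[2] * 10),
             rep(50, ng * nc), rep(log(lag_rng[2] * 2), nc))
  runs <- lapply(starts, function(p0)
    tryCatch(minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                                upper = upper,
                                control = minpack.lm::nls.lm.control(maxiter = 300)),
             error = function(e) NULL))
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) stop("global relaxation fit failed from every start")
  best <- runs[[which.min(vapply(runs, function(f) sum(f$fvec^2), 0))]]
  p <- best$par
  td <- exp(p[ng + 1])
  ti <- if (nc > 0) exp(p[ng + 1 + ng * nc + seq_len(nc)]) else numeric(0)
  ordc <- order(ti)
  A <- if (nc > 0) matrix(p[ng + 1 + seq_len(ng * nc)], nc, ng)[ordc, ,
                                                                drop = FALSE]
  else matrix(0, 0, ng)
  colnames(A) <- names(groups)
  ti <- ti[ordc]
  npts <- sum(vapply(prep, function(pg) length(pg$G), 0L))
  structure(list(
    t_diff = td, relaxation_times_s = ti, amplitudes = A,
    G0 = stats::setNames(exp(p[seq_len(ng)]), names(groups)),
    chi2_r = sum(best$fvec^2) / max(npts - length(p), 1),
    converged = best$info %in% 1:4, curves = names(groups),
    n_components = nc, kappa = kappa),
    class = "relaxation_fit_global")
}

#' @export
print.relaxation_fit_global <- function(x, ...) {
  cat(sprintf(
    "<relaxation_fit_global> %d curves, t_diff = %.3g s, chi2_r = %.2f\n",
    length(x$curves), x$t_diff, x$chi2_r))
  if (length(x$relaxation_times_s)) {
    cat("  shared relaxation times (s):",
        paste(signif(x$relaxation_times_s, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.relaxation_fit_global <- function(x, ...) {
  tibble::tibble(term = c("t_diff",
                          paste0("t_relax_", seq_along(x$relaxation_times_s))),
                 estimate = c(x$t_diff, x$relaxation_times_s))
}

#' @export
glance.relaxation_fit_global <- function(x, ...) {
  tibble::tibble(t_diff = x$t_diff, chi2_r = x$chi2_r,
                 n_components = x$n_components,
                 n_curves = length(x$curves), converged = x$converged)
}
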