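#' Plot a 2D MFD frequency histogram
#'
#' Filled 2D frequency map of two burst observables with the marginal
#' distributions available via [mfd_histogram2d()].
#'
#' @param object An `mfd_hist2d`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mfd_hist2d <- function(object, ...) {
  tbl <- dplyr::filter(object$table, .data$n > 0)
  ggplot2::ggplot(tbl, ggplot2::aes(.data$x_mid, .data$y_mid,
                                    fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "bursts") +
    ggplot2::labs(x = object$x, y = object$y) +
    ggplot2::theme_minimal()
}

#' Plot observed vs predicted PDA histograms
#'
#' One panel per time-window length with observed counts (points) and the
#' fitted shot-noise prediction (line).
#'
#' @param object A `pda_fit`.
#' @param ... Unused.
#' @export
autoplot.pda_fit <- function(object, ...) {
  pr <- stats::predict(object)
  ggplot2::ggplot(pr, ggplot2::aes(.data$mid, .data$observed)) +
    ggplot2::geom_col(fill = "grey80", width = diff(pr$mid[1:2]) * 0.9) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected), colour = "firebrick",
                       linewidth = 0.7) +
    ggplot2::facet_wrap(~delta_t, labeller = ggplot2::label_both) +
    ggplot2::labs(x = if (object$kind == "fret") "R_DA (A)" else "anisotropy",
                  y = "windows") +
    ggplot2::theme_minimal()
}

#' Plot correlation curves
#'
#' Log-lag correlation curves, one colour per species pair, with the
#' segment-derived uncertainty band.
#'
#' @param object A `corr_curve` tibble from [correlate()].
#' @param ... Unused.
#' @export
autoplot.corr_curve <- function(object, ...) {
  d <- dplyr::mutate(object,
                     pair = paste(.data$species1, .data$species2, sep = " x "))
  ggplot2::ggplot(d, ggplot2::aes(.data$lag_s, .data$G, colour = .data$pair)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$G - .data$sd,
                                      ymax = .data$G + .data$sd,
                                      fill = .data$pair),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lag (s)", y = "G") +
    ggplot2::theme_minimal()
}

#' Plot a relaxation fit
#'
#' Correlation data with the fitted diffusion x relaxation model and the
#' residuals underneath.
#'
#' @param object A `relaxation_fit`.
#' @param ... Unused.
#' @export
autoplot.relaxation_fit <- function(object, ...) {
  d <- tibble::tibble(lag_s = object$lag_s, G = object$G,
                      fitted = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(.data$lag_s, .data$G)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lag (s)", y = "G") +
    ggplot2::theme_minimal()
}

#' Plot an ITC titration and its single-site fit
#'
#' @param object An `itc_fit`.
#' @param ... Unused.
#' @export
autoplot.itc_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- object$fitted
  ggplot2::ggplot(d, ggplot2::aes(.data$injection_index, .data$heat_ucal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "injection", y = "heat (ucal)") +
    ggplot2::theme_minimal()
}

#' Plot a per-residue chemical-shift difference profile
#'
#' @param profile Output of [combined_shift_profile()].
#' @param threshold Optional horizontal reference line.
#' @export
plot_shift_profile <- function(profile, threshold = NULL) {
  p <- ggplot2::ggplot(dplyr::filter(profile, .data$matched),
                       ggplot2::aes(.data$residue, .data$delta_delta)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(x = "residue", y = expression(Delta * delta ~ "(ppm)")) +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                                 colour = "firebrick")
  p
}

#' Plot a dynamic-shift diagnostic
#'
#' Burst records in the distance-lifetime plane with the static FRET line.
#'
#' @param shift A `dynamic_shift` object.
#' @param line The [fret_line] used for the diagnostic.
#' @export
plot_dynamic_shift <- function(shift, line) {
  rec <- shift$records
  taus <- seq(line$tau_range[1], line$tau_range[2], length.out = 200)
  ld <- tibble::tibble(tau = taus, R = static_line_distance(line, taus))
  ggplot2::ggplot(rec, ggplot2::aes(.data$tau_DA_f, .data$RDA_E)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.4) +
    ggplot2::geom_line(data = ld, ggplot2::aes(.data$tau, .data$R),
                       colour = "darkgreen", linewidth = 0.8) +
    ggplot2::labs(x = "tau_D(A) (ns)", y = "R_DA (A)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
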