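#' Förster efficiency from an inter-dye distance
#'
#' Converts a donor-acceptor distance into a FRET efficiency via the Förster
#' relation `E = 1 / (1 + (R/R0)^6)`, and back.
#'
#' @param R Inter-dye distance in Angstrom. Vectorised.
#' @param R0 Förster radius in Angstrom (53.0 Å for the Alexa488/Alexa647
#'   pair used throughout the package defaults).
#' @return `efficiency_from_distance()` returns the efficiency in (0, 1];
#'   `distance_from_efficiency()` returns the distance in Angstrom.
#' @examples
#' efficiency_from_distance(53, 53)   # 0.5 at R = R0
#' distance_from_efficiency(0.727, 53)
#' @export
efficiency_from_distance <- function(R, R0) {
  stopifnot(all(R > 0), R0 > 0)
  1 / (1 + (R / R0)^6)
}

#' @rdname efficiency_from_distance
#' @param E FRET efficiency in (0, 1].
#' @export
distance_from_efficiency <- function(E, R0) {
  stopifnot(all(E > 0), all(E <= 1), R0 > 0)
  R0 * (1 / E - 1)^(1 / 6)
}

#' Static FRET line
#'
#' A static FRET line maps the fluorescence-weighted average donor lifetime
#' \eqn{\langle\tau_{D(A)}\rangle_f} of a burst to the FRET-averaged distance
#' \eqn{\langle R_{DA}\rangle_E} expected when every molecule holds a single
#' fixed distance during its transit.  Populations to the right of the line
#' (longer lifetime at a given distance) are the hallmark of conformational
#' exchange faster than the burst duration.
#'
#' The line is parameterised as
#' \deqn{\langle R_{DA}\rangle_E =
#'   \left(\frac{1}{\tau_0^{eff} / (a_2\tau^2 + a_1\tau + a_0) - 1}\right)^{1/6} R_0}
#' where the quadratic in \eqn{\tau} is an empirical linker correction.  The
#' two built-in lines (see [fret_line_builtin()]) carry the coefficients for
#' the non-phosphorylated and the Y88-phosphorylated p27 FRET constructs.
#' Note the constant term is negative: the formula adds a negative `a0`.
#'
#' @param label Short name for the line.
#' @param a2,a1,a0 Quadratic coefficients applied to the lifetime (ns).
#' @param tau0_eff Effective unquenched donor scaling constant (ns).
#' @param R0 Förster radius (Å).
#' @return An object of class `fret_line` carrying the coefficients and the
#'   valid lifetime range (where the inner polynomial is positive and the
#'   efficiency stays inside (0, 1)).
#' @export
fret_line <- function(label, a2, a1, a0, tau0_eff, R0) {
  stopifnot(is.numeric(a2), is.numeric(a1), is.numeric(a0),
            tau0_eff > 0, R0 > 0)
  line <- structure(
    list(label = label, a2 = a2, a1 = a1, a0 = a0,
         tau0_eff = tau0_eff, R0 = R0),
    class = "fret_line")
  line$tau_range <- .fret_line_domain(line)
  line
}

# Valid lifetime domain: inner polynomial positive and strictly below
# tau0_eff so that 0 < E < 1 and the distance is finite.
.fret_line_domain <- function(line) {
  tau <- seq(1e-3, 25, by = 1e-3)
  p <- line$a2 * tau^2 + line$a1 * tau + line$a0
  ok <- p > 0 & p < line$tau0_eff
  if (!any(ok)) stop("fret_line has an empty valid lifetime range")
  range(tau[ok])
}

#' @export
print.fret_line <- function(x, ...) {
  cat(sprintf(
    "<fret_line '%s'>  R0 = %.1f A, tau0_eff = %.4f ns\n  poly: %.4f*tau^2 + %.4f*tau + %.4f\n  valid tau: [%.3f, %.3f] ns\n",
    x$label, x$R0, x$tau0_eff, x$a2, x$a1, x$a0,
    x$tau_range[1], x$tau_range[2]))
  invisible(x)
}

#' Built-in static FRET lines
#'
#' Returns one of the two calibrated static FRET lines shipped with the
#' package: `"no_phos"` (non-phosphorylated construct) or `"pY88"`
#' (Y88-phosphorylated construct).  Both use R0 = 53.0 Å.
#'
#' @param which `"no_phos"` or `"pY88"`.
#' @return A [fret_line] object.
#' @export
fret_line_builtin <- function(which = c("no_phos", "pY88")) {
  which <- match.arg(which)
  switch(which,
    no_phos = fret_line("no_phos", a2 = 0.0079, a1 = 1.0179, a0 = -0.1618,
                        tau0_eff = 3.8306, R0 = 53.0),
    pY88    = fret_line("pY88",    a2 = 0.0202, a1 = 0.9655, a0 = -0.1527,
                        tau0_eff = 3.9997, R0 = 53.0))
}

#' Read static FRET line coefficients from CSV
#'
#' Expects columns `label, a2, a1, a0, tau0_eff, R0`; returns a named list of
#' [fret_line] objects.
#' @param path CSV file path.
#' @export
read_fret_lines <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "a2", "a1", "a0", "tau0_eff", "R0")
  if (!all(need %in% names(df)))
    stop("fret line CSV must have columns: ", paste(need, collapse = ", "))
  lines <- purrr::pmap(df[need], fret_line)
  stats::setNames(lines, df$label)
}

#' Evaluate a static FRET line
#'
#' @param line A [fret_line].
#' @param tau Fluorescence-weighted average donor lifetime(s), ns.
#' @return \eqn{\langle R_{DA}\rangle_E} in Angstrom.
#' @export
static_line_distance <- function(line, tau) {
  stopifnot(inherits(line, "fret_line"))
  p <- line$a2 * tau^2 + line$a1 * tau + line$a0
  bad <- p <= 0 | p >= line$tau0_eff
  if (all(bad)) stop("lifetime outside the valid domain of the static FRET line")
  E <- 1 - p / line$tau0_eff               # efficiency 1 - tau_eff/tau0_eff
  out <- (1 / E - 1)^(1 / 6) * line$R0     # Forster inversion of that E
  out[bad] <- NA_real_
  out
}

#' Invert a static FRET line: lifetime at a given distance
#'
#' Solves the line's quadratic for the lifetime at which a static molecule of
#' distance `RDA` would sit exactly on the line.  Used to place simulated
#' states on a line and to measure lifetime-axis deviations.
#'
#' @param line A [fret_line].
#' @param RDA FRET-averaged distance(s), Å.
#' @return Lifetime in ns (NA where the distance maps outside the domain).
#' @export
static_line_tau <- function(line, RDA) {
  stopifnot(inherits(line, "fret_line"), all(RDA > 0, na.rm = TRUE))
  E <- efficiency_from_distance(RDA, line$R0)
  target <- line$tau0_eff * (1 - E)
  # a2 tau^2 + a1 tau + (a0 - target) = 0, take the root in the valid range
  vapply(target, function(tt) {
    if (abs(line$a2) < 1e-12) {
      tau <- (tt - line$a0) / line$a1
    } else {
      disc <- line$a1^2 - 4 * line$a2 * (line$a0 - tt)
      if (disc < 0) return(NA_real_)
      tau <- (-line$a1 + sqrt(disc)) / (2 * line$a2)
    }
    if (tau < line$tau_range[1] || tau > line$tau_range[2]) NA_real_ else tau
  }, numeric(1))
}

#' Dynamic-shift diagnostic against a static FRET line
#'
#' For each burst/window record carrying `RDA_E` (Å) and `tau_DA_f` (ns) the
#' deviation from a static FRET line is computed.  The primary deviation is
#' measured along the lifetime axis, `tau_DA_f - static_line_tau(RDA_E)`:
#' positive values lie to the right of the line, the hallmark of exchange
#' faster than the observation window.  The distance-axis residual
#' `RDA_E - static_line_distance(tau)` is also reported (it has the opposite
#' sign for dynamically mixed populations).
#'
#' @param observables Data frame with columns `RDA_E` and `tau_DA_f`
#'   (as produced by [mfd_observables()]).
#' @param line A [fret_line].
#' @param censor_distance Records at or above this distance (donor-only
#'   censoring convention) are skipped. Default 150 Å.
#' @return A `dynamic_shift` object: tibble with `dev_lifetime` (ns) and
#'   `dev_distance` (Å) columns plus a summary (median deviation, fraction of
#'   records on the long-lifetime side, sign-test p-value, number skipped).
#' @export
dynamic_shift <- function(observables, line, censor_distance = 150) {
  stopifnot(inherits(line, "fret_line"))
  if (!all(c("RDA_E", "tau_DA_f") %in% names(observables)))
    stop("observables must carry RDA_E and tau_DA_f")
  obs <- tibble::as_tibble(observables)
  usable <- is.finite(obs$RDA_E) & is.finite(obs$tau_DA_f) &
    obs$RDA_E < censor_distance
  n_skipped <- sum(!usable)
  res <- obs[usable, , drop = FALSE]
  res$tau_line <- static_line_tau(line, res$RDA_E)
  res$dev_lifetime <- res$tau_DA_f - res$tau_line
  res$dev_distance <- res$RDA_E - static_line_distance(line, res$tau_DA_f)
  dom_skip <- !is.finite(res$dev_lifetime)
  n_skipped <- n_skipped + sum(dom_skip)
  res <- res[!dom_skip, , drop = FALSE]
  dev <- res$dev_lifetime
  n_pos <- sum(dev > 0)
  n_nonzero <- sum(dev != 0)
  p_sign <- if (n_nonzero > 0)
    stats::binom.test(n_pos, n_nonzero, p = 0.5)$p.value else NA_real_
  structure(
    list(records = res,
         summary = tibble::tibble(
           n = nrow(res), n_skipped = n_skipped,
           median_dev_lifetime = stats::median(dev),
           median_dev_distance = stats::median(res$dev_distance),
           frac_long_lifetime = if (nrow(res)) n_pos / nrow(res) else NA_real_,
           p_sign_test = p_sign)),
    class = "dynamic_shift")
}

#' @export
print.dynamic_shift <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<dynamic_shift> %d records (%d skipped)\n  median lifetime-axis deviation: %+.3f ns\n  fraction right of static line: %.3f (sign test p = %.3g)\n",
    s$n, s$n_skipped, s$median_dev_lifetime, s$frac_long_lifetime,
    s$p_sign_test))
  invisible(x)
}

#' @export
tidy.dynamic_shift <- function(x, ...) x$records

#' @export
glance.dynamic_shift <- function(x, ...) x$summary

#' Perrin equation: rotational correlation time and steady-state anisotropy
#'
#' `perrin_rho()` inverts the Perrin relation `r(rho) = r0 / (1 + tau/rho)` to
#' obtain the rotational correlation time from a measured steady-state
#' anisotropy; `perrin_r()` is the forward form.
#'
#' @param r Steady-state anisotropy, must satisfy `0 < r < r0`.
#' @param r0 Fundamental anisotropy (<= 0.4).
#' @param tau Fluorescence lifetime, ns.
#' @param rho Rotational correlation time, ns.
#' @return `perrin_rho()`: rho in ns; `perrin_r()`: anisotropy.
#' @examples
#' perrin_rho(r = 0.19, r0 = 0.38, tau = 4)  # 4 ns
#' @export
perrin_rho <- function(r, r0, tau) {
  stopifnot(all(r > 0), r0 > 0, r0 <= 0.4, all(tau > 0))
  if (any(r >= r0))
    stop("anisotropy r must be below the fundamental anisotropy r0 (unphysical otherwise)")
  tau / (r0 / r - 1)
}

#' @rdname perrin_rho
#' @export
perrin_r <- function(rho, r0, tau) {
  stopifnot(all(rho > 0), r0 > 0, r0 <= 0.4, all(tau > 0))
  r0 / (1 + tau / rho)
}
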