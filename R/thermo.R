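# Gas constant in kcal mol^-1 K^-1
.R_KCAL <- 1.9872e-3

#' Binding free energy and entropic term
#'
#' `free_energy()` converts a dissociation constant into the standard binding
#' free energy, `dG = R T ln(K_D)` (kcal/mol, R = 1.9872e-3 kcal/mol/K);
#' `entropy_term()` returns the entropic contribution `-T dS = dG - dH`.
#'
#' @param K_D Dissociation constant, molar.
#' @param T Absolute temperature, K.
#' @param dG,dH Free energy and enthalpy of binding, kcal/mol.
#' @return kcal/mol.
#' @examples
#' free_energy(4.9e-9, 298.15)        # about -11.4
#' entropy_term(-11.4, -50.6)         # +39.2
#' @export
free_energy <- function(K_D, T = 298.15) {
  stopifnot(all(K_D > 0), all(T > 0))
  .R_KCAL * T * log(K_D)
}

#' @rdname free_energy
#' @export
entropy_term <- function(dG, dH) dG - dH

#' Heat-capacity change from an enthalpy temperature series
#'
#' The heat-capacity change of binding is the slope of dH versus temperature,
#' estimated by ordinary least squares.
#'
#' @param dH_series Data frame with columns `temperature_K` and
#'   `dH_kcal_mol` (one row per ITC experiment temperature), or a two-column
#'   data frame interpreted in that order.
#' @return A tibble with `dCp_cal_mol_K`, its standard error, intercept-level
#'   `dH_at_298K` and the number of temperatures used.
#' @export
heat_capacity <- function(dH_series) {
  df <- as.data.frame(dH_series)
  if (!all(c("temperature_K", "dH_kcal_mol") %in% names(df))) {
    if (ncol(df) < 2) stop("need temperature and dH columns")
    names(df)[1:2] <- c("temperature_K", "dH_kcal_mol")
  }
  if (nrow(df) < 3)
    stop("heat_capacity needs at least 3 temperatures")
  fit <- stats::lm(dH_kcal_mol ~ temperature_K, data = df)
  # noiseless series are legitimate input; summary.lm warns on them
  co <- suppressWarnings(summary(fit))$coefficients
  slope_kcal <- co["temperature_K", "Estimate"]
  se_kcal <- co["temperature_K", "Std. Error"]
  tibble::tibble(
    dCp_cal_mol_K = slope_kcal * 1000,
    dCp_se = se_kcal * 1000,
    dH_at_298K = unname(stats::predict(fit,
      newdata = data.frame(temperature_K = 298.15))),
    n_temperatures = nrow(df))
}

#' Spolar-Record constants
#'
#' Constants of the Spolar-Record decomposition of the binding entropy into
#' hydration, rotational-translational and conformational terms.  Defaults:
#' the hydration entropy is `1.35 * dCp * ln(T / 386 K)` (the 386 K reference
#' temperature where hydration entropy vanishes), the rigid-body
#' rotational-translational penalty is -50 cal/mol/K, and each residue that
#' folds upon binding costs -5.6 cal/mol/K of conformational entropy.  All
#' constants are overridable; small changes move the residue count by
#' 5-10 percent.
#'
#' @param hydration_coeff Multiplier on `dCp * ln(T/T_s)`.
#' @param dS_rt Rotational-translational entropy, cal/mol/K.
#' @param dS_per_residue Conformational entropy per folding residue,
#'   cal/mol/K/residue (negative).
#' @param T_s Reference temperature, K.
#' @export
spolar_record_constants <- function(hydration_coeff = 1.35,
                                    dS_rt = -50,
                                    dS_per_residue = -5.6,
                                    T_s = 386) {
  stopifnot(T_s > 0, dS_per_residue < 0)
  list(hydration_coeff = hydration_coeff, dS_rt = dS_rt,
       dS_per_residue = dS_per_residue, T_s = T_s)
}

#' Residues folded upon binding (Spolar-Record)
#'
#' Dissects the measured association entropy into hydration (`dS_HE`),
#' rigid-body (`dS_rt`) and conformational (`dS_conf`) contributions and
#' converts the latter into the number of residues that fold upon binding:
#' \deqn{\Delta S_{HE} = c\,\Delta C_p \ln(T/T_s),\quad
#'       \Delta S_{conf} = \Delta S_{assoc} - \Delta S_{HE} - \Delta S_{rt},\quad
#'       \Re = \Delta S_{conf} / \Delta S_{res}}
#'
#' @param dCp Heat-capacity change, cal/mol/K (negative for folding-coupled
#'   binding; a positive value is rejected).
#' @param minus_TdS The entropic term `-T dS` of binding, kcal/mol, at
#'   temperature `T` (as printed in thermodynamic tables).
#' @param T Temperature, K (default 298.15).
#' @param constants See [spolar_record_constants()].
#' @return A tibble with `R_fold` (residues) and every intermediate entropy
#'   term (cal/mol/K) for audit; `unphysical` flags a negative residue count.
#' @examples
#' residues_folded(dCp = -1267, minus_TdS = 39.2)  # about 93 residues
#' @export
residues_folded <- function(dCp, minus_TdS, T = 298.15,
                            constants = spolar_record_constants()) {
  stopifnot(T > 0)
  if (any(dCp >= 0))
    stop("residues_folded expects dCp < 0 (folding-coupled binding)")
  dS_assoc <- -minus_TdS * 1000 / T                 # cal/mol/K
  dS_HE <- constants$hydration_coeff * dCp * log(T / constants$T_s)
  dS_conf <- dS_assoc - dS_HE - constants$dS_rt
  R_fold <- dS_conf / constants$dS_per_residue
  out <- tibble::tibble(
    R_fold = R_fold,
    dS_assoc = dS_assoc, dS_HE = dS_HE,
    dS_rt = constants$dS_rt, dS_conf = dS_conf,
    temperature_K = T,
    unphysical = R_fold < 0)
  if (any(out$unphysical))
    warning("negative residues-folded estimate; inspect the entropy terms")
  out
}

#' Assemble a full thermodynamic parameter set
#'
#' Convenience constructor enforcing the closure `dG = dH + (-T dS)` and the
#' relation between `dG` and `K_D`.
#'
#' @param K_D Molar dissociation constant.
#' @param dH Enthalpy, kcal/mol.
#' @param dCp Heat capacity change, cal/mol/K (optional).
#' @param T Temperature, K.
#' @param constants Spolar-Record constants, used when `dCp` is given.
#' @return A one-row tibble with K_D, dG, dH, minus_TdS, dCp, R_fold.
#' @export
thermo_params <- function(K_D, dH, dCp = NA_real_, T = 298.15,
                          constants = spolar_record_constants()) {
  dG <- free_energy(K_D, T)
  mTdS <- entropy_term(dG, dH)
  R_fold <- if (is.finite(dCp) && dCp < 0)
    residues_folded(dCp, mTdS, T, constants)$R_fold else NA_real_
  tibble::tibble(K_D = K_D, dG = dG, dH = dH, minus_TdS = mTdS,
                 dCp = dCp, R_fold = R_fold, temperature_K = T)
}

# ---- single-site ITC model ----------------------------------------------

# Concentrations in the cell after cumulative injection volume vcum (uL),
# with exponential displacement bookkeeping: cell species dilute by
# exp(-dv/V0) per injection, syringe species accumulate toward the syringe
# concentration.
.itc_concentrations <- function(cell_conc, syringe_conc, injection_volumes,
                                cell_volume) {
  vcum <- cumsum(injection_volumes)
  f <- exp(-vcum / cell_volume)
  list(M = cell_conc * f, X = syringe_conc * (1 - f))
}

# Bound complex concentration for 1:1 binding with n sites on M.
.itc_bound <- function(M, X, K_D, n) {
  Mt <- n * M
  b <- Mt + X + K_D
  (b - sqrt(pmax(b^2 - 4 * Mt * X, 0))) / 2
}

# Predicted heats (ucal) per injection for a titration.
.itc_heats <- function(K_D, dH, n, cell_conc, syringe_conc,
                       injection_volumes, cell_volume) {
  conc <- .itc_concentrations(cell_conc, syringe_conc, injection_volumes,
                              cell_volume)
  MX <- .itc_bound(conc$M, conc$X, K_D, n)
  MX_prev <- c(0, MX[-length(MX)])
  d <- exp(-injection_volumes / cell_volume)
  # dH kcal/mol * mol = kcal; cell volume in uL, conc in M -> mol = c * V * 1e-6
  # heats reported in ucal: kcal * 1e9
  dn_bound <- (MX - MX_prev * d) * cell_volume * 1e-6
  dH * dn_bound * 1e9
}

#' Fit a single-site binding model to an ITC titration
#'
#' Nonlinear least-squares fit of the exact 1:1 binding isotherm (with
#' per-injection displacement/dilution bookkeeping) to integrated injection
#' heats.  Parameters: `K_D`, `dH`, and the stoichiometry `n`.
#'
#' @param titration Data frame with columns `injection_index`, `volume_uL`,
#'   `heat_ucal` (and optionally `temperature_K`), as written by
#'   [simulate_itc_titrations()].
#' @param cell_conc Macromolecule concentration in the cell, M.
#' @param syringe_conc Titrant concentration in the syringe, M.
#' @param cell_volume Active cell volume, uL.
#' @param T Temperature, K (taken from the table when present).
#' @param fit_n Fit the stoichiometry (default) or hold it at 1.
#' @param start Optional named list of starting values (K_D, dH, n).
#' @return An object of class `itc_fit`; see [tidy.itc_fit()] /
#'   [glance.itc_fit()].  Carries a c-value reliability warning flag when
#'   `n * cell_conc / K_D` falls outside `[1, 1e4]`.
#' @export
fit_single_site <- function(titration, cell_conc, syringe_conc,
                            cell_volume = 200, T = NULL, fit_n = TRUE,
                            start = NULL) {
  df <- tibble::as_tibble(titration)
  need <- c("injection_index", "volume_uL", "heat_ucal")
  if (!all(need %in% names(df)))
    stop("titration must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) < 8) stop("need at least 8 injections for a single-site fit")
  stopifnot(cell_conc > 0, syringe_conc > 0, cell_volume > 0)
  if (is.null(T))
    T <- if ("temperature_K" %in% names(df)) df$temperature_K[1] else 298.15
  vols <- df$volume_uL
  heats <- df$heat_ucal
  if (all(abs(heats) < 1e-12)) {
    out <- structure(list(
      K_D = NA_real_, dH = 0, n = NA_real_,
      se = c(K_D = NA_real_, dH = 0, n = NA_real_),
      temperature_K = T, c_value = NA_real_, flagged = "unidentifiable",
      residuals = heats, fitted = heats * 0, data = df), class = "itc_fit")
    warning("all heats are zero: dH = 0, K_D unidentifiable")
    return(out)
  }

  model <- function(p) {
    .itc_heats(exp(p[["lKD"]]), p[["dH"]], p[["n"]],
               cell_conc, syringe_conc, vols, cell_volume)
  }
  if (is.null(start)) {
    dh0 <- sum(heats) / (cell_conc * cell_volume * 1e-6 * 1e9)
    start <- list(K_D = cell_conc / 50, dH = dh0, n = 1)
  }
  p0 <- c(lKD = log(start$K_D), dH = start$dH, n = start$n)
  free <- if (fit_n) c("lKD", "dH", "n") else c("lKD", "dH")
  resid_fn <- function(pf) {
    p <- p0; p[free] <- pf
    heats - model(p)
  }
  fit <- minpack.lm::nls.lm(
    par = p0[free], fn = resid_fn,
    lower = c(lKD = log(1e-15), dH = -Inf, n = 0.1)[free],
    upper = c(lKD = log(1), dH = Inf, n = 10)[free],
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  p <- p0; p[free] <- fit$par
  K_D <- exp(p[["lKD"]]); dH <- p[["dH"]]; n <- p[["n"]]
  # standard errors via the jacobian, delta method for K_D
  se <- rep(NA_real_, 3); names(se) <- c("K_D", "dH", "n")
  cv <- tryCatch(vcov(fit), error = function(e) NULL)
  if (!is.null(cv) && all(is.finite(diag(cv)))) {
    sdp <- sqrt(diag(cv))
    if ("lKD" %in% names(sdp)) se["K_D"] <- K_D * sdp[["lKD"]]
    if ("dH" %in% names(sdp)) se["dH"] <- sdp[["dH"]]
    if ("n" %in% names(sdp)) se["n"] <- sdp[["n"]]
  }
  c_value <- n * cell_conc / K_D
  flagged <- if (c_value < 1 || c_value > 1e4) "c_value" else NA_character_
  if (!is.na(flagged))
    warning(sprintf("c-value %.3g outside [1, 1e4]: K_D poorly constrained",
                    c_value))
  structure(list(
    K_D = K_D, dH = dH, n = n, se = se, temperature_K = T,
    c_value = c_value, flagged = flagged,
    residuals = fit$fvec, fitted = heats - fit$fvec, data = df),
    class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf(
    "<itc_fit> K_D = %.3g M, dH = %.2f kcal/mol, n = %.3f (T = %.2f K, c = %.3g)\n",
    x$K_D, x$dH, x$n, x$temperature_K, x$c_value))
  invisible(x)
}

#' Tidy an ITC single-site fit
#' @param x An `itc_fit`.
#' @param ... Unused.
#' @return One row per parameter with estimate and standard error.
#' @export
tidy.itc_fit <- function(x, ...) {
  tibble::tibble(term = c("K_D", "dH", "n"),
                 estimate = c(x$K_D, x$dH, x$n),
                 std.error = unname(x$se))
}

#' @rdname tidy.itc_fit
#' @return `glance()`: one-row summary with derived thermodynamics.
#' @export
glance.itc_fit <- function(x, ...) {
  dG <- if (is.finite(x$K_D)) free_energy(x$K_D, x$temperature_K) else NA_real_
  tibble::tibble(
    K_D = x$K_D, dG = dG, dH = x$dH,
    minus_TdS = if (is.finite(dG)) entropy_term(dG, x$dH) else NA_real_,
    n = x$n, temperature_K = x$temperature_K, c_value = x$c_value,
    rss = sum(x$residuals^2), flagged = x$flagged)
}
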