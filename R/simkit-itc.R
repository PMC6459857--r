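#' Simulation parameters for an ITC titration
#'
#' Defaults mirror a typical low-volume calorimeter run titrating 10 uM
#' ligand into 1 uM macromolecule: one 0.5 uL priming injection followed by
#' 3.1 uL injections.
#'
#' @param K_D Dissociation constant, M.
#' @param dH Binding enthalpy at the reference temperature, kcal/mol.
#' @param n_sites Stoichiometry.
#' @param cell_conc Macromolecule concentration in the cell, M.
#' @param syringe_conc Titrant concentration in the syringe, M.
#' @param injection_volumes Injection volumes, uL.
#' @param cell_volume Active cell volume, uL.
#' @param temperature Reference temperature, K.
#' @param noise_sd Gaussian noise per injection heat, ucal.
#' @export
itc_sim_params <- function(K_D = 4.9e-9, dH = -50.6, n_sites = 1,
                           cell_conc = 1e-6, syringe_conc = 10e-6,
                           injection_volumes = c(0.5, rep(3.1, 12)),
                           cell_volume = 200, temperature = 298.15,
                           noise_sd = 0.05) {
  stopifnot(K_D > 0, cell_conc > 0, syringe_conc > 0,
            all(injection_volumes > 0), cell_volume > 0, temperature > 0,
            noise_sd >= 0)
  structure(list(K_D = K_D, dH = dH, n_sites = n_sites,
                 cell_conc = cell_conc, syringe_conc = syringe_conc,
                 injection_volumes = injection_volumes,
                 cell_volume = cell_volume, temperature = temperature,
                 noise_sd = noise_sd),
            class = "itc_sim_params")
}

#' Simulate ITC titrations across temperatures
#'
#' Per-injection heats follow the exact 1:1 binding isotherm with
#' displacement/dilution bookkeeping across injections (the same model
#' [fit_single_site()] fits), plus Gaussian noise.  Across temperatures the
#' enthalpy varies linearly with the supplied heat-capacity change,
#' `dH(T) = dH_ref + dCp * (T - T_ref)`, and `K_D(T)` follows van't Hoff
#' integration of the same `dH(T)`.
#'
#' @param params An [itc_sim_params].
#' @param temperatures Temperatures, K.
#' @param seed Integer seed.
#' @param dCp Heat-capacity change, cal/mol/K (0 keeps dH constant).
#' @return A tibble with columns `temperature_K`, `injection_index`,
#'   `volume_uL`, `heat_ucal` (one titration per temperature).
#' @export
simulate_itc_titrations <- function(params, temperatures = NULL, seed = 1,
                                    dCp = 0) {
  stopifnot(inherits(params, "itc_sim_params"))
  if (is.null(temperatures)) temperatures <- params$temperature
  stopifnot(length(temperatures) >= 1)
  if (params$syringe_conc < params$cell_conc)
    warning("syringe concentration below cell concentration: titration will not saturate")
  set.seed(as.integer(seed))
  Tref <- params$temperature
  purrr::map_dfr(temperatures, function(Tk) {
    dH_T <- params$dH + dCp / 1000 * (Tk - Tref)
    # van't Hoff: d ln K_A / dT = dH / (R T^2) with linear dH(T)
    lnKA <- -log(params$K_D) +
      (params$dH - dCp / 1000 * Tref) / .R_KCAL * (1 / Tref - 1 / Tk) +
      dCp / 1000 / .R_KCAL * log(Tk / Tref)
    K_D_T <- exp(-lnKA)
    heats <- .itc_heats(K_D_T, dH_T, params$n_sites, params$cell_conc,
                        params$syringe_conc, params$injection_volumes,
                        params$cell_volume)
    if (params$noise_sd > 0)
      heats <- heats + stats::rnorm(length(heats), 0, params$noise_sd)
    tibble::tibble(
      temperature_K = Tk,
      injection_index = seq_along(params$injection_volumes),
      volume_uL = params$injection_volumes,
      heat_ucal = heats)
  })
}

#' Write / read ITC titration tables as CSV
#'
#' Schema: columns `injection_index, volume_uL, heat_ucal, temperature_K`.
#' @param titrations Tibble as produced by [simulate_itc_titrations()].
#' @param path CSV path.
#' @export
write_itc_csv <- function(titrations, path) {
  need <- c("injection_index", "volume_uL", "heat_ucal", "temperature_K")
  if (!all(need %in% names(titrations)))
    stop("titration table must have columns: ", paste(need, collapse = ", "))
  utils::write.csv(titrations[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_itc_csv
#' @export
read_itc_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  need <- c("injection_index", "volume_uL", "heat_ucal", "temperature_K")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed ITC CSV, missing field(s): ", paste(miss, collapse = ", "))
  df
}
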