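# smdyn

Single-molecule fluorescence and binding-thermodynamics analysis of protein
conformational dynamics in R.

Intrinsically disordered proteins can stay bound to a partner while parts of
the complex transiently release — the motivating system is the Cdk2/cyclin A
kinase complex inhibited by p27, where rarely populated, flexible states of
the bound inhibitor expose tyrosines for phosphorylation and thereby control
kinase reactivation.  smdyn implements the quantitative machinery used to
detect and characterise such minor states:

* **Photon-stream simulation** (`simulate_photon_stream()`): time-tagged,
  polarisation- and colour-resolved photons from freely diffusing molecules
  with k-state Markov conformational exchange, Förster colour statistics
  (`E = 1/(1 + (R/R0)^6)`), Perrin polarisation splitting
  (`r = r0/(1 + tau/rho)`), TCSPC micro times with a Gaussian IRF, and
  Poisson background — the ground-truth substrate for every downstream test.
* **Burst analysis** (`find_bursts()`, `time_windows()`,
  `mfd_observables()`, `mfd_histogram2d()`): sliding-window burst search and
  burst/window MFD observables — FRET-averaged distance `<R_DA>_E`,
  fluorescence-weighted donor lifetime `<tau_D(A)>_f`, scatter-corrected
  anisotropy `r_D`.
* **Shot-noise PDA** (`pda_predict()`, `pda_fit()`, `model_compare()`):
  probability distribution analysis of distance and anisotropy histograms —
  Gaussian states convolved with binomial shot noise and Poisson background,
  fitted globally across 1/2/3 ms time windows with a seeded multi-start.
* **Static FRET lines and the dynamic-shift diagnostic** (`fret_line()`,
  `static_line_distance()`, `dynamic_shift()`, `perrin_rho()`): populations
  right of a static FRET line flag exchange faster than the burst duration.
* **Species-filtered FCS** (`build_filters()`, `correlate()`,
  `fit_relaxations()`, `fit_relaxations_global()`): decay-pattern filters
  with an exact unbiasedness constraint, a multi-tau weighted photon
  correlator (sACF/sCCF), and diffusion x relaxation fits — globally across
  curves for exchange kinetics from microseconds to milliseconds.
* **ITC thermodynamics** (`simulate_itc_titrations()`, `fit_single_site()`,
  `heat_capacity()`, `residues_folded()`): exact 1:1 isotherm with
  dilution bookkeeping, `dG = RT ln K_D`, `dCp` from the enthalpy
  temperature series, and the Spolar–Record estimate of residues that fold
  upon binding from `dS_conf = dS_assoc - 1.35 dCp ln(T/386K) - dS_rt`.
* **Accessible-volume simulation and SASA** (`compute_av()`,
  `mean_fret_distance()`, `relative_sasa()`): coarse-grained dye clouds on
  structures, FRET-averaged inter-dye distance prediction, and
  Shrake–Rupley solvent accessibility.
* **NMR chemical-shift mapping** (`combined_shift_profile()`): per-residue
  `sqrt((d dH)^2 + 0.0289 (d dN)^2)` profiles.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()` methods for histograms,
fits and correlation curves.

## A worked example

Binding thermodynamics straight from tabulated quantities:

```r
library(smdyn)
free_energy(4.9e-9, T = 298.15)     # dG for K_D = 4.9 nM
#> [1] -11.3366
residues_folded(dCp = -1267, minus_TdS = 39.2)
#> # A tibble: 1 x 7
#>   R_fold dS_assoc dS_HE dS_rt dS_conf temperature_K unphysical
#>    <dbl>    <dbl> <dbl> <dbl>   <dbl>         <dbl> <lgl>
#> 1   93.4    -131.  442.   -50   -523.          298. FALSE
```

`R_fold = 93` residues fold upon binding: the measured association entropy
(-131 cal/mol/K), minus the hydration gain implied by the heat-capacity
change (+442) and the rigid-body penalty (-50), leaves -523 cal/mol/K of
conformational entropy at -5.6 per residue.

Five simulated minutes of dilute two-state smFRET, from photons to a global
PDA fit:

```r
library(dplyr)
states <- list(
  dye_state("closed", R_DA = 45, sigma_DA = 2,
            tau_D = donor_lifetime(45, R0 = 53, tau0 = 3.8), rho = 10),
  dye_state("open",   R_DA = 52, sigma_DA = 2,
            tau_D = donor_lifetime(52, R0 = 53, tau0 = 3.8), rho = 10))
model  <- exchange_model(states, rates = matrix(c(0, 0.85, 4.15, 0), 2, 2,
                                                byrow = TRUE))  # 83% closed
optics <- confocal_model(brightness = 150, mean_occupancy = 0.008)
stream <- simulate_photon_stream(model, optics, duration = 300, seed = 42)
stream
#> <photon_stream> 725833 photons over 300 s (2.42 kHz)

bursts  <- find_bursts(stream, min_photons = 100)
windows <- bind_rows(lapply(c(1, 2, 3), \(dt) time_windows(stream, bursts, dt)))
cal <- calibration_from_confocal(optics)
obs <- mfd_observables(stream, windows, cal, lifetime = FALSE)
fit <- pda_fit(pda_prepare(obs, "RDA_E", calib = cal), k_states = 2, seed = 1)
tidy(fit)
#> # A tibble: 2 x 6
#>    mean mean_se half_width half_width_se fraction fraction_se
#>   <dbl>   <dbl>      <dbl>         <dbl>    <dbl>       <dbl>
#> 1  44.8  0.0394       1.74        0.0340    0.777     0.00934
#> 2  51.5  0.148        2.72        0.102     0.223     0.00934
```

Five minutes of trace recover the simulated state means (45 and 52 Å) to
within a fraction of an Ångström and the 83/17 populations to a few percent;
`glance(fit)` reports a reduced chi-square of 0.29, and `autoplot(fit)`
overlays the shot-noise prediction on the observed histograms.  The longer
traces used by the shipped analyses tighten the fractions further.

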