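---
title: "Models and methods behind smdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(smdyn)
```

smdyn analyses the conformational dynamics of labelled proteins — the
motivating system is the intrinsically disordered inhibitor p27 bound to the
Cdk2/cyclin A kinase complex — with two complementary kinds of data:
single-molecule multiparameter fluorescence detection (MFD) of freely
diffusing molecules, and isothermal titration calorimetry (ITC).  This
vignette explains the models the package implements, the assumptions behind
them, the tunable parameters that matter, and what the simulation-based
tests do and do not demonstrate.

## The photon-stream simulator

All single-molecule inference in the package is validated against synthetic
photon streams with known ground truth, produced by
`simulate_photon_stream()`.  The generative model has three layers.

**Diffusion.**  Two modes are offered.  In `"tophat"` mode molecular
transits arrive as a Poisson process and last an exponentially distributed
dwell with mean `t_diff` (default 1.7 ms, the diffusion time of the labelled
complex through the confocal volume), with a constant emission rate inside
the volume.  This preserves the burst-duration statistics that burst search,
time windows and PDA depend on, at a fraction of the cost of Brownian paths.
In `"brownian"` mode molecules random-walk through a periodic box with a 3D
Gaussian detection profile (axial ratio `kappa = 3`), so the intensity
autocorrelation follows the closed-form 3D-Gaussian diffusion model
`G(tau) = G0 (1 + tau/td)^-1 (1 + tau/(kappa^2 td))^-1/2` with
`td = w^2/(4D)`; this mode backs every correlation-spectroscopy result.
Because the box holds a fixed number of molecules, number fluctuations are
slightly suppressed at long lags and recovered diffusion times run a few
percent low; this is visible in the acceptance output and stays well inside
the 10% control tolerance.

**Conformational exchange.**  The molecule carries a continuous-time Markov
chain over k states (`exchange_model()`), each state a `dye_state` with a
Gaussian-distributed inter-dye distance (mean `R_DA`, half-width
`sigma_DA`), a donor lifetime `tau_D`, and a rotational correlation time
`rho`.  The chain is evaluated exactly at photon arrival times through the
spectral form of `exp(Q dt)`, which keeps nanosecond-to-millisecond exchange
tractable over hundreds of simulated seconds.  A fresh distance is drawn
whenever the state changes or a new transit begins, so distances are
quasi-static within bursts for slow exchange — exactly the regime static PDA
assumes.

**Photon physics.**  Each detected photon receives a colour (red with the
Förster probability `E = 1/(1 + (R/R0)^6)`, `R0 = 53 Å` by default), a
polarisation (parallel with probability `g(1+2r)/(g(1+2r)+(1-r))`, where
`r = r0/(1 + tau/rho)` is the Perrin steady-state anisotropy of the emitting
state), and a TCSPC micro time (mono-exponential decay convolved with a
Gaussian instrument response, default width 0.25 ns, wrapped into the
15.625 ns excitation period of an 80 MHz-class pulsed laser running at
64 MHz).  Background is Poisson per channel with uniform micro times.
Crosstalk and direct acceptor excitation default to zero but are arguments.

**Default study conditions.**  The confocal defaults emulate a dilute
single-molecule measurement: mean occupancy well below 0.1 (a warning fires
above that), a peak molecular brightness of tens to ~150 kHz, and ~0.3 kHz
background per channel.  Diluteness matters more than it may appear: at an
occupancy of 0.04 about one time window in eight contains photons from two
molecules, and those mixed windows systematically drag a minor PDA state
toward the major one.  The recovery analyses therefore run at occupancy
0.008 (a few usable bursts per second, the regime the underlying experiment
targets) with correspondingly longer simulated traces.

## Burst search and MFD observables

`find_bursts()` is an all-photon sliding-window search: the interphoton-time
series is smoothed with a centred running mean (default 30 photons) and runs
below the `max_interphoton` threshold (default 0.1 ms) become bursts, kept
when they hold at least `min_photons` (default 60) after subtracting the
expected background.  The burst criterion of the original measurement is not
documented, so these thresholds are explicit arguments everywhere.

`time_windows()` tiles each burst into consecutive windows of `Delta t`
(1, 2 and 3 ms in the global analyses), dropping the trailing remainder.
`mfd_observables()` then computes, per burst or window:

* the background/crosstalk-corrected donor:acceptor ratio and the proximity
  efficiency `E = F_A/(F_A + gamma F_D)`, inverted through the Förster
  relation into the FRET-averaged distance `RDA_E`; windows with no
  corrected acceptor signal are right-censored at 150 Å and excluded from
  PDA fits (the donor-only region of the 2D histograms);
* the fluorescence-weighted donor lifetime `tau_DA_f` from a per-segment
  maximum-likelihood mono-exponential fit with analytic Gaussian-IRF
  convolution and a uniform micro-time background floor;
* the scatter-corrected anisotropy
  `r_D = (F_p - g F_s)/((1-3 l2) F_p + (2-3 l1) g F_s)` with polarisation
  mixing factors `l1 = l2 = 0` by default (instrument-specific values can be
  supplied; the exact correction used on the original instrument is not
  public, so the standard MFD form is used and stated as such).

## Shot-noise PDA

`pda_predict()` implements probability distribution analysis: for every
window photon total N it mixes over states, integrates each state's Gaussian
observable on Gauss–Hermite nodes, converts the observable into a
red/green (or parallel/perpendicular) splitting probability, convolves with
binomial counting statistics and truncated-Poisson background in both
channels, and pushes the resulting counts back through the same estimator
used on data.  The forward model is verified against brute-force Monte-Carlo
sampling of the same generative process (`pda_sample_windows()`, an
independent R implementation) to total-variation distance below 0.01.

`pda_fit()` fits k-state models globally across the 1/2/3 ms time windows:
state means and half-widths are shared, fractions are shared by default or
free per window length (`fractions_shared = FALSE`) — both conventions are
offered because the global convention is not uniquely pinned down by the
source analyses; the shared mode is the default used everywhere here.
Minimisation is Poisson-weighted bounded Levenberg–Marquardt with a seeded
multi-start (8 starts; the search stops early once a start reaches a reduced
chi-square near 1, which no further start can meaningfully beat);
label-switching is removed by sorting states by mean.  `model_compare()`
ranks fits by reduced chi-square with a 10% parsimony threshold: an extra
state must buy a >10% improvement, ties go to fewer states — mirroring the
judgement that more complex models yielding marginal chi-square improvement
are rejected.

Identifiability deserves a caution: two states 7 Å apart with ~17% minority
population need window totals of ~100+ photons and thousands of windows
before the likelihood reliably separates them.  With fewer photons the
best-fitting two-state solution can genuinely sit at a shifted minor state —
that is a property of the data, not the optimiser.

## Static FRET lines, dynamic shift and Perrin analysis

A static FRET line gives the expected `RDA_E` as a function of `tau_DA_f`
for molecules with one fixed distance per transit.  The two built-in lines
(`fret_line_builtin("no_phos")`, `"pY88"`) store the calibrated quadratic
coefficients exactly as printed for the non- and Y88-phosphorylated
constructs (the constant term is genuinely negative: the closed form adds a
negative a0); their derivation from dye photophysics is not re-done here.
The valid lifetime range is computed at construction from positivity of the
inner polynomial.  `dynamic_shift()` measures each record's signed deviation
from the line along the lifetime axis (`tau` measured minus `tau` on the
line at the record's distance): dynamically averaged bursts mix photons from
both states and land right of the line (positive deviation), while slow
exchange puts every burst on the line.  The equivalent deviation measured
on the distance axis has the opposite sign for mixed populations; both
columns are reported, and the summary (median deviation, fraction on the
long-lifetime side, sign-test p) uses the lifetime axis because that is the
direction in which the rightward shift of dynamic populations is usually
described.

`perrin_rho()`/`perrin_r()` are the exact forward/inverse Perrin relations
used to turn fitted anisotropy levels into rotational correlation times.

## Species-filtered FCS

`build_filters()` solves the standard least-squares unmixing problem on
reference decay patterns over (channel, micro-time) bins: filters return 1
on their own species' pattern and 0 on every other, verified post hoc to
1e-6; degenerate (collinear) patterns are rejected with the condition
number.  In simulation work the references are pure single-state streams; on
measured data they come from subpopulation-gated bursts.

`correlate()` is a multi-tau photon correlator (16 points per cascade, tick
coarsening per cascade) computing weighted pair correlations: sACF per
species, sCCF per ordered species pair, or the plain intensity ACF without
filters.  Uncertainties come from splitting the trace into 8 segments and
taking the standard error across them (Wohland-style), and those weights
feed the fits.

`fit_relaxations()` fits `G = 1 + G0 Gdiff(tau) (1 + sum A_i exp(-tau/t_i))`
to one curve; `fit_relaxations_global()` fits several curves of one
measurement jointly with shared diffusion and relaxation times and
per-curve amplitudes.  The global fit is the recommended route for exchange
kinetics: it is what breaks the diffusion/relaxation trade-off when a
relaxation time is within an order of magnitude of the diffusion time, and
it reproduces the simulated 1.5 µs, 20 µs and 250 µs exchange times within
about 10% on 100 s traces where single-curve fits can err by 20% or more.
Anticorrelated cross-correlation terms appear as negative amplitudes.

## ITC and the Spolar–Record dissection

`simulate_itc_titrations()` and `fit_single_site()` share one model: the
exact 1:1 isotherm with exponential displacement bookkeeping
(cell species dilute by `exp(-dV/V0)` per injection, titrant accumulates
toward the syringe concentration), defaults mirroring a low-volume
calorimeter titrating 10 µM ligand into 1 µM complex (0.5 µL priming shot
then 3.1 µL injections, 5–25 °C).  The fitter estimates `K_D`, `dH` and the
stoichiometry by bounded Levenberg–Marquardt, warns outside the c-value
window [1, 1e4], and round-trips noiseless synthetic titrations to machine
precision.  Across temperatures the simulator varies `dH` linearly with a
supplied `dCp` and propagates `K_D` by van't Hoff integration;
`heat_capacity()` recovers `dCp` as the ordinary least-squares slope of
`dH(T)`.

`residues_folded()` implements the Spolar–Record dissection
`dS_HE = 1.35 dCp ln(T/386 K)`, `dS_conf = dS_assoc - dS_HE - dS_rt` with
`dS_rt = -50 cal/mol/K`, and `R = dS_conf / (-5.6 cal/mol/K/residue)`.  The
three constants are the commonly used literature defaults and all
overridable (`spolar_record_constants()`), because reasonable alternative
choices shift the residue count by 5–10%; every intermediate entropy term is
returned for audit.  Applied to the tabulated thermodynamics of p27 and its
two phosphomimetics at 298.15 K these defaults give 93, 77 and 44 residues —
inside the tabulated uncertainties and strictly ordered, without any
constant tuned to match.  The dissection uses the 25 °C entropy directly
(the table's temperature); extrapolating `dS` to the 386 K reference first
is possible with the same machinery but is not the default, since the
source analyses do not state which convention they used.

## Accessible volumes and SASA

`compute_av()` is a single-sphere (AV1) accessible-volume search on a cubic
grid (default 0.9 Å): a dye position is allowed when it lies within the
linker length of the attachment atom, the dye sphere clears every atom, and
a straight path from the attachment keeps a clearance of half the linker
width (dial-out approximation; path samples closer to the attachment than
the linker width are exempt, since the linker emerges at van-der-Waals
contact with its own residue).  A three-radius dye option averages three
AV1 clouds.  Dye geometry defaults (20 Å linker, 4.5 Å width, 3.5 Å radius)
follow common practice for the maleimide-linked dyes in question and are
explicit assumptions.  `mean_fret_distance()` averages the Förster
efficiency over weighted dye-position pairs (seeded subsampling above 2e6
pairs) and reports `RDA_E = R0 (1/<E> - 1)^(1/6)` alongside the
mean-position distance.

`relative_sasa()` is Shrake–Rupley solvent accessibility (1.4 Å probe,
golden-spiral test points, 480 per atom by default) normalised either by the
extended Gly-X-Gly tripeptide reference areas (the convention for reporting
buried-interface percentages, default) or by the residue's own isolated
area.  PDB input goes through `read_structure()` (bio3d underneath), with
alternate locations resolved to the highest occupancy and missing
occupancy/B columns tolerated.

## What the synthetic tests do and do not show

The simulator reproduces the statistical structure the estimators rely on:
shot noise, Poisson background, Perrin polarisation splitting, quasi-static
distance heterogeneity, Markovian exchange, diffusion-shaped correlation
functions.  It deliberately omits dead time and afterpulsing, detector
crosstalk beyond a single coefficient, triplet photophysics, acceptor
photobleaching and blinking, spectral crosstalk calibration drift, and
pulsed interleaved excitation.  Passing the recovery tests therefore shows
the inference chain is correct for data matching its model assumptions; it
does not certify robustness to every instrumental artefact of real
measurements, which is what the calibration arguments (`calibration()`,
crosstalk, direct excitation, g-factor) are for.

Problem sizes used in the shipped analyses were chosen to make the
statistical claims testable at comfortable margins: ~1200 s of dilute
simulated trace (~10,000 time windows over the three window lengths) for the
two-state FRET recovery, ~800 s for the anisotropy recovery, 100 s traces
for each exchange-time recovery, and one-million-draw Monte-Carlo samples
for the PDA forward-model check.
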