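---
title: "Measuring benthic calcification with paired proton and oxygen eddy fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring benthic calcification with paired proton and oxygen eddy fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eddycalc)
```

## The measurement problem

Aquatic eddy covariance measures the exchange of a solute between the
seabed and the water column as the time-averaged covariance of the
turbulent vertical velocity and the solute concentration fluctuations,
without enclosing the community or parameterizing turbulent diffusivity.
Dissolved O₂ has long been the workhorse solute. A fast pH sensor adds a
second, chemically very different tracer: photosynthesis consumes CO₂ and
therefore consumes protons at equilibrium, respiration produces them, and
calcification — whether it proceeds by releasing CO₂ or by releasing H⁺
directly — is always a net proton source once the carbonate system has
re-equilibrated.

`eddycalc` exploits that asymmetry. The measured ecosystem proton flux is
modelled as the sum of a metabolic term, predicted from the O₂ flux, and a
calcification term:

$$\mathrm{flux\,H^+_{eco}} = -\frac{\mathrm{O_2 flux}}{Q}\,
  \frac{dH^+}{dDIC} \;+\; G_{net}\,\frac{dH^+}{d(DIC\,2A_T)}$$

Solving for $G_{net}$ turns two flux time series plus a handful of
carbonate-system scalars into a calcification rate per flux window.
The inversion assumes (i) carbonate-system equilibrium at the measurement
volume — reasonable in warm water, where 90% equilibration takes tens of
seconds while canopy-to-sensor transit takes minutes; (ii) that
calcification/dissolution is the dominant non-metabolic proton source, an
assumption that holds in oligotrophic seagrass and reef sediments, where
coupled fermentation–sulfate-reduction–reoxidation has the same net proton
and O₂ stoichiometry as oxic respiration, but that must be revisited where
anaerobic metabolism is strong or geologic CO₂ intrudes; and (iii) a
community photosynthetic quotient $Q$ that is known to ~10%.

## Carbonate chemistry

The solver works on the total pH scale with the constant set that is
standard for Mediterranean and open-ocean work: Lueker et al. K1/K2 (valid
for T 0–40 °C, S 19–43), Dickson KB and KSO₄, Perez & Fraga KF, Millero KW
(converted from the seawater scale), and the Lee boron–salinity ratio.
Nutrient alkalinity is excluded: the deployments this package targets do
not report nutrients, and in oligotrophic waters the phosphate and
silicate terms are well below the 1e-3 µmol kg⁻¹ closure tolerance the
solver enforces. Pressure is accepted for bookkeeping but constants are
evaluated at the surface; at the 8.5–13 m depths of interest the pressure
corrections are far below other error terms. Salinity defaults to 38,
typical Tyrrhenian surface water, for deployments that do not report it.

pH→DIC uses the closed-form carbonate-alkalinity balance; DIC→pH is a
bracketed root find on pH ∈ [2, 12] with tolerance 1e-10, guaranteed to
converge because alkalinity is monotone in pH at fixed DIC. Degenerate
requests (both or neither of pH/DIC supplied, non-positive alkalinity,
unbracketed roots, negative species) fail loudly rather than returning
anything.

The two proton-yield ratios are central finite differences re-solved at
perturbed states: ±1 µmol kg⁻¹ DIC at constant alkalinity for
$dH^+/dDIC$, and the calcification stoichiometry (∓1 DIC, ∓2 alkalinity)
for $dH^+/d(DIC\,2A_T)$. The unit step matches the definition of the
ratios as per-µmol yields; the suite verifies Cauchy convergence under
step halving (relative change < 1e-4) and agreement with a 0.01 µmol step
to 0.1%, so the step size is not a tuning knob. Both ratios are far more
sensitive to pH than to alkalinity at study conditions, which is why
per-window states are solved from window-mean pH and temperature at a
fixed deployment alkalinity (2650 µmol kg⁻¹ by default).

With no CO2SYS-family package available in this toolchain, the solver is
cross-checked in two independent ways: against a separately transcribed
Python implementation of the same constant set (frozen as the plain-text
grid `tests/testthat/carb_reference_grid.csv`, regenerable with
`tools/oracle_carb.py`; agreement to 0.2% over T {15, 25} × S {35, 38} ×
pH {7.7, 8.0, 8.1} × $A_T$ {2300, 2650}), and against two field anchors
computed at deployment conditions: a 0.1-unit pH drop at constant
alkalinity corresponds to ~65 µmol kg⁻¹ of DIC enrichment, and removing
30 mmol CaCO₃ from a ~1 m³ column moves pH by ~−0.035.

## Flux processing

The processing chain and its defaults:

* **Downsampling** of 16 Hz velocities to the 5 Hz optode rate by block
  means on the target grid; a block with under half its samples valid
  becomes a gap.
* **Planar fit**: one rotation per deployment, fitted to 30-minute mean
  velocity vectors (at least six, spanning at least two directions). The
  fitted normal defines the vertical; the `w` offset is removed before
  rotation. Whole-deployment scope is the default because tilt is a
  property of the frame, not of the window; the rotation is recorded in
  the output metadata.
* **Reynolds decomposition** with a 500 s centred running mean, long
  enough to retain low-frequency flux contributions; the window shrinks
  symmetrically at record edges (which makes the fluctuation vanish for
  linear trends), and the first/last 250 s are excluded from flux windows.
* **Lag alignment** within ±2 s at sample resolution (0.2 s at 5 Hz),
  maximizing |cross-correlation|, ties broken toward the smaller |lag|.
  When the correlation peak is weak (|r| < 0.1) the window reuses the
  deployment-median lag of the confident windows: at low signal-to-noise,
  picking the argmax of a noisy correlation function systematically
  inflates the covariance, and the physical lag (pump-tube transit plus
  sensor response) is a deployment constant, not a window property.
* **Flux windows** on a 30-minute grid, the recurring 1-minute pump flow
  reversal masked (29 usable minutes); masked and invalid samples are
  excluded from the covariance mean, and a window under 50% usable is
  invalidated. Fluxes convert to areal daily rates through the seawater
  density; a scalar in µmol kg⁻¹ yields mmol m⁻² d⁻¹, protons in
  nmol kg⁻¹ yield µmol H⁺ m⁻² d⁻¹.
* **Cumulative-flux QC**: the cumulative sum of $w'c'$ must grow linearly
  (R² ≥ 0.8 against time) without bursts (> 50% of the total change inside
  5% of the samples). Windows whose total covariance is indistinguishable
  from zero are flagged `low_flux` instead — the null scale is estimated
  from winsorized block sums, so a burst cannot inflate its own detection
  threshold and the autocorrelation of band-limited turbulence is
  respected. Thresholds are configuration keys, not calibrated to any
  particular rejection rate.
* **Cospectra** via FFT with gap interpolation, Parseval-closed to 1%,
  with normalized ogives; the high-frequency loss of the slower pH sensor
  is estimated by scaling the pH and O₂ cumulative flux curves to agree
  over the band carrying the first quarter of the reference flux (where
  neither sensor attenuates) and comparing them at Nyquist.
* **Despiking** (on by default, switchable) replaces samples deviating
  more than 6 robust sigmas from a 10 s running median with gaps.

Raw ISFET records calibrate through the linear 590 mV-per-pH sensitivity
against a single co-located reference pH; pH series convert to proton
concentration before decomposition because pH itself is not conservative.

## Calcification, metabolism, aggregation

Per-window $G_{net}$ follows the inversion above with the window's
carbonate state. Daily NEC weights the light and dark means by the light
and dark hours (default 12/12, near-equinox). Standard errors propagate
from light and dark to daily values as plain quadrature sums,
$\sqrt{se_L^2 + se_D^2}$ — deliberately not hour-weighted, matching the
convention of reporting a daily uncertainty that does not understate
either regime. O₂-based metabolism uses the same windows: R is the mean
dark flux taken as the around-the-clock respiration rate, NEM the
hour-weighted mean, GPP their difference. An O₂ storage correction
(inventory change below the sensor) is available and opt-in; no proton
storage correction is attempted, because vent CO₂ contaminates both pH
and O₂ inventories exactly when the correction would matter.

The community C:N ratio is the metabolism-fraction-weighted arithmetic
mean of the component ratios (e.g. epiphytes 13.7 at one third of
metabolism, seagrass 26.8 at two thirds → 22.4). Other defensible mixing
rules (carbon-weighted harmonic mixing gives ~20.3) disagree at the few
percent level, so `calcify_windows()` also accepts a direct quotient and
the worked examples use Q = 1.09 (n = 22.2) explicitly.

Vent-affected windows — geologic CO₂ enrichment masquerading as a huge
proton flux — are flagged when the CO₂-equivalent proton flux exceeds
3× the larger of the O₂-flux magnitude and a 50 mmol m⁻² d⁻¹ floor, or
when flow comes from a configured exclusion sector. The rule is explicit
and configurable; the field practice it formalizes was expert judgment,
so the defaults are an operationalization, not a claim of equivalence.
Flagged windows stay in the output but leave the aggregation.

## Error propagation

`gnet_error_curve()` quantifies how measurement errors corrupt the
inversion: generate exact forward fluxes at a true state, ratio
$r = G_{net}/P_{net}$ and quotient, then re-invert them as a biased
observer would. For a quotient error the observer simply divides the O₂
flux by the wrong Q. For an alkalinity error both proton-yield ratios are
evaluated at the offset alkalinity. For a pH error the pathway needs a
decision, because a biased pH sensor corrupts three things at once: the
measured proton flux (an offset δ scales the whole [H⁺] series, hence the
flux, by $10^{-\delta}$), the $dH^+/dDIC$ used to predict the metabolic
proton sink, and the CaCO₃ conversion ratio. Perturbing everything at
once largely cancels — the numerator and denominator biases offset —
and hides the divergence this analysis exists to expose, while perturbing
only the ratios ignores that the flux itself is measured through the same
biased sensor. The implemented pathway propagates the bias through the
measured flux and the metabolic-sink ratio and keeps the stoichiometric
conversion at its reference value, because its own bias enters $G_{net}$
as a ratio-independent scale factor rather than contributing to the
divergence at small $r$. This choice reproduces the expected behaviour —
roughly 10% error per 0.01 pH at $r = 0.2$, tens of percent for a 10%
quotient error at $r = 0.5$, errors growing as $1/r$ — and is the
package's own reconstruction of an error analysis whose exact published
procedure is not available; treat the absolute percentages as
pathway-dependent.

Properties enforced by the suite: zero perturbation inverts exactly;
small ±δ give near-antisymmetric errors; |error| grows monotonically as
$r$ shrinks; the $1/r$ asymptote holds (exactly for Q, at small $r$ for
pH, where the sensor-scale floor term becomes negligible).

## The synthetic deployment generator

`simulate_deployment()` realizes the study conditions as raw sensor
files with known truth: 16 Hz velocities with a 2–10 cm s⁻¹ slowly
rotating mean flow and ~0.6 cm s⁻¹ vertical turbulence (filtered Gaussian
noise with a low-frequency plateau rolling off as f^(−5/3) in power above
0.05 Hz); 5 Hz O₂ and pH channels whose fluctuations ride on the true
vertical velocity with per-sample covariance targets set by a square-wave
diel forcing — net photosynthesis +150 (light) / −60 (dark) mmol C
m⁻² d⁻¹, net calcification +30 / −15 mmol CaCO₃ m⁻² d⁻¹, Q = 1.09 —
passed through the carbonate forward model at At 2650 µmol kg⁻¹,
pH 8.04, 25 °C, S 38. Those magnitudes sit inside the ranges the method
targets in the field (daytime O₂ production up to ~250, nighttime uptake
60–150 mmol m⁻² d⁻¹; ecosystem CO₂-equivalent proton fluxes around
±100). Vent events add DIC at constant alkalinity (a 65 µmol kg⁻¹
intrusion depresses pH by ~0.1) plus a spurious covariant proton flux,
and are labelled in the truth record. Artifacts applied last: a 5°
instrument pitch, a 1.4 s pH intake lag, an optional first-order response
filter specified by its 90% response time (t₉₀ = τ ln 10), the 1-minute
pump gap every 30 minutes, and band-limited sensor noise (0.3 µmol kg⁻¹
O₂; 0.05 nmol kg⁻¹ H⁺, i.e. a few thousandths of a pH unit).

The scalar mixing ratio is set from the realized full-record velocity
variance, so the long-run covariance delivers the target flux while
individual windows scatter with the natural sampling error of turbulent
covariances; the truth record carries both the prescribed targets and the
realized correlated-component covariance per window. Everything is
deterministic under the scenario seed, down to the output bytes.

What the generator does **not** emulate: real inertial-subrange
intermittency and anisotropy, wave orbital contamination, canopy
wave-attenuation and transit-time dispersion, internal-wave thermal
stratification, biofouling drift, and O₂ optode response dynamics.
Passing the recovery tests therefore demonstrates that the estimator
chain is unbiased and correctly error-propagated under realistic
signal-to-noise, not that any particular field dataset would be
recovered.

## Problem sizes and runtime choices

The test suite exercises desk-scale chemistry everywhere, 10-hour
single-scalar turbulence records for flux recovery (20 windows of 29
usable minutes at 5 Hz), and one full 24-hour deployment (16 Hz
velocities, 5 Hz scalars, 48 windows) for end-to-end NEC recovery; the
command-line round trip runs a 3-hour null deployment. These sizes give
the statistical power the assertions need — e.g. the daily-NEC recovery
criterion is |error| ≤ the propagated s.e., which for the quadrature
convention is a ~2σ bound on the estimator — while keeping the whole
suite around half a minute.

## Known limitations

* The inversion attributes the entire non-metabolic proton flux to
  calcification; time-varying anaerobic processes, nitrification or DNRA
  are not modelled (their proton yields are documented to be minor in the
  target environments, but nothing in the code checks that for you).
* Proton storage below the sensor is not corrected.
* The published sensitivity percentages depend on the perturbation
  pathway (see above); comparisons across implementations should compare
  curves, not single points.
* The carbonate constants are surface values; below ~20 m the pressure
  corrections should be added before trusting the ratios.
* The vent flag is a screening rule, not a source model: windows with
  moderate geologic CO₂ below the threshold pass through and bias
  $G_{net}$ toward apparent calcification.
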