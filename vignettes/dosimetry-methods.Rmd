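---
title: "Methods: organ-level dosimetry from surrogate PET kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organ-level dosimetry from surrogate PET kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdose)
```

## The problem and the model

Targeted radionuclide therapy delivers dose systemically through a
tumor-avid carrier labelled with a beta emitter such as ¹⁷⁷Lu.  Because the
therapy nuclide images poorly, dosimetry is commonly estimated with a
chemically matched PET surrogate (here ⁸⁶Y on the same chelator): the
surrogate's region-of-interest kinetics, decay-corrected to injection, are
taken as the shared *biological* kinetics of the compound, and the therapy
nuclide's physical decay is imposed on them.

`mirdose` implements the organ-level MIRD schema on top of that
transposition.  For each source organ the measured concentration
$c_{src}(t)$ (%IA/g, percent injected activity per gram) is extrapolated to
whole-organ activity on a reference phantom,

$$\%IA_{src}(t) = c_{src}(t)\, m_{src},$$

non-delineated tissue receives a mass-proportional share of the remaining
whole-body activity, the therapeutic decay constant
$\lambda = \ln 2/T_{1/2}$ is applied,

$$A_{src}(t) = \%IA_{src}(t)\, e^{-\lambda t},$$

the cumulated activity per unit injected activity is the piecewise time
integral

$$\tilde A_{src} = \frac{1}{100}\int_0^\infty A_{src}(t)\,dt
\quad [\mathrm{MBq\,h\,/\,MBq}],$$

and the absorbed dose per injected activity in each target is the S-value
convolution over all sources, including the target itself:

$$\tilde D_{target} = \sum_{src} \tilde A_{src}\, S(target \leftarrow src)
\quad [\mathrm{Gy/MBq}].$$

Schedule totals are plain linear sums, fraction by fraction
($\mathrm{Gy} = \mathrm{Gy/MBq} \times \mathrm{MBq}$); no dose-rate,
repair or BED/EQD2 modelling is attempted, matching how fractionated-arm
dose totals are conventionally tabulated.

## Unit and convention contracts

* Time is hours everywhere; time zero is injection.  File readers refuse a
  time column not named `time_h`, so a day/hour mix-up is a hard error
  rather than a silent 24-fold dose error.
* Concentrations are %IA/g; whole-organ activity is %IA; cumulated activity
  is MBq·h per MBq injected; S-values must declare `Gy_per_MBq_h`.  The
  dose engine checks the label before convolving.
* Every time–activity table carries an explicit decay-correction flag.
  Whether ROI data were decay-corrected to injection is often left unstated
  in study reports; the reader defaults to "corrected" (the standard for
  PET workflows) and the flag is configurable.  Curves that are not
  corrected are refused by the whole-organ stage until the measured
  nuclide's decay is removed (`transpose_isotope(..., reverse = TRUE)`).
* The organ vocabulary is open but canonicalised (`"Bone Marrow"` →
  `marrow`); unknown names pass through flagged as custom sources.
  `whole_body` is reserved for the residual-allocation stage.

## Residual-body allocation

The mass-fraction rule assigns non-delineated organs
$\%IA_{src}(t) = \%IA_{WB}(t)\, m_{src}/m_{body}$.  Applied literally
(`allocation_mode = "strict_paper"`), this double-counts activity: the
delineated organs' share is never removed from the whole body.  The default
conserving mode therefore allocates only the deficit,

$$\%IA_{src}(t) = \bigl[\%IA_{WB}(t) - \textstyle\sum_{delin}\%IA(t)\bigr]
\frac{m_{src}}{m_{body} - \sum_{delin} m},$$

and emits a `remainder` pseudo-organ for the carcass mass not covered by
any listed organ.  With the remainder included, the source set satisfies
exact activity conservation at every sampled time — a property the test
suite checks directly.  If delineated activity exceeds the whole body
(inconsistent ROI data), the default is a hard error; `clamp = TRUE` clamps
the residual to zero with a warning.  Bone marrow, which is not
image-delineated, receives its activity through this allocation using the
phantom's marrow mass; since how marrow uptake was quantified in the
motivating study is not stated, marrow dose coefficients from this package
are structural estimates, not reproductions.

Curves sampled on different grids are first resampled to the union of
sampled times by linear interpolation (constant extension outside the
range): the simplest monotone scheme, adequate for smooth 4-point curves.

## Integration: head, body, tail

Cumulated activity is assembled piecewise.

* **Head** $[0, t_1]$: constant back-extrapolation at the first measured
  value (default).  Blood and tumor are typically near peak at a 4-h first
  sample, so a linear-from-zero ramp (`head_model = "linear_zero"`, offered
  as an option) would systematically underestimate.
* **Body** $[t_1, t_{last}]$: trapezoid rule on the decayed curve.  At
  sparse sampling the trapezoid is simple and conservative; the suite
  verifies convergence to closed forms as the grid densifies (steps 8, 4,
  2, 1 h).
* **Tail** $[t_{last}, \infty)$: by default `physical_decay` — biological
  retention is assumed constant after the last sample, so the tail is
  $A(t_{last})/\lambda$.  This is the conservative standard when terminal
  kinetics are unresolved.  `fitted_terminal` instead fits a
  monoexponential to the last samples (≥ 2, configurable) and uses
  $A(t_{last})/\lambda_{eff}$; `none` truncates.

Exponential fits use Levenberg–Marquardt least squares on the original
scale with a deterministic initialisation: the slowest rate is seeded by
log-linear regression through the last two points, its amplitude by
back-extrapolation, and (for two terms) the fast component from the residual
of the first point at 8× the slow rate.  The same data always produce the
same fit; noiseless data from the model class are recovered to numerical
precision (checked in the suite).  Rates are bounded positive; the reported
half-life is $\ln 2$ over the *slowest* fitted rate (the terminal
component).

## The toy S-value generator

Published rodent S-value tables come from Monte Carlo transport on
standardised mouse models and are consumed by `read_svalues()` when
available.  So the pipeline is exercisable without external kernels,
`generate_svalues()` builds an analytic matrix from energy bookkeeping:
each decay emits $\Delta$ MeV; a fraction $\phi$ (`self_fraction`) deposits
in the source organ and a fraction `cross_fraction` leaks, shared over the
other organs mass-weighted (equivalently, a uniform dose to the rest of the
listed tissue):

$$S(self \leftarrow self) = k\,\Delta\,\phi/m, \qquad
k = 1.602\times10^{-10}\ \mathrm{Gy\,g\,/\,MeV} \times 3.6\times10^{9}\
\mathrm{decays/(MBq\,h)}.$$

For ¹⁷⁷Lu ($\Delta = 0.1473$ MeV of locally absorbed emission per decay)
in a 1 g organ with $\phi = 1$ this gives 0.0850 Gy/(MBq·h).  $\phi = 1$,
`cross_fraction = 0` is the default: the beta range (< 1 mm) is small
compared to the organs of interest, so cross-organ beta dose is minimal;
reduce $\phi$ for millimetre-scale structures.  Photon and bremsstrahlung
contributions are folded into the single cross-fraction knob rather than
modelled.  The generator conserves energy by construction
($\sum_{t} S(t \leftarrow s)\, m_t = k \Delta (\phi + cross)$), which the
suite asserts on random instances.  No claim of agreement with any
transport-derived S-value table is made, and consequently absolute Gy/MBq
coefficients produced with toy kernels are structural, not reference,
values.

## The synthetic cohort generator

`generate_cohort()` emulates a longitudinal small-animal PET study: per
organ a noise-free kinetic curve, sampled at 4/24/48/72 h by default, with
multiplicative lognormal noise (mean 1) per observation and optionally a
per-animal amplitude factor (inter-animal variation in uptake level, not in
rates — the simplest structure consistent with summary-level mean ± SD
reporting).  All curves are sums of exponentials, so every biological and
decayed integral has a closed form that the generator emits as ground
truth; the suite checks numerical integration against those oracles to
0.1%.

The two presets encode the published summary kinetics of the
alkylphosphocholine agent in syngeneic TNBC grafts: sustained tumor
accretion peaking at 12.9 (4T07) or 11.0 (4T1) %IA/g at the last imaging
time; hepatobiliary clearance with liver peaks at 24 h of 9.3 / 11.3 %IA/g
then gradual decline; blood clearance with a 20.4 h half-life; all other
normal organs below 6 %IA/g at every sampled time.  Between-sample shapes
are modelling choices, not reported facts: peak amplitudes and times are
anchored to the printed values, while washout half-lives (48 h liver,
300 h tumor decline, 60 h whole-body biological elimination) and the blood
intercept (15 %IA/g at injection) were fixed once as kinetically plausible
for a phospholipid-analog radiotracer.  The default observation CV of 0.12
matches the printed mean-to-SD ratios (roughly 6–17%).  Seeds are
mandatory, and identical seed + spec gives a bit-identical cohort.

What passing tests on these cohorts show is that the *pipeline* recovers
what it assumes: generator and fitting share the exponential model family.
They do not show robustness to real-data features the generator omits —
partial-volume spill-in/spill-out, positron-range blur, ROI delineation
error, non-exponential redistribution, or correlated inter-organ noise.

## Problem sizes and numerical choices

The suite runs property checks on randomly generated instances of up to 6
organs, convergence ladders at 8/4/2/1 h steps, and cohort recoveries at
n = 100–1000 animals with 4 time points — a few seconds in total.  The
acceptance script regenerates a 1000-animal blood cohort (5% CV) for the
half-life recovery, a 100-animal 4T07 cohort for peak calibration, and the
noise-free 4T1 liver value; each quantity is recomputed from scratch at run
time from the given seed.  Uniroot tolerance for peak-time inversion is
1e-14; rate lower bounds 1e-9/h; conservation checks use a relative 1e-9
guard before declaring violation.

## Known limitations

* Organ-level only: no voxel or sub-organ dosimetry, no microdosimetry for
  sub-millimetre metastases (where mean-range arguments break down).
* No compartmental PK modelling; kinetics are empirical exponentials.
* Marrow dose depends entirely on the mass-allocation assumption (above).
* The toy S-matrix neglects organ adjacency: every non-self target receives
  the same leaked dose per decay regardless of geometry.
* Schedule totals assume dose linearity and no inter-fraction repair.
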