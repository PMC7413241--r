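# mirdose

Organ-level internal dosimetry for preclinical targeted radionuclide
therapy, following the MIRD schema.

`mirdose` is for researchers estimating absorbed doses of a therapeutic
radiopharmaceutical (e.g. a ¹⁷⁷Lu-labelled tumor-targeting agent) from the
kinetics of a chemically matched PET imaging surrogate (e.g. the same
vector labelled with ⁸⁶Y).  It takes organ time–activity curves — percent
injected activity per gram (%IA/g) versus hours post-injection, the
standard output of small-animal PET ROI analysis or ex vivo
biodistribution — and carries them through the full dosimetry chain:

1. **whole-organ activity** — %IA/g × organ mass on a reference mouse
   phantom;
2. **residual-body allocation** — activity not in delineated organs is
   distributed over the remaining tissues in proportion to their masses
   (with exact activity conservation by default);
3. **isotope transposition** — the decay-corrected surrogate kinetics are
   treated as the biological kinetics and the therapy nuclide's physical
   decay e^(−λt) is imposed;
4. **cumulated activity** — piecewise time integral Ã (MBq·h per MBq
   injected): constant head segment, trapezoid body, physical-decay tail
   A(t_last)/λ by default;
5. **absorbed dose** — the MIRD convolution
   D̃(target) = Σ_src Ã_src · S(target←src), in Gy/MBq;
6. **treatment planning** — schedule totals (Gy, linear over fractions)
   and tumor-to-organ dose ratios.

It also ships an exponential clearance fitter (deterministic
Levenberg–Marquardt, terminal half-life reporting), an analytic toy
S-value generator for exercising the chain without Monte Carlo kernels, a
radiochemical-purity helper for chromatogram peak areas, and a calibrated
synthetic cohort generator that emulates a longitudinal imaging study
(tumor peak 12.9 %IA/g, liver peak 9.3–11.3 %IA/g at 24 h, blood clearance
half-life 20.4 h, configurable lognormal noise) so every stage is testable
with no external data.

## Worked example

```r
library(mirdose)

# a 5-animal synthetic 4T07 cohort imaged at 4/24/48/72 h
coh <- generate_cohort(cohort_preset("4T07"), n = 5, seed = 42)

ph     <- mouse_phantom()
masses <- c(tumor = 0.4)                      # ~400 mm^3 graft
sv <- generate_svalues(ph, lu177(),
        extra_masses_g = c(masses, remainder = remainder_mass(ph, masses)))

report <- estimate_dosimetry(coh$tac, ph, sv)
report
#> <dose_report> nuclide Lu-177, tail physical_decay, head constant
#>       target gy_per_mbq
#> 1      blood       0.52
#> 3      liver       1.18
#> 13     tumor       2.26
#> 14 remainder       0.41
#> ...

schedule_dose(report, schedule(c(18.5, 9.25), c(0, 240)), target = "tumor")
#> <schedule_dose> coefficient 2.26 Gy/MBq
#>   fractions: 41.8 + 20.9 Gy
#>   total: 62.7 Gy

round(dose_ratio(report, "tumor", "liver"), 1)
#> [1] 1.9

fit_exponential(cohort_mean(coh$tac[coh$tac$organ == "blood", ]))
#> <exp_fit> 1-term exponential; terminal half-life 21.6 h (RSS 0.0515)
```

Reading: the tumor receives 2.26 Gy per MBq injected — the highest dose of
any target, 1.9× the liver's (the clearance organ) — so an 18.5 + 9.25 MBq
fractionated course delivers 62.7 Gy to the tumor.  The fitted blood
half-life (21.6 h here) recovers the generating 20.4 h within the cohort's
noise.  Coefficients computed with the *toy* S-value generator are
structural illustrations; for reference dosimetry supply a Monte
Carlo-derived S-matrix via `read_svalues()`.

File-based workflows use the same functions (`read_tac()`,
`read_phantom()`, `read_svalues()`; examples under `inst/extdata/`, all
synthetic), or the thin command-line front end:

```sh
Rscript inst/exec/mirdose simulate --model 4T07 --n 5 --seed 1 --out tac.csv
Rscript inst/exec/mirdose dose --tac tac.csv --schedule 18.5@0,9.25@240
```

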