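# xrftir

Hybrid elemental and molecular characterisation of thin tissue sections in
R: **reference-free X-ray fluorescence (XRF) quantification** with per-pixel
thickness correction, **FTIR amide-band secondary-structure analysis**, and
the **non-parametric group statistics** used to compare tissue conditions —
plus a synthetic-data generator that validates the whole chain by parameter
recovery.

The package is aimed at analysts working with synchrotron micro-XRF maps
and FTIR hyperspectral data of biological sections (here: murine pancreatic
tissue — healthy pancreas, untreated tumours, and tumours after 2 Gy or
6 Gy radiotherapy) who need absolute, standard-free elemental
concentrations next to protein secondary-structure ratios.

## What it computes

**Reference-free XRF.** For each fluorescence line *i*, the fitted count
rate *N<sub>i</sub>* is converted to a mass concentration (mg/cm³) from
first principles:

    C_i = 4π N_i / ( d · Φ0 · ε(E_i) · Ω · sin(θ_in) · γ_i · g_i · τ_i(E0) · A(d) )

with photon flux Φ0, detector efficiency ε, solid angle Ω, fluorescence
yield γ, transition probability g, K-shell photoionization cross section
τ(E0), and the self-absorption factor
A(d) = (1 − e^(−(μ₀+μᵢ)ρd/sinθ)) / ((μ₀+μᵢ)ρd/sinθ). No calibration
standards enter: everything comes from calibrated instrumentation and
bundled fundamental-parameter tables. The local section thickness *d* is
recovered per pixel from the Lambert–Beer attenuation of the substrate
Si Kα line against a bare-substrate reference,
d = −ln(I/I₀)·sinθ / ((μ_s(E0)+μ_s(E_Si))·ρ). Spectra are deconvolved with
a Gaussian detector-response model (FWHM² = noise² + 2.355²·F·w·E) and a
polynomial background by Poisson-weighted linear least squares.

**FTIR.** Baseline-corrected spectra are decomposed over the amide window
into pseudo-Voigt components at the canonical secondary-structure positions
(β-sheet 1630/1690, random 1650, α-helix 1660, β-turn 1678 cm⁻¹, fitted
jointly with the amide II band), and group areas are reported relative to
the integrated amide II band at 1540 cm⁻¹. Ensembles are aggregated as
arithmetic mean ± standard deviation per ratio.

**Statistics.** Conditions are compared with the two-sided
Mann–Whitney–Wilcoxon test (exact for small tie-free samples, tie- and
continuity-corrected normal approximation otherwise), annotated
`ns` / `*` / `**` / `***` / `****` at the 5e-2 … 1e-4 thresholds.

## Worked example

```r
library(xrftir)

calib  <- defaultCalibration()     # 5 keV, 1e10 ph/s, SDD response model
tissue <- defaultTissueMatrix()    # dried-tissue matrix, 1.35 g/cm^3

## simulate an untreated-tumour map and quantify it from the spectra alone
truth <- simulateMap(conditionProfile("PC"), nx = 12, ny = 12, seed = 42)
fwd   <- forwardXrf(truth, calib, tissue, dwell = 5, seed = 43)
map   <- quantifyMap(fwd$spectra, fwd$substrate, calib, tissue, nx = 12, ny = 12)
mapSummary(map)
#>   quantity    unit median   csu  mean   sd   n
#> 1     C(P) mg/cm^3  29.29 6.247 28.96 4.20 144
#> 2     C(S) mg/cm^3  23.49 5.011 22.93 3.22 144
#> 3    C(Cl) mg/cm^3  13.09 2.792 12.93 1.98 144
#> 4     C(K) mg/cm^3  45.69 9.746 46.37 7.40 144
#> 5        d      um   1.15 0.245  1.18 0.19 144
```

The medians land on the generator's ground truth (P 28.9, S 22.9, Cl 12.9,
K 46.3 mg/cm³; thickness 1.15 µm) to within the counting noise; the `csu`
column is dominated by the systematic fundamental-parameter budget, which
no amount of averaging removes.

```r
## FTIR: healthy-pancreas ensemble, fitted and aggregated
hp <- fitAmideEnsemble(simulateFtir("HP", n = 200, seed = 7))
hp$stats
#>           ratio  mean      sd   n
#> 1        beta_s 0.851 0.02307 200
#> 2         alpha 0.281 0.01016 200
#> 3        random 0.130 0.00669 200
#> 4        beta_t 0.161 0.00658 200
#> 5 amide_I_total 1.423 0.03008 200
```

Healthy tissue shows the high β-sheet / low α-helix signature and an
amide I/II total near 1.42, against 1.92 for the untreated tumour profile.

```r
## are the sulfur and potassium distributions different between conditions?
hpMap <- quantifyMap(forwardXrf(simulateMap(conditionProfile("HP"), 12, 12, seed = 44),
                                calib, tissue, seed = 45)$spectra,
                     fwd$substrate, calib, tissue, nx = 12, ny = 12)
compareConditions(list(PC = map, HP = hpMap), reference = "PC",
                  elements = c("S", "K"))
#>   element group_a group_b n_a n_b     U        p annotation method
#> 1       S      PC      HP 144 144 20512 1.01e-46       **** normal
#> 2       K      PC      HP 144 144 20149 1.46e-43       **** normal
```

A ready-made orchestration (`runPipeline()`) runs simulation,
quantification, FTIR fitting and statistics from one YAML/list config and
writes the report tables plus a provenance manifest; a thin shell wrapper
lives at `inst/scripts/xrftir-pipeline.R`. The methods vignette
(`vignettes/hybrid-tissue-characterisation.Rmd`) documents the models,
defaults and design choices.

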