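# cortimech

Coupled fluid–structure modelling of organ-of-Corti micromechanics in an
excised-cochlea microchamber, with the OCT-vibrometry analysis chain and the
sweep-based inference of tectorial-membrane and Deiters-cell stiffness
ratios.

## The scientific problem

The organ of Corti (OoC) must be stiff enough to turn transepithelial fluid
pressure into hair-bundle deflection, yet compliant enough to be deformed by
outer-hair-cell (OHC) motility. Two stiffness ratios organize this
trade-off:

- `r_TM = k_TM / k_HB` — the tectorial membrane's radial attachment
  stiffness relative to the hair-bundle deflection stiffness. With the two
  springs in series, `k_TM Δ_TM ≈ k_HB Δ_HB`, so the measurable deformation
  ratio `Δ_TM/Δ_HB` falls as `1/r_TM`.
- `r_DC = k_DC / k_OHC` — the Deiters-cell axial stiffness relative to the
  OHC soma, which sets the stiffness the actuator feels,
  `k_OoC,OHC = f_OHC/Δ_OHC − k_OHC`.

Neither ratio is directly measurable *in situ*; both are inferred by
sweeping a model parameter until the simulated deformation ratio matches the
measured one. `cortimech` is for researchers in cochlear mechanics who want
that full chain in one place: anatomy-based radial sections with
longitudinally graded properties, planar-frame + longitudinal-coupling
structural assembly (`M ẍ + C ẋ + K x = f_FLD`), an incompressible-fluid
chamber model (`∇²p = 0`, `A_pp p + A_pa a = b`) condensed onto the
structure (`M_EFF = M + A_ap A_pp⁻¹ A_pa`, `f_EFF = A_ap A_pp⁻¹ b`),
frequency-domain solves, and the measurement-side operators (subpixel NCC
displacement estimation, two-angle decomposition
`[d_r d_t]ᵀ = [sinθ₁ cosθ₁; sinθ₂ cosθ₂]⁻¹ [d₁ d₂]ᵀ`, elliptical-motion
summaries, volume compliance, contact stiffness, deformation ratios).

## Worked example

```r
library(cortimech)

model <- build_model(x = 8.5, span_mm = 0.2)
model$section
#> ooc_section at x = 8.50 mm: 23 nodes (13 BM / 6 TM / 5 OoC), 29 elements, BM width 299.0 um

fld  <- solve_static(model$system, dP = 5.6)   # one 5.6 Pa pressure step
prof <- bm_profile(fld, model$system)
vc   <- volume_compliance(prof)
c(vc$peak_nm_per_pa, vc$volume_mm4_per_n, fwhm_fraction(prof)$fraction,
  contact_stiffness(model$system))
#> peak compliance: 117 nm/Pa
#> volume compliance: 21.7 mm^4/N
#> FWHM fraction (static): 0.65
#> contact stiffness: 64 mN/m

stiffness_ratios(model$section)[c("k_tm", "k_hb", "k_ohc", "k_dc")]
#> k_TM 32.8, k_HB 4.9, k_OHC 4.3, k_DC 28.4 mN/m per section
```

The peak displacement per unit pressure (117 nm/Pa) is the mid-turn
compliance of the preparation; the volume compliance is the displaced BM
area per unit pressure; the contact stiffness is what a point probe at the
peak-displacement node (the first-row Deiters root) would report. A
stiffness-ratio inference then looks like:

```r
sw  <- sweep_ratio("rdc", grid = log_grid(0.1, 10, 9), freq_hz = 1000)
infer_ratio(sw, measured = 0.89, sd = 0.21)   # measured Delta_DC/Delta_OHC
```

which rebuilds the model nine times with only the Deiters-cell modulus
rescaled, solves the coupled response at 1 kHz, and interpolates the
deformation-ratio curve in log–log space at the measured value.

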