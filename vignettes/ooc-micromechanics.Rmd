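---
title: "Modelling organ-of-Corti micromechanics in an excised-cochlea chamber"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling organ-of-Corti micromechanics in an excised-cochlea chamber}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

An excised gerbil cochlear turn mounted over the slit of a two-compartment
microfluidic chamber separates two fluid spaces with the organ of Corti
(OoC). Pressurizing one compartment statically deforms the basilar membrane
(BM); driving it acoustically vibrates the whole complex. Optical coherence
tomography (OCT) resolves the motion of individual structures - the
tectorial membrane (TM), reticular lamina (RL), outer hair cells (OHC) and
Deiters cells (DC). Two stiffness ratios organize the micromechanics:

* `r_TM = k_TM / k_HB` - the TM's radial attachment stiffness relative to
  the hair-bundle deflection stiffness. The TM and the bundle are springs in
  series, so their deformation ratio `Delta_TM / Delta_HB` falls inversely
  with `r_TM`.
* `r_DC = k_DC / k_OHC` - the Deiters-cell axial stiffness relative to the
  OHC soma. It sets how rigidly the actuator is held, hence how OHC force
  partitions between the BM and the RL.

`cortimech` implements a coupled fluid-structure finite-element model of
the chamber preparation, the measurement-side analysis chain, and the
model-sweep procedure that converts measured deformation ratios into these
stiffness ratios.

# Structural model

## Radial section

A section carries 23 nodes: 12 along the BM chord plus the spiral-lamina /
limbus support (the clamped attachment shared by the BM and TM groups,
giving the canonical 13 BM / 6 TM / 5 OoC tag counts), 5 further TM nodes
(root-body junction, three bundle attachments, lateral end), and 5 OoC
nodes (pillar head, three OHC apices on the RL, and the first-row OHC-DC
cup). Geometry derives from 14 anatomic landmarks; the default set is a
mean anatomy whose radial positions scale with the interpolated BM width
and whose heights scale with the interpolated OHC length. At the two
most-measured positions the measured mean widths are used (299 um at
x = 8.5 mm, 274 um at x = 7.5 mm).

Material properties are anchored at x = 10 mm and x = 2 mm and vary
exponentially in between, `p(x) = p_b * exp(s (x - x_b))` with
`s = (log p_b - log p_a) / (x_b - x_a)`; the log-linear form is exact at
both anchors and monotone between them.

Elements are planar frames (axial + Euler-Bernoulli bending). Each node has
four DOF: radial, transverse, longitudinal and the in-plane rotation. The
longitudinal DOF is what makes the OHC / phalangeal-process Y-truss
three-dimensional: the OHC axis tilts one cell spacing basally while the
phalangeal process (axial stiffness about 150-200 x k_OHC at default
modulus) reaches the RL three sections apically. Collapsing this truss into
the plane would let the stiff process short-circuit the OHC force couple;
with the longitudinal DOF the two members share load only through genuine
3-D kinematics, which is essential for the stiffness an actuating OHC
feels. Within the 23-node budget only the measured first row carries an
articulated cup; rows 2-3 are series-equivalent single elements.

Hair bundles are direct-stiffness links (the table gives a stiffness, not a
modulus): the deflection stiffness `k_HB` acts against radial and
longitudinal shear of the subtectorial gap, and a 50 x stiffer spring
represents the near-inextensible stereocilia axis supporting the TM
vertically. The three stiffnesses are axis-aligned with no cross terms, as
for a pivoting bundle; a tilted rigid-rod link would leak the large axial
support force into the radial balance and mask the deflection compliance.

Longitudinal continuity of the BM, TM and RL uses membrane (axial) springs
on the longitudinal DOF and curvature-penalty node triplets
(`EI/h^3 [1, -2, 1]`, the exact finite-difference form of Euler-Bernoulli
bending) on the transverse DOF. Apical and basal end sections are fully
clamped, as are the BM edges and the limbus, matching the observed
clamped-edge deforming pattern.

## Damping

Four physically distinct mechanisms are represented:

* Rayleigh damping `alpha M + beta K`, with the coefficients calibrated so
  the first-row OHC and DC elements dissipate 5 nN s/m per 10 um of cell
  length (solved for the two elements; a negative coefficient is clipped
  and the other refit, which in practice yields mass-proportional damping).
* Subtectorial-gap dashpots across each bundle: Couette shear
  (100 nN s/m per section total, consistent with mu A / h for the ~8 um
  gap) on the in-plane-of-gap components, and squeeze-film damping on the
  gap-normal component, 30 x larger (lubrication theory scales it by
  (overlap width / gap height)^2, moderated by the open lateral boundary).
* TM gel viscoelasticity as stiffness-proportional damping on TM elements
  (`beta_tm = 5e-5 s`, i.e. a loss factor ~0.3 at 1 kHz, the order reported
  for TM material loss).
* A Stokes boundary-layer drag on tangential motion of the immersed TM
  faces, `sqrt(mu rho omega/2)` per unit area evaluated at 1 kHz - the
  inviscid interface model otherwise carries no tangential traction.

# Fluid model

The incompressible, inviscid chamber fluid satisfies the Laplace equation
with a prescribed input pressure (stimulus port), zero-pressure release and
open-to-air boundaries, rigid walls, and interface conditions
`dp/dn = -rho a` on the membrane faces. A finite-volume mesh covers the two
compartments of a radial-transverse plane section of the chamber: the slit
spans the BM width, the cells match the structural tributaries at the slit
and grow geometrically into the far field.

The plane choice deserves a note. The measured corner frequency (~1 kHz)
together with the static compliance implies a fluid added mass of order
rho x (BM width): the inertia is dominated by the near field within a few
hundred micrometres of the membrane, which the radial-plane model captures.
A longitudinal-plane channel model would force all displaced fluid along
the 10 mm channels and overestimate the added mass several-fold.

The planar mesh is extruded into a slab of one slice per structural section
(longitudinal conductances between slices, rigid end walls). This matters:
with longitudinally uncoupled slices every overtone of the clamped span
carries the full two-dimensional added mass and the overtone ladder
compresses into the measurement band; with the slab, short-wavelength modes
shed added mass and the response is the clean second-order resonator that
is observed.

Substituting the pressure solution into the structural equations gives the
effective system `M_EFF = M + A_ap App^-1 A_pa`, `f_EFF = A_ap App^-1 b`;
`App` is factorized once per model. Frequency-domain solves use the
equivalent real 2x2 block form of the complex system with symmetric Jacobi
scaling (rotational stiffnesses sit many orders below translational ones).
Rotational DOFs carry no lumped inertia (quasi-static rotations, standard
lumped-mass practice); a tiny floor keeps the mass matrix positive
definite.

# Measurement-side analysis

* `ncc_shift` / `ncc_displacement`: normalized cross-correlation with
  upsampled-DFT (global) or parabolic (windowed) subpixel refinement.
  Flat windows are flagged invalid rather than failing.
* `decompose_two_angle`: the exact 2x2 solve of the two-beam projection
  system. Angles are measured from the transverse axis, positive toward
  the lateral radial direction - one convention everywhere.
* `ellipse_major_axis`: the trajectory of a complex 2-D motion vector is an
  ellipse; the major axis is obtained analytically as the dominant
  eigenvector of `Re(d d^H)` (the brute-force time-sampled maximization is
  kept as the test oracle). Circular or zero motion has no defined
  direction and is flagged, with the angle reported as 0.
* `volume_compliance` / `fwhm_fraction`: trapezoid area between deformed
  and undeformed BM per unit pressure; half-maximum span by linear
  interpolation around the peak (the region containing the peak is used,
  and flagged, if several disjoint regions exist).
* `deformation_ratio_tm`: `Delta_TM` is the radial displacement of the TM
  point above the second-row bundle relative to the bone-fixed limbal
  attachment - exactly what the two-angle measurement reports. The
  end-to-end stretch along the attachment chord (insensitive to rigid TM
  rotation) is returned alongside as `ratio_elong`; it isolates true
  elongation and is the quantity used for rigid-limit checks.
* `deformation_ratio_dc`: axial length changes apex-joint and joint-root of
  the first row, on the 3-D element axes.
* `stiffness_felt_by_ohc`: a self-equilibrated force couple along the OHC
  axis, statically solved; `k_OoC,OHC = f_OHC / Delta_OHC - k_OHC`.
  A scaffold stiffer than `10^3 k_OHC` is reported as rigid (infinite).

# Sweeps and inference

`sweep_ratio` rescales exactly one property set per grid value - TM moduli
for `r_TM`, DC modulus for `r_DC`, phalangeal-process or RL modulus, or a
damping multiplier - rebuilds the model and solves at the stated frequency
(1 kHz at x = 8.5 mm, 2 kHz at x = 7.5 mm). Stiffness ratios are defined
operationally: `k_HB` directly from the table; `k_TM` as the series
stiffness of the limbus-to-second-bundle chain with each segment projected
on the radial axis (at the measured modulus this reproduces the reported
9-12 mN/m per 10 um section); `k_OHC`, `k_DC`, `k_PhP` as axial `EA/L`;
`k_RL` as the cantilever tip stiffness `3EI/L^3`. `infer_ratio`
interpolates the sweep curve in log-log space at the measured value and at
measured +/- SD, restricted to the longest monotone branch (the asymptotic
ends flatten where leakage terms take over). Only the measurement SD is
propagated.

# Synthetic data

`generate_speckle_pair` builds band-limited Gaussian speckle with an exact
Fourier-domain subpixel shift plus sensor noise (default SD 5% of unit
image SD - a conservative OCT B-scan noise floor); `generate_scan` projects
true complex in-plane motion onto two beam directions (default -30 and 13
degrees, the worked-example pair) and adds isotropic complex Gaussian noise
of relative magnitude 10%, the reported displacement-estimation error;
`generate_landmarks` jitters the mean anatomy with a 12 um per-coordinate
SD so the BM width scatter matches the measured 299 +/- 12 um. All
generators are pure functions of their parameters and seed. They emulate
the statistical structure the analysis assumes - they do not emulate OCT
image formation (coherence gating, shadowing, signal-dependent speckle
noise), so passing tests validate the analysis chain, not the imaging
physics.

# Problem sizes and numerical choices

The default model spans 0.2 mm (21 sections at 10 um spacing, ~1900 DOF,
~11800 fluid cells), which keeps a full stiffness-ratio sweep to a few
minutes on one CPU; the span is far longer than the ~10 um longitudinal
decay length of a point load on the fluid-loaded BM, so mid-span results
are insensitive to the clamped ends (halving the spacing changes the peak
static displacement by under 2%). The corner frequency is defined
operationally as the -3 dB point relative to the low-frequency asymptote,
taken at the first downward crossing at or above the response peak; the
high-frequency slope is fitted over the top octave; the phase accumulation
is the principal-value endpoint difference, which is robust to the
antiresonance-resonance excursions of internal modes. Dynamic comparisons
use the model after its static volume compliance has been calibrated to
the measured value, mirroring the study design; the calibration scales the
BM fiber-layer modulus by a single factor found by root-finding.

# Known limitations

* In this geometry the TM span between the limbal attachment and the
  measured point above the second-row bundle carries the summed radial
  force of all three bundle rows, so matching a given measured
  deformation ratio requires a stiffer TM than the single-bundle
  series-spring picture implies: the inferred `r_TM` sits roughly a
  factor ~2 above a series-model estimate. Conversely, for `r_TM` below
  ~1 the TM's radial inertia exceeds its attachment stiffness at the
  1 kHz stimulus and the deformation ratio saturates (the floating-mass
  regime), flattening the log-log curve at the soft end; the clean
  inverse-first-power regime holds for `r_TM` above ~1.
* The model's higher BM/TM modes and their preceding antiresonance fall
  inside the top octave of the measurement band, so a slope fitted at
  2.5-5 kHz is dominated by that notch and reads far from the clean
  second-order rolloff observed between the corner and ~2.5 kHz
  (itself close to -12 dB/octave).
* The static grid-convergence rate is limited by the TM's longitudinal
  coupling terms, whose decay length is comparable to the default
  10 um spacing; halving the grid moves the static peak by 2-3%
  (under 0.2% with those terms disabled).
* Only the first OHC row is articulated with a cup and phalangeal process;
  rows 2-3 are series-equivalent members.
* The chamber dimensions are plausible defaults, not measured values; the
  hydrophone-normalized response is exposed but the exaggerated
  structure-radiated pressure of a plane model makes the port-normalized
  response the better-behaved observable.
* Tissue density is uniform (1000 kg/m^3); viscous fluid effects enter
  only through the explicit damping terms above, not the pressure field.
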