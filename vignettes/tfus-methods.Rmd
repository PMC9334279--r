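---
title: "Models and methods: pulsed transcranial ultrasound simulation and tracer quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tfusim)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the parameters that matter, and the numerical and
design choices made where more than one defensible option existed. The
companion test suite computes every empirical statement made here; nothing
below reports a number the tests or the acceptance script do not themselves
produce.

## Pulsed sonication algebra

A pulsed exposure is a sinusoidal carrier at the fundamental frequency
(200 kHz throughout the motivating application), gated on for one pulse
duration (PD) at the pulse repetition frequency (PRF). The duty cycle
DC = PD × PRF is the active fraction; pulses must not overlap
(PD × PRF ≤ 1), with equality the continuous-wave limit. Intensities follow
the standard exposure metrics: the pulse-average intensity I_SPPA describes
the "on" intensity, the temporal-average I_SPTA = I_SPPA × DC the delivered
power. Holding I_SPTA constant while sweeping DC therefore scales I_SPPA as
1/DC — the algebra behind the constant-0.5 W/cm² exposure series that
`sonication_table()` reproduces.

Pressure–intensity conversion uses the travelling plane-wave relation
P_r = √(2 ρ c I) with I in W/m². Two conventions circulate in this
literature — peak-rarefactional (P_r) and peak-to-peak (P = 2 P_r in the
linear regime) — and conflating them is a silent factor-of-four error in
intensity. Every conversion function therefore takes an explicit
`convention` argument, defaulting to peak-rarefactional. The default water
constants (ρ = 997 kg/m³, c = 1494 m/s) are those of a 24 °C degassed bath;
with them, 5 W/cm² pulse-average corresponds to ~386 kPa peak-rarefactional.

## Bowl transducer and the free-field reference

The source is an ideal uniformly vibrating spherical cap (aperture 28 mm,
radius of curvature 22 mm — the only geometry a single-element bowl needs).
No apodization is modelled: nothing finer is known about the physical
element. `freefield_pressure()` evaluates the Rayleigh–Sommerfeld summation
over a spiral, equal-area discretization of the cap (patch size at most
λ/8 by default), treating each patch as a baffled simple source. The
independent oracle in the tests is a 1D ring quadrature of the same
integral — a different discretization of the radiating surface, which is
what makes the comparison meaningful.

Two conventions deserve note:

* **Exit plane.** Focal distances are quoted from the plane through the bowl
  rim (apex + cap depth, here ~5.0 mm), not the apex. With that convention
  the ideal cap's axial pressure maximum lands ~11 mm beyond the exit
  plane — well short of the 22 mm geometric centre of curvature, the normal
  focal shift of a low-gain (ka ≈ 12) focused source.
* **Focus sizing.** The −6 dB focus is the full width at half-maximum
  pressure (FWHM); the tighter FW90%M is the full width at 90% of maximum
  pressure. `profile_width()` interpolates linearly between samples at the
  level crossings and flags profiles that never cross the level (plateau
  into the boundary) as unbounded rather than guessing.

## Skull model: CT calibration and property mapping

Micro-CT volumes are calibrated so the mean over a water reference region is
exactly 0 HU (`calibrate_hu()`, an idempotent affine shift), then resampled
by separable trilinear interpolation to the simulation spacing
(`resample_isotropic()`, default 0.25 mm = 30 voxels per 7.5 mm wavelength).

Acoustic properties come from the pseudo-porosity mapping on
φ = 1 − HU/HU_max: density and sound speed interpolate linearly between
water/soft-tissue and cortical-bone endpoints (monotone in HU), attenuation
interpolates as α_min + φ^β (α_max − α_min), peaking in porous trabecular
bone where scattering dominates. The endpoint constants are **not**
universal — they vary across scanners and calibration protocols — so all of
them are exposed in `property_mapping()`; the defaults (ρ_bone
2100 kg/m³, c_bone 2800 m/s, bone attenuation 23–70 Np/m at 200 kHz,
β = 0.5) are mid-range literature values and are documented as stand-ins,
not measurements. Voxels are labelled water/soft, brain or skull; the
brain/water distinction is topological (soft tissue not connected to the
volume boundary is interior, hence brain), which needs no anatomical prior.

## Acoustic FDTD solver

`run_fdtd()` integrates the first-order linear acoustics equations on a
staggered grid: velocity on cell faces, pressure at centres, face
coefficients averaged between neighbours. Choices that matter:

* **Attenuation** is an exponential loss on the velocity update with rate
  γ = 2 α c, which reproduces e^(−αx) plane-wave decay exactly at a single
  frequency — the regime of a harmonic steady-state solver. The 1D
  Beer–Lambert test holds this to 2%.
* **Boundaries** are an exponential-damping sponge of one wavelength
  (quadratic ramp, σ_max = 8 c / thickness). Measured normal-incidence
  reflection is a few tenths of a percent; the verification tests that need
  better use three wavelengths. The output field is zeroed inside the
  sponge margin so downstream metrics cannot read absorbed regions.
* **Stability.** The automatic time step takes 80% of the CFL bound
  dx/(√nd · c_max) and snaps to an integer number of steps per carrier
  period. The margin below the textbook bound is deliberate: the lossy
  sponge shrinks the stability region of the leapfrog scheme, and Courant
  numbers above ~0.9 ring up at the layer edge. A user-supplied step that
  violates the bound is refused, not clamped.
* **Source injection.** Bowl patches become additive monopole injections at
  their nearest voxels with volume velocity 2 u0 A per patch — the factor 2
  makes a free-space monopole equivalent to the baffled simple source of
  the Rayleigh reference. Each patch carries a phase correction for its
  sub-voxel snap (referenced to the geometric focus), and the drive ramps
  on over two periods with a cosine taper to limit startup transients.
* **Steady state** is declared when the per-period focal peak changes by
  less than 0.5% between consecutive periods (after a floor of two domain
  transits); one further full period is then recorded as the per-voxel
  peak-to-peak map. Reverberant cavities ring up slowly, so the phantom
  runs raise the floor to 80 periods.

Intensity maps apply the local plane-wave relation
I_SPPA = (P_pp/2)²/(2 ρ c) per voxel — an approximation inside standing-wave
regions, where "intensity" is used in the exposure-metric sense rather than
as time-averaged energy flux. I_SPTA multiplies by the duty cycle, and the
relative map normalizes to the global maximum.

The free-field check compares the FDTD focal pressure against the Rayleigh
oracle at the same voxel (3% tolerance at 0.5 mm = λ/15 resolution). The
domain must be wide enough that the converging cone of a 28 mm aperture
clears the sponge; clipped runs lose focal amplitude and the effect is
easily mistaken for solver error.

## The transcranial phantom configuration

`phantom_domain()` reproduces the sonication arrangement of the in-vivo
exposure: the beam travels along the shortest (height) axis of the skull,
entering through the cap, with the geometric focus 1 mm below the outer
skull surface — the targeting depth from the top of the head. The phantom
itself (`make_phantom_ct()`) is an ellipsoidal bone shell, outer semi-axes
8 × 10 × 7 mm with a 0.9 mm wall, enclosing a ~14 × 18 × 12 mm soft
interior: rat scale, i.e. within about two wavelengths at 200 kHz, which is
precisely the regime where cavity reverberation matters. Air outside the
shell is replaced by coupling water in the simulation domain, as for an
immersed ex-vivo skull or a gel-coupled head.

In this configuration the converged field shows the pattern the package's
acceptance test asserts: the strongest intensity at the skull surface facing
the transducer (standing wave between incident and reflected waves), a
mid-cavity maximum at least as intense as the geometric focus (the focus
sits just inside the proximal wall where shell interference suppresses it,
while reflections off the concave far wall reinforce mid-cavity), and
labelled maxima i–iv from `find_local_maxima()`. The classifier is
geometric: iv is a maximum within 1.5 voxels of bone on the incident side of
the cavity midpoint; iii the mirror case in brain; ii a brain maximum clear
of bone (≥2 voxels) within the middle half of the cavity along the beam; i
is always reported at the geometric focal point itself, whether or not it is
a distinct local maximum. The prominence floor (25% of the global maximum)
and the 2 mm minimum separation are configuration values, since the
published precedent identifies these maxima visually.

## Pennes bioheat solver

`solve_bioheat()` integrates ρ c_t ∂T/∂t = ∇·(k∇T) + q − w_b c_b (T − T_a)
explicitly with harmonic-mean face conductivities (exact for layered media)
and either fixed-temperature or insulated outer boundaries. Tissue constants
default to: brain specific heat 3600 J/kg/K and conductivity 0.528 W/K/m;
skull 1300 J/kg/K and 0.4 W/K/m; blood perfusion 8.24 kg/m³/s with density
1030 kg/m³ and specific heat 3620 J/kg/K; arterial and initial temperature
37.5 °C. Brain and skull densities (1040 and 1900 kg/m³) are standard values
supplied by the package, configurable like everything else. Perfusion
applies to brain voxels only by default. CSF pulsation and thermoregulation
are deliberately not modelled, which biases the temperature estimate
conservatively upward.

The acoustic heat source is q = 2 α I. Two modes exist: **duty-averaged**
(q = 2 α I_SPTA, constant — the default for 30-minute runs, stable at steps
of ~1 s on a 1 mm grid) and **pulse-resolved** (q = 2 α I_SPPA gated by the
binary envelope, 0.5 ms steps). Both deposit identical energy per pulse
period and agree on slow thermal scales, which a test verifies; the system
is linear, so the averaged mode is exact for any observable slower than the
PRF. The explicit diffusion stability bound ρ c dx²/(6k) is enforced, never
silently adjusted.

The most result-sensitive free constant in the whole thermal chain is the
**brain absorption at 200 kHz**, which the source literature does not state.
The default, 0.25 Np/m (≈0.022 dB/cm), follows from quadratic-in-frequency
scaling of soft-tissue attenuation near 0.55 dB/cm/MHz; halving or doubling
it scales peak ΔT proportionally (the solver is linear in q). It is a named
argument everywhere it enters.

Verification stacks three independent closed forms: the lumped perfusion ODE
(uniform heating: ΔT_ss = q/(w_b c_b), τ = ρc/(w_b c_b) ≈ 125 s for brain,
t₉₅ = 3τ); the time-dependent Green's-function convolution for an isotropic
Gaussian source in an unbounded medium, ΔT(0,t) = (q₀σ²/k)(1 − σ/√(σ²+2κt)),
whose t→∞ limit is the textbook q₀σ²/k; and the screened (perfused) steady
form with the perfusion length √(k/(w_b c_b)) ≈ 4.2 mm. The transient form
is compared at 300 s — long enough to be discriminating, short enough that
heat has not reached the domain boundary, where the infinite-medium form
stops being the right oracle.

The thermal-safety headline of the acceptance script — the in-vivo heating
configuration (Gaussian source, σ = 2.1 mm, in-situ focal I_SPTA
0.65 W/cm², 30 min) — is run on a 40 mm cube at 0.5 mm / 0.1 s resolution;
the test suite uses the 1 mm grid, which a refinement test pins to the finer
result within 2%.

## Image quantification

**Foam scans.** Dye is darker than foam on a flatbed scan, so segmentation
keeps pixels at or below the fixed threshold of 150 (the polarity is a
configuration switch, since scanner conventions differ), takes the largest
connected component, and measures the maximal Feret extent (front view,
"inlet diameter") or the maximal extent along the sonication axis (section
view, "depth"), counting pixel footprints (max − min + 1). An empty mask
yields zero with a warning rather than an error, since unsonicated controls
legitimately show no dye.

**Fluorescence sections.** Each tracer channel is min–max normalized to
0–255; the background is the minimum normalized intensity inside the brain
mask, floored at 1 grey level so the multiplicative threshold cannot
degenerate at an exact zero; uptake is the percent of brain-mask pixels
above 170% of that background. The measure is invariant to affine intensity
rescaling by construction. An external brain mask is preferred; the
automatic fallback (Otsu threshold, with a second-pass re-threshold when
bright deposits dominate the first split, then hole filling and largest
component) approximates manual masking guided by background fluorescence
but is documented as a heuristic.

**Statistics.** `group_stats()` wraps the standard one-way ANOVA and Tukey
HSD machinery (`aov`, `TukeyHSD`) behind tidy accessors, and `paired_t()`
the two-sided paired t test. A Monte-Carlo test calibrates the Tukey
family-wise error under the null at 0.05 ± 0.01 over 10⁴ simulated triples
of n = 6 groups — the package's guard against wiring errors between the
pipeline and the inference step.

## What the synthetic generators do and do not emulate

The generators are first-class, seeded, and ship ground truth, because every
quantitative claim in the test suite needs a known answer. They emulate:
CT geometry, HU contrast, calibration offsets and scanner noise (phantom);
background fluorescence, peri-ventricular tracer placement, target uptake
fractions exact to the pixel at zero noise (sections); dye geometry and foam
texture (scans). They do not emulate: anatomical skull shape (ellipsoid, no
sutures or thickness gradients), trabecular microstructure, vascular or
perivascular geometry, section-to-section registration error, or
non-Gaussian scanner artefacts. Passing tests therefore demonstrate that the
pipelines are correct and well-calibrated on data with known structure — not
that real-data estimates inherit the same error bars.

For the same reason, three headline quantities of the motivating study are
declared out of desk-scale reach (`reproducibility_notes()`): in-vivo uptake
percentages (raw animal sections not deposited), the in-situ intensity table
from real skulls (ex-vivo CTs not deposited), and wet-lab infiltration
distances. The package reproduces their *structure* — the pipelines,
orderings and bounds — and is explicit about the substitution.

## Problem sizes and numerical defaults used by the shipped tests

Free-field FDTD verification runs on a 45 × 50 × 50 mm water box at 0.5 mm
(λ/15); the transcranial phantom on ~59 × 50 × 50 mm at 0.5 mm with an
80-period convergence floor; 1D verification at λ/30 with a 3λ sponge;
thermal runs on 30–40 mm cubes at 0.5–1 mm. These sizes are chosen as the
coarsest grids at which each check's tolerance is comfortably met by the
convergence data above; all scale up by changing one argument.

## Known limitations

Linear acoustics only: no cavitation, no nonlinear propagation, no shear
waves in bone (a real simplification for oblique bone incidence). Single
carrier frequency; no broadband pulses. The intensity maps inside
reverberant regions are exposure-metric conventions, not energy flux. The
HU→property mapping constants are stand-ins wherever a study's own
calibration is unavailable. The bowl is ideal; a physical element's
effective aperture and apodization will move the focal geometry within the
~30% envelope the tests allow. Acoustic streaming itself — the fluid
mechanics linking these fields to solute transport — is outside scope.
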