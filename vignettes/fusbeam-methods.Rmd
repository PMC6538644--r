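---
title: "Simulating transcranial focused ultrasound with fusbeam: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating transcranial focused ultrasound with fusbeam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fusbeam` simulates transcranial focused ultrasound (FUS) delivered by a
1024-element hemispherical phased array (30 cm aperture, 15 cm radius of
curvature, 680 kHz) and reproduces the MR-thermometry-side analysis used to
validate such simulations against treatments of essential tremor. This
vignette is the package's own account of the science: the models, the
parameters that matter, the numerical choices, and what the synthetic
phantoms do and do not establish about real data.

## From CT to acoustic properties

Every skull voxel receives acoustic properties from its Hounsfield unit (HU)
value. The package's curves are parametric and live in a `property_set`, so
alternative literature relationships can be dropped in without touching the
solver:

* **Bone fraction / porosity.** `bone_fraction(HU) = clip(HU / HU_bone, 0, 1)`
  with `HU_bone = 2000` for pure cortical bone; porosity is the complement.
  A single, patient-independent porosity curve is used: with a consistent CT
  acquisition protocol this gives a one-to-one HU-to-property relationship
  and keeps results repeatable across subjects.
* **Density.** A linear mixture between water (1000 kg/m³) and cortical bone
  (`rho_bone = 1920` kg/m³) in bone fraction. The 1920/2000 pair describes
  cortical bone rather than pure hydroxyapatite; the shipped `"vyas"`
  comparison set keeps the hydroxyapatite-referenced constants
  (3000 kg/m³, 3115 HU).
* **Velocity.** Linear in bone fraction from 1500 m/s (water/soft tissue) to
  `c_max = 2800` m/s at 2000 HU. The `scale` argument rescales only the bone
  maximum, producing the ±10 % sensitivity pair 2520/3080 m/s used to bound
  the effect of velocity-curve uncertainty on simulated heating.
* **Attenuation.** Inside bone,
  `alpha = alpha_cortical + (alpha_plateau − alpha_cortical) · sqrt(porosity)`
  Np/cm at 680 kHz, scaled linearly with frequency. The study plateau is
  2.136 Np/cm (trabecular bone); the Vyas comparison set plateaus at
  3.625 Np/cm; `"constant:<v>"` sets give flat skull attenuation for
  sensitivity experiments. `alpha_cortical` defaults to 0.9 Np/cm and the
  soft-tissue baseline to 0.04 Np/cm at 680 kHz; both are configurable, and
  the curve parameters are deliberately exposed because skull attenuation is
  the least certain quantity in this field and dominates absolute heating.

A design point worth stating explicitly: `map_attenuation()` is the
*bone-material* curve over the whole HU line — continuous, attaining its
trabecular plateau at maximal porosity (HU ≤ 0). Tissue-class assignment is
the volume builder's job: `build_property_volumes()` gives water/soft-tissue
values to every voxel at or below its `soft_hu_max` threshold (default 0).
Applying class masks at volume level rather than hiding them inside the
curve keeps each curve evaluable everywhere (useful for plotting and for the
sensitivity sets) and mirrors how masked HU-property curves are used in
practice.

**Skull density ratio (SDR).** HU is sampled along each element-to-focus
segment at 0.25 mm steps; samples above 300 HU count as skull; the per-line
min/max ratio is averaged over elements. Sampling is nearest-neighbour by
default: any sub-voxel interpolation sweeps through all partial-volume
values at the skull surface, so the line minimum would collapse to the bone
threshold and even a perfectly homogeneous skull could not score an SDR of
1. Nearest sampling preserves the defining property that a homogeneous
shell scores exactly 1 and a 900/1800 HU sandwich scores 0.5.

## Array model and plate decomposition

The element layout of the clinical array is proprietary, so elements are
placed by a deterministic Fibonacci spiral on the spherical cap —
quasi-uniform, equal-area, and adequate for focal-zone physics, which is
governed by the aperture envelope rather than the exact packing. Element
areas tile the cap to within 1 %.

The angular spectrum method propagates planes perpendicular to one axis, so
the cap is split into seven plates: a polar axis plus six axes at 40°
inclination and 60° azimuthal spacing (configurable). Each element joins the
plate whose axis best aligns with its direction. Each plate's source plane
is computed by summing the free-field Rayleigh–Sommerfeld kernel over all
element patches (elements subdivided at ≤ λ/4) with the sonication's element
phases and amplitudes applied; planes are then scaled by one common factor
so the summed plane flux `∑ |p|²/(2ρc) dA` equals the applied acoustic
power. Pressure is stored as peak (not RMS) complex amplitude.

Plane placement: beyond the skull's extent along the plate axis (2 mm
clearance) and behind the plate's elements where the marching length
allows. For a skull that surrounds the focus, the most grazing elements of
the oblique plates can end up in front of their plane; their contribution
is then only approximate and the count of such elements is reported in the
result metadata. This is an accepted fidelity limit of plate-based HAS at
desk scale, not silently ignored.

## Hybrid angular spectrum propagation

Each marching step across a slab of thickness `dz` is split-step:

1. spatial domain: `exp(i k₀ (n − 1) dz − α dz)` per pixel, with
   `n = c_water / c(x, y)` and `α` in Np/mm;
2. 2-D FFT; multiply by the diffraction factor
   `exp(i dz (√(k̄² − kx² − ky²) − k̄)) · exp(i k₀ dz)` where `k̄` is the
   wavenumber at the slab's arithmetic-mean speed (configurable to the water
   speed); evanescent components (`kx² + ky² > k̄²`) decay through the
   imaginary axial wavenumber and are never amplified;
3. inverse FFT.

The working plane is zero-padded by 25 % per side (water in the pad ring) to
suppress periodic wraparound, and padding is carried across the whole march
rather than re-cropped each step. Per-plate volumes are fused onto the
focus-centred target grid by complex trilinear resampling and summed.
Forward-only marching is used; reflections and standing waves are not
modelled, and neither are nonlinearity nor shear-mode conversion — the
method solves the linear scalar wave problem at steady state.

Verification anchors (all in the test suite): free-field marching agrees
with direct Rayleigh–Sommerfeld integration on axis to ~10⁻⁵ relative;
uniform slabs advance plane waves with exact `exp(−α d)` decay and
`k₀ n d` phase; lossless marching conserves spectral axial flux to < 2 %;
halving `dz` moves the reference-phantom peak pressure by < 2 %.

## Grids and problem sizes

The default ("desk") configuration marches 128 × 128 × 192 planes at λ/3 in
water (0.735 mm) per plate and fuses onto a 96³ focus-centred grid — chosen
as the smallest grid that resolves the ~1.5 mm focal spot, keeps the full
skull cap of the reference phantom inside the marching cone of every plate,
and lets a full 1024-element, 7-plate sonication solve in tens of seconds
on one CPU. The clinical full-resolution grid (1097 × 1097 × 1201 voxels at
0.365 × 0.365 × 0.200 mm) is available as the `"paper-grid"` preset for
production use. The pipeline tests use a further reduced 256-element,
96 × 96 × 128 configuration: every physical mechanism is exercised, only the
angular sampling of the aperture is coarser.

## Bioheat integration

Temperature rise follows the Pennes equation,
`ρC ∂T/∂t = κ∇²T − ρ_b C_b ρ ω (T − T_b) + α P²/(ρc)`,
integrated explicitly with a 7-point Laplacian on a subgrid cropped around
the focus (default ± 40 mm, ± 25 mm in the tests; heating is negligible
elsewhere). The source term uses α in Np/m — the Np/cm-to-SI conversion is
centralised and unit-tested. Perfusion `ω` is stored in ml/kg/min and
converted by 10⁻⁶/60 to m³/(kg·s); the perfusion term is implemented
literally as `ρ_b C_b ρ ω (T − T_b)`.

Defaults are common brain values: κ = 0.51 W/m/°C, C = 3600 J/kg/°C,
ω = 559 ml/kg/min, ρ_b = 1050 kg/m³, C_b = 3617 J/kg/°C, T_b = 37 °C.
Uniform brain coefficients are used over the cropped focal region by
default — the focal volume in this application is thalamic tissue, and skull
heating is not analysed. The solver refuses steps above the explicit
stability bound `dt ≤ 0.9 (ρC/κ) / (2 Σ 1/Δx²)` and defaults to half the
bound. Temperature-dependent property changes (the late-treatment roll-off
regime) are deliberately not modelled; the analysis side instead *excludes*
roll-off sonications, as described below.

MR frames are the instantaneous temperature-rise fields at the frame-centre
times — no k-space temporal averaging is simulated. The default protocol
places three frames at 1.75/5.25/8.75 s (3.5 s frame period, acquisition
starting with the ultrasound) with 10 s on-time, making timepoint 3 the
latest frame with ultrasound on; the frame period is configuration, and
nothing in the analysis depends on its exact value.

## Thermometry-matched analysis

Simulated volumes are reduced to thermometry geometry by block averaging
(clinically 3× frequency-encode, 6× phase-encode, 15 slices through-plane:
768 × 768 × 15 → 256 × 128) followed by a ×2 phase-axis upsample to
256 × 256 — the underlying resolution is unchanged, which is why position
errors are still quoted at 1.094 × 2.188 mm pixel sizes. The focal spot is
the hottest pixel of the timepoint-3 image (ties break to the lowest
row-major index); temperature rises at all three timepoints are read at
that one position; treatment efficiency TrEff = peak ΔT(tp3) / power, and a
treatment's effective TrEff is the mean of its two largest non-alignment
values. Noise SD is measured in a regular-octagon annulus (40 × 40 outer
box, thickness 10) around the focal spot — the octagon is inscribed in the
box with pixel-centre membership, the natural reading of an "octagonal
frame" of stated dimensions.

A sonication enters the calibration comparison iff it is within 3 noise SDs
of the effective-TrEff line, is not the first of the treatment, is not an
alignment shot, and its phase encoding is not superior–inferior. The
per-treatment *averaged* noise SD is used in the 3-SD rule (the per-frame
variant is available to callers by passing a different value). Calibration
is a robust linear regression of measured on simulated rise: Huber IRLS
with tuning constant 1.345 — the standard default among robust estimators;
the estimator sits behind `robust_regression()` and can be swapped.
Confidence intervals and the slope p-value come from the fit's asymptotic
covariance with t quantiles at n − 2 df; exactly collinear inputs fall back
to OLS with zero-width intervals rather than letting the IRLS scale
estimate degenerate.

Phase-to-temperature conversion uses the proton-resonance-frequency
coefficient −0.00909 ppm/°C at the given TE and B0; referenceless
correction fits and subtracts a constant-plus-linear phase surface over a
user-supplied background mask (≥ 50 pixels, hotspot excluded).

## Synthetic data: what it emulates, and what it does not

The phantom is a spherical shell with cortical–trabecular–cortical layering
(default 85 mm inner radius, 2 + 3 + 2 mm at 1800/900/1800 HU — adult-scale
geometry with a mid-range SDR of 0.5), water/brain at 0 HU elsewhere, and
an optional "temporal window": both ±direction patches of the shell thin by
a Gaussian angular profile (default 60 % thinning, 30° width), emulating
thin temporal bone. The shell is centred at the geometric focus — the
thalamic target sits near the head centre, and any centre offset large
enough to push the shell outside the transducer would be unphysical for
this array geometry. Thermometry frames are generated by converting
temperature to phase, adding a planar drift, and injecting Gaussian noise
in the *complex signal* domain, so the apparent temperature noise is TE-
and B0-dependent as in real data. Sonication logs draw peak rises around a
true TrEff line with designated roll-off outliers suppressed below it.

What passing tests on these phantoms show: the propagation, heating,
downsampling, selection and calibration machinery is internally consistent,
ranks physical effects correctly (attenuation halving, conductivity and
perfusion ranges, temporal-window smearing), and recovers constructed
truths. What they cannot show: agreement with clinical position-error or
per-patient slope statistics, which depend on real skull morphology, CT
acquisition, patient positioning and scanner noise — phantom shells carry
none of that variability. Absolute simulated temperatures also inherit the
attenuation-curve uncertainty discussed above; the calibration regression
exists precisely because absolute heating has multiplicative error.

## Numerical and implementation notes

* Hot loops (Rayleigh–Sommerfeld summation, FFT marching, trilinear
  resampling, bioheat stepping) are compiled. The projection kernel uses a
  branchless single-precision sin/cos with Cody–Waite range reduction
  (absolute error ~3 × 10⁻⁵ rad, two orders below the λ/4 patch
  discretisation error); accumulation is double precision. Complex volumes
  are stored as R double-complex — a memory, not accuracy, choice.
* All generators and solvers are deterministic given their seeds; pipeline
  runs write their configuration and seed beside their outputs and
  re-running a configuration is bit-identical.
* Degenerate inputs fail loudly: non-finite HU, unstable `dt`, aliasing
  plane spacings, empty skull-line sets, all-zero drives at positive power.
* Water-bath pipeline runs use soft-tissue absorption at the focus (water
  itself is modelled as lossless), so thermometry metrics remain defined.

## Known limitations

Forward-only propagation (no reverberation); no nonlinearity or shear-mode
conversion; grazing elements of oblique plates approximated as described;
uniform thermal coefficients over the focal subgrid; spherical-shell
phantoms rather than anatomical skulls; DICOM ingestion is not provided
(CT volumes are read from NIfTI-1 or plain arrays).
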