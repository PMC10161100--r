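---
title: "Methods: dosimetric verification in inhomogeneous phantoms"
author: "gkverify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosimetric verification in inhomogeneous phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gkverify)
```

# Scope and model

`gkverify` implements an end-to-end verification pipeline for stereotactic
radiosurgery dose calculations in the presence of bone and air
inhomogeneities: a synthetic inhomogeneous phantom and CT, an HU-to-density
calibration, two dose engines (a deterministic convolution-style kernel
engine and a stochastic "MC-lite" kernel engine), a simulated radiochromic
film measurement, dose-to-medium conversion with K_med factors, rigid
fiducial registration, a local dose-difference / distance-to-agreement gamma
index, and GUM-style uncertainty budgets.

The package verifies the *structure* of such a verification chain — density
handling, absolute normalization, registration, masking and gamma analysis —
on synthetic data. It does not contain a clinical dose engine: the vendor's
TERMA tables and point-spread kernels are proprietary, and no coupled
photon–electron transport is performed. Consequently absolute beam-on times
and the K_med values themselves are *inputs*, not predictions, and the
air-cavity electron disequilibrium that full Monte Carlo reveals is
reproduced only qualitatively (reduced dose in air). That is the declared
fidelity boundary of the package.

# The phantom and synthetic CT

The phantom is a 160 mm solid-water sphere whose five central slabs are
replaced by RW3 carrying a mirrored-C bone inset (6 cm long in z; two
lateral bars 1.5 cm thick in x and a posterior bar 1 cm thick in y), a
2 × 2 × 6 cm RW3 core centred on the unit centre point (UCP, (100, 100,
100) mm in the Leksell frame), and a 1.5 × 2 × 6 cm air cavity abutting the
core on −x. The mirrored C is modelled as three axis-aligned boxes abutting
the core/cavity assembly — the simplest shape consistent with the published
axial cross-section, which gives thicknesses and lengths but no corner
coordinates. Default CT voxels are (0.53 × 0.53 × 1) mm.

Three metal fiducial pins sit at 70 mm radius in the central axial plane at
azimuths 90°, 210° and 350°. A symmetric (equilateral) pin set would make
the three-point correspondence problem exactly degenerate — three congruent
cyclic pairings with zero residual each, 120° apart in rotation — so the
default layout is deliberately scalene; this is what real fiducial designs
do. The pins are voxelized as small spheres (radius `max(1, 1.25·max
spacing)` mm so at least one voxel survives coarse rasterization) and imaged
at a fixed 3000 HU plateau, mirroring clinical metal saturation; they sit
intentionally outside any calibration curve.

The synthetic CT inverts the calibration curve at each material's relative
electron density and adds Gaussian HU noise (default 0; the tests also use
sd 20, a typical soft-tissue noise level at 120 kVp). Ambient air outside
the sphere gives ray tracing a defined entry medium.

# Density calibration

HU map to relative electron density η by piecewise-linear interpolation of
the scanner curve; out-of-range HU **clamp** to the end values, so CT noise
cannot produce negative densities. The packaged default curve passes through
(−1000, 0.001), (0, 1.0), (1600, 1.9), approximating a 120 kVp scanner; all
worked-example tests feed η directly and are curve-independent.

Mass density follows the continuous piecewise conversion

ρ = η (η ≤ 1),  ρ = (η − 0.15)/0.85 (η > 1).

The η > 1 branch is fixed as the unique affine form that is continuous at
η = 1 and reproduces all three tabled conversions (0.993 → 0.993,
1.013 → 1.015, 1.605 → 1.7118); this verification is a mandatory unit test.
The Monte Carlo pathway can instead map HU directly to mass density via a
second set of curve breakpoints, and assigns one of five packaged
density-interval composition bins (air / lung / adipose / soft / bone); the
full 24-bin tissue segmentation is intentionally out of scope — the engines
only consume ρ.

# Machine model and absolute calibration

The source model places 192 cobalt-60 sources (8 sectors × 24) on five
latitude rings of a cone at 400 mm source–focus distance, all aimed at the
focus. Ring angles and the source–focus distance are not published and are
configurable; every package result is designed to be insensitive to them
(counts, normalizations and ratios only). Collimator parameters: field radii
2/4/8 mm for the 4/8/16 mm fields, relative output factors 0.814/0.900/1
(clinical-magnitude values; 16 mm ≡ 1 by definition), effective attenuation
μ = 0.063 cm²/g (cobalt-60 narrow-beam value in water), penumbra sigmas
0.7/0.8/1.0 mm, and per-collimator scatter amplitude/range for the
deterministic engine.

Decay correction uses T½(⁶⁰Co) = 5.2711 y. The chamber dose chain is the
plain product M·kTP·kPol·kIon·N_D,w·K_Q·K_Qmsr with the machine-specific
reference-field correction defaulting to 1.0037.

Absolute dose ties to the decay-corrected reference dose rate Ḋ_ref through
the reference configuration — a single 16 mm shot at the UCP of the
homogeneous 160 mm water sphere: the engine's relative dose there
corresponds to Ḋ_ref, so the UCP dose of the reference configuration equals
Ḋ_ref × BOT by construction (calibration closure, tested to 0.1%). The
prescription then sets the scale (max dose = prescription / isodose
fraction) and the beam-on time.

# Deterministic engine

Per-beam primary dose = output factor × inverse square × exp(−μ·d_rad) ×
error-function penumbra, where d_rad is the exact voxel-traversal
(Siddon-style) radiological path length through the density maps and the
penumbra is evaluated at the off-axis distance projected to the focal
plane. The penumbra width is scaled by the ratio of radiological to
geometric depth — the simplest reading of kernel scaling by radiological
path length. Scatter is modelled collapsed-cone-lite: the summed primary
convolved (FFT) with a normalized isotropic exponential kernel whose range
is scaled by the **mean** density of the computation region; a spatially
varying kernel range cannot be expressed as a single convolution, so the
per-voxel scaling is approximated at region level.

Numerical choices: dose grids default to 1 mm voxels over the shot bounding
box + 30 mm margin; ray tracing runs on the density maps resampled to 1 mm
isotropic (the dose-grid resolution; the periphery contributes only through
path integrals, which a 1 mm grid resolves to well under the engine's other
approximations). Beams whose projected off-axis distance exceeds the field
radius + 10 mm are skipped (profile < 1e−6).

# MC-lite engine

Histories sample a (shot, sector) category with probability
P_i = t_i·N_i / Σ t_j·N_j (t_i the sector's active time — the shot duration
weight — and N_i the phase-space particle count of its collimator), then a
source uniformly within the sector and an aim point uniformly in the focal
disc. Rays deposit exp(−μ·d_rad) × step / voxel-volume along a 0.5-voxel
marching step, with at most one scatter redirect at an exponentially
sampled radiological depth (Gaussian angular kick, sd 0.35 rad). Per-voxel
uncertainty uses the batch method: the standard error of batch means
(default 10 batches), which scales as histories^(−1/2) (tested). Absolute
scale follows the same reference-ratio construction as the deterministic
engine, with the per-history reference UCP dose computed by an independent
run of the same engine; for the reference configuration the two engines
therefore agree within statistics by construction, which is the tested
closure property. Source positions are not translated by the (few-mm) shot
offset — only the aim point moves; at 400 mm source–focus distance the
resulting direction error is below 1e−2 rad. There is no electron
transport: air-cavity disequilibrium appears only through the density term.

# Film simulation and dose-to-medium conversion

The simulated film samples the 3D dose trilinearly on the (optionally
rigidly perturbed) film plane at 0.169 mm/px, multiplies pixels by
(1 + ε), ε ~ N(0, noise fraction), and punches zero-dose holes (radius
0.5 mm) where the pins lance the film. The film is flagged dose-to-water:
a water-calibrated film inside bone or air reads D_med/K_med, so the
generator divides the sampled dose-to-medium by K_med inside the
inhomogeneity masks when a medium response is supplied. The downstream
`applyKmed()` step multiplies those regions back — the same inferential
chain applied to the physical measurement, and the package's device for
exercising it end-to-end.

K_med factors are packaged data (bone 0.941/0.946/0.946, air
0.745/0.748/0.749 for 16/8/4 mm), as determined by full Monte Carlo
transport elsewhere; the package does not re-derive them (electron
transport out of scope). Multi-field plans use the unweighted mean over
distinct field sizes, which reproduces the published averages 0.944 (bone)
and 0.747 (air) exactly at three decimals; whether that published average
was time-weighted is not stated, and unweighted is the only variant that
reproduces the printed values — a BOT-weighted mean remains available via
the `weights` argument.

# Registration

Pin centroids come from thresholding the CT (default 2000 HU) and
intensity-weighted centroids of the 6-connected components; film holes from
unweighted centroids of zero-dose 4-connected components. Both sets are
canonically ordered by angle about their centroid; the rigid fit (Kabsch
cross-covariance SVD with a determinant +1 constraint) tries all six
pairings and keeps the lowest RMS. With three points the fit is closed-form
and exact for congruent triangles. Because three fiducials are always
coplanar, a mirrored configuration is reachable by a proper rotation, so
the reflection branch of the decomposition never activates; the determinant
+1 invariant is tested directly on noisy inputs instead.

# Gamma analysis

γ(r) = min over evaluated points e of √(|r−e|²/DTA² + (D_e−D_r)²/(f·D_r)²),
f = DD%/100, with local normalization using the reference point's own dose.
Defaults: 3%/1 mm, 1 Gy cut-off, 0.1 mm resampling of the searched
distribution, search radius 3×DTA (configurable; the oracle-equivalence
tests run uncapped). The published protocol resampled the *reference*
distribution — ambiguous under the standard formalism, where the evaluated
distribution is searched — so the resampled side is a criteria flag
(`resample = "evaluated"` default, `"reference"`, `"both"`), asserting
neither choice as the original's internal one. The optimized search walks
expanding Chebyshev shells of the resampled raster around each reference
point and terminates when the purely spatial term exceeds the incumbent —
exactly equivalent to exhaustive search (tested to 1e−9 on random maps
against an independent brute-force oracle). Film/MC play reference, the
planning-system dose evaluated; passing rate is the percentage of evaluated
reference points with γ ≤ 1, reported with and without the air-cavity mask.

# End-to-end run and what it shows

`runVerification()` chains all stages with seeds derived from one master
seed, logs each stage, and emits a passing-rate table (reference source ×
with/without air mask), the applied K_med factors and the packaged
uncertainty budgets (quadrature combinations 0.9% for the calibration
chain and 2.0% for film dosimetry, displayed half-up at one decimal).
Default study conditions: CT-resolution phantom (0.53, 0.53, 1) mm, single
16 mm shot at the UCP, 4 Gy at the 50% isodose, noiseless film at
0.169 mm/px covering 150 mm (the pins must lance the film), 1 mm dose
grid over the film region, 3%/1 mm local gamma with 1 Gy cut-off. With the
K_med conversion applied the noiseless chain passes at 100% excluding air;
disabling the conversion strictly lowers the including-air rate — the
qualitative analogue of the published excluding/including-air contrast.

What passing does **not** show: agreement with a clinical convolution
algorithm or with full Monte Carlo (no proprietary kernels, no electron
transport), reproduction of published beam-on times or absolute passing
rates, film chemistry or scanner response (films are simulated directly in
dose), or CT artifacts beyond white Gaussian HU noise.

Problem sizes were chosen so the whole chain runs comfortably on one CPU:
the default end-to-end run uses the full-resolution phantom with a
161 × 161 × 31 dose grid; unit tests use coarsened phantoms (2 mm) and a
2 mm dose grid where only structure, not resolution, is under test.

# Known limitations

* The scatter model is a single isotropic exponential kernel; no angular
  discretization, no kernel tilting, no field-size-dependent spectra.
* MC-lite is photon-ray energy deposition; K_med physics (electron
  disequilibrium in cavities) is consumed as data, never predicted.
* The five-bin composition table is a deliberate simplification; engines
  use ρ only.
* DICOM is not written; grids use MetaImage (single-file `.mha`) with JSON
  sidecars, film uses 16-bit TIFF + JSON, plans and phantom specs YAML.
* The registration model is rigid; film curl or scanner distortion are out
  of scope.
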