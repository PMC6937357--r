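---
title: "petiq: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petiq: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Whole-body FDG PET at European dose levels is a low-count measurement:
weight-based activities (quadratic rule with a 120 MBq floor), 1–2.5 minutes
per bed position, and an axial field of view short enough that a whole-body
scan is a chain of overlapping bed positions. Under these conditions the
choice of reconstruction — early-stopped OSEM (with or without resolution
modelling) versus penalized-likelihood reconstruction run to convergence —
changes small-lesion recovery, background noise, and the visibility of
"noise bands" where bed positions overlap. `petiq` builds a fully synthetic,
seeded version of that measurement chain so these effects can be studied,
regression-tested and taught without scanner access.

# The acquisition model

**Geometry.** Acquisition and reconstruction are slice-wise 2D: each axial
slice is projected with a parallel-beam system over angles in [0°, 180°).
Oblique 3D lines of response and time-of-flight are deliberately out of
scope; the studied quantities (per-slice ROI statistics, recovery of
spheres several voxels wide) are driven by in-plane sampling, counts, and
the axial sensitivity profile, all of which are retained.

**Projector.** The system matrix uses Joseph's method (bilinear
interpolation along the ray's major axis), built once per geometry by a
small Rcpp routine and cached as a sparse `Matrix`. Entries are intersection
lengths in mm, so `A·x` is a line integral of concentration (kBq/ml·mm). An
independent fine-step ray-marching integrator in the test suite bounds the
projector's error at ≤ 1% on partial-volume rasterized disks (binary
hard-edge images are intentionally not used as oracle inputs — at clinical
voxel sizes Joseph's single sample per column is only ~2% accurate against
a discontinuity, and the rasterizer never produces one).

**Physics.** Lines of response are attenuated by `exp(-∫μ dl)` with
water-equivalent μ = 0.096 cm⁻¹ at 511 keV and a lung insert at 0.3×water
(polystyrene-bead surrogate). Detector resolution is a radial Gaussian blur
in projection space (default FWHM 5 mm, the scanner class's intrinsic
resolution). Scatter and randoms are assumed perfectly corrected: only
trues are simulated. Decay of F-18 (T½ = 109.77 min) is integrated in
closed form over each bed's scan window, with beds scanned sequentially.

**Axial sensitivity and beds.** A bed has 47 slices (157 mm axial FOV) with
a triangular sensitivity profile that reaches zero exactly one slice
outside each FOV edge — so for 47 slices the edge slice sits at 1/24 of
peak, and two beds overlapping by 11 slices sum to a *constant* 50% of peak
across the whole overlap, reproducing the published overlap-sensitivity
arithmetic exactly. Scaled-down geometries used in tests keep the same
invariant by choosing `(overlap+1)/(slices+1) = 1/4`.

**Counting.** Expected counts are
`calibration × effective seconds × slice sensitivity × blurred, attenuated
line integral`; counts are Poisson draws under a mandatory seed. The
calibration constant (default **0.01 counts per kBq/ml·mm·s**) is the one
deliberately free constant of the simulator: it was chosen once so that the
OSEM+PSF background COV at 1 min/bed lands near 25%, the regime in which
the published COV curves and overlap noise bands live, and was not revisited
afterwards. Shorter acquisitions are obtained by binomial thinning of a
stored long acquisition (`thin_acquisition`), which reproduces the exact
Poisson law of a direct short scan — the software analogue of list-mode
retro-reconstruction.

# Phantoms

The NEMA NU2 IQ phantom uses the standard six sphere sizes (10–37 mm inner
diameter; shell walls ignored) on the conventional 57.2 mm ring around the
50 mm cold lung cylinder. The body outline is a 300 × 230 mm rounded
rectangle (corner radius 77 mm); since every reported metric is a contrast
or ratio *within* the phantom, the exact outline constants are not
load-bearing. The micro hollow-sphere phantom has 4/5/6/8 mm spheres placed
equiradially (90° apart, ring radius 20 mm — chosen so spheres never
overlap; no standard value exists) around the extra central 10 mm sphere,
at the same axial plane. Fill concentrations per contrast case are the
printed ones (10/1, 6.5/1.6, 4.8/2.6 kBq/ml). Patient-like objects are
ellipse-sectioned bodies per bed (legs 140 × 100 mm, torso 300 × 200 mm)
with uniform muscle background (SUV ≈ 0.8 of the administered
activity/weight) and spherical lesions.

Rasterization supersamples each voxel (`supersample³` points), so
compartment boundaries carry exact sub-voxel volume fractions; rasterized
sphere volumes converge to the analytic `4/3·π·r³` and the 37 mm sphere is
within 1% at `supersample = 4`. Labels (background / lung / sphere_i /
outside) use a majority rule and partition the grid; a thin boundary ring
of partial-volume voxels outside the majority surface carries the remaining
activity fraction, which is physically intended.

# Reconstruction

**OSEM.** Standard multiplicative updates over angle subsets with the
matched projector; the per-slice axial sensitivity enters through the
subset normalization. Defaults mirror the clinical protocol: 2 iterations,
24 subsets, 6.4 mm Gaussian post-filter and `[1:4:1]` axial weighted
smoothing (interpreted as post hoc; whether the scanner applies it within
iterations is not documented). `OSEM_PSF` includes the acquisition's radial
blur in the projector; plain `OSEM` does not.

**BSREM with the relative difference penalty.** The penalty

$$U(f) = \beta \sum_j \sum_{k \in N_j} w_{jk}
   \frac{(f_j - f_k)^2}{f_j + f_k + \gamma |f_j - f_k| + \varepsilon}$$

uses inverse-distance weights over the in-plane 8-neighbourhood (plus axial
neighbours for 3D arrays), γ = 2 (the value established for this
penalty family) and ε = 10⁻⁹. The optimizer is block-iterative ascent
on the penalized Poisson log-likelihood with the diminishing relaxation
λ_n = 1/(1 + n/10), run to a relative objective change < 10⁻⁵ (cap 200
passes) instead of a vendor-style iteration heuristic. Persistent objective
decrease (5 consecutive passes) raises an error with the trace attached.

One numerical choice deserves emphasis: the textbook BSREM preconditioner
x/S overshoots badly at large β in a desk-scale, low-count simulator
(subset sensitivities are O(1), so penalty gradients can exceed the
likelihood curvature and drive the image into the nonnegativity wall). The
update therefore divides the gradient by `S/x + β·c/M`, where `c` is the
separable curvature majorizer of the RDP (2w/s per neighbour pair,
evaluated at the current image). At β = 0 this is *exactly* the block-EM
update — the required first-iteration identity with OSEM holds to 10⁻¹⁰ —
and for β > 0 it is a diagonally-majorized ascent step that stays monotone
across the calibrated β range. A multiplicative trust region (per-update
change clipped to [0.1×, 10×], active only when β > 0) remains as a
backstop.

**β analogues.** The vendor's unit-less β (450/550/700) does not transfer
to this simulator. `calibrate_beta` defines the **high-β analogue**
operationally as the β whose BPL background COV matches OSEM+PSF on the
same 1 min/bed data — the published empirical anchor for β = 700 — by
log-space bisection; the mid and low analogues keep the vendor's ratios
(×550/700, ×450/700). Experiments report both the raw β and the analogue
label.

**Stitching.** Overlap slices combine per-bed reconstructions with
sensitivity weights `(s₁v₁ + s₂v₂)/(s₁ + s₂)` — the minimum-variance convex
combination when slice noise scales like 1/sensitivity. This predicts
overlap-slice COV of √2 × bed-centre COV under the default triangle, which
is the mechanism behind the noise bands.

# Metrics

All SDs are sample (n−1). The 50%-isocontour VOI is
`T = background + 0.5·(local max − background)` inside a box of 1.5× the
sphere diameter around the known centre; the VOI is the 6-connected
component containing the maximum, with ties included (≥). A sphere whose
local maximum does not exceed the background is reported at background
level and flagged invisible — mirroring the published boldface convention.
Background ROIs follow the NU2 convention (12 positions × 5 slices, ROI
diameter per sphere size) but are *placed algorithmically*: greedy
farthest-point selection among candidate centres that clear the spheres,
lung and boundary — deterministic, and robust to scaled-down geometries.
The lung ROI is a 30 mm circle, the customary NU2 choice. COV profiles use a large background mask on the sphere plane
with an 8 mm erosion margin, excluding spheres and lung; the patient
analogue excludes labelled lesions. The noise–counts law is fitted as
`log COV = log a + b log N`; pure Poisson statistics give b = −1/2.

# What the synthetic world does and does not establish

The generator's defaults *are* the published study conditions (geometry,
fills, scan times, dose rule, cohort constraints).
What it cannot reproduce is scanner-absolute numbers: no TOF, no
detector-block physics, no scatter/randoms residuals, 2D rather than fully
3D sampling, and a count calibration chosen rather than measured. A green
trend test therefore establishes *orderings and scalings* — RC growing with
diameter and with penalized convergence, COV falling with time and with β,
lung error lower for BPL, overlap-edge noise exceeding bed centres — not
agreement with the published absolute recovery or lung-error values, which
the acceptance design explicitly treats as trend targets only. One known
divergence: with a perfectly matched PSF model, converged penalized
reconstruction recovers 10–13 mm spheres almost fully (mild ~4% edge
ringing), so its RC-versus-diameter curve is flatter than the scanner's;
the acceptance monotonicity check allows local decreases up to 6% — the
size of the largest violation present in the published recovery tables
themselves — and averages three seeds to control Monte Carlo error.

# Numerical details

* EM ratio stabilizer and RDP ε: 10⁻⁹; BSREM image floor 10⁻¹².
* Voxels with zero subset sensitivity (outside every ray) stay at zero.
* Gaussian filters use truncated (3σ), edge-renormalized kernels: constants
  are preserved everywhere, totals wherever the support is ≥ 2 kernel radii
  from the volume edge; `fwhm = 0` is the identity.
* The `[1:4:1]` axial filter renormalizes over available support at the
  first/last slice.
* The VOI threshold comparison is ≥ (plateaus join the VOI).
* Sub-voxel spheres with `supersample = 1` trigger a quantization warning.
* All randomness flows through explicit seeds; a missing seed is an error,
  not a default.

# Limitations

No TOF, no 3D LOR sampling, no scatter/randoms estimation, no dead time,
no respiratory motion, no DICOM. The patient cohort is a stated synthetic
world (uniform weights in 44–75 kg, 1–3 lesions from a configurable size
menu at 4:1 contrast), not a resampling of the study's patients: the real
lesion-size distribution is not printed. NIfTI support covers the float32
single-file subset this package writes.
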