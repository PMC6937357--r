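# petiq — simulated image-quality evaluation of penalized-likelihood PET reconstruction

`petiq` is an R package for studying, entirely in software, a question that
normally requires scanner time: **how does Bayesian penalized-likelihood PET
reconstruction (BSREM with a relative difference penalty, the "Q.Clear"
family) compare with conventional OSEM / OSEM+PSF under low-count clinical
conditions** — short acquisitions, weight-based low doses, and whole-body
scans built from overlapping bed positions?

It is aimed at medical-physics and image-reconstruction researchers who want
a controlled, reproducible desk-scale testbed for contrast recovery, noise
(COV) and multi-bed overlap artefacts, without access to a PET/CT.

## What it provides

* **Digital phantoms** — the NEMA NU2 image-quality phantom (six spheres,
  10–37 mm, around a 50 mm cold lung insert), a micro hollow-sphere phantom
  (4–10 mm spheres), uniform cylinders, and elongated patient-like objects
  spanning several bed positions; all rasterized with sub-voxel
  (partial-volume-correct) supersampling into activity / attenuation /
  label volumes.
* **An acquisition simulator** — attenuated parallel-beam projection
  (sparse Joseph system matrix, Rcpp), radial Gaussian detector blur,
  a triangular axial sensitivity profile, multi-bed geometry (47 slices/bed,
  11-slice overlap by default: `100·11/47 ≈ 23%` overlap, and a constant
  50%-of-peak combined sensitivity across each overlap), F-18 decay within
  the scan, Poisson counting, and binomial thinning that replays a stored
  acquisition at shorter effective scan times (list-mode
  retro-reconstruction analogue).
* **Reconstruction** — OSEM (2 it × 24 subsets, 6.4 mm Gaussian post-filter,
  `[1:4:1]` axial weighting), OSEM with resolution modelling, and BSREM with
  the relative difference penalty

  `U(f) = β Σ_{j} Σ_{k∈N_j} w_jk (f_j − f_k)² / (f_j + f_k + γ|f_j − f_k| + ε)`

  run to an objective-change tolerance rather than early stopping, plus
  sensitivity-weighted stitching of overlapping beds.
* **Image-quality metrics** — background-corrected 50%-isocontour recovery
  coefficients (RC = measured/true concentration), NU2 background
  variability, residual lung error, per-slice COV profiles with overlap
  annotation, the COV ∝ N^(−1/2) noise–counts fit, micro-to-NEMA
  cross-calibration, and the exponential ratio-versus-size fit.
* **Experiment drivers + CLI** — contrast series (10:1 / 4:1 / 2:1 fills at
  the published scan times), acquisition-time series (1–5 min/bed),
  a β-calibration routine that anchors the penalty-weight analogues to the
  OSEM+PSF noise level, and an overlap noise-band study on a synthetic
  cohort prescribed by the quadratic dose rule
  `A[MBq] = max(0.027·W², 120)`.

## Worked example

```r
library(petiq)

# NEMA IQ phantom at the 10:1 fill, one bed, 5 min
grid    <- voxel_grid(c(96, 96, 15), c(3.5, 3.5, 157/47))
phantom <- build_nema_iq("10:1", axial_length_mm = 15 * 157/47)
vols    <- rasterize(phantom, grid, supersample = 2)
geom    <- bed_geometry(slices_per_bed = 15, overlap_slices = 5, n_beds = 1)
acq     <- acquisition_config(time_per_bed = 300, seed = 42, angles = 96)
sinos   <- simulate_acquisition(vols, geom, acq)

osem <- osem_reconstruct(sinos, recon_config("OSEM_PSF", subsets = 24))
bpl  <- bsrem_rdp_reconstruct(sinos, recon_config("BPL", subsets = 24,
                                                  beta = 0.3,
                                                  bpl_max_passes = 40))
for (v in list(osem, bpl)) {
  bkg <- mean(background_roi_means(v, phantom)$mean)
  rt  <- recovery_table(v, phantom, bkg)
  le  <- residual_lung_error(v, phantom, bkg, slice_offsets_mm = c(-10, 0, 10))
  cat(sprintf("%-8s  RC(10..37 mm): %s   lung error: %.1f%%\n",
              v$provenance$algorithm,
              paste(sprintf("%.2f", rt$recovery_coefficient), collapse = " "),
              le$mean))
}
```

prints (seed 42):

```
OSEM_PSF  RC(10..37 mm): 0.35 0.56 0.72 0.87 0.86 0.91   lung error: 17.0%
BPL       RC(10..37 mm): 0.65 0.95 0.93 1.00 0.99 1.01   lung error: 7.5%
```

Read: with early-stopped OSEM+PSF the 10 mm sphere recovers only ~35% of its
true concentration; the converged penalized reconstruction nearly doubles
small-sphere recovery and more than halves the spurious activity in the cold
lung insert — the qualitative behaviour reported for BPL on real scanners.

## Command line

```sh
Rscript inst/cli/petiq.R contrast-series --config cfg.json --out out/ --seed 7
```

Subcommands: `contrast-series`, `time-series`, `overlap-study`, `cohort`.
Configs are JSON (a strict YAML subset); a seed is mandatory, unknown keys
are rejected, and every run writes a config echo plus a JSON run manifest.
Volumes are written as NIfTI-1 with JSON provenance sidecars, metrics as
CSV tables.

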