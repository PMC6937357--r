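{
  "seed": 7,
  "grid": {"nx": 96, "ny": 96, "nz": 15, "dx_mm": 3.5},
  "acquisition": {"time_per_bed": 60, "angles": 96, "psf_fwhm": 5,
                  "calibration": 0.01},
  "geometry": {"slices_per_bed": 15, "overlap_slices": 5, "n_beds": 2},
  "metrics": {"supersample": 2, "central_slices": 5},
  "experiment": {"name": "time-series", "times_min": [1, 2, 5],
                 "ratio_cases": ["10:1"], "n_patients": 4,
                 "betas": {"low": 0.2, "mid": 0.25, "high": 0.32}}
}
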