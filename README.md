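# ferrokin

Phantom-calibrated R2\* relaxometry and iron-tracer kinetics for
quantitative MRI.

## What this is for

Iron-labeled dextran injected into a brain lateral ventricle is an
MRI-visible tracer: its iron core shortens T2\*, so the effective transverse
relaxation rate R2\* (= 1/T2\*, s⁻¹) of tissue rises linearly with the local
iron concentration,

    R2*(cFe) = a · cFe + b,        cFe in µg/mL.

Calibrate `a` and `b` once on an agarose vial phantom of known
concentrations, and every dynamically acquired R2\* map becomes an absolute
concentration map — which is how tumor-vs-normal tracer kinetics (arrival,
peak time, preferential accumulation) are quantified in µg/mL rather than in
arbitrary signal units.

`ferrokin` implements that pipeline for scientists analyzing dynamic
contrast studies of CSF-delivered tracers:

* **synthetic data** — seeded generators for an 11-vial phantom and a
  dynamic dual-echo study (9 baseline frames, post-injection frames at
  30/45/60/90/120 min; six scenario presets `group1`–`group6`), with Rician
  magnitude noise and known ground truth;
* **relaxometry** — the dual-echo closed form
  `R2* = ln(S(TE1)/S(TE2)) / (TE2 − TE1)` and SNR-gated (3:1) weighted
  log-linear multi-echo fitting, with per-voxel validity reasons and
  slice-geometry resampling;
* **calibration** — OLS of per-vial mean R2\* on iron concentration, its
  inversion (intercept mode for phantoms, per-voxel baseline subtraction for
  in vivo dynamics), and mean ± SD (n), SE = SD/√n ROI reporting;
* **kinetics** — ROI concentration time courses, peak times,
  tumor/normal ratio series and preferential-accumulation windows;
* **pipeline + CLI** — one seeded, manifest-tracked run from simulation to
  group report, and `simulate` / `fit` / `calibrate` / `quantify` /
  `kinetics` / `run` subcommands.

All interchange is NIfTI-1 volumes with JSON sidecars, delimited-text tables
and JSON models; the package carries its own minimal NIfTI-1 reader/writer.

## Worked example

Fit the calibration from the shipped 11-vial reference table, simulate a
"group 1" dynamic study (tumor peak at 45 min, preferential accumulation
through 90 min), and recover its kinetics:

```r
library(ferrokin)

tab <- read_table1(system.file("extdata", "table1_phantom_calibration.tsv",
                               package = "ferrokin"))
calib <- fit_calibration(tab$cfe_ug_ml, tab$mean_r2star)
calib
#> <calibration_model> R2* = 10.02 x cFe + 88.02  (R^2 = 0.9781, n = 11)

sp <- group_preset("group1")                       # sigma/S0 = 0.02 default
frames <- generate_dynamic_study(sp, seed = 42)    # 14 dual-echo frames
tumor  <- extract_timecourse(frames, sp$compartment_masks$tumor,  calib, 9, "tumor")
normal <- extract_timecourse(frames, sp$compartment_masks$normal, calib, 9, "normal")

preferentiality(tumor, normal, threshold = 1.1)
#> <preferentiality> peak 45 min; window {30,45,60,90} at threshold 1.1

tumor
#> <roi_timecourse> tumor: 14 frames (9 baseline)
#>    time_min conc_ug_ml
#> 9      0.00    0.03712
#> 10    30.00    4.02200
#> 11    45.00    5.97300
#> 12    60.00    4.50900
#> 13    90.00    2.47800
#> 14   120.00    1.22300
```

Reading the output: the fitted calibration (slope 10.02 s⁻¹ per µg/mL,
agarose intercept 88.02 s⁻¹, R² 0.98) converts baseline-subtracted R2\* to
µg/mL. The nine baseline stamps hover at zero (±0.07 µg/mL of noise); the
tumor ROI rises to 5.97 µg/mL at 45 min — the recovered peak — and the
tumor/normal ratio exceeds the noise-robust 1.1 threshold at the 30, 45, 60
and 90 min stamps, i.e. preferential accumulation through 90 min, matching
the scenario's generative curves.

The same run as one reproducible pipeline:

```r
cfg <- run_config(scenario = "group1", seed = 42, output_root = "out/run1")
manifest <- run_end_to_end(cfg)   # simulate -> fit -> calibrate -> kinetics
```

which writes the phantom R2\* map, calibration JSON, time-course CSV/JSON,
group report and a `manifest.json` with an MD5 per artifact (identical
config + seed ⇒ identical hashes). From the shell:

```sh
inst/cli/ferrokin calibrate --table inst/extdata/table1_phantom_calibration.tsv --out calib.json
inst/cli/ferrokin simulate study --scenario group1 --seed 42 --out-dir out/sim
inst/cli/ferrokin kinetics --frames out/sim --tumor-mask out/sim/mask_tumor.nii.gz \
    --normal-mask out/sim/mask_normal.nii.gz --calib calib.json --out out/report
```

## Documentation

`vignettes/ferrokin-methods.Rmd` describes the signal model, the estimator
choices (why the log-linear fit is two-pass, why Rician floor correction is
off by default, why SNR gating is per-region on phantoms), what the
synthetic generator does and does not emulate, and the package's
degenerate-input contracts.
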