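---
title: "ferrokin: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ferrokin: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferrokin)
```

# The problem

Iron-cored dextran tracers shorten the effective transverse relaxation time
T2\* of tissue water, so the effective relaxation rate R2\* (= 1/T2\*, in
s^-1) rises with the local iron concentration. Over the concentration range
used for intraventricular tracer studies the relationship is linear,

$$R_2^*(c_{Fe}) = a \, c_{Fe} + b,$$

with $c_{Fe}$ in µg/mL. Once the slope $a$ and intercept $b$ are calibrated
on a vial phantom of known concentrations, a dynamically acquired R2\* map
becomes a concentration map, and tumor-vs-normal tracer kinetics — arrival,
peak time, preferential-accumulation window — can be read off region-of-
interest (ROI) time courses in absolute units (µg/mL).

`ferrokin` implements this chain end to end: a seeded synthetic-data
generator (vial phantom and dynamic dual-echo study), voxelwise R2\*/R2
relaxometry, phantom calibration, concentration quantification, ROI
kinetics, and a CLI that orchestrates one reproducible, manifest-tracked
run. Everything downstream of acquisition is testable against the
generator's known ground truth.

# Signal model and estimators

## Forward model

A voxel with amplitude $S_0$ and rate $R$ decays mono-exponentially across
echoes: $S(TE) = S_0 e^{-R \cdot TE}$. Echo times are stored in ms
everywhere; rates are reported in s^-1, and the ms-to-s conversion happens
only inside the two fitting routines, never at I/O boundaries.

Magnitude MRI noise is Rician: the magnitude of the complex signal after
adding iid Gaussian noise of standard deviation $\sigma$ to both
quadratures. At zero underlying signal the magnitude mean is
$\sigma\sqrt{\pi/2}$ (the Rayleigh floor), which is how
`estimate_noise_sigma()` recovers $\sigma$ from a signal-free background
ROI. A Gaussian additive model is available in the generator purely for
oracle tests.

## Dual-echo closed form

For the fast dynamic scans (TE1 = 1.85 ms, TE2 = 7.2 ms) the two-point
solution is exact:

$$R_2^* = \frac{\ln\{S(TE_1)/S(TE_2)\}}{TE_2 - TE_1}.$$

Voxels where either magnitude is non-positive are marked invalid with a
reason code rather than raising; downstream ROI statistics exclude invalid
voxels instead of absorbing sentinel values.

## SNR-gated multi-echo fit

For multi-echo acquisitions the fit uses only the leading echoes whose
signal-to-noise ratio exceeds a gate (default 3:1): late echoes of
fast-decaying voxels sit on the noise floor, where the log transform is
badly behaved. `select_echoes_by_snr()` returns the longest leading run of
echoes with magnitude $> 3\sigma$; a voxel with fewer than two usable echoes
is invalid (`insufficient_echoes`).

**Gating granularity matters.** Gating each voxel on its own noisy
magnitudes conditions the kept data on the noise: a borderline echo survives
only when its noise fluctuated upward, so the kept late echoes are biased
high and the fitted rate biased low — catastrophically so near the gate (in
our phantom simulations the calibration slope collapses from 10 to below 1).
For phantoms, where vial membership is known, `multi_echo_map(gate_regions=)`
therefore applies the gate to each vial's *mean* decay, which is nearly
noise-free, and shares the echo count across the vial's voxels. Per-voxel
gating remains the default for in vivo maps, where no region structure is
available and rates are far from the gate.

## Weighted log-linear fit, and why it is two-pass

`fit_exponential_decay()` fits $\ln S$ on TE by weighted least squares with
weights $S^2$, the standard variance-stabilizing choice that undoes the log
transform's distortion (the log-domain noise variance of a magnitude $S$
scales as $1/S^2$). It is exact on noiseless data and deterministic, which
is why it is the production estimator; an independent nonlinear
least-squares fit serves as the test oracle only.

Two refinements were adopted after measuring estimator bias at the package's
own operating point ($\sigma/S_0 = 0.05$, 3:1 gate, 25-seed phantom
simulations; the numbers below are reproduced by the test suite):

* **Predicted-value weights (second pass).** Using the *measured* magnitudes
  as weights correlates the weights with the log-domain noise and biased the
  recovered calibration slope by +1.3%. The fit therefore runs twice: the
  first pass with $w = S^2$, the second with $w = \hat S^2$ from the first
  pass's predictions. With deterministic weights the 25-seed mean slope is
  10.025 ± 0.012 (SE) against a generative 10.02. The refinement is a no-op
  for two echoes and on noiseless data.
* **No Rician floor correction by default.** The magnitude-domain correction
  $\sqrt{\max(M^2 - 2\sigma^2, 0)}$ looks natural (it inverts
  $E[M^2] = A^2 + 2\sigma^2$) but *overshoots* in the log domain: for Rician
  data $E[\ln M] \approx \ln A + O((\sigma/A)^4)$ — the second-moment
  inflation and the log's concavity cancel — so "correcting" the magnitudes
  introduced a −2σ²/A² log bias and pushed the recovered slope to 11.24. The
  correction is retained as an off-by-default option
  (`rician_correction = TRUE`) for magnitude-domain workflows.

## Slice-geometry harmonization

`resample_to_reference()` averages blocks of thin slices into each thick
reference slice (e.g. 48 × 0.5 mm into 24 × 1 mm) so that co-acquired R2\*
and R2 maps share a grid. It is deliberately *not* spatial registration: the
maps come from the same session and differ only in slice thickness. An
output voxel is valid when at least one contributor is valid, and means over
fully valid regions are conserved exactly.

# Calibration

`fit_calibration()` is ordinary least squares of per-vial mean R2\* on iron
concentration — per-vial means, not pooled voxels, because that is what a
calibration table tabulates and what the printed reference fit
(slope 10.02, intercept 88.028, R² 0.98 on 11 vials spanning 0–96 µg/mL)
was computed from. Refitting the shipped reference table reproduces
slope 10.0200, intercept 88.023, R² 0.978; the 0.005 discrepancy in the
intercept's third decimal traces to the table's means being printed rounded
to 0.1 s^-1, so regression tests use a 0.5% band on the intercept and exact
2-decimal agreement on the slope. Likewise the table's SE column was
computed from unrounded SDs: recomputing SD/√n from the printed (rounded)
SDs matches only within the propagated rounding bound
$0.05/\sqrt{n} + 0.0005$, which is the tolerance the tests encode.

Inversion has two modes:

* **intercept mode** (phantoms): $c_{Fe} = (R_2^* - b)/a$ — valid because
  the intercept *is* the carrier-agarose rate;
* **baseline mode** (in vivo, the default for dynamic data):
  $c_{Fe} = (R_2^*(t) - \bar R_{2,\text{baseline}}^*)/a$ with the per-voxel
  baseline averaged over the nine pre-injection frames — tissue baseline
  R2\* varies voxel to voxel and the agarose intercept cannot apply.

Negative concentrations are retained and counted (`n_negative`), with
clipping opt-in: silently clipping would hide noise-floor bias in exactly
the low-concentration regime where it matters.

ROI summaries follow the mean ± SD (n pixels), SE = SD/√n convention, with
the population SD (divisor $n$); at the pixel counts involved (hundreds to
thousands) the $n$ vs $n-1$ distinction is far below reporting precision.

# The synthetic generator: what it emulates, and what it does not

## Phantom

Eleven vials (agarose blank plus the dilution series 0.02–0.20 mg/mL of
formulation, iron fraction 0.48, i.e. 0–96 µg/mL iron) as disks on a
128 × 128 × 10 grid, `S0 = 1000`, default Rician σ = 50 (σ/S0 = 0.05), with
the generative calibration slope 10.02 / intercept 88.028. The vial geometry
of the physical phantom is unspecified, so the layout is an explicit,
config-driven choice (disks on a rack grid), not a reconstruction.

## Dynamic study

Nine baseline frames (stamps −2 … 0 min at the 15 s dynamic repeat) followed
by post-injection frames at 30/45/60/90/120 min, on a scaled-down
32 × 32 × 3 grid with disjoint tumor, contralateral normal-tissue and
ventricle compartments; dual-echo acquisition timing from the
`dual-echo-dynamic` preset. Compartment R2\* follows
$R_2^*(t) = R_{2,\text{base}}^* + a\,c(t)$ with baseline rates
tumor 30 / normal 20 / ventricle 12 s^-1 and piecewise-linear concentration
curves; default σ/S0 = 0.02.

The six scenario presets `group1` … `group6` encode the qualitative
behaviours reported for the six experimental groups (three dextran sizes at
337 mOsm/L; three vehicle osmolarities at 10 kD): groups 1/4/5 —
preferential tumor accumulation through 90 min with the tumor peak at
45 min; group 2 — preferential for the full two hours, peak anchored at
60 min (within the reported 45–60 range); group 3 — fastest arrival, peak at
30 min, preferential only through 45 min; group 6 — tumor and normal curves
identical (no preferential accumulation). No numeric concentrations are
published for these curves, so the anchor values are the package's own
choice, made once: peak tissue concentrations of a few µg/mL, the scale at
which the dual-echo protocol (TE2 = 7.2 ms) keeps post-injection signal well
above the noise floor. They are *not* tuned to any test outcome.

Seeding is hierarchical: one top-level seed draws per-frame sub-seeds
sequentially, so extending the frame list never reshuffles earlier frames,
and identical seeds give bit-identical output.

**What a green test does not establish.** The generator omits k-space
effects, coil sensitivities, B0 inhomogeneity, motion, partial-volume
mixing, T1 saturation and physiological variability; its compartments are
homogeneous and its curves noise-free in shape. Passing recovery tests
therefore validates the *estimators and their composition* under the stated
noise model — not the in vivo findings themselves, which rest on animal
data this package cannot and does not reproduce.

# Kinetics

`extract_timecourse()` requires a voxel to be valid in **all** nine baseline
frames (strict, so baselines are never a mixture), subtracts the per-voxel
baseline-mean R2\*, inverts by the calibration slope and summarizes the ROI
per frame. By construction the mean of the nine baseline concentrations is
exactly zero per voxel; individual baseline stamps fluctuate at the noise
level, which is the visible sanity check in reports.

`peak_time()` is the stamp of the post-injection maximum, ties broken to
the earliest stamp. `preferentiality()` computes the tumor/normal ratio per
stamp; the preferential window is the *set of sampled stamps* above
threshold — no interpolation, since only five post-injection stamps exist.
The strict threshold is 1; the recommended noise-robust threshold is 1.1
(with only ratio noise separating "equal" from "preferential", a strict
threshold flips on the noise sign at stamps where the true ratio is 1), and
1.1 is what the pipeline defaults to and what the noisy acceptance checks
use. Stamps with non-positive normal-tissue concentration give an undefined
ratio: flagged, never counted as preferential.

# Numerical and degenerate-input choices

* Invalid voxels carry reason codes (`nonpositive_signal`,
  `insufficient_echoes`), not sentinel values; ROI statistics exclude them
  and error on an all-invalid ROI.
* A whole-image fit failure (no valid voxel anywhere) is a distinct error.
* `fit_calibration()` rejects fewer than two distinct concentrations;
  inversion rejects slope 0.
* Vials whose ROI has no valid voxel are dropped from calibration with a
  warning — at σ/S0 = 0.05 the 3:1 gate removes the five highest
  concentrations entirely (their second echo sits below 3σ), and the
  calibration is fitted on the surviving vials, as the gating rule dictates.
* The `phantom-multiecho` preset stores `NA` for the flip angle (the
  protocol does not document a value) and the generator's pure-decay model
  does not use it; the dual-echo preset stores 2 mm slices and ignores the
  protocol's 0.5 mm gap, which nothing downstream consumes.
* `tracer_curve()` rejects negative concentrations at construction; curves
  evaluate to 0 at and before injection and hold their last anchor beyond it.
* Manifest hashes are MD5 over file bytes; gzip output in R carries no
  timestamp, so identical config + seed gives identical hashes.

# Limitations

Out of scope by design: susceptibility (QSM) reconstruction, phase/B0
processing, true spatial registration, T1/flip-angle corrections, nonlinear
(saturating) calibration models, compartmental pharmacokinetic model
fitting, and between-group hypothesis testing (group comparisons are
descriptive, mirroring how the underlying study reported them). The NIfTI-1
layer is deliberately minimal (single-file little-endian volumes, common
datatypes, scl slope/intercept on read) — enough for the pipeline's own
interchange, not a general neuroimaging I/O library.
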