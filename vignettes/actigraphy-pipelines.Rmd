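---
title: "Methods: actigraphic signal-processing pipelines and their effect on sleep-wake analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: actigraphic signal-processing pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Wrist actigraphs sample acceleration at tens of hertz but store
epoch-level "activity" values produced by manufacturer-specific, largely
proprietary compression. Two devices on the same wrist can therefore
disagree substantially about the wearer's rest-activity rhythm — not
because the motion differed, but because the signal processing did. This
package implements, as a reusable and fully testable pipeline, the
machinery needed to quantify that effect: raw triaxial acceleration in,
the family of generalized and device-specific activity signals out, then
nonparametric circadian indicators and sleep-wake scores, and finally
similarity matrices and dendrograms that show which processing choices
drive which analytical outcomes.

Because the real study cohort is a multi-gigabyte download, a synthetic
recording generator with ground-truth annotations stands in for it;
every stage of the pipeline is exercised against that stated world.

## Activity determination

A pipeline is a *preprocessing scheme* followed by an *activity metric*.

Preprocessing schemes (all in g units, at the recording rate):

* `UFX/UFY/UFZ/UFXYZ` — raw axes and their bundle (gravity-bearing);
* `UFM` — Euclidean norm of the axes (gravity-bearing);
* `UFNM = |UFM - 1|`, `ENMO = max(UFM - 1, 0)` — gravity removed by
  subtraction; ENMO truncates, UFNM reflects;
* `FX/FY/FZ/FXYZ` — per-axis 3rd-order Butterworth band-pass,
  0.25–2.5 Hz; `FMpre` — norm of the filtered axes; `FMpost` —
  band-pass of `UFM` (filtering and norm do not commute, which is
  exactly what separates the "pre" and "post" families);
* `HFMpre` — norm of 4th-order 0.2 Hz high-passed axes.

Metrics per 60 s epoch: `PIM` (integral of |a|, g·s), `ZCM` (upward
crossings of a threshold), `TAT` (time above threshold, s), `MAD` (mean
absolute deviation about the epoch mean), `AI` (root mean of per-axis
variances above a noise floor, axis bundles only), `HFEN` (epoch mean,
`HFMpre` only). The ZCM/TAT threshold follows the SD rule: the standard
deviation of all preprocessed samples, pooled across the cohort by
default (`+1` g for the gravity-bearing `UFM`). Proper pairings yield
exactly 35 generalized methods (`valid_combinations()`); the roster is
one table constant, reconstructed from the pairing constraints
(HFEN↔HFMpre; AI on axis triplets), so it can be corrected in one place
if an authoritative enumeration differs.

Device emulations: `MW` (per-second peak of the filtered magnitude,
peaks > 0.1 g summed per epoch; the device's 3–11 Hz band cannot be
realized at 10 Hz and is approximated by the generalized band, as the
original analysis did) and `AC` (per axis: linear resample to 30 Hz,
0.29–1.63 Hz band-pass, deadband 0.068 g, ceiling 2.13 g, 0.0164 g per
count, decimation, epoch sum, axes combined by Euclidean norm; see
`ac_parameters()`). Both are emulations of the published stage
structures, not bit-exact clones of any vendor release. ActTrust-style
devices map to `ZCM/TAT/PIM(FMpre)` and the GGIR default to
`PIM(ENMO)`.

## Circadian indicators

From a 24 h mean profile (60 s bins for activity, 1 s for acceleration;
only complete midnight-to-midnight days enter), L5 and M10 are the
circular 5 h / 10 h windows with extreme means, slid in 60 s onset steps
with earliest-onset tie-breaking. RA = (M10val − L5val)/(M10val +
L5val). IS and IV are computed on clock-hour means over complete days:

* IS = (Σ_h (x̄_h − x_m)² / 24) / (Σ_i (x_i − x_m)² / N) — day-to-day
  stability, 1 for a perfectly repeating pattern, ≈ 1/D for noise;
* IV = (Σ_{i≥2} (x_i − x_{i−1})² / (N−1)) / (Σ_i (x_i − x_m)² / N) —
  fragmentation, ≈ 2(1 − cos(2π/24)) for an hourly sinusoid, ≈ 2 for
  noise.

Both closed forms are asserted in the test suite. Mean normalization
(dividing a series by its grand mean before the profile) removes the
value-range differences between pipelines; RA, IS and IV are
scale-invariant by construction, and the suite asserts exact invariance.

NPCRA applies directly to acceleration signals whose mean is not
constant: `ENMO`, `UFNM`, `FMpre`, `HFMpre` as-is, `FX/FY/FZ/FMpost`
after `rectify()`. `UFM` is rejected: its mean converges to the
gravitational constant, degenerating every mean-based indicator. A
useful identity: IS/IV from the ENMO acceleration signal equal those
from PIM(ENMO) activity exactly, because hourly means of the integrated
series are proportional to hourly means of the signal and both
indicators are scale-free.

## Sleep-wake scoring

Two scorers, re-implemented from their published descriptions (the
original analysis called existing Python/R packages; ours are documented
approximations with pinned parameters recorded in every result):

*Trend-threshold (MASDA-style)*: trend = centered 24 h moving average
(edge windows truncated, never below 12 h); raw sleep where activity <
0.25 × trend; rescoring stage 1 bridges wake runs < 30 min flanked by
sleep, stage 2 removes sleep runs < 30 min. The stage order is fixed and
documented; rescoring is idempotent (asserted).

*Z-angle (van Hees-style)*: angle = atan(z̃/√(x̃²+ỹ²)) on 5 s rolling
medians, averaged per 5 s block; sustained inactivity bouts are runs of
block-angle changes < 5° lasting ≥ 5 min; the nightly sleep-period-time
window per noon-to-noon day keeps ≥ 30 min blocks of 5-min-rolling-median
angle change < 0.4, bridges < 60 min gaps, and takes the longest block;
sleep = SIB ∩ SPT on a 60 s epoch grid (which makes IoU comparisons with
the activity scorer well defined). The `0.4` is interpreted as the fixed
z-angle-change threshold of the SPT heuristic — the parameter's exact
meaning in the original toolchain is ambiguous, and this reading is the
one consistent with a fixed constant.

## Comparison

For scalar indicators, SMAPE (Symmetric Mean Absolute Percentage Error,
0–200%) is averaged across subjects per pipeline pair; window onsets
compare by circular overlap / window length (0–100%); sleep segment sets
by the Jaccard index of interval measures (0–100%). Undefined cells
(zero denominators) abort with an error naming subject and pair rather
than being silently skipped. For dendrograms, matrices convert to
dissimilarities (SMAPE/200, or 1 − M/100), are min–max rescaled to
[0, 1] over the off-diagonal range (each matrix independently), and each
pipeline's feature vector is its row of the rescaled matrix; Euclidean
distances between rows feed complete-linkage agglomeration, exported as
Newick with merge-height branch lengths. Using rows as feature vectors
mirrors the default behavior of the clustering stack the original
analysis used when handed a square matrix.

## The synthetic world

`generate_recording()` emulates the acquisition of the study hardware —
10 Hz sampling, ±8 g range, quantization to 16 mg — and a free-living
adult: sleep nominally 23:30–07:00 with 15 min/day schedule jitter (plus
subject-level jitter in cohorts), near-motionless nights interrupted by
~4 posture reorientations, and wakefulness as Poisson-arriving movement
bouts (default 5/min, ~5 s, 0.25 g scale, band-limited to 0.3–3 Hz)
*each of which also reorients the gravity vector*. That last point
matters: an early version kept the wrist orientation fixed while awake,
and both sleep scorers then saw implausible all-day stillness/stability
and scored roughly twice as much sleep per day as they do on real
cohorts. Real wrists reorient with essentially every arm movement, so
reorientation-per-bout is part of the stated world, chosen once for
realism (not tuned to any test threshold).

What a green test establishes: the pipeline mechanics — threshold
metrics zeroing quiet night epochs and depressing L5; the
threshold/non-threshold bipartition of the RA dendrogram; recovery of
ground-truth sleep timing by both scorers. What it does not: real-data
effect sizes. In particular, the tight (< 5%) clustering of total sleep
time across threshold-metric pipelines seen on real recordings is not
reproduced quantitatively here (the synthetic night noise floor
interacts with each device's threshold slightly differently, spreading
the cluster to ~20%); the suite asserts the direction — every
threshold pipeline scores more sleep than PIM on the same signal — not
the real-data tightness. Likewise the anomalously low real-data TST of
PIM(ENMO) (driven by real daytime ENMO baselines) is outside the
generator's vocabulary.

## Numerical choices

* Butterworth filters are designed in zero-pole-gain form with bilinear
  transform and frequency pre-warping (no design routine ships with the
  installed stack); coefficients were verified against an independent
  reference implementation during development, and the test suite checks
  steady-state sinusoid amplitudes against the analytic |H(f)|.
* Filtering is causal single-pass (emulating on-device real-time
  processing; zero-phase available via `zero_phase = TRUE`), initialized
  at rest relative to the first sample: both designs have zero DC gain,
  so this leaves steady state untouched while removing the artificial
  turn-on step transient. Transients are retained, not trimmed.
* Epochs anchor at the first timestamp rounded up to a whole minute;
  partial epochs are dropped. Timestamp regularization snaps to the
  exact 1000/rate ms grid (nearest sample, earlier-wins ties,
  repeat-last gap fill with a gap report) and is idempotent.
* The sphere-fit calibration estimates per-axis scale and offset from
  ≥ 30 still 10 s windows (per-axis SD < 0.013 g, the conventional
  stillness threshold) with an orientation-diversity guard, by
  alternating projection onto the unit sphere and per-axis regression.
  It reports the estimated distortion, applies its inverse, and is a
  flagged no-op whenever still data are insufficient or the fit does not
  reduce the residual — calibration can never make a recording worse.
  Cross-axis (orthogonality) correction is out of scope.
* `MAD` is the mean absolute deviation about the epoch mean (the
  standard reading of the name); the AI noise variance σ₀² defaults to
  0 and is configurable. ZCM counts upward crossings only, without
  hysteresis — the SD-rule threshold already sits above the noise floor.
* L5/M10 onset steps stay at 60 s even on 1 s acceleration profiles
  (minute-step window placement is the stated general procedure;
  configurable via `step`).
* Pooled thresholds over a cohort are computed from streaming moments in
  a first pass; recordings are regenerated (or re-read) in the second
  pass, so memory stays flat in cohort size.

## Scale of the shipped analyses

The desk-scale cohort is 10 subjects × 3 days (the acceptance-level
mechanism and recovery checks run in ~2–3 min on one CPU). Three days
give two-plus complete noon-to-noon nights per subject, the minimum that
makes profile averaging, IS/IV and per-night recovery meaningful; the
real study's 42 × 10-day scale changes runtimes, not code paths.

## Known limitations

* The AC emulation pins plausible published-stage constants; it is not
  bit-exact against any specific vendor release version.
* The MW band (3–11 Hz) is unrealizable at 10 Hz and approximated by the
  0.25–2.5 Hz band, as in the original analysis.
* The calibration substitute fits scale/offset only.
* The generator models the statistical structure the analysis needs
  (circadian alternation, gravity, posture, noise, quantization) — not
  tremor, heart-rate artifacts, or naps; scorer performance against the
  synthetic truth says nothing about performance against polysomnography.
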