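---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lutphysio)
```

`lutphysio` analyzes three recording modalities used to study the neural
control of micturition in rodents: simultaneous fiber photometry and
cystometry (bladder-pressure recording under constant saline infusion),
optogenetic stimulation with external-urethral-sphincter (EUS)
electromyography, and overhead thermal imaging of urine spots on filter
paper. Because raw in-vivo recordings of this kind are rarely shareable,
the package pairs every analysis stage with a synthetic-session generator
that produces the same statistical structure with known ground truth, so
each stage is validated by ground-truth recovery rather than by eye.

## Photometry: dF/F0, isosbestic correction, normalization

**dF/F0.** Raw fluorescence is downsampled to 0.1 s resolution by
non-overlapping block means (`downsample()`), then converted to
`dF/F0 = (F - F0) / F0`, with `F0` a best-fit baseline over the entire
trace (`compute_dff()`). GCaMP photobleaching is empirically well described
by a sum of exponentials, so the default fit family is a double
exponential plus constant; when that fit fails to converge or yields a
non-positive baseline, the cascade falls through to a single exponential
plus constant, then a 2nd-order polynomial, and finally a constant mean.
The family actually used is kept in the `baseline_model` field. The fit is
performed on the downsampled trace: at 0.1 s resolution the bleach curve
is fully resolved and the fit is two orders of magnitude cheaper.

**Isosbestic correction.** The 405 nm excitation of GCaMP is
calcium-independent, so deflections shared by the 465 and 405 channels
index motion rather than neural activity. `isosbestic_correct()` subtracts
a least-squares gain+offset rescale of dF/F0(405) from dF/F0(465). One
numerical subtlety: with sparse artifacts, ordinary least squares over the
whole trace is attenuation-biased — the 405 channel's own noise dilutes
the regressor and the fitted gain shrinks toward zero, leaving a visible
artifact residual. The gain and offset are therefore estimated on the
motion-informative samples (|dF/F0(405) - median| > 5 MAD) and the fitted
line is applied to the whole trace; when fewer than 10 samples qualify the
fit uses all samples. A literal direct subtraction (gain 1, offset 0) is
available via `lut_config(isosbestic_fit = "raw")`.

**Per-event normalization.** For event-averaged traces, each +/-60 s
window is normalized to its own pre-event baseline,
`(x - baseline) / baseline x 100`, with baseline the mean dF/F0 over the
60 s preceding the alignment point. This removes between-session
differences in expression level and fiber placement. Because a
baseline-fitted dF/F0 trace is approximately zero-centered, the divisive
baseline can be arbitrarily close to zero; below a guard of
`baseline_guard_eps = 0.005` dF/F0 units the window is normalized
subtractively only (reported in dF/F0 percentage points) and flagged,
rather than silently dropped or divided by a near-zero number. Heatmaps
use `Z = (x - mean(x)) / sd(x)` per event window; the window is the full
+/-60 s range so rows remain comparable.

## Cystometry: detection, gating, alignment

Saline is infused at 15-30 uL/min, so bladder pressure rises linearly
between voids; voiding contractions are large (tens of cmH2O) and
non-voiding contractions (NVCs) smaller single-peaked rises.
`detect_contractions()` removes the filling trend with a running median
over `detrend_span_s = 120` s, smooths with a `smooth_s = 1` s moving
average, and keeps episodes whose rise over the median of the preceding
30 s reaches `contraction_prominence_cmh2o = 5`. The paper-level inclusion
rules are applied by `classify_and_gate()`: episodes with more than one
contraction peak are excluded (`multi_peak`), as are unconfirmed
contractions rising less than 5 cmH2O (`sub_threshold`). "Single peak" is
operationalized as exactly one local maximum with topographic prominence
at least 20% of the episode rise; the threshold is configurable because no
numeric rule exists in the literature, only the qualitative criterion.
Void confirmation comes from an external source — in real sessions the
thermal camera, in synthetic ones the ground-truth flag.

Voids are aligned to the maximum of dP/dt (centered finite difference of
the smoothed trace) within a 15 s window before peak pressure — the
steepest pre-void pressure rise; NVCs to peak pressure. Two numerical
choices matter here. First, the dP/dt maximum is broad relative to sample
noise, so the derivative segment is smoothed once more before the argmax;
without this the located maximum wanders +/-0.5 s along the plateau.
Second, ties break to the earliest sample with a relative tolerance of
1e-9, because analytically tied maxima routinely differ by one floating
point ulp.

## EMG: total power, epoch normalization, response rates

Each stimulation trial is split into three equal epochs: before (baseline,
same duration as the stimulation), during, after. EMG activity per epoch
is summarized as Total Power — the sum of power across all frequencies
within the epoch. By Parseval's theorem this equals the sum of squared
mean-removed samples; the time-domain form is canonical and the
periodogram form (`total_power_freq()`) is retained as a cross-check, the
two agreeing to 1e-9 relative. The epoch mean (DC) is removed by default
so electrode offset cannot dominate the statistic; `ttp_remove_dc = FALSE`
restores the literal all-bins sum. Raw epoch powers are normalized to
percent shares, `TTP_p / (TTP_before + TTP_stim + TTP_after) x 100`, which
removes between-trial and between-animal voltage scale.

Trials with artifacts during the **baseline** epoch are excluded (default
flag: any excursion beyond 8x the session's MAD-based amplitude scale
lasting >= 2 ms); artifacts during the stimulation or recovery epoch never
cause exclusion, to avoid biasing trial selection. Response rates are
computed per animal: an EMG response is a >= 5% drop of stim-epoch total
power relative to baseline; a pressure response is a stim-epoch mean
pressure >= 3 cmH2O above the value predicted by extrapolating the
baseline-epoch linear trend (which accounts for the infusion-driven
filling rise; the prediction method is this package's choice, as no
explicit method exists to cite). Equal per-animal weighting is enforced by
seeded subsampling of a fixed number of trials per animal
(`subsample_trials()`); the count is analysis-specific and always an
explicit argument.

The >= 5% drop rule's false-positive rate on non-responsive trials is set
by the sampling variance of the total-power ratio, roughly
`sqrt(4 / (2 B T))` for bandwidth B and epoch length T. Sphincter EMG is
recorded broadband (kHz-range bandpass at 10 kHz sampling), where the rule
is near-exact; narrow-band simulations overstate the false-positive rate.
The acceptance cohort therefore runs at 2 kHz sampling with an 800 Hz
noise band as a compute-scaled emulation of the broadband chain.

## Thermography (MVT): segmentation, calibration, classification

Frames are 8-bit grayscale; warm urine spots and a bright 10 cm2
reflecting template sit on a cool background. `segment_spots()` thresholds
(Otsu by default; a fixed level is available for fidelity to manual
thresholding) and labels connected components with 8-connectivity; touching
spots merge into one region, a documented limitation. The template —
identified as the brightest region — calibrates pixels-per-cm2, absorbing
camera height and angle. Volume is a linear function of calibrated area,
by default through the origin at 50 uL/cm2; the generator assigns
ground-truth volumes through the same curve, so analyzer recovery is
closed and tests exercise the area pipeline, not the curve itself (the
published calibration curve's coefficients are not available; the slope is
explicit config, not a claimed value).

Void-vs-leak classification is a geometric proxy for the behavioral
definition (mice walk to a corner to void; leaks appear mid-arena): a spot
is a void when its area reaches `void_area_min_cm2 = 0.5` and its centroid
lies within `corner_radius_cm = 7` of an arena corner; otherwise it is a
leak, except that in marking mode sub-void-size non-corner spots are
marks. Both thresholds are config; the proxy is exact on synthetic frames
that respect the margins, and only approximates the behavioral scoring of
real videos. The dominance screen for scent-marking sessions is the
literal rule: marking must start within 5 minutes of the urine stimulus
and produce at least 10 marks in the session, with latency censored at
session end when no marks occur.

## The synthetic-session generator

The generator's defaults encode the study conditions: 2-h sessions,
infusion 20 uL/min with compliance 0.024 cmH2O/uL (fill slope 0.008
cmH2O/s, ~8 cmH2O between voids), 6 voids and 4 NVCs per session placed so
every +/-60 s analysis window fits, void contractions peaking 25 cmH2O
above the local baseline with a logistic upstroke (steepest rise = the
alignment ground truth), single-peaked Gaussian NVCs of 8 cmH2O, and
pressure noise of 0.5 cmH2O SD. Each void "empties" the bladder by a
smooth sigmoid release of the accumulated fill just after the contraction
peak — a step reset at void onset would sit exactly on the alignment
point and distort the dP/dt maximum.

Photometry carries a double-exponential bleach (time constants 120 s and
3000 s), void-locked transients as a difference of exponentials (rise
0.5 s, decay 4 s, peak dF/F0 0.15 with 20% per-event jitter), NVC-locked
transients attenuated to 0.3x the void amplitude (an emulation of
attenuated NVC-related activity, not a measured value), Gaussian motion
artifacts (sigma 0.08 s) injected identically into both channels, and
independent white noise. No quantitative transient amplitude or kinetics
are available to cite, so all kernel parameters are documented config.
EMG is brick-wall band-limited Gaussian noise at RMS 0.1 mV whose RMS
drops by the programmed relaxation depth during responsive stimulations
(total power scales with RMS squared). Thermal frames rasterize ellipses
by pixel-center inclusion, so ground-truth pixel areas are exact counts.

Everything is deterministic given `(params, seed)`: each generator seeds a
local RNG stream (offset per modality so channels are independently
reproducible) and restores the caller's RNG state.

**What passing tests do and do not show.** The generator reproduces the
statistical structure the analyses assume — linear fill, single-peaked
contractions, bleach, shared artifacts, RMS-scaled relaxation, elliptical
spots. It does not model detrusor-sphincter biophysics, bursting EUS
patterns, perspective distortion, animal locomotion, or correlated
physiological noise; ground-truth recovery on synthetic sessions validates
the implementation of the analysis chain, not its adequacy for any given
real recording.

## Problem sizes used in the tests

Module tests run minutes-long sessions at reduced sampling rates for
speed. The acceptance suite uses the full default conditions where they
are the point: 20 seeded 2-h cystometry sessions for detection/alignment
recovery, 50 seeds for artifact attenuation and transient retention, 500
shuffle draws over 100 fresh transient-free traces (a single finite trace
has a fixed placement bias, so unbiasedness is assessed over the
generative process), 200 four-animal cohorts for the void-vs-null power
property, a 200-trial stimulation cohort for response-rate recovery, and
20 synthetic frames for thermography recovery.
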