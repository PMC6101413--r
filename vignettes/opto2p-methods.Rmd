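---
title: "Models and methods behind opto2p"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind opto2p}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opto2p)
```

`opto2p` analyzes sessions that combine optogenetic stimulation with
two-photon calcium imaging and a behavioral readout. This vignette explains
the models each stage assumes, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## Frame-locked gating

Stimulation light leaking into the photomultipliers saturates them, so the
widefield stimulation laser is gated against the scan: it is powered down
whenever the scan covers the central `blank_fraction` of the field of view.
`build_gating()` turns a `scan_config()` into explicit per-frame on-windows.
With the defaults (32-ms frame, 75% central blanking) each frame carries
8 ms of stimulation — 25% duty at 31.25 Hz, the reciprocal of the frame
period.

Where within the frame the on-window falls is not dictated by the scan
geometry alone: a resonant raster enters and leaves the central band
mid-frame, so the default places half the window at the frame start and
half at the end (`split = TRUE`); a single contiguous end-of-frame window
is available for hardware that gates once per frame. Duty cycle and
repetition frequency are unaffected by this choice; only the artifact's
spatial footprint in `inject_stim_artifact()` depends on it, and both
placements leave the central band clean.

Pulse trains are described by `pulse_on_ms`/`pulse_off_ms`; a 22-ms-on,
44-ms-off train has duty 1/3 and a period of 66 ms, i.e. a repetition rate
of 15.15 Hz. `repetition_frequency()` reports the exact period reciprocal
rather than a rounded nominal rate. Pulse trains are phase-locked to the
cue: the first pulse sits at cue onset, which is what lets saccade
latencies be decomposed pulse by pulse (`latency_split()`).

Trial scheduling (`schedule_trials()`) apportions conditions by
largest-remainder rounding — deterministic, ratio-faithful, and exact when
the total divides the weight sum — then randomizes order under the given
seed. The 8:3:1 NoStim:OptoStim:MisStim session design yields 66.7% catch
and 8.3% mistargeted-control trials.

## The synthetic-data generator

Every downstream stage is tested against data whose ground truth is known,
produced by pure functions of (parameters, seed).

**Movies.** Each neuron is a disc with baseline fluorescence `baseline_F`;
its signal is `baseline_F * (1 + dF/F(t))` with dF/F the sum of per-trial
responses convolved with a peak-normalized double-exponential kernel.
Defaults of 0.18-s rise and 1.0-s decay are slow-indicator-like; the
kinetics of the indicators actually in use are not published quantities, so
both constants are exposed in `calcium_kernel()`. Visual trials scale with
a circular-Gaussian tuning of the trial's grating orientation; optogenetic
trials drive only opsin-expressing cells, scaled by the hyperbolic dose
curve `I/(I + K)` with half-saturation `K = 0.0889` mW/mm² — placed so that
90% of maximum falls at 0.8 mW/mm², the regime where widefield
stimulation saturates. Frames are globally translated by i.i.d. Gaussian
per-frame motion and carry additive Gaussian noise; values are rounded to
integers, matching the 16-bit TIFF container so that written movies
round-trip exactly.

The generator emulates what the analyses assume — tuned somata, global
translation, stationary noise, saturating dose response — and deliberately
not what they ignore: no neuropil, no optical point-spread, no
photobleaching, no non-rigid or intra-frame motion, no spiking
nonlinearity. Passing recovery tests therefore validates the analysis
arithmetic, not robustness to every artifact of real tissue. Published
movies come with no quantitative SNR figures, so the default noise level
(noise SD a few percent of soma baseline) is a package choice, exposed as a
parameter.

**Artifact.** `inject_stim_artifact()` keys saturation to scan position:
any image line acquired while the laser is on is driven to the saturation
level. Continuous stimulation whites out the whole frame; gated stimulation
contaminates only the top and bottom margins.

**Eye traces.** 120-Hz traces with white Gaussian fixation noise. GO trials
contain a saccade modeled as a logistic position step (30-ms transit — a
typical small-saccade duration; the profile is a modeling choice, placed so
the true 1° crossing falls exactly at cue onset + latency, which makes
latency recovery testable to sample precision). Endpoints scatter around
the target with configurable per-component SD (default 0.22°); NO-GO
trials hold fixation apart from spontaneous saccades at a configurable
guess rate.

## Registration

The template is the pixel mean of up to 1,000 frames centered at the middle
of the session. Each frame's translation is estimated by exhaustive
normalized cross-correlation over integer shifts within `max_shift`
(default 20 px — wide enough for slow drift, narrow enough to exclude
spurious matches), normalizing within the overlap region per candidate
shift so that partial overlaps are compared fairly. The integer peak is
refined by separable 3-point quadratic interpolation, clamped to ±0.5 px; a
perfect correlation peak skips refinement so that exact integer shifts are
returned exactly. Peaks below a correlation of 0.3 are flagged unreliable
rather than rejected. Frames are shifted back by bilinear interpolation
with median fill at the exposed edges, which avoids biasing ROI means near
borders. Whether the field's original implementations used integer or
subpixel shifts varies; subpixel is the default here because it measurably
improves trace fidelity and costs one interpolation.

## Signals and statistics

Per (ROI, trial): `F0` is the mean fluorescence in a 1-s window ending at
onset, and the amplitude is the mean of `(F − F0)/F0` over the stimulus
duration plus 1 s. The windows are package choices — the design only
guarantees >2-s interstimulus gaps — and both are configurable; the 1-s
extension captures the slow indicator tail. ΔF/F is invariant to
multiplicative gain, differential images to additive offsets; tests assert
both.

The visual-vs-opto comparison uses a two-sample rank-sum test per cell (no
test is canonical here; the rank test avoids normality assumptions at the
typical 9–10 trials per mode) and classes cells at `p < 0.05` by the sign
of the mean difference. Orientation selection is a one-way ANOVA across six
orientations, assumed equally spaced at 0°–150° in 30° steps; cells with
zero between-group variance get `p = 1` rather than NaN. Both procedures
hold their nominal 5% type-I rate in 10,000-replicate null simulations run
by the test suite.

Cross-day stability is summarized by the unity-line R²,
`1 − Σ(yᵢ−xᵢ)²/Σ(yᵢ−ȳ)²`, which can be negative and deliberately measures
agreement with `y = x`, not with the best-fit line.

## Tuning and dose-response fits

The tuning curve is a von-Mises-style circular Gaussian on doubled angle,
`r(θ) = B + A·exp[(cos 2(θ−θp) − 1)/σc²]`, period 180°. The exact
parameterization behind published fits of this kind varies by lab; this
form is standard for orientation data and is documented rather than
asserted as identical to any particular one. Fitting is
Levenberg–Marquardt with multi-start over θp ∈ {0°, 30°, …, 150°} because
the objective is periodic and single starts find local minima. Flat inputs
(zero variance) short-circuit to `A = 0` with θp flagged unidentifiable.
The reported width `sigma_deg` is the small-angle Gaussian SD, σc/2 in
radians.

The dose-response model is hyperbolic, `r(I) = Rmax·I/(I + I50)` — the
simplest monotone saturating form consistent with the observed plateau.
"Saturation" needs an operational definition, set here at 90% of `Rmax`,
i.e. `I50·0.9/0.1`; the level is configurable. Wildly non-monotone level
means flag the fit rather than suppress it.

Pixelwise orientation maps take, per pixel, the vector sum
`Σ r(θ)e^{i2θ}` over orientation-mean responses (negatives clipped — a
negative response carries no orientation signal) and halve its argument;
strength is the mean response. Pixels with no positive response are NA, not
zero-orientation.

## Targeting geometry

Spiral paths grow geometrically, `r(φ) = r0·rate^(φ/2π)`, over
`rotations × 2π`, sampled finely enough that consecutive points are ≤0.25 px
apart. "Expansion rate 1.2" is read as radius growth per rotation and
"0.01 pixel/µs" as scan speed; both printed figures are ambiguous in the
original scan-software convention, so each is isolated behind one function
with a documented switch (`speed_is_dwell`) for the alternative reading.

Grid specificity reduces a K×K stimulation map to an on-target index:
response at the site containing the ROI centroid over the sum of all
(clipped) site responses — 1 for perfectly specific stimulation, 1/K² for
uniform spread. Boundary ties go to the nearer site center. The sequential
targeting matrix `M[i,j]` (response of cell i when cell j is stimulated) is
scored by mean diagonal over mean off-diagonal, undefined (flagged) when
nothing responds.

## Behavior scoring

A saccade is the first sample whose distance from fixation exceeds 1° and
stays above it for 2 consecutive samples — the confirmation rejects
single-sample noise spikes that a bare crossing definition would count.
Distance from fixation (not along-axis position) is used throughout.
Latency is measured from cue onset; at 120 Hz detection quantizes latencies
upward by at most one sample, and the test suite holds recovery to that
bound. The endpoint is read 50 ms after crossing, once the saccade has
settled. GO trials succeed within a 500-ms window at the block's amplitude
rule (1° visual, 2° optogenetic — both rules are separate config entries);
NO-GO trials succeed by holding fixation for 2,000 ms. For pulse trains,
each saccade is assigned to the latest pulse preceding it by at least a
60-ms minimum reaction time (a physiological floor; configurable), giving
per-pulse latency groups.

## Problem sizes and reproducibility

The test suite and acceptance script run everything at desk scale as the
package's own validation design: a 200-frame 128×128 movie with 2-px
Gaussian motion for registration recovery (RMS error ≤ 0.5 px), 10,000
null replicates for the type-I calibrations, 500 replicates for
preferred-orientation recovery at 10% noise (median error ≤ 5°), 200 GO
trials and 10,000 fixation-only trials for the behavioral detector. Every
stochastic step takes an explicit integer seed; `run_pipeline()` records
seed and config hash in its manifest, and identical (config, seed) pairs
produce bit-identical outputs.

## Known limitations

Rigid translation only — no rotation, scaling or within-frame correction;
ROI means are unweighted with no neuropil subtraction (none is modeled);
no spike inference; the behavioral detector is positional, not
velocity-based, so it does not separate microsaccades from drift. The
behavioral accuracies, latencies and endpoint scatter observed in animals
are properties of the animals, not of this code; here they appear only as
generator defaults whose recovery the tests verify.
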