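---
title: "Detecting bursts in preterm EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bursts in preterm EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegburst)
```

## The problem

The EEG of very preterm infants (roughly 23–30 weeks gestational age) is
normally *discontinuous*: short stretches of higher-voltage activity
("bursts", also called spontaneous activity transients) alternate with
low-voltage quiescent periods ("inter-bursts"). The durations of these
periods — especially the inter-burst intervals (IBIs) — are markers of brain
maturation, and segmenting a recording into bursts and inter-bursts is the
first stage of most downstream automated analysis. Human annotation is
expensive and only moderately reproducible between experts, which motivates
an automated per-sample detector.

`eegburst` implements a multi-feature detector: each channel is described by
26 features of amplitude, spectral shape and frequency-weighted energy; a
linear support vector machine (SVM) combines the features selected by a
maximum-relevance minimum-redundancy (mRMR) filter plus a
backwards-elimination wrapper; a threshold and class-wise minimum-duration
rules turn the continuous discriminant into a binary segmentation.

## Signal model and feature set

Channels are processed independently (bursts can be focal; asynchronous
activity would be blurred by averaging across channels). The acquisition
rate is assumed to be 256 Hz; all features are delivered on a common 64 Hz
grid.

Four analysis bands are used throughout: 0.5–3, 3–8, 8–15 and 15–30 Hz,
tiling the total band 0.5–30 Hz. Band-limiting uses 5th-order Butterworth
filters applied forward–backwards (zero phase). Internally the designed
filter is factorised into second-order sections and transients are settled
on a constant pad sized by the slowest pole; a direct-form implementation of
the 10th-order band-pass polynomial is numerically ill-conditioned at 0.5 Hz
normalised to a 64 Hz rate, and would leak DC and break time-reversal
symmetry at the 1e-3 level.

The 26 features are:

* **Envelope** (4 bands, 1 s windows, median summary): squared magnitude of
  the analytic signal, `a(n) = |x(n) + jH[x(n)]|^2`. For a tone of amplitude
  A the envelope is A², so this is an instantaneous power measure.
* **Relative spectral power** (4 bands, 2 s windows): in-band DFT power over
  the 0.5–30 Hz total power. Band membership is half-open (`low <= f < high`)
  so the four bands partition bins exactly; the four values sum to 1.
* **Log–log PSD slope and r²** (4 bands each, 2 s windows): ordinary least
  squares of `log |X(k)|²` on `log f_k` over in-band bins. Inter-burst
  spectra are close to a straight line in log–log coordinates (power-law),
  burst spectra are not — the slope captures the exponent, r² the linearity.
* **Mean frequency** (4 bands, 2 s windows): circular (periodic) mean of the
  one-sided power spectrum with the half-spectrum mapped onto the full
  circle, so a pure tone recovers its own frequency. The circular form avoids
  the edge bias of a linear moment near band boundaries.
* **Instantaneous frequency** (4 bands, 2 s windows, median summary):
  central finite difference of the analytic-signal phase.
* **Higuchi fractal dimension** (1 feature, 0.5–30 Hz, 1 s windows): slope
  of log curve-length against log scale, `k_max = 8` (a 1 s window at 64 Hz
  leaves 8 usable scales; configurable). D is 1 for a smooth curve and
  approaches 2 for uncorrelated noise.
* **Envelope-derivative operator (EDO)** (1 feature): non-negative
  frequency-weighted energy operator,
  `Γ(n) = ¼[(x(n+1)−x(n−1))² + (h(n+1)−h(n−1))²]` with `h` the discrete
  Hilbert transform. A tone `A cos(ωn)` gives the constant `A² sin²(ω)`:
  energy weighted by frequency, vanishing at DC. The expanded quarter/half
  term form with the cross terms *added* instead (kept behind
  `cross_sign = "printed"`) peaks at DC and contradicts the operator's
  intended frequency weighting; the subtracting variant is the default.
  The EDO (like the NLEO and line-length baselines, which are implemented
  for comparison but are not part of the feature set) is sensitive to the
  sampling rate, so it is computed at 256 Hz after a 0.5–10 Hz pre-filter
  (1st-order Butterworth high-pass, 6th-order elliptic low-pass with 0.5 dB
  ripple and 50 dB stop-band), smoothed by a 1.5 s moving average, and only
  then decimated to 64 Hz. The moving average already defines its time
  support, so no additional 1 s framing is applied on top.

Windowed features use 75% overlap (hop = window/4). Each window's value is
held piecewise-constant over its central hop on the 64 Hz grid, with
nearest-window padding at the record edges — the simplest scheme that keeps
all columns aligned and NaN-free. Degenerate windows are mapped to neutral
values rather than NaN (flat log–log spectrum: r² = 1, a constant is a
perfect fit by a constant line; silent window: mean frequency falls back to
the band centre; constant window: fractal dimension 1).

Heavy-tailed energy features (EDO, envelopes, relative powers) are
natural-log transformed (floored at 1e-12 to keep silent segments finite),
then every feature is z-scored. The z-score parameters are always estimated
on training data only and applied unchanged to test records.

## Training, selection and post-processing

Training uses only every 500th defined sample of the feature stream (about
2.6 s spacing): neighbouring 64 Hz samples are nearly identical, so this
keeps the class distributions while making the SVM tractable. Testing always
uses every defined sample.

Selection is two-stage. The mRMR filter (difference form: relevance minus
mean redundancy, mutual information on 10 equal-frequency bins) reduces 26
features to 16 candidates. The wrapper then runs backwards elimination:
at each step it removes the feature whose removal maximises the mean
held-out AUC over inner leave-one-record-out folds, and finally returns the
best subset seen along the path (ties prefer the smaller subset, then
earlier alphabetical order). Inner-fold scoring uses every 10th defined
sample of the held-out record: scoring on the sparse 1/500 training grid
quantises the AUC so coarsely on separable data that ties collapse the
selection to singletons, while near-full-resolution scoring follows the
principle that testing uses all available data.

The linear-kernel SVM (`e1071`, C = 1, class-balanced weights, tolerance
1e-4) yields the discriminant `D[x] = Σ w_p x_p + b`, oriented so positive
means burst. Two thresholds are provided: static (0) and adaptive (the
record mean of D; invariant to constant shifts of the discriminant, but it
fails on continuous or inactive EEG, which is why static is the default).
Segments shorter than the class-wise 2.5th percentile of annotated segment
durations (linear-interpolation percentile, computed in seconds so the
label rate is irrelevant) are relabelled to the flanking class, shortest
first, bursts before inter-bursts on ties; edge-touching segments are
truncated rather than complete, so they are exempt. The operation is
idempotent.

Evaluation is nested: the outer leave-one-record-out loop holds one record
(one infant) out; z-scores, selection, SVM weights and duration limits are
all re-fitted per fold on the training records only. Reported metrics are
the sample-wise AUC (midrank ties), time-based sensitivity/specificity,
event-based sensitivity/specificity (an event counts as detected when
strictly more than 75% of its duration is covered, coverage pooled across
fragmented detections), Cohen's kappa with bias (|b−c|/n) and prevalence
(|a−d|/n) indices, and IBI summaries (median and maximum of complete,
non-edge inter-burst segments; burst ratio as percent of defined time).
Aggregates are medians with seeded 1000-iteration percentile-bootstrap 95%
CIs; paired comparisons use the Wilcoxon signed-rank test.

## The synthetic generator

Clinical preterm recordings cannot be shipped, so the package carries a
generator of discontinuous EEG that reproduces the *statistical* structure
the detector exploits:

* alternating burst/inter-burst segments with log-normal (right-skewed)
  durations, medians 5.7 s (burst) and 4.1 s (inter-burst), log-space SD
  0.75 — matching published duration statistics for this population;
* a shared coloured-noise background with log–log spectral exponent −2
  (near-linear log–log inter-burst spectrum), inter-burst RMS 10 µV;
* bursts as the background scaled by `burst_gain = 3`, plus a 3–15 Hz
  band-limited component with relative power `burst_bump = 0.15`, which
  bends the burst log–log spectrum away from a straight line. The bump is
  kept small: in real data the burst-to-inter-burst spectral ratio is
  largest at *low* frequencies, and a large mid-band bump would invert that;
* 0.25 s logistic cross-fades between segments, so no step discontinuity
  trivially cues the detector;
* a null construction (`burst_gain = 1`, `burst_bump = 0`) in which bursts
  and inter-bursts are statistically identical — any detector output better
  than chance on it would indicate leakage.

Simulated annotator pairs corrupt the ground truth by Gaussian boundary
jitter and random whole-segment label flips, supporting consensus and
inter-rater-agreement machinery end to end.

What the generator does **not** emulate: delta brushes and other
microstructure, inter-hemispheric asynchrony, artifacts, and — importantly —
the frequency *profile* of the burst/inter-burst contrast. The gain is flat
across frequency, so every envelope band carries the same mean contrast, and
the 0.5–3 Hz envelope (few degrees of freedom per 1 s window, hence the
noisiest envelope) is a mid-strength feature here, whereas on real preterm
EEG the low-frequency contrast dominates and that feature ranks first.
Passing the synthetic recovery experiments therefore demonstrates that the
pipeline finds and fuses the discriminative structure that is present — not
that feature rankings on real data would be reproduced.

## Problem sizes and numerical choices

The shipped experiments use 20 records × 600 s (record seeds 0–19) for the
main parameter-recovery run and 10 records × 240 s for the chance-level
control — the null case is the slow one for the SVM solver (heavily
overlapping classes), and 10 folds of 240 s give a stable median at chance.
The acceptance script uses 10 records × 300 s. These sizes were chosen as
the smallest runs whose medians are stable across seeds.

Other numerical choices: DFT windows are used raw (no taper) for the
spectral features, since the defining ratio is written directly on `X(k)`;
the Hamming-tapered Welch machinery is reserved for cohort-style PSD
summaries. DFT length equals the window length (no zero padding),
frequencies are mapped as `f_k = k fs/N`. Decimation 256→64 Hz applies a
zero-phase 6th-order Butterworth anti-alias filter at 0.9 × the target
Nyquist before taking every 4th sample. Detector state is serialised to
JSON with 17 significant digits, which round-trips IEEE doubles exactly.

## Known limitations

* The detector assumes largely artifact-free input; no artifact rejection
  stage is included.
* The adaptive threshold needs the whole record before it can be applied.
* Multi-channel records are processed strictly per channel; no cross-channel
  fusion or consensus of channel decisions is attempted.
* EDF support covers the continuous 16-bit single-rate subset of the format
  that the package itself writes.
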