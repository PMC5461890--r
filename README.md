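# eegburst

Multi-feature burst detection for the EEG of very preterm infants.

The EEG background of infants born before ~30 weeks gestation is normally
*discontinuous*: higher-voltage bursts (spontaneous activity transients)
alternate with low-voltage inter-burst intervals (IBIs). Segmenting a
recording into bursts and inter-bursts per sample is the first stage of
automated preterm EEG analysis — IBI statistics are maturation markers — but
expert annotation is slow and only moderately reproducible. `eegburst` is
for neurophysiology researchers and methods developers who need that
segmentation, its training machinery, and its evaluation metrics in one
place.

## Method

Each channel is described by 26 features on a common 64 Hz grid:

* band envelopes `a_i(n) = |x_i(n) + jH[x_i(n)]|²` in the four bands
  0.5–3, 3–8, 8–15 and 15–30 Hz (1 s windows, median summary);
* relative spectral power `P_i = Σ_{k∈i}|X(k)|² / P_total`, log–log PSD
  slope and fit r², periodic mean frequency and instantaneous frequency per
  band (2 s windows, 75% overlap);
* Higuchi fractal dimension over 0.5–30 Hz;
* the envelope–derivative operator
  `Γ(n) = ¼[(x(n+1)−x(n−1))² + (h(n+1)−h(n−1))²]`, a non-negative
  frequency-weighted energy measure computed at 256 Hz (NLEO and
  line-length baselines are included for comparison).

Features are log-transformed where heavy-tailed, z-scored with training-set
parameters, reduced by mRMR (mutual-information filter) plus a
backwards-elimination wrapper, and combined by a linear SVM
`D[x(n)] = Σ_p w_p x_p(n) + b`. A static (0) or adaptive (record-mean)
threshold and class-wise 2.5th-percentile minimum-duration rules produce the
final per-sample segmentation. Evaluation: sample-wise AUC, time- and
event-based sensitivity/specificity (strict >75% coverage rule), Cohen's κ
with bias/prevalence, IBI summaries, nested leave-one-out cross-validation
with bootstrap CIs. A synthetic generator of discontinuous EEG (log-normal
segment durations, power-law background, burst gain + 3–15 Hz excess) makes
the whole pipeline testable without clinical data.

## Worked example

```r
library(eegburst)

# ten minutes of synthetic discontinuous EEG with ground truth
gen <- generate_record(synthetic_config(duration_s = 600, seed = 1))
gen$annotation
#> <annotation> 600.0 s @ 256 Hz: 55.2% burst, 44.8% inter-burst, 0.0% undefined

# a small cohort, a trained detector, and detection on a held-out record
sset <- lapply(0:4, function(s)
  generate_record(synthetic_config(duration_s = 300, seed = s)))
det <- train_detector(lapply(sset[-1], `[[`, "record"),
                      lapply(sset[-1], `[[`, "annotation"))
det
#> <trained_detector> 6 features, static threshold, limits 1.36/0.72 s
#>   features: env_b1, env_b2, env_b3, r2_b3, rpsd_b1, slope_b4

found <- detect_bursts(sset[[1]]$record, det)
ref <- resample_annotation(sset[[1]]$annotation, 64,
                           n_out = length(found$labels))
evaluation_report(found, ref, decision = attr(found, "decision"))
#> <evaluation_report> AUC 0.999 | time 97.7/98.5% | event 92.0/100.0% | kappa 0.96
#>   IBI median 5.38 s, max 13.00 s, burst ratio 53.8%
```

The detector reaches near-perfect sample-wise AUC on this synthetic cohort
(the burst/inter-burst contrast is a 3× amplitude gain plus a mid-band
spectral excess); the IBI line summarises the detected segmentation — the
numbers that matter clinically. `nested_cv()` runs the full leave-one-record-
out protocol in which selection, weights and limits are refitted per fold.

A command-line front end for shell use ships under `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/eegburst.R", package="eegburst"))')" \
  simulate --out data --n 3 --duration 300 --seed 7
```

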