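---
title: "valvecg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{valvecg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model, the
label construction, the synthetic cohort that stands in for clinical data,
and the numerical and design choices a maintainer would want written down.

## 1. The discrete-time survival model

Let the follow-up axis be partitioned by edges
$0 = t_0 < t_1 < \dots < t_K$ (the last interval open). For a subject with
hazard vector $h = (h_1, \dots, h_K)$, $h_k$ is the conditional probability
of first progression to moderate-or-severe regurgitation inside interval
$k$, given survival to its start. The likelihood of an observed label is a
product of Bernoulli terms over the *observed* intervals only:

$$\mathcal{L} \;=\; \prod_{k\,\text{observed}} h_k^{y_k} (1-h_k)^{1-y_k}.$$

Censoring is handled by masking: intervals that the follow-up does not
fully cover contribute nothing to the loss or its gradient — the masking
property is verified by tests that flip labels under the mask and assert
bit-identical losses.

**Prevalent-disease encoding.** The first interval spans the 60-day
ECG–echo pairing window. A paired echo with a moderate-or-severe grade sets
$y_1 = 1$ and masks all later intervals; hence $h_1$ acts as a diagnosis
score while $1-\prod_{k \in (60\text{d},5\text{y}]}(1-h_k)$ is the 5-year
progression risk. The baseline interval's hazard is deliberately excluded
from the 5-year risk: prediction is conditional on no prevalent disease,
matching the evaluation protocol in which prevalent patients are removed
from prediction tasks. ECGs with *no* echo inside the pairing window keep a
masked first interval but still contribute their follow-up intervals —
this is why the survival head trains on more ECG–echo pairs than the
binary classification head, which only sees baseline-window pairs.

**Interval grid.** Default edges are 0, 60 d, 1–5 y yearly, then open:
seven intervals. The grid is configurable (`default_interval_edges()`); the
first timepoint is aligned with the 60-day diagnosis window and the 5-year
horizon used for prediction read-outs. Whether the first "timepoint" should
span exactly the pairing window is not derivable from the protocol we
emulate; aligning the two is this package's choice.

**Labels from tables.** An incident event is the first follow-up echo with
a grade of at least moderate; its time is measured from the ECG date. A
later grade regression (moderate back to mild) does not undo the first
qualifying echo. A significant grade recorded *before* a non-significant
baseline pair is flagged as a data inconsistency and the row is fully
masked rather than guessed about. For ECGs without a baseline echo whose
patient already had a significant echo earlier, the disease is treated as
prevalent (grades are assumed not to regress below moderate); on the
synthetic cohort this assumption is exact.

## 2. The network

A residual 1-D CNN: a strided stem convolution, then residual blocks (two
convolutions plus a strided 1×1 projection skip), ReLU activations,
inverted dropout, global average pooling, and a linear head with one logit
per interval. Two profiles:

| profile | input | channels | kernel | dropout | use |
|---|---|---|---|---|---|
| `default` | 12 × 4096 @ 400 Hz | 32, 64, 128, 196, 256 | 17 | 0.2 | full-scale rendition |
| `tiny` | 12 × 1000 @ 100 Hz | 16, 24, 32 | 9 | 0.1 | CPU training, tests |

The `tiny` input is the standard 400 Hz/4096 output low-passed at 40 Hz,
decimated by 4 and centre-cropped — the morphology that carries the signal
(QRS width, P amplitude, T polarity) survives at 100 Hz.

Optimization is mini-batch Adam (lr $10^{-3}$, batch 64) with model
selection on tuning-set loss, early stopping (patience 5) and
learning-rate halving on plateau (patience 2); all RNG (initialization,
shuffling, dropout) flows from one integer seed through a dedicated
generator, so training is bit-reproducible. The depth, widths, optimizer
schedule, and interval count are configuration with documented defaults,
not claims about the original training recipe, which is not public.

**Head initialization.** Head weights start at zero and head biases at the
logit of the per-interval training base rates. Without this, the first
optimizer steps — dominated by the mean "push all hazards down" gradient —
suppress outputs in proportion to input energy, and short runs sit in a
transient where predictions anti-correlate with high-energy (broad-QRS)
inputs. Prior-logit initialization removes the mean gradient at step one;
it is standard practice in imbalanced detection models.

Gradients of every layer are checked against central finite differences at
$10^{-5}$ relative tolerance in the test suite; convolutions are im2col +
GEMM with exact adjoints.

## 3. The synthetic cohort

The generator emulates the *structure* of hospital ECG–echo cohorts: per
patient, a latent remodelling factor $z \sim N(0,1)$ sets resting
morphology — QRS width $95 + 18z$ ms, P amplitude $0.12 - 0.03z$ mV, QRS
amplitude $1.1 + 0.15z$ mV, T inversion more likely at high $z$ — and the
per-valve progression hazard is log-linear in the *standardized* morphology
(default coefficients $+0.5$ per SD of QRS width, $-0.5$ per SD of P
amplitude) plus a lognormal frailty (SD 0.25). Event times are exponential
with that constant per-patient hazard, so closed-form survival functions
serve as test oracles. Overt disease expresses an additional
conduction-type signature (QRS +25 ms, higher QRS amplitude, T inversion)
that ramps in over the 3 years before the event — deliberately *not* a
scaled copy of the subclinical signature, mirroring the distinction between
established-disease morphology and early remodelling.

Defaults emulate reported cohort structure: baseline prevalence 5.5 / 3.1
/ 5.3 % (MR/AR/TR), annual progression hazards 2.0 / 0.8 / 2.2 %/y (about
3.4 / 1.5 / 4.0 % over a median two-year follow-up), age 56 ± 15, 54 %
male, ~2 ECGs per patient, echo surveillance every 180 days with ±20 %
jitter, exponential loss to follow-up (0.10/y) truncated at 8 years, 3 %
of patients carrying the surgery/prosthesis/device exclusion flag. The
prevalence intercept is calibrated per cohort so the realized prevalent
fraction equals the configured one. Where the emulated protocol publishes
no value (echo interval, censoring rate, ECG count per patient), the
defaults are conventions chosen once, not estimates.

Waveforms are sums of Gaussian bumps (P, Q, R, S, T) at a heart rate
sampled from 50–100 bpm, with per-lead amplitude scaling, additive white
noise ($\sigma = 0.02$ mV) and sub-0.5 Hz sinusoidal baseline wander —
simple, controllable, and enough to exercise every pre-processing stage.
What passing tests on this cohort *do* show: the pipeline recovers a
planted morphology–hazard coupling end to end, labels reconstruct the
generative truth exactly, and the metrics are correct against oracles.
What they *cannot* show: performance on real ECGs with arrhythmia,
artefact, pacing, or morphology–risk relationships outside this family.

## 4. Signal processing

The emulated chain names only cutoffs, so realizations are design
decisions: a 4th-order Butterworth bandpass (0.5–100 Hz) and an RBJ biquad
notch (quality factor 30; 60 Hz default, 50 Hz selectable), both applied
forward–backward for zero phase; polyphase rational resampling with a
Kaiser-windowed sinc anti-alias FIR (symmetric, hence delay-free) to
400 Hz; tail zero-padding / centre-cropping to 4096 samples so each sample
keeps its time meaning. Designed responses are verified directly: ≥ 20 dB
attenuation at the notch, ≤ 1 dB at 10 Hz, and exact output geometry.
Poor-quality ECGs are not excluded anywhere; non-finite samples are zeroed
with a warning.

R peaks come from a Pan–Tompkins-style detector (QRS-band filter,
derivative, squaring, 150-ms integration, adaptive threshold at 35 % of
the 98th percentile, 250-ms refractory period, refinement to the largest
absolute deflection within ±60 ms) on lead II, falling back to the
maximal-energy lead; the emulated protocol delegates this to external
software, so the algorithm here is the package's own and is validated
against planted peak locations (±10 ms). Median beats use a 600-ms window
(200 pre-R / 400 post-R), cross-correlation alignment within ±50 ms
against the first beat, and a per-sample median; fewer than three usable
beats is an error, and a single artefactual beat cannot move the median.

## 5. Evaluation choices

* Harrell's C: usable pairs need distinct observed times with an event at
  the earlier one; score ties count ½; tied times are excluded. Verified
  to $10^{-12}$ against an $O(n^2)$ oracle and `survival::concordance`.
* AUROC is midrank Mann–Whitney; DeLong variance/tests are written out and
  cross-checked against `pROC`.
* Quartile cutpoints: linear-interpolation (type-7) quantiles computed on
  the tuning set and frozen; degenerate cutpoints collapse groups with a
  warning. Hazard ratios come from `survival::coxph` (Efron ties) with age
  and sex adjustment.
* Brier score and continuous NRI at a horizon use determinate-status
  subjects only (event by the horizon, or followed past it); subjects
  censored earlier are excluded rather than inverse-probability weighted —
  a transparency-over-efficiency choice, flagged as a potential difference
  from the emulated analysis. IPCW is a possible extension.
* Bootstrap CIs are percentile, patient-level, seeded; 2000 replicates by
  default (tests use 200 to stay within their time budget, and verify
  92–98 % empirical coverage at n = 500).
* Nested Cox models are compared by likelihood-ratio test; its type-I
  error is verified by simulation. Competing-risk (Fine–Gray) models and
  the partial likelihood-ratio test for non-nested models are out of
  scope; the comparison API reports them as not computed.

## 6. Explainability

The VAE is fully connected (one tanh hidden layer of 64 each side),
diagonal Gaussian posterior, linear Gaussian likelihood on internally
standardized beats, $\beta = 1$, latent dimension 8 for the test-scale
beats (30 is a reasonable default at scale; the emulated architecture is
not public). Latent ranking regresses the prediction on all posterior
means and sorts by $|t|$; posterior means rather than samples keep the
ranking deterministic. Traversal decodes the cohort-central code sweeping
one coordinate ±3 posterior-mean SDs in 7 steps. Extreme-group averaging
scales its group size down automatically on small cohorts (the full-scale
default of 10 000 is cohort-sized). QRS width of an averaged beat is
measured as the contiguous span above 20 % of the dominant deflection.

## 7. Problem sizes used by the tests

The acceptance-style tests train the `tiny` profile on a cohort of 1000
patients (≈ 2000 training/tuning ECGs after the 50/10/40 patient split),
18 epochs — sizes chosen so the whole suite runs on one CPU in well under
half an hour while leaving the planted signal comfortably detectable.
Statistical calibration uses 1000 likelihood-ratio replicates at n = 150
and 500 bootstrap-coverage replicates at n = 500.

## 8. Known limitations

* On this simulator the survival and classification heads tie for the
  prediction C-index at matched seeds (the ordering test passes within its
  stated tolerance): a single latent factor drives both prevalence and
  hazard, so the baseline-window label already carries nearly all
  progression information. Real cohorts, where the two heads differ
  materially, have richer risk structure than this generator.
* The generator's constant per-patient hazard cannot express
  time-varying risk within a patient beyond the pre-event morphology ramp.
* The WFDB support covers format 16 single-segment records as written by
  this package, not the full header grammar. Tensor and median-beat
  archives are plain CSV; a hierarchical binary store would be preferable
  at full scale.
* Median-beat extraction assumes a dominant, roughly periodic QRS; heavy
  arrhythmia or paced rhythms are out of scope.
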