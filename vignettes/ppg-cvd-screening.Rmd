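---
title: "Two-stage CVD screening from PPG time-domain features: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage CVD screening from PPG time-domain features: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Photoplethysmography (PPG) measures blood-volume changes in the
microvascular bed with a cheap optical sensor; each heartbeat produces one
pulse wave. The shape of that pulse carries vascular information: stiff or
obstructed arteries attenuate the reflected (diastolic) wave, flatten the
dicrotic notch, and slow the systolic upstroke. This package implements a
screening pipeline that turns per-beat pulse morphology into a
subject-level classification: first healthy vs cardiovascular disease
(CVD), then — for subjects flagged as diseased — a five-way typing among
acute coronary syndrome (ACS), cerebrovascular accident (CVA), deep vein
thrombosis (DVT), heart failure (HF) and atrial fibrillation (AF).

Because no public dataset accompanies the protocol the pipeline mirrors
(the clinical recordings are private), the package ships a synthetic
cohort generator with analytic ground truth. All empirical claims in the
test suite are claims about that generator's output, not about clinical
data; the generator's role is to make every stage of the pipeline
*auditable*, not to substitute for patients.

# The synthetic cohort generator

## Waveform model

A beat is the sum of two Gaussian-shaped components on $[0, T)$:

$$p(t) = A_s e^{-(t-c_s)^2/2w_s^2} + A_d e^{-(t-c_d)^2/2w_d^2},$$

a systolic ejection wave $(A_s, c_s, w_s)$ and a diastolic reflection wave
$(A_d, c_d, w_d)$, $c_s < c_d < T$, $A_d \le A_s$. This is the simplest
shape that exhibits every landmark the feature catalogue needs — onset,
systolic peak, dicrotic notch (the local minimum between the components),
diastolic peak, end — while keeping them analytically recoverable: the
ground truth locates peak and notch by dense-grid search with parabolic
refinement on the *continuous* model, so detector errors can be measured
in fractions of a sample.

A notch whose depth below the diastolic peak is less than 1% of the
systolic amplitude is recorded as *absent* in the ground truth: such a dip
is far below any realistic measurement resolution and the pulse is, for
every practical purpose, a shoulder-type wave. Landmark times are
invariant under uniform amplitude scaling and under period changes, which
lets one landmark search serve all jittered copies of a subject's beat.

## Study conditions

The default configuration *is* the emulated study: 200 healthy subjects
and five CVD classes (ACS 63, CVA 50, DVT 23, HF 13, AF 13; the stated
total of 360 and the per-class counts, which sum to 162 CVD subjects,
disagree in the source protocol — the per-class counts are taken as
authoritative, giving 362), each recorded for 120 s at 120 Hz, the output
format of a fingertip pulse oximeter.

Per-class morphology priors encode the qualitative physiology reported
for CVD pulses, with magnitudes chosen once as physiologically plausible
(no per-class waveform statistics exist to calibrate against):

* **Healthy**: tall diastolic wave ($A_d = 0.45$), clear notch, period
  0.85 s.
* **ACS / CVA / DVT**: attenuated diastolic wave (0.22 / 0.28 / 0.32),
  longer crest time, class-specific periods (0.80 / 0.90 / 0.78 s).
* **HF**: weakest pulse ($A_s = 0.75$), near-absent diastolic wave
  (0.12, mostly a shoulder), slow rhythm (1.0 s).
* **AF**: fast rhythm (0.70 s), attenuated diastolic wave (0.20).

Between-subject variation is Gaussian on every parameter (sds in
`default_class_morphology()`); within-subject disturbances are period
jitter (sd 0.02 s), per-beat amplitude jitter (5%), a 0.25 Hz sinusoidal
respiratory baseline drift (amplitude 0.2 a.u., inside the band the
filter removes) and white noise (sd 0.01 a.u.). Demographics follow
per-class priors: CVD classes are older (means 55–72 vs 35 years), more
hypertensive, smoke more, exercise less; HF depresses SpO2 (mean 92%).
Weight is derived as BMI × height² so the BMI identity holds exactly.

What the generator does **not** emulate: motion artifacts beyond baseline
drift, sensor saturation, arrhythmic beat-to-beat morphology change
(AF gets a faster, jittered rhythm but each beat keeps the subject's
shape), and any realistic hemodynamic coupling (no Windkessel model).
Passing tests therefore show the *pipeline* is sound — they do not show
the classifier would reach these accuracies on clinical data. The
separation between classes in the default configuration is deliberately
strong; it is an achievability benchmark, not a clinical simulation.

# Preprocessing

The band-pass is an elliptic (Cauer) design with the stated edges
0.6–15 Hz at $f_s = 120$ Hz: the lower edge removes respiration and
baseline drift, the upper edge removes wide-band noise. Order (4),
pass-band ripple and stop-band attenuation (40 dB) are free design
parameters. The filter is applied forward–backward (`signal::filtfilt`),
so the phase is exactly zero and no timing feature is delayed; the cost is
that the magnitude response applies twice. For that reason the default
pass-band ripple is 0.1 dB rather than a more conventional 0.5 dB: the
squared response doubles the ripple in dB, and the resulting harmonic
re-weighting measurably displaces shallow dicrotic notches (about 1.5
samples at 0.5 dB, about 0.5 at 0.1 dB on the AF-class morphology).
A side effect of any finite elliptic design worth knowing: DC is *not* a
true zero — it sits on the equiripple stop-band floor (−40 dB here).

Beat segmentation is peak-first: systolic peaks are prominence-thresholded
maxima (threshold 0.3 × IQR of the filtered signal), candidates below half
the median candidate height are discarded (after band-passing, diastolic
peaks sit far below systolic ones — this prevents a late diastolic wave
from being read as an extra beat), and peaks closer than the minimum beat
duration (0.33 s, i.e. 180 bpm) are suppressed in favour of the taller
one. The onset separating two beats is the minimum of the inter-beat
valley, taken at the valley's **right edge** — the last sample within 1%
of the valley minimum. In slow rhythms the diastolic runoff flattens and
the literal minimum wanders with residual ripple by up to ~10 samples;
the right-edge rule is stable to ~1 sample. The cost is a small constant
convention offset (~5 samples) between the detected onset and the
generative beat boundary, visible only in crest-time comparisons against
ground truth; peak and notch times are unaffected. Beats outside
0.33–2.0 s (30–180 bpm) or with a peak rise below 10% of the record's
median are rejected.

# Fiducial detection

* **Systolic peak**: global maximum of the beat, first sample on ties; a
  maximum on the beat boundary is a malformed beat.
* **APG**: the acceleration plethysmogram is the smoothed second
  derivative, computed with a Savitzky–Golay filter (order 3, 11-sample
  window at 120 Hz; the window shrinks, with a warning, for very short
  beats). Plain finite differences would amplify noise quadratically in
  frequency. The `a` wave is the first prominent APG maximum, `b` the
  first prominent minimum after `a`, `e` the first prominent maximum after
  the systolic peak (prominence threshold: 5% of the APG range). An `e`
  candidate is accepted only if a local APG minimum follows it — the dip
  is the diastolic wave's negative curvature, and without it the
  "maximum" is just the decaying tail of a single-component pulse.
* **Dicrotic notch**: primary rule — the lowest local minimum of the beat
  within 40% of the pulse interval after the systolic peak (a conventional
  physiological bound), with a prominence floor of 0.5% of the beat range
  so residual filter ripple cannot fabricate micro-notches. Fallback —
  the APG `e` wave, which marks the notch on shoulder-type pulses where no
  signal minimum exists. If both fail the notch is absent: a valid
  outcome, and all notch-dependent features are missing for that beat.

# The 24 features

Per beat: systolic amplitude SA, peak-to-peak interval ΔT (to the next
accepted consecutive beat; pairs spanning a rejected beat are dropped),
pulse interval, crest time CT, pulse width PW (width at half the systolic
amplitude, sub-sample interpolated), notch amplitude, systolic time
(onset→notch), diastolic time (notch→end), pulse transit time PTT
(peak→notch), total area, inflection point area ratio IPA
(diastolic/systolic area, split at the notch), AI of amplitude
(SA−notch)/SA, reflection index RI notch/SA, AI of time PTT/pulse
interval, stiffness index SI = height/PTT (m/s), the time ratios
T1 = CT/ΔT, T2 = systolic time/ΔT, T3 = PTT/ΔT, and the APG quantities
a, b, e, b/a, e/a, (b−e)/a.

Conventions that the source protocol leaves open, fixed here:

* **Baseline**: per-beat, the amplitude at onset. Amplitudes and areas are
  measured above it (filtering removes drift, not per-beat offsets).
* **Systolic time**: defined as onset→notch, which makes
  systolic time = CT + PTT and hence T2 = T1 + T3 exact algebraic
  identities — both are tested to 1e−9.
* **SI units**: height in metres over PTT in seconds.
* **Aggregate dispersion**: the stored aggregate is the sample *variance*
  (n−1); a display layer can take square roots if standard deviations are
  preferred.
* **Pulse rate**: the device-reported value is used as the feature; a
  derived 60/mean(ΔT) estimate is kept alongside for cross-checking
  (correlation ≈ 0.97 on the default cohort).

Aggregation is feature-wise over the beats where each feature is defined
(missing notches simply reduce that feature's n); subjects need at least
5 valid beats, and the per-subject notch-presence fraction is retained.

# Statistics and classification

The univariate screen is a Welch two-sample t-test per subject-level
column, healthy vs pooled CVD, α = 0.05, uncorrected — matching the
screening protocol this mirrors — with a Benjamini–Hochberg column
alongside. Welch rather than pooled-variance because the groups are
unequal (200 vs 162) with no variance-equality justification.

Feature selection is a greedy stepwise *wrapper*: forward search adds, at
each step, the feature that maximises the 10-fold cross-validated accuracy
of the wrapped classifier, stopping when no addition improves it (strict
improvement, tolerance 0); backward search removes symmetrically. Ties
break by candidate order (feature declaration order, then demographics),
making the search deterministic given the fold seed. The same folds are
reused across all candidate evaluations within a search so accuracies are
comparable.

Seven classifier families are provided: a pruned decision tree (rpart),
random forest (100 trees), Gaussian naive Bayes (with a per-class sd floor
so constant-in-class features cannot produce degenerate densities), a
one-hidden-layer perceptron (nnet, hidden size (p + classes)/2 capped at
20, 500 epochs, standardized inputs), 1-nearest-neighbour (standardized),
and two rule learners written in-package: a RIPPER-style
sequential-covering inducer (classes from rarest to most frequent,
rules grown greedily by Laplace-corrected precision over quantile
thresholds) and a PART-style variant (each rule targets the majority class
of the still-uncovered rows). The rule learners exist because no
maintained R implementation of those families was available to build on;
they are deliberately simple and their role in the analysis is
comparative.

The cascade: stage 1 classifies healthy vs CVD on feature means +
variances + demographics; stage 2 types the disease among CVD subjects on
feature *means* + demographics only (the five-class search space is
larger, so the variance columns are dropped — stage 2's schema actively
rejects them, and Healthy rows, rather than silently filtering). A
subject predicted healthy by stage 1 exits the cascade; the rest get a
stage-2 label.

## Class imbalance and leakage

Minority classes are rebalanced by whole-subject replication
(⌈n_max/n_c⌉ copies, truncated to n_max). *When* to replicate matters:
replicating before cross-validation places copies of one subject on both
sides of a fold split, which leaks and inflates accuracy. The default is
therefore `replicate-train-only` (replication inside each training fold;
an audit verifies zero shared subject ids between any train/test
partition), with `replicate-global` available for comparability with
protocols that balance up front. On the default cohort the global mode
inflates stage-2 naive-Bayes accuracy by several points and the audit
shows every minority subject shared.

Missing feature values (absent notches, last-beat ΔT) are imputed with
training-fold medians, computed per fold.

# Numerical choices and degenerate inputs

Fold assignment is stratified (per-class round-robin over shuffled
indices) and seeded; every stochastic step (generator, folds, forest,
perceptron) flows from an explicit seed, and identical seeds give
byte-identical results. Degenerate cases are classed errors, not silent
results: flat signals raise a no-beats error, monotone beats a
malformed-beat error, sub-5-beat subjects a subject-excluded error,
stage-2 schema violations a schema error; t-test groups with fewer than
two finite values are skipped with a warning, and two constant groups
yield t = 0, p = 1 (equal means) by convention.

# Problem sizes used by the checks

The packaged checks run at the following sizes, chosen to make the
properties measurable with comfortable margins: fiducial recovery on a
noise-free 60-subject cohort (10 per class, 120 s at 120 Hz, ~8,600
beats); formula identities on 1,000 random beats drawn across all class
priors; selection soundness over 20 seeded datasets (n = 100, one
informative feature at 2 sd, 10 noise features); t-test calibration over
200 null replicates of 10 features (2,000 tests); and the full two-stage
evaluation on the default 362-subject cohort.

# Known limitations

* Synthetic separability is by construction; accuracy figures are
  achievability checks, not clinical estimates.
* The onset convention (valley right edge) introduces a constant few-sample
  offset in crest time relative to the generative beat boundary; all
  peak-referenced timings are unaffected.
* The amplitude features inherit a small (≲3%) bias from pass-band
  distortion of the doubled elliptic response.
* The rule learners are minimal sequential-covering implementations; no
  incremental reduced-error pruning or MDL stopping.
* The `e`-wave fallback places the notch at the APG maximum, which on
  true shoulder pulses sits earlier than the (unresolvable) inflection
  midpoint; notch-timing features on shoulder beats are correspondingly
  approximate.
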