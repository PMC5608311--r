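---
title: "Predicting couple-therapy outcomes from speech acoustics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting couple-therapy outcomes from speech acoustics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dyadvox)
```

## The problem and the data model

Couples in distressed relationships are recorded during 10-minute
problem-solving conversations at three timepoints: before therapy, after 26
weeks, and after 2 years. Each session comprises two interactions, one on a
topic chosen by the husband and one chosen by the wife. A clinical outcome
rating on a 4-level scale (1 deteriorated, 2 no change, 3 improved, 4
recovered) is attached to each (pre, post) session pair, so a couple
contributes up to two *outcome samples* — one per follow-up horizon — and
both samples share the identical pre-therapy session data (stored by
reference, never copied). The reference outcome mix used throughout the
package's data-independent checks is 12/26/34/67 across the four classes
(139 samples); note that the corpus description this mix derives from also
quotes a total of 141 samples, which does not match the per-class counts —
the package follows the counts, whose implied majority-class chance rates
(51.8%, 47.2%, 48.2%) are internally consistent.

Audio is mono far-field 16 kHz, 16-bit PCM. Interval conventions are
half-open `[start, end)` seconds; couples with only one of the two topic
interactions at a timepoint are excluded from sample assembly, because the
fixed-length feature vectors below require all four interactions.

## Pre-processing

**Voice activity detection.** An energy plus spectral-flatness detector:
a frame is speech when its energy exceeds an adaptive threshold (at least
`vad_offset_db` = 15 dB above the observed floor and within
`vad_dynamic_range_db` = 40 dB of the peak) and its spectral flatness
(geometric over arithmetic mean of the power spectrum) is below 0.5. Gaps
under 0.2 s are bridged, segments under 0.1 s dropped. This detector is a
deliberately simple, self-contained design: it needs no training data,
behaves deterministically, and its translation equivariance is tested.

**Speaker segmentation and clustering.** Within speech regions, candidate
speaker changes are scored by the generalized likelihood ratio between "two
full-covariance Gaussians" and "one merged Gaussian" over adjacent 1.0 s
windows of 15 MFCCs, sliding at 0.1 s. The decision threshold (107) was
calibrated once on stationary synthetic Gaussian input to a 5% false-alarm
rate per 30 s and then frozen; a 5-SD mean shift scores roughly five times
the threshold, so power is not delicate. Speaker-homogeneous segments are
then merged by agglomerative clustering under the GLR merge cost until two
clusters remain. Ties break toward the earliest segment.

**Role assignment.** The cluster with the higher mean voiced pitch becomes
the wife (`W`); a tie (exactly equal means) assigns the earlier cluster to
`H` with a warning. Turns are built by merging same-role segments across
gaps under 0.3 s and dropping turns under 0.2 s — the operational definition
of "turn" is ours, since the construct is otherwise under-specified.
Diarization error rate (missed + false alarm + confusion over reference
speech time, best global role mapping) is the evaluation metric; on
schematic rendered audio it sits around 1%, which validates the machinery
but says nothing about real far-field recordings.

## The 74 frame-level features

The inventory is 37 base features and their derivatives: 15 MFCCs (c1–c15
from a 26-filter mel bank; c0 is excluded as redundant with intensity), 8
log mel filterbank energies (a separate 8-band bank), 8 line spectral
frequencies from order-8 linear prediction, intensity (dB), pitch (Hz),
loudness, jitter, shimmer, and harmonics-to-noise ratio. The reference
feature count of 74 is not itemized in the corpus documentation this design
descends from; this decomposition is the natural reading that reaches
exactly 74 with loudness included among the prosodic features, and it is
configurable. Mel filters
are area-normalized so that a flat spectrum yields equal band energies — a
property the tests rely on.

Analysis runs on 25 ms Hamming windows at a 10 ms hop. Specific choices
worth knowing:

* **Pitch**: autocorrelation method over a 40 ms window, search range
  75–500 Hz (both sexes), with the power spectrum low-passed before the
  autocorrelation so that candidate peaks are smooth enough for 3-point
  parabolic interpolation; a small octave cost (0.02 per octave) penalizes
  longer-period candidates. Voicing requires a normalized autocorrelation
  of at least 0.45. Synthetic harmonic signals are recovered within 1%
  across 90–400 Hz. Unvoiced frames carry `NA` — never 0 — in pitch,
  jitter, shimmer, HNR and their derivatives; zero-filling would bias every
  delta downstream.
* **Loudness**: sum over the 26 mel bands of (band energy)^0.3, a standard
  perceptual compression; no more specific definition is available for this
  quantity, so the exponent-0.3 power sum is declared here.
* **Jitter/shimmer**: computed over a ±5-period window per voiced frame.
  The segment is matched-filtered with a zero-phase Hann-windowed cosine at
  the expected period; local periods are read from the Hann-unbiased
  autocorrelation of that band at one-period spacing (parabolic
  interpolation), and jitter is the mean absolute consecutive period
  difference over the mean period. Shimmer uses per-cycle RMS amplitudes
  over one median period with fractional-sample end weighting, which is
  phase-robust for arbitrary waveforms. On clean sawtooths both measures
  stay below 0.005; period-averaging means rapid cycle-to-cycle
  perturbations are somewhat smoothed, which we accept for stability.
* **HNR**: `10 log10(r / (1 - r))` at the chosen period's normalized
  autocorrelation.
* **Derivatives**: 5-point regression slopes (±2 frames), missing-aware
  (slopes over the non-missing frames in the window); with fewer than 5
  frames the window shrinks.

## Functionals

The statistic set is {mean, median, SD, min, max, IQR}. Six is forced by
the reference static dimension 3552 = 74 features × 6 statistics × 2
speakers × 2 topics × 2 timepoints; the set itself is the minimal standard
choice containing the three statistics that are named explicitly. SD is the
population form so a single observation gives 0, not `NA`. The canonical
vector ordering is timepoint-major, then topic, speaker, feature, statistic,
and is written to a sidecar registry so vectors are byte-comparable.

* **Static**: the six statistics of each feature over a speaker's frames in
  one interaction (444 values per speaker-interaction).
* **Short-term dynamic**: per-turn feature means (turns with under 3 frames
  dropped), then deltas between adjacent turns — husband→husband (skipping
  intervening wife turns), wife→wife, and husband→wife at each adjacency.
  Wife→husband deltas are omitted: they are the HW deltas with the sign
  reversed. The six statistics of each delta sequence per (timepoint,
  topic) give 74 × 3 × 6 × 4 = 5328 values. Computing them per timepoint
  and topic (rather than pooled) is our resolution of an ambiguity.
* **Long-term dynamic**: per interaction, features are z-normalized over
  both spouses' speech frames pooled (per-spouse normalization is a config
  option; degenerate SD 0 maps to 0), the pooled speech frames are split
  into four equal-count quarters — equal frame count, not wall-clock,
  since silence is already removed — and the functional is the post-minus-
  pre difference of per-quarter per-spouse means: 74 × 4 × 2 = 592 per
  topic, 1184 per sample. Session-level normalization makes these deltas
  invariant to per-session affine rescaling of any feature, i.e. to
  recording-condition mismatch between sessions, and the construction is
  antisymmetric under pre/post swap — both are tested properties.

The full dynamic set is 5328 + 1184 = 6512 dimensions under defaults. The
reference dynamic dimensionality (6696) and combined dimensionality are
not decomposable from any stated construction, so the package documents
its own sizes rather than forcing those numbers; the code-vector (264) and static
(3552) dimensions match exactly.

**Behavioral codes**: 33 dimensions (20 SSIRS + 13 CIRS), rated 1–9 by 2–9
annotators per interaction, averaged per cell. The 264-dimensional code
vector (33 × 2 spouses × 2 topics × 2 timepoints) implies codes are
assigned per 10-minute interaction; that is the only reading consistent
with the dimension, and it is adopted. Agreement is interval-metric
Krippendorff's alpha, missing-tolerant; both the pooled form and the
per-code-then-averaged form are returned, since either convention is
defensible for summarizing corpus-level agreement.

## Feature relevance and selection

For interpretation, the outcome is binarized (recovery, rating 4, vs the
rest) and Pearson's r with a two-tailed t-test (n − 2 df) is computed per
feature; the report keeps, per base acoustic feature, the functional with
the largest |r|. For prediction, features are scored by plug-in mutual
information with the class label after equal-frequency discretization into
10 bins (order-statistic quantile breaks, so scores are invariant under
strictly monotone transforms; a column with at most 10 distinct values is
binned by value). The bin count is a documented choice: the MIM
criterion itself does not fix an estimator for continuous features. The selected count k is chosen per training fold by
inner 5-fold CV over {5, 10, 15, 20, 25}% of the dimension — a grid
consistent with the reported selected fractions. Ties in scores break
toward the lower canonical index.

## Classification experiments

Three tasks: (1) recovery vs non-recovery on all samples; (2) ratings 1/2/3
on the non-recovered subset (by construction exactly experiment 1's
negative class); (3) all four ratings. The classifier is an RBF-kernel SVM;
multiclass uses one-against-all with margin-argmax and ties resolved toward
the lowest rating. Cross-validation is 10-fold with both samples of a
couple always in the same fold (no leakage through shared pre-sessions);
fold draws are re-attempted until every training split contains every
class. Within each outer fold, in order: median imputation, z-score
normalization, MIM selection with inner-CV k, and a (C, γ) grid search over
C ∈ {1, 10, 100, 1000, 10000} × γ ∈ {1e-4, …, 1} by inner 5-fold CV (ties:
smallest C, then smallest γ; degenerate inner splits fall back to 3-fold) —
all fitted on the training split only. Whether normalization should precede
or follow the fold split is the classic leakage ambiguity;
training-fold-only fitting is the stricter reading and precludes leakage,
which instrumentation enforces: every fitted statistic records the sample
ids it touched, and tests assert the intersection with test ids is empty.
Class imbalance is deliberately left unhandled so chance comparisons stay
honest. Grid search nested per fold (rather than global) is likewise our
choice.

Evaluation reports mean and SD over folds of accuracy and macro-averaged F1
(macro chosen for imbalance sensitivity; the averaging convention is
otherwise unstated). Feature sets are compared by a two-tailed exact
binomial test on the discordant pooled out-of-fold predictions — the exact
McNemar construction, which we document prominently because the trial
definition of such comparisons is often left implicit — with a Clopper–Pearson 95% interval
for the proportion of discordant samples favoring the first system (one
plausible reading of the interval whose reference quantity is undefined).

## The synthetic corpus generator

The generator defines the study conditions under which the pipeline is
validated. Defaults: 88 couples (60% with both horizons), class
probabilities proportional to 12/26/34/67, two topic interactions per
session, 14–20 alternating turns of 0.5–1.5 s separated by 0.2–0.6 s gaps,
role f0 baselines 110 Hz (H) and 210 Hz (W). Per-turn latent feature means
follow an AR(1) within-speaker process (coefficient 0.6) with a
cross-speaker coupling term (0.3) — so short-term HH/WW and HW deltas are
informative, echoing the entrainment motivation. Frame values are turn
means plus white noise; simulated tracks use a 50 ms frame spacing, a
resolution choice that keeps corpora of a hundred couples tractable while
leaving every functional well-estimated.

Class effects scale with `effect_size` (d) through a class score mapping
ratings 1..4 to −1..+1: the mean of the pitch-delta feature shifts by
+0.5·d·s, jitter by −0.4·d·s, and loudness variability is multiplied by
(1 + 0.35·d·s) — the sign pattern mirrors the strongest reported
feature-outcome associations (mean pitch-delta +, loudness SD +, jitter −),
giving the correlation stage a known recovery target; the magnitudes are
free parameters of the generator, not claims about the clinical data.
Post-therapy sessions add a class-scaled within-session linear trend on two
channels so the long-term quarter deltas carry signal (a pure mean shift
would be removed by session normalization). Behavioral codes are generated
as class-shifted 1–9 ordinal draws (half the inventory loaded positively,
half negatively) with annotator noise. Ground truth (classes, turn plans,
latent turn means) is emitted alongside and tested for exact agreement with
the corpus.

The audio renderer produces amplitude-modulated harmonic complexes with
vibrato and a slow random f0 walk per turn, separated by silence. This is
deliberately schematic: it exercises VAD, GLR segmentation, clustering,
role assignment, and pitch tracking with known truth, but it contains no
formants, consonants, overlap, reverberation, or channel noise — passing
tests on it demonstrate the machinery, not field performance on clinical
recordings.

## Calibration, problem sizes, and limitations

The test suite and the acceptance script validate, at these sizes chosen as
the package's own working points: null calibration with `effect_size = 0`
(10 seeds × 30 couples; mean accuracy within 3 SD of the majority-class
rate, and correlation p-values uniform by a Kolmogorov–Smirnov test on 148
independent feature columns of a 60-couple single-horizon corpus — one
sample per couple, because paired horizons share pre-session data and
dependence would invalidate the uniformity reference); effect recovery with
`effect_size = 2` (one 120-couple corpus for the accuracy margin over
chance, 20 seeds of 120 couples for the sign pattern); and accuracy
monotonicity in effect size on reduced corpora. Null-calibration and other
reduced runs use a smaller SVM grid, which does not change the null
distribution being checked.

Known limitations: no overlapped-speech handling and at most two speakers;
the VAD is untrained and threshold-based; the 74-feature inventory is a
reconstruction; jitter/shimmer are smoothed period-variation measures
rather than strict cycle-mark statistics; the dynamic-set dimensionality
intentionally differs from the reference figure (see above); and all
quantitative guarantees are demonstrated on synthetic corpora whose
generative assumptions (Gaussian latents, linear effects, schematic audio)
are far simpler than clinical recordings.
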