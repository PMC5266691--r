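---
title: "Methods: linking positive-emotion ratings to EEG spectral power"
author: "emospect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking positive-emotion ratings to EEG spectral power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Discrete positive emotions — amusement, awe, gratitude, hope, inspiration,
interest, joy, love, pride, serenity — are behaviourally distinct, but their
electrophysiological signatures are far less studied than those of negative
affect. The paradigm emospect implements is a film-clip viewing study: each
participant watches a set of clips (30 positive, three per target emotion,
plus 6 negative and 1 neutral control) with multichannel EEG recorded, and
rates every clip on 14 seven-point Likert items (the ten positive emotions
plus arousal, valence, familiarity and liking). Three families of analysis
connect the ratings to the EEG:

1. **Rating structure** — inter-rater reliability (ICC), pairwise item
   correlations, a manipulation check that target emotions really are rated
   highest, and non-metric MDS of item similarities, from which the ten
   emotions group into three clusters: *encouragement* (awe, gratitude,
   hope, inspiration, pride), *playfulness* (amusement, interest, joy) and
   *harmony* (love, serenity).
2. **Correlation topographies** — per participant, the Pearson correlation
   over clips between baseline-corrected band power of every channel and
   each item's rating, averaged across participants into channel x band x
   item maps.
3. **Classification** — binary, 10-fold cross-validated SVM classification
   of 1-s epoch features (5 bands x 32 channels = 160 dimensions), with
   labels derived from clip ratings by median split, from cluster scores by
   median split, and from pairwise cluster-score differences; run per
   participant and on grand-average (cross-participant mean) features.

No human data ship with the package. Every analysis is exercised end to end
on synthetic data whose structure is planted and therefore known, so that
each stage's ability to *recover* that structure is a testable property.

## Band-power features

Spectral power is estimated with a single rectangular-window FFT per
segment (no taper, no Welch averaging). The one-sided periodogram is
normalised so that the bin powers sum to the mean squared signal; this
Parseval identity is locked by a unit test, because every other convention
choice follows from it. A band's value is the **mean per-bin power** over
the DFT bins whose frequency lies in `[f_lo, f_hi]`, edges inclusive, for
the default bands theta 3–7, low alpha 8–10, alpha 8–13, beta 14–29 and
gamma 30–47 Hz. Power is kept in linear uV^2 units and baseline correction
is the elementwise subtraction of the 5-s pre-onset baseline's band power
from the clip window's band power (a dB mode is deliberately absent from
the default path).

One consequence worth stating plainly: mean per-bin power is
*resolution-dependent*. A 30-s window spreads the same variance over 30x
more bins than a 1-s epoch, so clip-level and epoch-level features sit on
different numeric scales. This is inherent to the "average over bins"
convention and harmless here — correlations are scale-invariant and the
classifier standardizes features within training folds — but the two
feature levels should never be mixed in one model.

Clip-level features use the final 30 s before each clip's offset;
epoch-level features cut that window into 30 non-overlapping 1-s epochs,
each corrected by the clip's single 5-s baseline (the only baseline
available). With the default design this yields exactly 900 positive-clip
epochs of 160 features per participant.

Preprocessing is a zero-phase 50 Hz biquad notch (Q = 30) plus a
Butterworth 0.05–50 Hz bandpass, both applied forward–backward. An
artifact-mask hook lets an externally computed rejection (e.g. from ICA)
be multiplied in; artifact *detection* is out of scope. The synthetic
pipeline helpers default to `preprocess = FALSE`: generated signals are
band-limited with no line noise, so filtering is an identity up to
passband ripple, and skipping it keeps the 20-participant recovery run
fast. Setting `preprocess = TRUE` wires the filters into the same path.

## The synthetic rating model

Ratings are drawn from a latent linear model. Each clip `c` carries a
three-vector of cluster activations `a_c` (SD `clusterActivationSd`,
default 0.8); a positive clip's target emotion adds `clusterBoost` (1.2)
to its own cluster's activation and `targetBoost` (1.5) to the item
itself; control clips sit low on all three clusters. Item `i`'s latent
mean is `base + loadings[i,] . a_c (+ boosts)` plus a clip-by-item noise
term shared across participants (`itemNoiseSd`, 0.3). Each participant
adds independent noise (`participantNoiseSd`, 0.8) before round-half-up
discretization and clipping to [1, 7]. Arousal, valence, familiarity and
liking are generated from clip category and the activations (valence high
for positive clips, arousal raised by playfulness and lowered by harmony,
liking tracking valence), reproducing the qualitative correlation pattern
between the appraisal items and the emotion items.

These defaults were chosen once to emulate the study conditions
qualitatively — elevated target-emotion ratings, three recoverable
clusters, high inter-rater reliability — since no deposited rating data
exist for this paradigm to calibrate variances against. `participantNoiseSd` is
the reliability dial: ICC is monotone decreasing in it (a tested
property). `nullLatentEmotionModel()` switches *all* structure off
(no activations, boosts or shared item noise; mid-scale base so Likert
clipping stays symmetric), making items exchangeable — that, not merely
`targetBoost = 0`, is the correct null for type-I-error checks, because
shared clip-level item structure is not averaged away by the
repeated-measures ANOVA's participant-by-item error term.

## The synthetic EEG model

EEG is generated per participant as a continuous 32-channel recording:
each clip is preceded by a rest gap containing the 5-s baseline window,
and clips longer than the 30-s analysis window get base-power filler
before it. Within a clip's analysis window, the target band power of
channel `ch` in band `b` is

```
P[ch,b] = basePower[ch,b] + sum_i beta[ch,b,i] * z(rating_i) + noise
```

where `z` standardizes each item's ratings across that participant's 37
clips and `noise` is N(0, `powerNoiseSd` = 1) per clip, channel and band
(floored at zero). Segments are synthesized by spectral shaping: per-bin
amplitudes are set exactly from the per-bin power targets (narrower bands
resolved first, so the nested low-alpha/alpha pair is honoured exactly)
with fresh uniform random phases per segment and channel, and a 1/f
background fills the out-of-band bins. Because amplitudes are exact, the
rectangular-window periodogram of a whole segment equals its target with
zero synthesis error — clip-level corrected power is literally
`beta . z + noise` — while 1-s sub-epochs fluctuate around the target
with the natural chi-squared-like spread, which is what makes epoch-level
classification non-trivial.

The `planted` effect preset plants the qualitative topographies the
analysis should recover: encouragement items gain central alpha and beta
(and lose a little gamma), playfulness items gain theta globally and gamma
broadly, harmony items gain parieto-occipital alpha, arousal suppresses
parieto-occipital alpha, and valence is a frontal alpha asymmetry (right
frontal up, left frontal down). Familiarity and liking carry no planted
effect. `plantedTruth()` exports the coefficient array as a topography so
sign recovery can be scored with `recoveryScore()`.

What the generator does **not** emulate: eye-blink/EMG artifacts and their
removal, volume conduction from a head model, non-stationarity within
segments, inter-individual spectral differences (every participant shares
one base spectrum), and any nonlinearity between experience and power.
Passing tests therefore demonstrate that the *pipeline* recovers planted
linear structure at realistic noise levels — not that real EEG contains
such structure.

## Statistics

- **ICC**: consistency, average-measures (the ICC(2,k)/ICC(C,k) family),
  computed from the two-way mean squares of each item's clips x raters
  matrix as `(MSR - MSE)/MSR`; absolute-agreement and single-measure
  variants are selectable. The study leaves the variant unstated;
  consistency/average is the standard choice for cross-rater reliability
  of stimulus ratings. Zero between-clip variance makes the ICC undefined
  and returns NA with a warning.
- **MDS**: Kruskal's non-metric scaling (`MASS::isoMDS`) on item
  dissimilarities `1 - r` between cross-participant mean rating profiles
  over the 30 positive clips (Euclidean-on-z selectable). Eight random
  restarts plus a classical-scaling start under a fixed seed; best
  Stress-1 kept, reported on the [0, 1] scale. `mdsStressProfile()` seeds
  each dimensionality with the previous best configuration (zero-padded),
  which guarantees the reported stress is non-increasing in dimension.
  Cluster assignment is either k-means in the embedding (for synthetic
  recovery, with labels mapped to the published clusters by majority
  overlap) or the published manual assignment.
- **Manipulation check**: per target emotion, a one-way repeated-measures
  ANOVA across the ten positive items (ratings averaged over the emotion's
  three clips within participant) plus paired t-tests of the target
  against each other item, flagged target-higher / ns / reversed at
  uncorrected alpha = 0.05 (Holm optional). Constant paired differences are
  resolved analytically (t = 0, p = 1 when the difference is zero).
- **Median splits**: epochs are ordered by (clip value, clip id, epoch
  index) with a stable radix sort and the lower half labeled "low", which
  guarantees the exact 450/450 balance deterministically under any tie
  pattern; at most one tie-straddling clip has mixed labels.
- **Classification**: linear-kernel SVM (libsvm via e1071), cost 1,
  features z-standardized with training-fold statistics only, stratified
  epoch-level 10-fold CV, accuracy = mean fold accuracy. Kernel, cost and
  scaling have no canonical values in this paradigm; these are the
  plainest defaults and both are configurable. Epoch-level folds mean
  epochs from one clip can appear in both training and test folds — the
  convention this design follows, and the accuracy regime it implies —
  but that inflates accuracy relative to clip-grouped CV (provided as the
  leakage-safe alternative); treat absolute accuracies accordingly. Grand-average
  classification averages features across participants at aligned
  (clip, epoch) positions and derives labels from cross-participant mean
  ratings with the same split rules.

## Reproducibility and problem sizes

One integer seed governs a whole study; per-stage and per-participant
streams are derived by hashing tokens into 31-bit sub-seeds, so any subset
of participants can be regenerated bit-identically in any order. The
heavier simulation checks run at deliberately chosen sizes: the
topography-recovery check uses the full 20-participant default design; the
grand-average-versus-individual comparison uses ten simulated studies of
four participants with 30–31 s clips (the noise-averaging property does
not depend on participant count) and is measured on the harmony-cluster
task — the hardest of the three cluster tasks under the default preset —
because a task at the accuracy ceiling leaves no headroom in which the
grand-average gain can show; the label-permutation check uses five
shuffles of the 900-epoch labels; the type-I-error check uses 120 null
studies (1200 ANOVA p-values). Degenerate inputs — constant rating
profiles, zero-variance items, tied cluster scores, single-class folds —
are either resolved deterministically or rejected with named errors, never
silently imputed.

## Known limitations

Beyond the generator's idealisations listed above: the pipeline computes
no significance maps for topographies and no cluster-based permutation
statistics; Likert data are treated as interval-scaled; the MDS cluster
count (three) is taken as given rather than selected; and EDF I/O is not
provided — sessions interchange as delimited matrix plus JSON event
sidecar.
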