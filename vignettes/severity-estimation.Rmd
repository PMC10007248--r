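---
title: "Estimating dyspnea severity from controlled vocalizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dyspnea severity from controlled vocalizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dyspnea (breathlessness) is routinely graded with the modified Medical
Research Council (mMRC) scale, an ordinal score assigned by a clinician in
an interview. `voxmmrc` implements a telephone-compatible alternative: the
speaker produces three controlled vocalizations in one breath — an /ae-ae/
vowel alternation, a /sa-sa/ syllable repetition, and counting from one to
thirty as fast as possible — and the system estimates the mMRC class (0-3,
with the rare most-severe speakers merged into class 3) from the recordings
alone. The vocalizations are deliberately non-stationary so that the noise
suppression of mobile handsets does not cancel them, and they differ in how
fast they spend exhaled air and how much fluent, spontaneous speech they
elicit. Severity manifests as shorter phonation, more involuntary pauses,
and a less steady pitch.

All recordings are mono 8 kHz WAV (telephone bandwidth). Each participant
produces two repetitions of each vocalization: up to six recordings per
person.

## Pipeline overview

1. **Features.** Two complementary kinds per recording:
   - *Time-independent* (one 3-vector per recording): the linear slope of
     the F0 trajectory over voiced frames normalized by the mean F0
     (1/s), the standard deviation of F0 (Hz), and the recording duration
     (s). F0 comes from an autocorrelation pitch tracker (40 ms frames,
     10 ms hop, search range 75-500 Hz, voicing decision by normalized
     autocorrelation peak > 0.45 plus an energy floor).
   - *Time-dependent* (one matrix per recording): a log power spectrogram
     from 50 ms (400-sample) Hann windows with 50% overlap, zero-padded to
     a 512-point FFT (257 bins). For /ae-ae/ and /sa-sa/: 14 triangular
     Mel filter log energies per frame. For counting: the lowest 193 bins
     (75% of the band) plus their first-order deltas, 386 per frame.
2. **Normalization.** Mean-variance normalization (MVN) per feature
   dimension. Under the default `train` scope the statistics come from the
   training subset of each partition only; the `all` scope (whole-dataset
   statistics) is also available. Time-dependent matrices are then
   zero-padded to the longest training utterance of the same vocalization
   type (longer test utterances are truncated — the network input is fixed
   size).
3. **Classifiers.** One classifier per (vocalization, feature kind) slot,
   six in total: MLPs for the time-independent features (softmax head,
   learning rate 0.001; hidden layers 20-20 for /ae-ae/, 20 for /sa-sa/,
   30 for counting), a 1-d CNN over time for the /ae-ae/ and /sa-sa/
   spectral features, and a CNN-LSTM (convolutional front end, LSTM read
   out at the last frame) for counting; the time-dependent models use a
   stick-breaking head and learning rate 0.0001. All are trained with
   Adam and cross-entropy.
4. **Ordinal head.** The stick-breaking layer maps three activations to
   four probabilities via sigmoid "breaks" of the remaining mass:
   `p0 = s0`, `p1 = s1(1-s0)`, `p2 = s2(1-s0)(1-s1)`,
   `p3 = (1-s0)(1-s1)(1-s2)`. The probabilities sum to one by
   construction and respect the class ordering.
5. **Fusion.** Probability vectors are combined element-wise with five
   rules — minimum, maximum, mean, median, product — each renormalized to
   a probability vector, then averaged. The combiner is applied across the
   two repetitions of each slot, the two feature kinds are then combined by
   a simple average, and the three vocalizations by the five-rule combiner
   again. The estimated mMRC is the argmax, ties broken toward the lower
   (healthier) class.
6. **Protocol.** Nine speaker-disjoint folds (for 104 participants: five
   folds of 12, four of 11). Per partition the non-test participants split
   70/15/15 into training, validation 1 (early stopping, patience 20, on
   the validation loss) and validation 2. Each slot is trained eight times
   with distinct initialization seeds; the replicate with the highest mean
   accuracy across the two validation subsets is kept, so validation 2
   acts as an untouched generalization probe for replicate selection.
   Test predictions pooled over all partitions cover every participant
   once; the whole procedure is repeated five times and metrics averaged.
7. **Metrics.** Four-class accuracy and RMSE on the mMRC scale, plus
   binary screening metrics (class 0 vs 1-3): false positive rate over the
   reference-healthy participants, false negative rate over the
   reference-dyspneic ones, and AUC of the continuous dyspnea score
   `1 - p0` computed with the rank (Mann-Whitney) statistic, ties counted
   one half.

## The synthetic cohort

Clinical recordings of this kind cannot be redistributed, so the package
ships a severity-conditioned synthesizer that reproduces the *structure*
of such a study: 104 participants (34 healthy, 19/29/22 in classes 1-3),
two repetitions of three vocalizations each, 624 mono 8 kHz recordings
plus a CSV manifest. Waveforms come from a source-filter model: a
glottal-pulse-like impulse train at the speaker's F0 (with a slow seeded
wander) drives a cascade of two formant resonators for vowels; fricatives
are high-pass filtered noise; counting is a train of up to 30 syllable
tokens with Poisson-like involuntary pauses, truncated when the phonation
budget is spent. Peak amplitude is normalized to 0.5 and white noise is
added at 30 dB SNR to emulate telephone capture.

Severity enters through the default profile table: phonation budget
(12, 9, 6, 4) s for classes 0-3 for /ae-ae/ (20% shorter for /sa-sa/,
(14, 10, 7, 5) s for counting), pause rate (0.2, 1, 2, 4) per 10 s, pause
length (0.25-0.6) s, F0 wander SD (2, 4, 7, 10) Hz, base F0 120 Hz with a
per-participant offset drawn uniformly in ±20 Hz. No clinical source
reports these distributions; the values are the package's own choice,
picked so classes separate clearly but overlap after the per-participant
perturbation (lognormal scatter of about 8% on the budget), and they
should not be read as estimates from any patient population. Every
waveform is a pure function of the configuration and one seed.

What the simulator does *not* reproduce: real phonetic content (the
"numerals" are generic syllables), speaker identity beyond an F0 offset,
telephone codecs, channel dropouts, background speech, coughing, and the
much weaker and messier covariance between severity and voice found in
real patients. A passing end-to-end run therefore validates that the
pipeline can recover a severity signal of plausible form from audio — it
says nothing about clinical accuracy, and the headline numbers published
for real cohorts are out of reach of any synthetic benchmark by design.

## Numerical choices

- Natural logs with a floor of `1e-10` on power before taking logs; MVN
  makes the log base immaterial.
- Hann analysis window (the window function is otherwise unconstrained).
- 75% of 257 bins is 192.75; 193 bins are kept so that bins plus deltas
  give the stated 386 features per frame.
- Deltas are symmetric differences over ±1 frame with edge replication.
- The 70/15/15 split applies to the non-test participants of a partition
  (the test fold is removed first), with
  `n_val = floor(0.15 m + 0.5)` per validation subset; for a 12-person
  test fold of a 104-person cohort this gives 64/14/14/12.
- Folds are stratified by class (with 22 class-3 participants an
  unstratified 9-fold draw can leave a test fold without a class); fold
  sizes are fixed to the equal-as-possible rule, larger folds first, and
  each of the five protocol repetitions redraws fold assignments and
  replicate seeds from the master seed.
- Early stopping monitors the validation-1 *loss* (not accuracy); the
  epoch cap is 500 as a safety bound. The stick-breaking head is trained
  with cross-entropy on the composed probabilities.
- The renormalized product rule is not idempotent on non-uniform vectors
  (renormalizing `v^n` sharpens `v`); the other four rules are. This is
  inherent to the classic product combining rule once its output is
  required to be a probability vector, and the test suite checks the
  combiner against an independent brute-force oracle instead of assuming
  blanket idempotence.
- MVN floors the per-dimension standard deviation at `1e-8` (constant
  dimensions normalize to zero with a warning). Zero-sum rule vectors are
  excluded from the fusion average with a warning.
- All randomness — synthesis, fold shuffling, weight initialization,
  minibatch order — derives from one master seed through a mixing
  function, so every result in the package is exactly reproducible.

## Validation scale

The neural stack is hand-rolled matrix code; every backward pass (dense,
convolution, pooling, LSTM, both heads) is verified against numerical
gradients. End-to-end behavior is validated on synthetic cohorts at two
scales chosen for single-CPU runs: a 24-participant cohort through a
3-fold, 2-replicate, single-repetition protocol with small networks, and
the full 104-participant cohort through the same reduced protocol with
the `smoke` configuration of `default_protocol_configs()` (coarser time
decimation, one convolution block, tighter epoch caps). The test suite
asserts that the reduced protocol recovers four-class severity at
accuracy at least 0.50 (majority-class baseline is about 0.28) with
binary AUC at least 0.80 on that cohort; the study-scale defaults
(9 folds, 8 replicates, 5 repetitions, full network sizes) are available
through the same functions for larger runs.

## Known limitations

- The CNN and CNN-LSTM layer dimensions are declared defaults drawn from
  a plausible search grid, not a reconstruction of any particular
  published architecture.
- The pitch tracker is a plain normalized-autocorrelation design; octave
  errors on strongly irregular voices are possible. It sits behind the
  pitch-track contract and can be replaced.
- Training is plain single-threaded R; the defaults are sized for
  hundreds, not tens of thousands, of recordings.
- `predict_single()` requires a trained bundle from the same feature
  configuration; there is no cross-version checkpoint compatibility.
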