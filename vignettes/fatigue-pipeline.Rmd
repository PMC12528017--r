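---
title: "Recognising muscle fatigue from surface EMG: methods and design"
author: "semgFatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising muscle fatigue from surface EMG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgFatigue)
```

## The problem

During sustained cyclic exercise (squats at a fixed cadence, say),
working muscles fatigue progressively. Surface electromyography (sEMG)
shows this in well-established ways: the signal amplitude rises as more
motor units are recruited to maintain force (root mean square, RMS, and
integrated EMG go up), the power spectrum compresses toward lower
frequencies as fibre conduction velocity drops (median frequency, MF,
and root-mean-square frequency, RMSF, go down), and the signal becomes
more regular (sample entropy falls). This package implements a complete
pipeline that (i) identifies, from a multi-channel recording, the
muscles that dominate the movement, (ii) extracts eight windowed fatigue
features from those channels, and (iii) classifies windows of activity
as *relaxed* versus *fatigued* with a self-attention (Transformer
encoder) sequence model, compared against recurrent (LSTM) and
gradient-boosted-tree baselines.

Because no public recording accompanies the method, the package ships a
first-class synthetic-data generator that plants all of the structure
the pipeline is meant to recover. Every stage is therefore testable end
to end without any download.

## The generator and what it emulates

A simulated trial (`generateTrial()`) is

$$x_c(t) = g(u(t)) \, [W h(t)]_c \, s(t) \; + \; \sigma_0 \, w_c(t)$$

* $h(t)$: `nSynergies` (default 3) periodic activation envelopes at the
  movement cadence (default 40 repetitions/min). Each is a small tonic
  baseline (default 0.05) plus a raised-cosine burst occupying two
  thirds of the cycle, phase-shifted so the bursts hand over smoothly
  and sum to a constant.
* $W$: the nonnegative channel-mixing matrix
  (`defaultMixingWeights()`). The three dominant channels load their own
  synergy at 1.0 and the others at 0.7 — prime movers co-contract across
  the whole cycle, so their envelopes are comparatively smooth. Each
  remaining channel loads a single synergy at 0.9: accessory muscles
  fire phase-locked to one movement phase. This split is deliberate: the
  accessory channels' deep, mutually out-of-phase bursts are what makes
  the envelope matrix numerically rank-3 (so the synergy count is
  identifiable from the variance-accounted-for curve), while the smooth
  dominant channels let the planted amplitude trend dominate their
  windowed RMS. With all off-dominant weights small the envelope matrix
  collapses towards rank 1 and no threshold can recover the planted
  count.
* $u(t)$: the monotone fatigue level (default linear from 0 to 1 over
  the trial). It drives the amplitude gain $g$ (default 1.0 → 1.5) and
  the carrier's target median frequency (default 90 → 60 Hz), the two
  phenomenological handles of fatigue.
* $s(t)$: a stochastic carrier built block-wise (0.5 s Hann blocks,
  50 % overlap-add) by frequency-domain shaping of white noise with a
  symmetric raised-cosine band mask (default width 40 Hz) centred on the
  current target MF — so the empirical median frequency tracks the
  target by construction, with no calibration table. A final slow
  automatic-gain stage divides out the amplitude envelope below 10 Hz:
  without it, the chi-square fluctuations of narrow-band noise power
  dominate the 100 ms windowed RMS and bury the planted trend. The
  carrier is shared across channels (a common interference-pattern
  approximation); channel-specific stochasticity enters through the
  additive noise floor (default 0.05). The shared carrier is also what
  makes the noiseless rectified-envelope matrix factorise *exactly* at
  rank `nSynergies`.
* Ground-truth labels: first 30 % of the trial *relaxed*, last 30 %
  *fatigued*, middle 40 % excluded (all configurable) — transition
  windows carry no reliable label and are left out.

What the generator does **not** emulate: motor-unit action potential
trains, electrode lift/motion artefacts, inter-muscle crosstalk with
channel-specific spectra, force/kinematics, or inter-participant
variability (per-trial parameter jitter is possible by varying the
config, but no population model is claimed). Passing tests on this
generator therefore demonstrates that the pipeline recovers planted
synergy structure and planted monotone trends — not that it would reach
any particular accuracy on real recordings.

Default trial duration is 40 s (a desk-scale stand-in for a squat set;
about 26 cycles). All randomness is derived from one integer seed, and
identical configs give bitwise-identical trials.

## Preprocessing

Filtering follows standard sEMG practice: a Butterworth band-pass
(default 20–150 Hz, order 4) then a narrow power-line notch (50 Hz,
Q = 30), both applied forward–backward (`filtfilt`) for zero phase —
this doubles the attenuation in dB and removes group delay, at the cost
of edge transients; the first and last 0.25 s are therefore trimmed
before windowing. The notch is applied after the band-pass (the order is
not critical for these widths and is documented rather than load-bearing).
The nonnegative input for synergy analysis is the full-wave rectified
signal low-passed at 5 Hz, clipped at zero, and decimated to 50 Hz
(safe, because the envelope is band-limited far below that rate).

## Synergy analysis

The envelope matrix $V$ (samples × channels) is factorised as
$V = WH + E$ with nonnegative $W$ (samples × k) and $H$ (k × channels)
by Frobenius-norm multiplicative updates, best of 20 random restarts,
at most 500 iterations, stopping when the relative error decrease falls
below 1e-6. Reconstruction is scored with the matrix-level
variance-accounted-for,

$$\mathrm{VAF} = 1 - \|V - WH\|_F^2 \, / \, \|V\|_F^2,$$

the dominant convention in the synergy literature. The synergy count is
the smallest $k$ whose mean VAF over repeated fits exceeds 0.95. NMF's
scale indeterminacy is resolved by normalising each column of $W$ to
unit maximum with the compensating factor absorbed into $H$ (VAF is
unchanged).

Channel contributions: each synergy's loading vector (row of $H$) is
scaled to unit maximum and a channel's score is its summed normalised
loading — continuous scoring rather than a thresholded "frequency of
occurrence", which would need an arbitrary cut-off. Scores are invariant
to rescaling any synergy; ties rank by channel index; the top three
channels are selected. Across trials, per-trial scores are aggregated by
mean rank. Whole trials are decomposed (no per-repetition segmentation,
whose criteria would be arbitrary here).

## The eight features

Windows are 100 ms long with a 25 ms step (200/50 samples at 2000 Hz);
only complete windows are used. Per window, in fixed column order:

| Feature | Definition | Fatigue direction |
|---|---|---|
| RMS  | $\sqrt{\tfrac1n\sum x_i^2}$ | up |
| IEMG | $\sum |x_i|$ (rectified sum) | up |
| WL   | $\sum |x_{i+1}-x_i|$ | up |
| SSC  | sign changes of consecutive differences (threshold $\delta$, default 0) | down |
| MF   | half-power crossing of the tapered periodogram, with linear interpolation inside the crossing bin | down |
| RMSF | $\sqrt{\sum f_i^2 P_i / \sum P_i}$ | down |
| SE   | sample entropy, $m=2$, $r = 0.2\,\mathrm{SD}$, Chebyshev, self-matches excluded | down |
| FD   | Higuchi fractal dimension, $k_{\max} = 8$ | toward 1 |

Numerical choices worth stating: the periodogram removes the mean and
applies a Hann taper (windows are short; Welch averaging is unnecessary
at 200 samples). MF interpolation matters because a 100 ms window has
10 Hz bins — without it the estimate is quantised to four or five
distinct values across the whole fatigue trajectory and rank
correlations drown in ties. Sample entropy returns 0 for a constant
window and is capped at $\log$ of the possible pair count when no
$m{+}1$ match exists; a mean-frequency variant
($\sum f_i P_i/\sum P_i$) is exported alongside the median because the
two conventions coexist in the literature. $k_{\max}=8$ keeps Higuchi's
regression well-conditioned for 200-sample windows. Windows where a
spectral or nonlinear feature is undefined (zero power) yield NA and are
counted in a message.

## Dataset preparation

Features are min–max normalised to [0, 1] per trial (each trial's own
minima/maxima); a `train_set` scope is also available that stores
bounds on training data and clips held-out values into range — both
appear in practice and the package does not assert which is "right".
Variable-length window sequences can be brought to a standard length by
proportional deletion or predecessor-duplication (`equalizeLength()`),
preserving order and continuity. The classifier consumes sub-sequences
of 16 consecutive windows (stride 8) with the unanimous window label;
sequences never straddle the excluded transition. Splits are a
stratified 80/20 holdout plus 5-fold cross-validation inside the
training set, optionally group-aware so no trial straddles the
boundary.

## Models

The Transformer encoder is implemented in plain R matrix algebra:
linear input embedding, sinusoidal positional encoding (base 10000),
then per layer multi-head scaled dot-product attention
($\mathrm{softmax}(QK^\top/\sqrt{d_k})V$), a position-wise ReLU
feed-forward block, residual connections and post-sublayer layer
normalisation; mean pooling over time feeds a two-class linear head.
Training is Adam on cross-entropy with seeded initialisation, shuffling
and dropout; both forward and backward passes are hand-written and were
verified against central-difference numerical gradients to ~1e-11
absolute error. Defaults (`modelConfig()`): d = 64, 4 heads, 2 layers,
feed-forward 128, dropout 0.1, lr 1e-3, 50 epochs, batch 32. Mean
pooling was chosen over last-step or CLS-style pooling for stability on
short sequences. Single-feature runs reuse the identical architecture
with input width 1, so feature comparisons are architecture-controlled.

Baselines: a single-layer LSTM (hidden width d, mean-pooled states,
same training loop, forget-gate bias 1) and gradient-boosted trees
(xgboost, binary logistic, depth 4, eta 0.1, 100 rounds, single thread)
on per-sequence mean/SD summaries of each feature.

The tests and the acceptance script run a reduced configuration (d = 32,
feed-forward 64, 30 epochs, one to two 40 s trials, ~200–350 sequences)
that trains in seconds on one CPU while exercising the identical code
path; these problem sizes are the package's chosen desk-scale defaults.

## Evaluation

Confusion counts treat *fatigued* as the positive class (missing
fatigue is the costly error). Accuracy, precision, recall and F1 are
reported fold-wise as mean ± SD; zero denominators are flagged and
reported as 0 with a warning. ROC curves sweep the unique scores with
trapezoid AUC. Feature attribution uses model-agnostic
permutation-sampling Shapley values against a background of feature
means (absent features are replaced column-wise), reported as mean
|value| per feature. Model comparison uses the Friedman rank test over
matched blocks (CV folds by default; the blocking unit is the caller's
choice) with Nemenyi studentized-range post-hoc comparisons at
α = 0.05. For small untied tables (k ≤ 4, n ≤ 12) the Friedman p-value
is exact, computed from the full permutation null by dynamic
programming — the chi-square approximation is noticeably off at
fold-scale n.

## Known limitations

* The generator's shared carrier makes channels maximally correlated at
  zero noise floor; real crosstalk is partial and channel-specific.
* Accuracy on the clean synthetic conditions sits near ceiling for all
  three models; the generator plants strong, clean trends, so model
  ranking on it says little about real-data margins.
* The Shapley estimator is Monte-Carlo; scores for weakly contributing
  features carry sampling noise of order a few percent of the top score.
* Per-participant personalisation, transfer learning, artefact
  rejection and multimodal fusion are out of scope.
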