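---
title: "Recognizing sign-language subwords from sEMG and accelerometer signals"
author: "slrforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing sign-language subwords from sEMG and accelerometer signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slrforest)
```

## The problem

A wearable sign-language recognition system records, from each forearm,
four surface-electromyography (sEMG) channels and one tri-axial
accelerometer (ACC), all sampled at 1 kHz.  sEMG measures muscle
activation — which fingers and wrist muscles are working, and how hard —
while the ACC at rest measures the projection of gravity (hand
orientation) and during movement adds the motion trajectory.  The two
modalities are complementary, and `slrforest` implements a hierarchical
classifier that exploits exactly that complementarity to recognize
isolated subwords (gesture units) excised from continuous signing.

The pipeline is: energy-based segmentation of the continuous recording,
per-segment feature extraction, a four-stage "improved decision tree"
(IDT), and class-stratified bootstrap bagging of such trees into a random
forest (RF) with majority voting.

## Synthetic signal model

Real recordings of this kind are signer-specific and rarely shared, so the
package ships a generator that reproduces the statistical structure every
stage of the classifier relies on — not muscle physiology.

* **sEMG**: per channel, amplitude-modulated AR(4)-colored Gaussian noise
  plus a baseline noise floor (default standard deviation 0.05 in signal
  units where envelope peak gains are 2.2–3.0).  The AR(4) shaping is the
  simplest process whose LPC features are informative; each class draws
  its own stable filter (two conjugate pole pairs, radii 0.4–0.85).
* **Envelope**: a 64 ms raised-cosine onset/offset taper times a sustained
  level (default floor 0.8 of peak) modulated by 1–3 raised-cosine bumps.
  The sustained level represents co-contraction through the stroke and
  keeps mid-subword energy above the segmentation threshold, so detected
  boundaries land on the taper — within about one analysis window of the
  true onset.
* **ACC**: per axis, a constant gravity component selected from 8
  candidate orientations (the axis directions plus two diagonals,
  mirroring the 7–8 empirical orientation clusters such systems exhibit),
  plus a smooth windowed-sinusoid trajectory (amplitude 0.15–0.45 of
  gravity) and sensor noise (sd 0.03).
* **Handedness**: one-handed classes keep every non-dominant channel at
  the noise floor and the non-dominant hand at a fixed rest orientation.
* **Confusable pairs**: the second member of a declared pair copies the
  first and perturbs only envelope timing and trajectory amplitude
  (relative scale 0.25 by default).  Orientation, handedness and AR
  shaping are shared, so pairs collide in the coarse tree stages and must
  be resolved by the pre-classifier or the HMMs — the behaviour the
  architecture exists to fix.
* **Execution jitter**: every synthesis jitters durations, gains, bump
  timing and trajectory amplitudes by about 10% relative, emulating
  execution-to-execution variability.  Without it, within-class variance
  collapses to sensor noise and every class pair would be trivially
  separable.
* **Durations** are drawn from 800–1100 ms (at least 640 ms, so a segment
  always yields ≥ 9 energy windows and survives the duration filter).

All randomness flows from one seed through a counter-mixing scheme
(`split_seed()`), so any subword's signal is reproducible independent of
generation order.  What the generator does *not* model: motor-unit
physiology, electrode shift, fatigue, or realistic sensor noise spectra —
passing tests therefore demonstrate the correctness and the relative
behaviour of the algorithms under the assumed structure, not performance
on human data.

## Segmentation

The dominant hand participates in every subword, so its four sEMG
channels drive detection.  The signal is cut into 128-sample windows with
a 64-sample step; each window's energy is the channel-averaged mean
square amplitude.  The threshold is 20% of the mean windowed energy of
the signer's maximal voluntary contraction (MVC; the generator provides
`synthesize_mvc()`, real deployments must supply an MVC recording).  A
segment starts where three consecutive windows exceed the threshold after
two below it, ends symmetrically, and is discarded unless it spans more
than 8 windows.  Decisions the underlying description leaves open, fixed
here: window `t` maps to samples `[t*64, t*64 + 127]` (adjacent windows
tile contiguously); the five-window patterns are only evaluated where all
five windows exist; a recording that ends while active is closed at the
last window; exact equality with the threshold counts as *below*
(conservative onset).

## Features

* MAV `mean(|x|)`, arithmetic mean, and unbiased variance.
* LPC by the autocorrelation method: biased autocorrelation plus
  Levinson–Durbin, sign convention `x(n) ≈ -Σ l_k x(n-k)`, so the
  returned coefficients equal the `a_k` of the matching AR-plus-noise
  model — one routine serves both formulations.  Burg or covariance
  variants would also be defensible; the autocorrelation method is
  standard, deterministic and guaranteed stable.  Constant input returns
  all-zero coefficients.
* Stage vectors: 42-D pre-classifier vector (dominant hand, 7 channels ×
  {MAV, VAR, LPC1..4}), 10-D handedness vector (non-dominant: 4 sEMG MAVs,
  3 ACC means, 3 ACC standard deviations), 3-D orientation vector
  (dominant ACC means).
* HMM observations per hand: `O_A`, each ACC axis linearly interpolated
  onto 64 points (inclusive endpoints), which normalizes movement
  duration; `O_E`, 128/64 sliding frames with MAV + LPC1..4 per channel
  (20 values per frame).

SVM stages z-score their inputs on the training data (raw sEMG and ACC
scales differ by orders of magnitude and unscaled margins degenerate);
the HMM streams are left unscaled, since their Gaussians adapt.

## Multi-stream Gaussian-mixture HMMs

Each class gets one 5-state, 3-component diagonal-covariance HMM per
stream (ACC and sEMG), per active hand.  Choices the description leaves
open:

* **Topology**: left-to-right with self-loops and single-step forward
  transitions, the standard gesture topology; the last state is
  absorbing.
* **Initialization**: segmental — each training sequence is split into 5
  equal chunks; the pooled frames of each state are clustered into 3
  components by seeded k-means.
* **Covariance floor**: `1e-6` times the per-dimension training variance
  (with a `1e-8` absolute guard for degenerate dimensions).  Because the
  M-step projects onto the floored region and the initial variances
  respect it, the EM log-likelihood trace remains non-decreasing — which
  the tests assert to `1e-8` relative.
* **Fusion**: the per-class score is `δ_A·logP(O_A) + δ_E·logP(O_E)` with
  `δ_A = δ_E = 0.5` by default.  A convex combination of *raw*
  likelihoods is not computable for 14–64-frame continuous observations —
  they underflow catastrophically — so the package combines
  log-likelihoods, standard multi-stream HMM practice.  Each stream's
  log-likelihood is divided by its frame count before fusion (config
  switch `normalize_loglik`) so the 64-frame ACC stream cannot swamp the
  ~10–15-frame sEMG stream.
* Two-handed classes sum the fused scores of both hands; ties break
  toward the lowest class id everywhere.

The forward pass scales per frame by the total reachable probability
mass (not the best emission over all states), which keeps wrong-class
scoring finite even when the left-to-right topology makes the
best-emitting state unreachable.

## The improved decision tree and the forest

Stages, each of which can only shrink the candidate set (a filter that
would empty it is skipped, so the set is never empty):

1. **Pre-classifier**: one linear SVM per confusable pair, trained only on
   that pair's samples; every pair still fully in the candidate set votes
   and the loser is removed, in fixed pair order.  Pairs come from the
   generator's declarations, or — for data without declared pairs — from
   ranking class pairs by the Euclidean distance of their standardized
   class-mean 42-D vectors (a data-driven stand-in for expert selection).
   Omitting this stage reproduces the baseline decision tree (DT).
2. **Handedness**: a linear max-margin SVM on the 10-D vector; the losing
   handedness's classes are dropped.
3. **Orientation**: per handedness branch, fuzzy K-means (K = 8,
   fuzzifier m = 2, both configurable) on the 3-D orientation vectors;
   classification is nearest-center by Euclidean distance, and a class is
   admitted at every cluster that is nearest for at least one of its
   training samples — the most permissive admission rule, chosen to avoid
   false eliminations.
4. **HMM leaves** score the survivors as above.

The forest draws, per tree, a class-stratified bootstrap sample (class
`i` keeps its size `N_i`, drawn with replacement), trains an IDT on it,
and predicts by plurality vote with the lowest-id tie-break.  Following
the design it reproduces, there is *no* per-node feature subsampling —
trees differ only through their bootstrap samples — and all trees carry
equal vote weight.  Stratified bootstraps also mean no class can vanish
from a tree.

## Evaluation harness and the robustness experiment

`threefold_cv()` folds by repetition group (each class contributes one
sample group per repetition), reporting per-fold and mean accuracies plus
handedness/orientation stage accuracies.  `forest_size_sweep()` evaluates
sizes as prefixes of one maximal forest, so the sweep isolates the effect
of size from bootstrap noise.  Both harnesses were validated with stub
classifiers (perfect and chance) before any model-dependent claim.

`robustness_experiment()` emulates bad training samples: a fraction (up
to 4 of the 8 per-class training samples) is replaced by samples of the
class's confusable partner, relabeled, training on repetitions 1 and 3
and testing on clean repetition 2.  Method pairs are compared with the
paired Wilcoxon signed-rank test across seeds, chosen because the
per-seed error rates cannot be assumed normal.

One design point deserves emphasis.  With mutually-linked pairs,
*symmetric* contamination at the 50% level replaces half of class a's
samples with b's and half of b's with a's: the two training sets then
follow the *identical* mixture distribution, every classifier is
provably at chance within the pair, and ensembling cannot help.  Real
lexicons do not behave this way: a sign's confusable partner is itself
confusable with further signs, so the confusion graph is not a perfect
matching and replacement is effectively directional.  The default
(`pair_direction = "one_way"`) therefore contaminates, per seed, one
randomly chosen member of each pair from its partner, which preserves the
asymmetry that makes bagging recoverable; the symmetric variant remains
available as `pair_direction = "both"` for studying the degenerate case.

## Problem sizes and defaults

The default benchmark used throughout the tests is 20 classes, 8
confusable pairs, half two-handed, 12 samples per class in 3 repetition
groups — small enough to iterate on quickly, large enough that all four
tree stages do real work.  HMM training runs at most 20 EM iterations to
relative tolerance `1e-4`; forests default to 30 trees, the size at which
the sweep plateaus.  Cross-validation orderings are averaged over 5
independently generated benchmarks and robustness over 10 contamination
seeds.

## Known limitations

* Tree serialization: HMMs round-trip bit-exactly through a documented
  JSON schema (`write_hmm_json()`); full-tree persistence is not provided
  because the SVM stages wrap `e1071` fits that have no stable JSON
  form.  Refitting from the seed is the supported reproduction path.
* The generator's confusable pairs perturb envelope timing and trajectory
  amplitude only; real confusable signs may differ in ways that interact
  differently with the stage ordering.
* Continuous (sentence-level) recognition with language models, Viterbi
  decoding, out-of-bag weighting and signer-independent evaluation are
  out of scope.
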