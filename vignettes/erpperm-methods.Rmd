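---
title: "Methods: cluster permutation tests, default-prior Bayes factors, and effect-injection power simulation for ERP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster permutation tests, default-prior Bayes factors, and effect-injection power simulation for ERP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`erpperm` implements the statistical core of a multi-electrode ERP reading
study: spatio-temporal cluster-based permutation testing of
event-related-potential differences, Jeffreys–Zellner–Siow (JZS)
default-prior Bayes factors on window-averaged amplitudes, and a
single-trial effect-injection simulation that estimates, for a given
analysis pipeline, the probability of detecting components such as a
sustained anterior negativity (SAN) or a P600 as a function of effect
size and sample size. Because the motivating experiment's raw EEG is not
publicly deposited, the package ships a synthetic-data generator that
emulates the study's design, so every stage is testable end to end.

## The emulated experiment

The generator's defaults describe a word-by-word (RSVP) reading study in
Mandarin: `N = 37` subjects, 61 active electrodes sampled at 500 Hz,
eight conditions — four sentence types (indirect question, direct
question, declarative, whether-question) crossed with two dependency
lengths — at 48 trials each. Words appear for 300 ms with a 300 ms blank
(SOA 0.6 s). Epochs are locked to the main verb; the critical
wh-word/demonstrative ("target") appears 2.4 s (short) or 3.6 s (long)
after the verb, and interval analyses span the verb-to-target window
(−0.3 to 2.2 s or −0.3 to 3.0 s). Target-word analyses use −0.3 to 1.0 s
epochs around the per-condition target onset.

Scalp regions are *identity-based*: the six printed electrode-ID lists
(left/midline/right × anterior/posterior), with the derived 24-electrode
anterior and 20-electrode posterior unions used as injection targets. The
source lists place electrodes 17 and 42 in both the left-anterior and
left-posterior regions; `build_region_map()` preserves this verbatim and
warns, rather than silently "fixing" the overlap — region membership is
part of the stated analysis, not ours to amend. Since the true cap
coordinates are not part of those definitions, `build_default_layout()`
generates a deterministic quasi-equidistant stand-in on the upper unit
hemisphere (concentric rings of 1, 6, 12, 18, 24 electrodes; outermost
ring first, each ring starting at the anterior midline, so ID 1 is an
anterior-midline electrode). Coordinates only drive spatial adjacency and
spline interpolation, neither of which needs the literal cap geometry.

## Synthetic background EEG

Each trial's background is zero-mean Gaussian noise that is

* temporally colored: amplitude spectrum `f^(-exponent/2)` (default
  exponent 1, with a 0.75 Hz knee so the DC region stays bounded) plus a
  Gaussian alpha bump (10 Hz, SD 1.5 Hz) holding `alpha_power_fraction`
  (default 0.2) of the variance;
* spatially correlated: channel correlation `exp(-d / L)` with `L` =
  2 median inter-electrode distances (Cholesky mixing);
* scaled to a single-trial per-sample SD of 15 µV (typical of 20 Hz
  low-passed scalp EEG; the source study reports no noise level), with
  lognormal per-subject and per-trial gains (σ = 0.1).

This is deliberately a *minimal* model: it reproduces the temporal
autocorrelation and spatial smoothness that make cluster-level inference
nontrivial, which is what the permutation machinery must cope with. It
does not model dipolar topographies, ocular or muscle artifacts,
non-stationarity, or realistic ERP waveshapes. A green calibration test
therefore establishes that the *statistics* behave correctly under a
plausibly structured null — not that the generator passes for real EEG.

ERP components are injected as `amplitude × envelope` on an electrode set
and time window, with the subject-level amplitude drawn from
`Normal(amplitude, amplitude_sd)` — a random-subject-effect structure
matching what the repeated-measures analyses assume. The default envelope
is a half-cosine-ramped plateau (50 ms ramps) to avoid the filter ringing
a hard-edged boxcar would cause; a boxcar is available and is what the
exactness tests use.

## The cluster-based permutation test

For per-subject condition-average maps over (electrode, time):

1. a pointwise statistic at every (electrode, time) point — one-way
   repeated-measures ANOVA `F = MS_cond / MS_(cond×subject)` with
   `df = (k−1, (k−1)(n−1))` for `k ≥ 3` conditions, or a paired t
   (`df = n−1`) for `k = 2`;
2. points with uncorrected `p < 0.05` are clustered under spatio-temporal
   adjacency — two points connect iff they share an electrode and are one
   sample apart, or share a time point and are neighbouring electrodes
   (chord distance below 1.5× the median nearest-neighbour distance;
   t clusters form within one sign);
3. the statistic is summed within each cluster;
4. a permutation null is built by shuffling condition labels *within
   every subject* (sign flips of the paired differences for t) and
   recording the maximum cluster sum per permutation (1,000 permutations
   by default);
5. a cluster is significant when its (absolute) sum exceeds the 95th
   percentile of that null; we report `p = (1 + #{null ≥ sum})/(1 + P)`
   so p-values are never exactly zero.

Numerical choices worth stating: condition sums whose SS falls below
`1e-10` of the total SS are treated as exactly zero (so identical
conditions give `F = 0` rather than `0/0`); points with zero error
variance but non-zero effect give `F = ∞` with a warning; ties in the
maximum cluster sum are broken by value only (sums are continuous; exact
ties are measure-zero). The permutation unit is the per-subject
condition-average map, not the single trial — that is the exchangeability
unit the repeated-measures model implies. Each permutation pass permutes
all `k` labels jointly; pairwise contrasts use the dedicated t pathway.
One master seed derives all permutation substreams, so results are
bit-reproducible.

The two-sided handling for t (clusters within sign, tested against the
null of maximum |signed sum|) is our choice — the motivating analysis
reported both negative (SAN) and positive (late positivity) effects, so a
one-sided rule would be indefensible.

## Preprocessing

* Mastoid re-reference subtracts the average of two designated reference
  channels per sample; on the synthetic montage the two outer-ring
  electrodes nearest the retro-auricular directions stand in for
  mastoids (`default_mastoids()`).
* The 20 Hz low-pass is a 4th-order Butterworth applied forward and
  backward (zero phase, squared magnitude, −6 dB at cutoff), with odd
  end-reflection padding and steady-state initial conditions. The
  motivating analysis names only the cutoff; order, family and zero-phase
  application are our (configurable) choices, matching common ERP
  practice.
* Baseline correction subtracts the per-trial, per-electrode mean over
  the baseline window (first 100 ms of the interval epoch; 100 ms before
  each word for the per-word analyses; 100 ms pre-stimulus at the
  target).
* Bad channels are replaced by spherical-spline interpolation: kernel
  `g(cosθ) = (1/4π) Σ (2n+1)/(n(n+1))^m P_n(cosθ)` truncated at 50
  terms, order `m = 4`, ridge `λ = 1e-5` on the good-channel system with
  a sum-to-zero constraint. The defaults follow the standard EEG spline
  literature; constants are reproduced exactly and smooth low-order
  fields to well under 5% leave-one-out error.

## JZS Bayes factors

Window-averaged amplitudes (trials → electrodes in the region → samples
in the window, one scalar per subject × condition) feed two Bayes
factors:

* **Paired t**: `BF10` with a Cauchy(0, r) prior on the standardized
  effect (`r = √2/2` by default), computed by adaptive quadrature of the
  standard scale-mixture integral on the log-g scale (relative error
  reported, ~1e-10 requested).
* **Repeated-measures ANOVA**: `{condition + subject}` vs `{subject}`
  with g-priors on standardized sum-to-zero effects (`r_effect = 0.5`
  fixed, `r_subject = 1` random — the reference implementation's
  documented defaults; the motivating analysis says only "default
  priors"). In the balanced one-way design the subject and condition
  effect spaces are orthogonal, giving a closed-form marginal likelihood
  for fixed `(g_s, g_c)`; the two g integrals are evaluated by Monte
  Carlo over prior draws (10,000 by default, seeded, shared subject
  draws in numerator and denominator) with a delta-method Monte-Carlo
  SE. This implementation was cross-checked during development against
  the reference R package on the same tables (agreement within MC
  error), and in the test suite against an independent two-dimensional
  quadrature oracle of the same model.

One genuinely open design point: whether the original Bayesian ANOVA
modelled subject as an additive random factor. We assume it does (the
reference default), and say so in outputs.

**A deliberate red test.** The acceptance suite asserts that the `k = 2`
ANOVA Bayes factor agrees with the paired-t Bayes factor within 3
Monte-Carlo SEs. That property does not hold for this model family: with
subject effects under a g-prior in *both* models, the subject block
couples to the condition effect through the shared error variance, so
the `k = 2` ANOVA BF differs from the paired-t BF (at the matched scale
`r_t = r_effect`) by a systematic few percent — sometimes tens of
percent — regardless of Monte-Carlo precision. The reference
implementation exhibits the same gap. We keep the faithful model and let
that single assertion fail rather than bending either the model or the
tolerance; the paired-t route remains the one used for two-condition
contrasts throughout the pipeline.

Verbal labels accompany every BF (below 3.2 "inconclusive", 3.2–10
"substantial", 10–100 "strong", above 100 "decisive", with the favoured
model named).

## Effect-injection power simulation

The power engine asks: *if an effect of mean size μ were present, would
this exact pipeline find it?* Per repetition:

1. each subject's single trials are pooled across all true conditions,
   shuffled, and split into three near-equal pseudo-condition
   partitions;
2. a stochastic effect `E ~ Normal(μ, σ_subject)` — σ estimated per
   subject as the across-trial SD at a single reference point (electrode
   1, an anterior-midline channel, at 250 ms for SAN; a posterior-midline
   channel for P600) — is added to one partition, on the 24 anterior
   (SAN, negative-going) or 20 posterior (P600, positive-going)
   electrodes, constant over the injection window;
3. partitions are trial-averaged per subject and the same
   three-condition cluster permutation test as the experimental analysis
   is run; a repetition counts as a detection when any cluster is
   significant (a stricter must-overlap-the-injected-electrodes criterion
   is available for diagnostics).

Defaults follow the stated grids: μ ∈ {0.5, 1, 1.5, 2, 2.5, 3} µV for
SAN, {0.5, 1, 1.5, 2} µV for P600, N ∈ {20, 30, 37} subjects subsampled
without replacement, 100 repetitions per cell. Choices the source leaves
open, fixed here: `E` is drawn per trial (per-subject drawing is
available); the SAN injection window is the full verb-to-target interval
and the P600 window 0.5–0.7 s post-target, matching each component's
analysis window; the injected sign follows the component's polarity.
Units are microvolts throughout — the source prints "mV", which is
physiologically impossible for scalp ERPs and inconsistent with the
cited literature.

**Calibration subtlety.** With few trials per partition, the stochastic
draw `E ~ N(0, σ)` at μ = 0 is *not* an exchangeable null: it adds
condition-specific between-subject variance (of order `σ/√m` for `m`
trials per partition) and inflates the detection rate well above α. The
ratio of injection noise to data noise is independent of the trial
count, so this is an intrinsic property of the injection design, not a
small-sample artifact. The μ = 0 calibration cell therefore uses
`sigma_scale = 0` (injection disabled — the exact null of the test),
while all μ > 0 cells run the faithful stochastic procedure. The
acceptance fixture's μ grid {0.5, 1.5, 3, 5} µV and N grid {8, 16, 24}
were chosen once to span sub- to supra-threshold group effects at the
miniature scale (24 subjects, 48 pooled trials, 20 electrodes, 0.5 s at
100 Hz, P = 200, 50 repetitions).

## Reproducibility

Every stochastic function takes a seed; child seeds for permutations,
repetitions and subjects are derived deterministically from one master
seed, and the RNG state of the calling session is always restored.
`run_full_study(config)` re-runs bit-identically from `(config, seed)`;
the report JSON, BF and power tables are plain text. Epoch sets persist
as a serialized R list with a documented schema (`amp`, `time`, `srate`,
`layout`, `design`, `lock`, `provenance`); an HDF5 container would be the
natural alternative but has no R binding in the supported environment.

## Known limitations

* The generator's background is stationary Gaussian; real EEG is neither,
  and real cluster-test power will differ from synthetic power. The
  power engine's *numbers* are therefore only meaningful relative to the
  data fed into it — which is exactly how it is meant to be used (feed it
  your own pre-processed single trials).
* The BrainVision reader covers the common binary layouts (multiplexed /
  vectorized; float32 / int16 / int32) and is intended for re-analysis,
  not as a general converter. ICA-based artifact removal is out of scope;
  synthetic data are artifact-free.
* Full-scale default tensors (37 × 8 × 48 × 61 × ~2,500 samples) are
  large (~17 GB); simulate at reduced sampling rate / trial counts unless
  you have the memory, or analyze real data read from disk.
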