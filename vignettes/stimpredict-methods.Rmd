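---
title: "Quantifying prediction and short-term memory in stimulated cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying prediction and short-term memory in stimulated cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Cultured cortical networks on multielectrode arrays (MEAs) respond to
repeated stimulation with stereotyped network bursts. If a network's ongoing
activity reduces the uncertainty about *upcoming* stimuli, the network
predicts; if it reduces uncertainty about *recent* stimuli, it remembers.
`stimpredict` implements the full information-theoretic machinery for
quantifying both from spike data, together with a synthetic data generator
that reproduces the relevant phenomenology of such experiments, so that the
whole chain can be exercised, tested and calibrated without access to
recordings.

# Binary words and mutual information

Activity from 59 electrodes is divided into 100-ms bins and binarised:
`x_i(n) = 1` when electrode `i` fired at least once in bin `n` (bins are
0-based and half-open, and a stimulus belongs to the bin containing its
onset — the convention is arbitrary but must be fixed for the alignment of
activity and stimulus vectors). The stimulus train becomes a binary vector
`s(n)` the same way. Mutual information is always computed through the
entropy identity

    MI(S; X) = H(S) + H(X) - H(S, X),

with all three entropies estimated by the same estimator and the result
clamped at zero (the identity can come out marginally negative in finite
samples). Base-2 logarithms are used throughout; all quantities are in bits.

## Entropy estimation

Word alphabets grow as `2^k` with the word width `k`, so even one hour of
data (36,000 bins) undersamples wider words. Three estimators are provided:

* **plugin** — maximum likelihood, exact oracle for the small-alphabet tests;
* **miller_madow** — plug-in with the first-order bias correction
  `(K_obs - 1) / (2 N ln 2)`;
* **dirichlet_bayes** (default) — the posterior-mean entropy under a mixture
  of symmetric Dirichlet priors over the full alphabet, with 25 log-spaced
  concentrations between 10^-3 and 10 weighted by the marginal likelihood of
  the observed counts.

The mixture estimator follows the usual Bayesian recipe for undersampled
discrete distributions; a benchmark in the test suite (10-bit words, 500
samples, 100 replicates) shows its RMSE is roughly seven times smaller than
the plug-in estimator's in that regime. The estimator is a pluggable
strategy (`infotheory.estimator`), so a different prior construction can be
dropped in without touching the pipeline.

## Greedy electrode selection

The joint word over all 59 electrodes is hopelessly undersampled, so the
pipeline greedily builds a word of at most five electrodes: start with the
single electrode with the highest MI with the stimulus vector, then add
whichever electrode maximises the joint MI, and so on. Ties break towards
the lower electrode index for determinism. Greedy selection is a lower
bound: the test suite contains an XOR construction in which greedy provably
misses the synergistic optimum — this is accepted behaviour, not a defect.

One practical refinement: with optogenetic-like (global) stimulation the
evoked response starts one bin after the stimulus, so zero-lag MI carries no
signal to select on. `greedy_select()` therefore accepts an `align_shift`
(bins), and `run_session()` picks it per hour as the lag in 0–3 bins at
which the best single electrode is most informative. For immediate-response
sessions this reduces to the zero-lag selection.

# Prediction and memory curves

For positive shifts `dt` (prediction), each stimulus bin is paired with the
activity word `dt/100` bins *before* it; for `dt <= 0` (memory), with the
word `|dt|/100` bins *after* it. `dt = 0` belongs to the memory range.
Curves are evaluated on `dt = 100..2000 ms` (prediction) and
`-1000..0 ms` (memory); their sums over the full grids are the scalar
summaries ΣMIfuture and ΣMIpast. This sign convention is the one under
which the prediction curve peaks at the modal interstimulus interval (the
network signals that the next stimulus most probably arrives one modal
interval after the last response) and the memory curve peaks at the response
latency — both structural facts the acceptance tests verify on synthetic
sessions.

Two controls isolate where predictive information lives:

* **Masking** — the words in the stimulation bin and the three following
  bins are replaced by words drawn (seeded, uniformly with replacement)
  from stimulation-free donor bins, defined as bins at least 1 s (10 bins)
  after every preceding stimulus and not themselves stimulus or masked
  bins. Whole rows are substituted, preserving within-word correlations;
  whether per-electrode substitution would be preferable is undecidable
  from the description the analysis follows, and whole-row substitution is
  the conservative choice.
* **Self-information** — MI between the stimulus vector and a shifted copy
  of itself, the intrinsic predictability of the stimulus process. With
  perfectly reliable responses confined to the stimulation bin, the
  prediction curve collapses onto the self-information curve, and the
  difference no longer peaks at the modal interval.

# The stimulus process

The generator reproduces the constraints of the experimental protocol:
interstimulus intervals (ISIs) on a 0.1-s grid with a hard 1-s floor, a
mean rate of 0.2 Hz (stationary mean ISI 5 s), a modal interval of 1.1 s,
and positive correlation between consecutive ISIs, produced by a sticky
two-state hidden Markov chain.

The default parameterisation was chosen once, from variance arithmetic, as
follows. The marginal ISI distribution is a two-component log-normal
mixture: a sharp short component (σ_log = 0.12) whose mode sits exactly at
1.1 s, and a broad long component (σ_log = 0.25) whose location is
calibrated by root finding at construction so the stationary mean is
exactly 5 s. The two hidden states share these components but weight the
short one differently (0.40 vs 0.10); with a self-transition probability of
0.9 this yields slowly alternating short-heavy and long-heavy regimes, a
lag-1 ISI autocorrelation of about 0.07, and — because the state means
differ by only ±0.75 s — a standard error of the n = 10^4 sample mean of
about 0.033 s, comfortably inside the 2% mean-rate calibration the quality
checks enforce. Making the hidden states differ in component *weights*
rather than component *means* is what reconciles long-range correlation
with a tight rate calibration: state-mean differences enter the variance of
the sample mean multiplied by `(1+rho)/(1-rho)` of the state chain, which
for very sticky chains makes a 2% calibration at n = 10^4 statistically
unattainable. Discretisation is by interval mass on the 0.1-s grid, with
the 1.0-s point carrying only its right half-interval `[1.0, 1.05)`; this
left truncation is what makes the mass at 1.2 s exceed the mass at 1.0 s
and thereby pins the prediction-curve peak at 1100 ms rather than 1000 ms
for immediate responses.

# The synthetic MEA

`simulate_recording()` is a statistical emulation, not a biophysical model:

* spontaneous activity — independent Poisson processes per electrode with
  log-normal rates (median 0.5 Hz, σ_log = 1), so that typically all but a
  couple of electrodes clear the 250-spikes-per-hour activity criterion;
* evoked responses — per stimulus, with probability `reliability` the 15
  response electrodes fire Poisson spikes at 50 Hz for 200 ms (defaults;
  latency 0 for focal-like sessions, 100 ms for global-like ones);
* slow rundown — reliability decays by 2.5% per elapsed hour by default,
  emulating the reported late decrease in responsiveness over 20-h
  experiments; unit tests set this to zero.

The generator does **not** emulate network bursts in spontaneous activity,
electrode crosstalk, stimulation artifacts, non-stationary background
rates, or the gradual absorption of response patterns into spontaneous
activity that accompanies long-term memory-trace formation. Passing tests
therefore demonstrate the correctness of the analysis chain on data with
known structure, not the physiological findings themselves.

`simulate_cascade()` is a minimal mechanistic stand-in used to ask one
qualitative question: does the prediction peak require synaptic
transmission? Units evolve in 1-ms steps with one refractory step; a spike
of unit `j` triggers unit `i` at the next step with probability
`adjacency[i, j]`. Stimuli force a small target subset to fire. The
default wiring makes ordinary edges weak (background branching ratio ~0.5,
so spontaneous spikes rarely cascade) and edges *out of the stimulus
targets* strong — direct stimulation fires the targets synchronously, and
synchronous volleys are what reliably recruits the network burst. The
targets default to units outside the recorded 59 (electrodes record small
groups of neurons, and stimulation directly activates a small, largely
unrecorded subset), so with synapses disabled the recorded raster contains
nothing stimulus-locked, and the prediction curve falls inside the
shuffled-stimulus control band — reproducing, at the level of the
simulation, the claim that prediction depends on synaptic propagation.

# The predictive information bottleneck

For the efficiency analysis the full stimulus past and future at each bin
are replaced by the time since the last stimulus (`S+`) and the time to the
next (`S-`), both capped at 20 bins (2 s, matching the maximal prediction
shift) with one overflow bucket; stimulus bins carry `S+ = S- = 0`, a
self-consistent convention chosen here since the analysis description fixes
none. The measured point of a culture is `Imem = I[S+; X]`,
`Ipred = I[S-; X]`.

The frontier — the maximal predictive power achievable at given memory —
is solved as an information bottleneck over encoders `p(x | s+)`: for each
of 50 log-spaced trade-off parameters β in `[0.1, 1000]`, the standard
self-consistent updates (encoder, representation marginal, decoder) are
iterated to an objective change below 10^-8 (cap 2000 iterations) from 5
seeded random initialisations, keeping the best restart. The deterministic
identity encoder is appended as the high-memory endpoint, which attains the
data-processing cap `I[X; S-] = I[S+; S-]` exactly. The upper concave
envelope of the achieved (memory, prediction) pairs is the reported curve;
concavity and monotonicity are asserted on every solve, and on 2×2 joints
the envelope matches an exhaustive scan over the encoder simplex within
0.005 bits. Efficiency is `100 · Ipred / D*(Imem)` with `D*` linearly
interpolated on the envelope (the measured memory clipped into the solved
range); interpolation rather than nearest-point comparison is used because
the envelope is piecewise-linear by construction.

The representation cardinality `n_x` defaults to the number of `S+`
categories, which is sufficient for the optimum; the tests verify that
growing `n_x` never lowers the frontier.

# Session analysis and exclusion rules

`run_session()` mirrors the experimental bookkeeping: electrodes qualify as
active with at least 250 spikes in the first hour; cultures qualify with at
least ten active electrodes and a clear response — some post-stimulus bin
of the pooled 10-ms PSTH strictly exceeding the pre-stimulus mean plus five
standard deviations (windows of 500 ms either side; the 5-SD rule is fixed,
the windows are this implementation's choice). Sessions failing either rule
are flagged excluded rather than analysed. Analysis then proceeds per
one-hour segment — activity filter, alignment, greedy selection, the four
MI curves plus self-information, and the two curve sums — with electrode
selection recomputed per hour, since informativeness may drift over long
experiments.

Across segments or cultures, `fit_pred_mem()` regresses ΣMIfuture on
ΣMIpast (ordinary least squares, Pearson correlation, t-test), and
`trend_over_hours()` tests the per-hour slope and offset series for a
linear time trend. Both across-culture-per-hour and across-hour-per-culture
groupings are available, since either framing is legitimate and they answer
slightly different questions.

# Problem sizes and reproducibility

The package's own verification runs at desk scale: one-hour sessions
(36,000 bins, ~720 stimuli) for the peak-location and masking checks,
twenty one-hour segments for the prediction–memory coupling, and
half-to-one-hour cascade runs; 20-hour experiments remain supported through
`experiment.hours`. Every stochastic stage takes an explicit seed, derived
from a single experiment seed plus a fixed per-stage label, and the
experiment driver's outputs are byte-identical across reruns of the same
configuration.

# Known limitations

* The Dirichlet-mixture estimator approximates, but is not, the specific
  binary-data prior construction used in the experimental literature; the
  estimator interface exists precisely so a faithful port can replace it.
* The bottleneck treats the activity word as a channel from `S+` only; for
  stimulus processes with strong inter-interval correlations a richer past
  summary could in principle carry more, and measured points are then only
  guaranteed to respect the frontier within estimator tolerance.
* The cascade model is a caricature (1-ms clock, one-step refractoriness,
  no adaptation or inhibition); it supports a qualitative claim about
  synaptic propagation, nothing more.
* Masked and unmasked curves share the greedy electrode set of the
  unmasked data; selecting afresh on masked data would bias the control
  upward.
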