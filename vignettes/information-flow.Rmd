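---
title: "Measuring information flow in fluorescence time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring information flow in fluorescence time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infoflow)
```

## The problem

Time-lapse fluorescence imaging of a tissue — say, embryonic stem cell
explants expressing a calcium indicator in one channel and an actin
reporter in another — yields one intensity trace per region of interest
(ROI) per channel. The scientific questions are relational: does a
region's future depend on its own past (self-predictability)? Do nearby
regions share information? Does information *flow* from one region or
channel to another, in a specific direction? Information theory answers
these questions model-free, but each estimator has well-known failure
modes, and distinguishing genuine temporal organization from
small-sample bias and imaging artifacts requires an explicit null.
`infoflow` implements the full chain — extraction, binarization,
estimation, surrogate testing — together with synthetic dynamics that
realize each failure mode on demand.

## From pixels to binary states

**Extraction.** An ROI is a static, axis-aligned pixel rectangle
(0-based offsets, half-open extents, so a `width`×`height` ROI at
(`x0`,`y0`) covers columns `x0..x0+width−1`). The trace value at frame
*t* is the arithmetic mean of all pixels inside the rectangle — the
standard summary for fluorescence signals, robust to single-pixel noise
and indifferent to ROI size rescaling. ROIs must lie fully inside the
image plane; motion correction and tracking are out of scope (in
practice ROIs are chosen to remain within one cell). Channels are
assumed frame-synchronous: one stack per channel with equal frame
counts. The conventional acquisition this mirrors is 60 frames at one
frame per minute, with nine 100×100-pixel ROIs per specimen.

**Binarization.** All estimators here operate on binary (active /
inactive) state sequences. Each `(roi, channel)` trace is thresholded
*on its own values* — per-trace rather than per-channel, because the
signal-to-noise framing is local to a region — with

* `mean` (default): the trace's arithmetic mean as the cutoff between
  signal and noise;
* `median`: guarantees a balanced state sequence;
* `fixed`: a user-supplied absolute level;
* `otsu`: the level maximizing between-class variance of the trace's
  value histogram, appropriate for clearly bimodal traces.

Ties (values exactly at the threshold) map to **inactive**. This
tie-break makes the degenerate constant trace deterministic — nothing
exceeds its own mean, so the output is all zeros — and such traces are
flagged with a warning rather than an error, because a dead ROI is data,
not a program fault. Mean and median thresholds are invariant under
adding a constant to the trace and under positive rescaling, so
binarization is unaffected by detector offset and gain.

Binarization discards amplitude information by design; continuous-valued
estimators (kernel or nearest-neighbor) are deliberately out of scope.

## The estimators

All metrics are plug-in (maximum-likelihood) estimates: empirical joint
frequencies substituted into the defining formulas, base-2 logarithms,
`0·log 0 ≡ 0`, undefined conditionals contribute zero. No analytic bias
correction is applied — plug-in estimates of MI-like quantities are
positively biased at small samples, and that bias is absorbed by the
surrogate null instead, which is subject to exactly the same bias.

For a binary sequence with active fraction *p*:

* **Shannon information** `I = −[p log₂ p + (1−p) log₂(1−p)]`, the
  information content of the binarized signal; 1 bit at *p* = 0.5,
  0.47 bits at *p* = 0.1 or 0.9. It bounds every other metric, which is
  why a reporter active half the time is more informative than a
  brighter one active 90% of the time.
* **Mutual information** `MI(X;Y) = Σ p(x,y) log₂ p(x,y)/(p(x)p(y))`
  over frame-aligned pairs. Symmetric; self-MI equals the information
  content (the diagonal of an MI table). MI detects *any* shared
  structure — including shared artifacts such as illumination
  fluctuations or photobleaching.
* **Delayed MI** at lag *u*: MI over pairs `(x[t], y[t+u])`. Detects
  lagged correlation; it cannot distinguish propagation from independent
  oscillation (two in-phase period-2 oscillators have DMI = 1 bit at
  lag 1 with no interaction whatsoever).
* **Active information storage** with history *k*:
  `I(X_t ; X_{t−k..t−1})`, pooled over every frame with a complete
  history window. High AIS marks periodic or persistent dynamics whose
  past predicts their present.
* **Transfer entropy** (source history *l*, target history *k*):
  `H(X_t|X^{(k)}) − H(X_t|X^{(k)}, Y^{(l)})`. Directional, and zero
  whenever the target is already deterministic given its own history —
  this is what rescues the oscillator and common-driver cases where DMI
  fires spuriously.
* **Effective information** of an *n*-state row-stochastic transition
  model: MI between a uniformly distributed intervention (each state
  imposed with probability 1/*n* — maximum-entropy "noise injection")
  and the resulting next-state distribution. `log₂ n` bits for a
  permutation map, 0 for a constant map. A non-uniform intervention
  distribution can be supplied, but uniform is the default because it
  is the assumption-free choice.

**Windows and alignment.** Metrics pool over every frame index with
complete history windows; there is no circular wrapping, which would
fabricate transitions between the last and first frames.

**Embedding defaults.** `k = l = 1`, `lag = 1`. With T ≈ 60 frames and
`2^(k+l+1)` joint states to populate, anything beyond 1 is severely
undersampled; the package warns whenever the joint state count exceeds
T/3. Larger embeddings are available but should only be used with
proportionally longer recordings.

## Surrogate significance

The null hypothesis for every metric is "no temporal organization": the
observed value is compared against `n` replicates in which the
designated trace(s) are re-ordered by independent uniformly random frame
permutations. Permutation preserves each trace's marginal exactly (so
surrogate entropy equals observed entropy replicate for replicate) while
destroying all temporal structure — the plug-in bias is therefore
present in the null too, and significance reflects structure, not bias.

The empirical p-value is one-sided with the add-one correction,
`p = (1 + #{surrogate ≥ observed}) / (1 + n)`, bounded below by
`1/(n+1)` and never zero. One-sided because all metrics are
non-negative and the question is whether the observed value *exceeds*
the null; the add-one form is the standard finite-sample-valid
permutation p-value. The conventional choice is `n = 1000` surrogates
and a significance level of 0.05. Because the metrics are discrete
statistics, surrogates tie with the observed value at an appreciable
rate and ties count toward the numerator, so the test is mildly
conservative: calibration on independent 60-frame traces yields
rejection rates slightly below the nominal 0.05 (the acceptance script
reports the realized rate).

Null construction is selectable (`shuffle_source`, `shuffle_target`,
`shuffle_both` for pairwise metrics; `shuffle_self` for entropy/AIS);
whole-series permutation is the only surrogate family offered — block
or phase-randomized surrogates, which preserve some temporal structure,
are out of scope.

Two levels of inference are provided, because they answer different
questions: per-cell empirical p-values (is *this* pair's value above
its own shuffle null?) and Mann–Whitney rank-sum tests
(`rank_sum_compare()`) for group-level contrasts between collections of
metric values, exact for group sizes up to 8 without ties and
tie-corrected normal approximation otherwise. **No multiple-testing
correction is applied across table cells**; the flags are exploratory
screen output, and users comparing many cells should treat the expected
false-positive count (`alpha ×` number of cells) accordingly.

## The synthetic regimes

The generators produce tidy trace tables from a seed and nothing else
(every generator is a pure function of its arguments; `withr::with_seed`
isolates the RNG). Defaults mirror the reference acquisition — 9 ROIs,
60 frames — while recovery *simulations* in the tests and acceptance
script use T = 600 and 3 ROIs, because 60-frame plug-in estimates are
dominated by sampling noise and the point of those simulations is to
verify estimator behavior, not to re-enact a single noisy acquisition;
problem sizes are stated in each test.

* `gen_iid()` — independent Bernoulli(q) states; the calibration null.
* `gen_oscillator()` — square waves (default period 6 frames, a
  several-minute pulsing cycle; per-frame flip noise 0.05) with random
  phases unless specified. In-phase noiseless period-2 oscillators are
  the canonical DMI false positive.
* `gen_coupled_chain()` — ROI *j*+1 copies ROI *j* at lag 1 with flip
  probability `(1−ε)/2` (default ε = 0.8); genuine directed flow whose
  direction TE must recover.
* `gen_common_driver()` — observed ROIs copy a hidden driver with
  independent noise (default 0.1). The `driver = "oscillator"` option
  uses a deterministic period-2 driver, which makes the noiseless
  marginals exactly balanced and hence MI exactly 1 bit on even-length
  series; the Bernoulli driver realizes the same regime up to sampling
  fluctuation in its marginal.
* `gen_bleaching()` — intensity traces: independent Gaussian noise (sd
  5) on a shared exponential decay (rate 0.05/frame from baseline 100,
  i.e. an ~20-frame mean lifetime — strong bleaching over a 60-frame
  movie). After mean binarization, every trace is high-early/low-late,
  and pairwise MI is flagged significant against the shuffle null: the
  photobleaching artifact, reproduced end-to-end. With zero drift the
  traces are pure noise and flags fall to the nominal rate.
* `gen_two_channel_model()` — a stylized validation mechanism, **not**
  a biophysical model: channel A ("actin"-like) is per-ROI persistent
  (symmetric Markov chains, self-transition 0.9 → high AIS ≈ 1 − H(0.9)
  ≈ 0.53 bits); channel B ("calcium"-like) copies its ROI's previous A
  state with probability 0.3, else — only when the local A gate is open
  — copies the neighboring ROI's previous B state with probability 0.6,
  else flips a coin. Its designed signatures: AIS(A) > AIS(B);
  inter-ROI TE significant within B but not within A; within-ROI
  TE(A→B) > TE(B→A). Ground-truth couplings are attached as an
  attribute. The parameter triple (0.9, 0.3, 0.6) was chosen once so
  that each pathway is individually strong enough to detect at T = 600
  while keeping `w_a + coupling ≤ 1` (the branches are mutually
  exclusive draws of one uniform variate).

What the generators do **not** emulate: continuous intensity dynamics
within the active state, photon/shot noise, cell motion, optical
crosstalk between channels, or spatially structured propagation. Passing
the recovery suite therefore shows the estimators and the testing
machinery behave correctly on binary dynamics with known structure — it
does not validate any particular biological claim about real tissue.

## Numerical and design choices

* Joint distributions are accumulated as integer word codes
  (`tabulate` over `2^k`-state histories); the test suite checks every
  estimator against an independent brute-force enumeration oracle to
  1e-12 on series up to length 12, and properties (symmetry, bounds,
  lag-0 and self-metric reductions) on random series.
* Transition matrices must be row-stochastic within 1e-9; effective
  information is invariant under simultaneous row/column permutation
  (checked), and its uniform-intervention value is cross-checked
  against a Monte-Carlo interventional sampler.
* Surrogate comparisons use `observed − 1e-12` as the tie boundary so
  floating-point noise cannot flip a tie.
* Per-cell surrogate seeds in `pairwise_table()` and per-stage seeds in
  `run_pipeline()` are drawn from the master seed, so a whole table or
  run is reproducible bit-for-bit from `(inputs, seed, n)`; re-running
  a pipeline config produces byte-identical CSVs.
* The MI table diagonal reports information content without a p-value:
  the permutation null preserves marginals, so it cannot test a
  marginal quantity (every surrogate would tie the observed value and
  `p` would be 1 by construction).
* Trace CSVs encode the channel in the header as `label@channel`; bare
  labels inherit a default channel.

## Limitations

* Plug-in estimates at T = 60 with k = l = 1 remain noisy; single-cell
  conclusions should rest on the surrogate test and, across specimens,
  on rank-sum group contrasts, not on raw bit values.
* TE conditions only on the target's own k-history — a hidden process
  influencing both traces at longer memory than k can still produce
  spurious transfer (the shuffle null does not protect against
  realized higher-order structure in a *finite* target series, which is
  why directional claims are made on recovery rates across
  realizations, not single runs).
* The mean threshold registers any slow trend as state structure —
  useful for catching bleaching, dangerous for interpreting it; inspect
  `plot_binarized()` output before trusting downstream flags.
* No multiplicity correction across table cells, matching exploratory
  practice; treat flag counts accordingly.
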