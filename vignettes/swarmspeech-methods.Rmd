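---
title: "Methods: swarm-selected speech features for binary screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swarm-selected speech features for binary screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmspeech)
```

## Scope and intent

`swarmspeech` implements a speech-based binary screening pipeline of the
kind used in computational-psychiatry studies of depression: MFCC feature
extraction from audio, wrapper feature selection driven by three swarm
optimizers (dragonfly, firefly, moth-flame), a compact 1D-CNN + LSTM
sequence classifier, and macro-averaged evaluation. The clinical corpora
such pipelines are usually run on (clinical interviews with per-session
depression labels) are access-restricted, so the package ships
deterministic synthetic generators with known ground truth and every
claim made by its test suite is a claim about statistical structure the
generators control — not about clinical performance. Nothing in this
vignette states an empirical number that the test suite or the
acceptance script does not itself compute.

## The MFCC front end

The front end is implemented from first principles (the environment this
package targets has no speech-DSP library, and the chain is simple
enough that owning it keeps every convention explicit):

1. **Pre-emphasis** `y[t] = x[t] - 0.97 x[t-1]`, compensating the
   spectral tilt of voiced speech.
2. **Framing**: 25 ms Hamming windows, 10 ms hop, no edge padding, so
   the frame count is exactly `floor((len - L)/H) + 1`. One second of
   16 kHz audio yields 98 frames.
3. **Power spectrum**: `|FFT|^2 / n_fft` on 512 points (zero-padded).
4. **Mel filterbank**: 40 triangular filters with peaks uniformly
   spaced on `m = 2595 log10(1 + f/700)` between 0 Hz and 8 kHz.
   Triangle vertices are snapped to FFT bin indices (the HTK-style
   integer-bin construction). This makes the filter geometry exactly
   testable — each interior filter's peak bin carries weight 1 in its
   own row and weight 0 in both neighbors — at the cost of slightly
   ragged triangles at low frequencies. A filter whose three vertices
   collapse into one bin is a configuration error (`n_mels` too large
   for the FFT resolution).
5. **Log compression** with floor `1e-10`, so silence maps to a finite
   constant instead of `-Inf`.
6. **Orthonormal DCT-II**, first 13 coefficients retained. The
   orthonormal scaling (rather than HTK's unnormalized dialect) is
   chosen so that round-trip and Parseval-style identities hold
   exactly in tests, and so golden values are dialect-stable.

Coefficient 0 — a frame log-energy proxy — is retained: nothing in the
problem statement excludes it, and the downstream feature selector can
drop it if it does not help. A consequence used as a test invariant:
scaling the waveform by gain `g` adds `sqrt(n_mels) * log(g^2)` to
coefficient 0 of every frame and (absent flooring) changes nothing
else.

Recording-level **functionals** (mean, sd, min, max per coefficient,
coefficient-major, names like `c03_sd`) produce the fixed-length
52-vector the wrapper selector operates on. Whether selection should
operate on frames, segments or recordings is genuinely open in this
literature; recording-level functionals are this package's documented
choice, because the wrapper's surrogate classifier needs one row per
labeled unit and the labels are per recording.

The oracle for all of this is an independent from-first-principles
implementation inside the test suite (explicit DFT basis matrices,
literal triangle formulas, explicit DCT cosine sums); the pipeline
matches it to better than `1e-8`, far inside the `1e-4` acceptance
tolerance.

## The three optimizers

All three run behind one interface (`swarm_optimize()`): uniform
initialization inside box bounds, `pop_size * (n_iter + 1)` objective
evaluations, clipping to bounds after every move, and an incumbent that
is non-increasing by construction. Defaults follow the reference
experiment settings: population 50, 200 iterations; dragonfly
`alpha` decaying linearly 1 to 0.1 with `beta = 0.5`; firefly
`alpha = 0.2`, `beta0 = 1`; moth-flame `b = 1`.

**Dragonfly.** The update is implemented exactly as printed in the
source description: `x_new = x_old + alpha * r + beta * Delta`, with
`r` uniform(-1, 1) per dimension (the description says only "a random
vector") and `Delta` the difference of two randomly selected other
agents. The classical dragonfly algorithm weights five behavioral terms
(separation, alignment, cohesion, food attraction, enemy distraction);
the description names them but provides neither equations nor weights,
so they are deliberately not parameterized here.

**Firefly.** Asynchronous index-order sweep; firefly `i` moves once
toward every currently brighter `j` by
`beta(r) (X_j - X_i) + alpha (rho - 0.5)` with
`beta(r) = beta0 exp(-gamma r^2)`, `gamma = 1`; the brightest firefly
performs only the random walk. `gamma = 0` recovers the literal
constant-`beta` reading of the printed equation; both modes are tested.
Each firefly is re-evaluated once after its full sweep.

**Moth-flame.** Flames are the best `flame_count()` positions from the
sorted union of previous flames and current moths, with
`flame_count = round(N - l (N - 1)/T)` (the canonical schedule; the
source states only that flames are reduced each iteration). Moth `i`
spirals per dimension around flame `min(i, n_flames)`:
`X = D e^{bt} cos(2 pi t) + F`, `t` uniform(-1, 1).

### Optimizer behavior on benchmark functions

This is the one place the implementation's faithfulness produces an
uncomfortable but honest result, asserted as-is by the acceptance
suite (criterion 2 there is red for two of the three optimizers):

* **Moth-flame** contracts: the flame set shrinks and `D -> 0` pulls
  moths onto flames. Median best on the 10-D sphere (`[-5,5]^10`,
  pop 50, 200 iterations, 10 seeds) is about `2e-6`.
* **Dragonfly as printed cannot converge.** The update has no
  attraction toward any incumbent; treating positions as random
  variables, the population variance obeys
  `Var' = (1 + 2 beta^2) Var + alpha^2/3`, which grows every step
  (factor 1.5 at `beta = 0.5`). The swarm diffuses until clipped at the
  box walls, and the incumbent is that of a correlated random walk:
  measured median ~12.6 on the same benchmark, statistically
  indistinguishable from pure random search with the same evaluation
  budget (4/10 paired-seed wins, computed in the test suite). This is
  a property of the printed equation, not a bug; the canonical
  five-term dragonfly would behave differently, but implementing it
  would mean inventing the weights the source omits.
* **Firefly with `gamma = 1` on `[-5,5]^10`** never activates its
  attraction: typical inter-firefly distances give
  `exp(-r^2) ~ exp(-40)`, so the algorithm degenerates to an
  `alpha = 0.2` random walk (measured median ~26). The firefly
  literature usually rescales `gamma` by the domain width; the
  configured value is kept because it is the stated setting. On
  *small* domains — including the `[0,1]^d` cube the feature selector
  actually uses, where distances are order 1 — the attraction term is
  active and firefly search works as intended (it beats random search
  in 10/10 paired seeds on the 2-D sphere and recovers planted
  features reliably, both computed in the suite).

The practical consequence for feature selection is mild: on `[0,1]^d`
with threshold decoding, all three optimizers pass the recovery and
brute-force-equivalence acceptance checks — coarse binary masks are a
much easier target than an `1e-2` basin on a continuous sphere.

## Wrapper feature selection

Positions live in `[0,1]^d`; feature `j` is selected iff
`position[j] >= 0.5`. Fixed-threshold decoding (rather than sigmoid or
V-shaped transfer functions) is the simplest reproducible choice. An
all-below-threshold position decodes to the single largest-position
feature — a deterministic, testable rescue that guarantees non-empty
masks.

The fitness of a mask is

```
(1 - macroF1_cv) + lambda * n_selected / d ,   lambda = 0.01
```

where `macroF1_cv` is 3-fold stratified cross-validated macro F1 of a
surrogate classifier on the masked columns. The source names only "an
objective function"; this composite is the standard wrapper objective
and directly targets the pipeline's reporting metric, with `lambda`
small enough that accuracy always dominates a one-feature difference
unless the F1 gain is below 1/d percentage points.

The default surrogate is an in-package ridge-penalized logistic
regression fit by IRLS. A full CNN-LSTM per fitness call (the
`cnn_lstm` surrogate mode, which exists and is tested) would cost
minutes per evaluation; at 50 agents x 201 evaluation sweeps that is
infeasible on a desk machine, and the wrapper principle — score masks
by a trained classifier — survives the substitution. Two purity
details matter for reproducibility:

* Fold assignment derives from a package-local Lehmer generator seeded
  by the selection seed, so `mask_fitness()` never touches R's global
  RNG and is a pure function of `(mask, seed)` even when called from
  inside an optimizer's RNG-driven loop.
* The folds are computed once per selection run, so every mask is
  scored against the same partition.

With `lambda = 0` and small `d`, the swarm's best fitness is checked
against brute-force enumeration of all `2^d - 1` masks; the sparsity
term's effect is checked by enumeration as monotone (larger `lambda`
never grows the optimal mask).

## The sequence classifier

Architecture (per the reference system description, gaps filled with
stated defaults): three 1D convolution blocks
`Conv1D(32/64/128, kernel 5) + ReLU -> MaxPool(2) -> Dropout(0.3) ->
BatchNorm` — the block-internal order follows the description's
sentence order — then temporal pooling, `LSTM(64)` returning its
sequence, `LSTM(32)` returning its final state, `Dense(32, ReLU)`,
`Dense(1, sigmoid)`. Input sequences are center-cropped or zero-padded
to 512 frames.

The description places a *global* average pooling before the two LSTM
layers, which is contradictory as written: a global pool collapses the
time axis the LSTMs need. The default here is a sequence-preserving
temporal average pooling with factor 4 at that position (512 frames ->
64 after three max pools -> 16 LSTM steps); `literal_gap = TRUE`
implements the literal reading (a length-1 LSTM input) for anyone who
wants it.

No deep-learning backend exists in the supported environment, so
forward and backward passes are hand-written in base R (batches as
`(B, T, C)` arrays, all dense algebra on `(B*T, C)` matrix views) with
Adam, inverse-frequency class weights (on by default, since screening
corpora are imbalanced and the reporting metric is macro-averaged),
early stopping on validation macro F1 with patience 8, and
best-checkpoint restoration. Backpropagation through every layer —
including batch-norm batch statistics and stacked-LSTM BPTT — is
verified against central-difference numerical gradients in the test
suite. Dropout is active only in training-mode forward passes;
inference uses batch-norm running statistics, which is what makes
predictions batching-invariant and deterministic.

Training this implementation is CPU-bound: the default spec (~117k
parameters) trains at desk scale, and the end-to-end acceptance run
uses a reduced spec (filters 8/12/16, kernel 3, LSTM 16/8, 256 frames)
that trains in seconds on 72 recordings.

## Metrics

One-vs-rest precision, recall and F1 for both classes, macro-averaged
(unweighted mean — the reporting convention of the reference study;
whether its printed precision/recall were macro or positive-class
values is ambiguous there, so the per-class table is always reported
alongside the macro row). Any 0/0 ratio is defined as 0 and warned
about, keeping the macro average total; this matches scikit-learn's
`zero_division=0`, and agreement with scikit-learn is asserted to
`1e-12` over random label vectors.

## The synthetic world

`generate_audio_dataset()` emulates the *cue families* the screening
literature associates with depressed speech, not speech itself:

| cue | control class | case class |
|---|---|---|
| pitch level (f0 mean) | 180 Hz | 120 Hz |
| pitch variability (f0 sd across recordings) | 25 Hz | 8 Hz |
| energy modulation rate (syllable-rate proxy) | 5 Hz | 2 Hz |
| pause fraction | 0.10 | 0.35 |

Each recording is a 5-harmonic stack with per-recording f0,
depth-0.9 amplitude modulation, four non-overlapping silent gaps
totaling the pause fraction (one per quarter, random offset — which is
what makes the realized silent share exactly the configured fraction,
up to sine zero crossings), additive Gaussian noise (sd 0.005), peak
normalization to 0.95, 4 s at 16 kHz, written as 16-bit PCM WAV. The
generator is bit-reproducible from its seed, including WAV bytes.

What a green test on this world establishes: that the pipeline's
machinery — extraction, selection, training, evaluation, seeding —
does what it claims on data whose class structure is known and large.
What it does not establish: anything about real depressed speech,
which differs in essentially every hard way (speaker variability,
recording conditions, label noise, far smaller effect sizes, interview
turn structure). The class separation here is deliberately strong
(holdout macro F1 >= 0.9 from functionals plus a linear model), because
the tests are about correctness, not about difficulty.

`generate_feature_table()` is the analytic counterpart: `k` informative
columns at class means `±delta/2` (unit variance), `d - k` pure-noise
columns, informative positions seeded-random and returned as ground
truth. Gaussian columns were chosen so per-feature separability is
exactly `d' = delta` and test thresholds can be calibrated from normal
theory rather than tuned.

## Orchestration and seeding

`run_pipeline()` composes the stages with a stratified 60/20/20
recording-level split (train/validation/test — proportionally
mirroring the train/dev structure of the usual interview corpora).
Feature selection sees only the training split; reported metrics come
from the untouched test split — a leakage guard the reference study
does not discuss. One global seed drives everything; stage seeds are
small fixed offsets of it (selection `+1`, training `+2`), and split
and fold assignments use the package's own Lehmer stream, so two runs
with the same config are identical including selected features and
metrics. The end-to-end acceptance run (60 recordings per class,
firefly pop 15 / 30 iterations, reduced model) completes in well under
a minute and reaches held-out macro F1 >= 0.85 on the synthetic
classes.

The acceptance *report* (`scripts/acceptance.R`) deserves a note: the
build specification this package implements defines an empty numeric
target list — the reference study's headline F1 values are measured on
access-restricted corpora and are explicitly not reproduction targets —
so the script emits an empty JSON object after a self-check, and all
acceptance substance lives in `tests/testthat/test-acceptance.R`.

## Numerical choices and degenerate inputs

* Frame-count law enforced with no centering/padding; signals shorter
  than one frame are errors, not silently empty outputs.
* Silence, impulses and full-scale square waves produce finite MFCCs
  (log floor).
* `sd` uses denominator `T - 1`; single-frame sequences are rejected
  by `functionals()`.
* Bounds handling in all optimizers is clipping (simplest contract;
  reflection/wrapping would change none of the tested properties on
  these problems but would complicate the hand-checkable examples).
* Ties in mask decoding resolve to the first index; ties in flame
  sorting resolve by `order()`'s stable sort.
* Seeds: user-facing seeds are 32-bit integers; internally derived
  seeds stay far below `2^31`.

## Known limitations

* The dragonfly implementation is the printed two-term equation; it is
  a diffusion, not an optimizer, on continuous benchmarks (see above),
  and is retained for fidelity.
* The CNN-LSTM is CPU-bound base R; it is meant for the scale of the
  synthetic experiments (10^2 recordings, 10^2 frames), not for
  corpus-scale training.
* No voice-activity detection, delta features, CMVN, or speaker
  normalization — all out of scope of the front end contract.
* The `cnn_lstm` surrogate mode is provided and smoke-tested but
  impractical beyond toy budgets, as discussed.
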