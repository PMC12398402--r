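---
title: "Time-varying recurrent networks for early decoding: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying recurrent networks for early decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvrnn)
```

## The problem

Trial-structured neural recordings — widefield calcium imaging of mouse
cortex, region-averaged fMRI, or simulated surrogates — give a matrix of $R$
channels by $T$ time points per trial, with a binary label: did the animal
(or subject) initiate the behavior in this trial, or is it a control trial?
Two questions matter for applications such as pre-movement intervention:
*can the behavior be decoded at all*, and *how early in the trial can it be
decoded reliably*.  The difficulty is that neural data shift their
statistics across a trial (amplitude and frequency content both change as
movement approaches), so a classifier whose parameters are fixed across the
whole trial tends to be good only where its loss looked.

## Models

### Standard recurrent classifier

The base model is an Elman network with a per-time-point readout:

$$h_t = \tanh(W_h h_{t-1} + W_x x_t + b_h), \qquad
  y_t = \sigma(W_y h_t + b_y), \qquad t = 1,\dots,T,$$

with $h_0 = 0$, $x_t \in \mathbb{R}^R$, $h_t \in \mathbb{R}^N$ and a scalar
sigmoid output $y_t$, thresholded at $0.5$ (ties to class 1) to produce a
class call at every time point.  Two loss placements are supported, both
binary cross-entropy against the trial label:

* **S1** — loss on the final output $y_T$ only: optimises whole-sequence
  classification, but nothing encourages informative early outputs.
* **S2** — loss on every $y_t$: encourages early decoding at the cost of
  averaging the objective over regimes with very different statistics.

S2 aggregates the per-time-step cross-entropies by **mean** over time
rather than sum, so losses are comparable across sequence lengths; under
Adam with a tuned learning rate this rescaling does not change the optimum,
and it makes `loss_s2` reduce exactly to `loss_s1` at $T = 1$.

### Time-varying RNN

The package's core model replaces the single weight set by one bundle
$(W_x^k, W_h^k, W_y^k, b_h^k, b_y^k)$ per temporal window
$k = \lceil t/w \rceil$ of length $w$, while the hidden state flows
*continuously* across window boundaries — it is carried, never reset.  All
$\lceil T/w \rceil$ bundles are optimised jointly (end-to-end) in every
mini-batch by backpropagation through time under the all-step loss.  The
model can therefore specialise each window to the local statistics of the
trial while still accumulating evidence in the hidden state.

The all-step loss is used for the time-varying model because it is
evaluated — and expected to perform — at every time point; an optional warm
start (`warm_start = TRUE`) first trains a static S1 network and initialises
every window from it.  When `w` does not divide `T` the final window is
simply shorter; the configurations of interest ($w = 30$, $T = 300$ and
$w = 2$, $T = 12$) divide evenly.

### Causal transformer baseline

For comparison the package ships a strictly causal self-attention encoder:
learned positional embeddings, pre-LayerNorm blocks of masked multi-head
attention and a ReLU feed-forward, and a per-time-point sigmoid head.  The
causal mask guarantees $y_t$ depends only on $x_{1..t}$, which the test
suite verifies bitwise by perturbing future inputs.  Defaults are 2 layers,
4 heads, width 64.  Dropout is deliberately omitted: training stays fully
deterministic given the seed, and over-fitting is handled the same way as
for the RNNs, by checkpointing the epoch with the lowest validation loss.
Forward and backward passes are written out explicitly in R and verified
against finite differences.

### Sliding-window baselines

The classical alternative cuts the trial into windows of `window_len` time
points and fits an independent classifier per window: standard RNNs
(restarted from $h_0 = 0$ each window, so no information crosses windows)
or SVMs (`e1071`, RBF kernel by default, library-default cost and gamma) on
the flattened `[time x channel]` window.  Each window's accuracy is
reported at the window's last time point.

## Training

Optimisation is Adam (defaults: learning rate $10^{-4}$, batch size 64,
1000 epochs at full scale) on mini-batches, in single precision — the
convention of the frameworks this mirrors; analysis-time forward passes and
attribution gradients run in double precision.  Weights start from
fan-based (Glorot-style) uniform draws, each window initialised
independently; biases start at zero.  A stratified validation split
(default 20% of the training trials) is evaluated every epoch and the
epoch with the lowest validation loss is kept as the checkpoint; the
final-epoch weights are also retained.  No gradient clipping or learning
rate schedule is applied — clipping would confound the vanishing/exploding
gradient diagnostic below.  The gradient of one example recurrent weight
per window is recorded every epoch, flagged as "vanishing" below $10^{-7}$
or "exploding" above $10^{2}$ in magnitude (labels only; training is never
altered).

Cross-validated evaluation (`tvrnn_cv`) uses stratified 5-fold splits:
each fold holds out 1/5 of trials for testing and splits the remainder
80/20 into training and validation.  All reported metrics come from the
held-out test predictions.

## Metrics

* **Temporal accuracy** — per time point and fold, predictions are
  thresholded and accuracy computed as $(TP+TN)/(TP+TN+FP+FN)$; the curve
  is the fold mean.  Chance level is the pooled majority-class fraction
  (0.5 for balanced designs).
* **AUAC** — the trapezoidal integral of (accuracy − chance) over a time
  span, in accuracy-seconds; below-chance excursions are not clipped.
* **Earliest decoding time (EDT)** — at each time point the $K$ per-fold
  accuracies are tested against chance with a one-sample one-tailed t-test
  (alternative: greater); p-values are Benjamini–Hochberg corrected across
  the $T$ time points of one model/dataset (never across models).  The EDT
  is the earliest $t^*$ such that every time point from $t^*$ to behavior
  onset is significant; a configurable `gap_tolerance` (default 0) may
  allow isolated non-significant points.  The first significant time point
  (`onset_index`) is reported alongside.

Two conventions deserve note.  The t-test replicates are the per-fold
accuracies — the only replicate structure a single-dataset design provides;
with multi-session data per-session accuracies can be supplied instead by
building the fold list accordingly.  And when the fold accuracies at a time
point are all equal the t-statistic is undefined; the package sets $p = 0$
if their common value exceeds chance and $p = 1$ otherwise, the limit of
the test as the variance shrinks.

## Attribution

Per-feature importance uses integrated gradients as a SHAP approximation:
for output time $\tilde t$,

$$\mathrm{IG}_i(x) = (x_i - x'_i) \int_0^1
  \frac{\partial F(x' + \alpha (x - x'))}{\partial x_i}\, d\alpha,$$

with $F$ the model output $y_{\tilde t}$, approximated by the trapezoid
rule (default 128 intervals; completeness
$\sum_i \mathrm{IG}_i = F(x) - F(x')$ is computed and reported for every
call).  The baseline $x'$ is the all-zero trial — its sigmoid output sits
at 0.5 for zero-bias models and near 0.5 for trained ones — with a
class-mean baseline available as an option.  The importance map is the mean
of $|\mathrm{IG}|$ across test trials (the signed mean is kept too, since
signed attributions carry the class direction).  Exact Shapley enumeration
is intractable beyond a dozen features; the linear-model closed form and a
finite-difference path-gradient oracle serve as the correctness checks in
the test suite.  For the transformer the quadrature converges noticeably
more slowly (LayerNorm makes the path gradient steep near the zero
baseline); attribution is primarily intended for the recurrent models.

## Gradient-stability diagnostics

During backpropagation through time the gradient reaching time $t'$ from
time $t$ is proportional to a product of recurrent Jacobians, and for the
static network that product is a matrix power $\hat W_h^{\,t-t'}$: its norm
grows or decays exponentially at the rate set by the spectral radius, the
root cause of exploding and vanishing gradients.  A time-varying network
multiplies *different* matrices, and the product of independent draws grows
at the ensemble's Lyapunov exponent, which submultiplicativity bounds by
the mean log norm of a single factor.  The package exercises this
empirically rather than formally: `jacobian_product_norms` computes
$\log\|\prod W\|_1$ over horizons (induced 1-norm — the choice for which
submultiplicativity is guaranteed) and fits the Lyapunov exponent as the
least-squares slope of log-norm against horizon (lower variance than the
single-horizon quotient; both are reported), and
`gradient_inequality_experiment` draws static and per-window matrices from
the same Gaussian ensemble and tests one-sided whether the time-varying
products grow more slowly in expectation.  The inequality is a statistical
tendency of the ensemble, not a per-draw fact, and that is exactly how it
is asserted.

`weight_distance_map` complements this with pairwise Frobenius distances
between the learnt window weights, and `output_trajectories` summarises the
class-conditional mean output over time, with a divergence time defined as
the first time the class means differ by more than one pooled standard
deviation (the multiplier is configurable; the choice is a reporting rule,
not a test).

## The simulated chirp dataset

`generate_chirp_trials` builds the synthetic benchmark: each behavior
trial carries the same linear-frequency chirp on all 10 channels, scaled
per channel by a distinct coefficient from the open interval (1, 4), with
an amplitude ramp and additive Gaussian noise; control trials are behavior
trials whose time indices are randomly permuted.  Defaults: 2000 trials of
300 time points at 30 points/s, sweep 2 → 30 cycles per trial, amplitude
0.2 → 1.0, noise sd 0.5.  Design choices where the construction was open:

* **Chirp form** — linear instantaneous-frequency sweep, the canonical
  reading of "chirp" and the one that produces a monotone STFT ridge
  (`stft_magnitude` visualises exactly this distribution shift).
* **Channel coefficients** — evenly spaced inside (1, 4): deterministic
  and reproducible; `random_coeffs = TRUE` draws them uniformly instead.
* **Per-trial phase** — each trial gets an independent random initial
  phase; without it all behavior trials would be identical up to noise.
* **Control shuffling** — one permutation per trial applied *jointly*
  across channels, preserving instantaneous cross-channel structure while
  destroying temporal order, which is precisely what a temporal classifier
  must exploit; per-channel shuffling would also break the spatial
  correlations and make the task easier for non-temporal classifiers.  The
  permutations are stored so every control trial can be un-shuffled.
* **Noise placement** — observation noise added after the
  coefficient/amplitude scaling; `noise_placement = "pre_scaling"` adds it
  to the unit chirp first.
* **Onset convention** — `t_zero_index` is the last time point: the class
  is decided by the whole sequence.

What the simulator emulates is the *temporal distribution shift* of real
recordings (low-frequency/low-amplitude early, high/high late) and the
existence of class-discriminative temporal structure.  What it does not
emulate: spatial structure of real imaging modalities, hemodynamics,
inter-session variability, or class differences confined to a sub-interval
of the trial.  Passing tests on this data therefore demonstrate the
machinery — not performance on any particular real modality.

Note one property of the shuffled-control construction: because control
values at any single time point are drawn from the whole-trial amplitude
distribution while behavior values are amplitude-ramped, the marginal
distributions differ from the first time points on, so early decodability
exists by design; what distinguishes the models is whether their training
strategy lets them use it.  The final-loss network (S1) stays at chance for
roughly the first half of the trial before rising, while the time-varying
network decodes from the start and holds the highest final accuracy — the
contrast the acceptance suite retrains and checks.

## Problem sizes and numerical choices

The test suite and the acceptance script run a desk-scale version of the
study: 400 trials, 300 time points, 32 hidden units, 200 epochs, 5-fold
cross-validation, three training seeds — sizes chosen so the whole
retraining study completes in minutes on one CPU core while preserving the
qualitative contrasts; unit tests use far smaller instances (a few units,
a few time points) where closed forms and scalar-loop oracles are exact.
Training runs in single precision with denormals flushed to zero (the
backward signal of a final-step loss decays below the normal float range
within a few dozen steps, and denormal arithmetic is pathologically slow);
gradient correctness is verified against double-precision finite
differences.  The divergence guard aborts with the last recorded gradients
if the loss goes non-finite.

## Limitations

* Binary classification only; GRU/LSTM cells and multi-class heads are out
  of scope.
* The transformer is a baseline: no dropout, no attribution guarantees,
  and small default capacity.
* The window size $w$ is a hyperparameter; nothing selects it
  automatically (the cross-validated sweep used to pick $w = 30$ at full
  scale is the user's job).
* Real-data preprocessing (image alignment, component extraction) is out
  of scope; the package starts from trial tensors.
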