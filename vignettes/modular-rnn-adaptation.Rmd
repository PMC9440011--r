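---
title: "Modelling rapid motor adaptation with a modular recurrent network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling rapid motor adaptation with a modular recurrent network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motoradapt)
```

## The scientific question

When an animal adapts its reaches to a visuomotor rotation (VR) — visual
feedback rotated by a fixed angle — neural activity in dorsal premotor
(PMd) and primary motor cortex (M1) changes while the *statistical
interactions* across neurons (their covariance) stay largely intact.
Preserved covariance is usually read as evidence that local synaptic
connectivity is stable, i.e. that adaptation is driven by altered *inputs*
from upstream areas rather than by plasticity within the motor cortices.
Because synaptic strengths cannot yet be tracked in vivo during rapid
learning, this package tests that inference in a model where the site of
plasticity is under experimental control.

The model is a modular recurrent firing-rate network: an upstream module
projects to a PMd module which projects to an M1 module; a fixed linear
readout of M1 rates produces a planar hand trajectory. Two hypotheses are
implemented as *plasticity masks* that restrict which parameter groups
gradient descent may change during adaptation:

* `H_input` — plasticity upstream of the motor cortices
  (`W_up`, `W_in_up`, `W_up_pmd`);
* `H_local` — plasticity within PMd/M1
  (`W_pmd`, `W_m1`, `W_pmd_m1`).

A third, training-free mechanism — *input reassociation* — permutes which
input pattern each cue evokes without changing the patterns themselves
(`input_remap()`).

## Model and dynamics

Each module holds $N$ rate units with state $\mathbf{x}_t$, rates
$\tanh(\mathbf{x}_t)$, and forward-Euler leaky dynamics with time constant
$\tau = 50$ ms and step $dt = 10$ ms:

$$
\mathbf{x}^{\mathrm{UP}}_{t+1} = \mathbf{x}^{\mathrm{UP}}_{t}
 + \tfrac{dt}{\tau}\big(-\mathbf{x}^{\mathrm{UP}}_{t}
 + \mathbf{W}^{\mathrm{UP}}\tanh(\mathbf{x}^{\mathrm{UP}}_{t})
 + \mathbf{W}^{\mathrm{in,UP}}\mathbf{s}_t\big)
$$

and analogously for PMd (which receives the stimulus and the upstream
rates) and M1 (which receives only PMd rates). The output is
$\mathbf{x}^{\mathrm{out}}_t = \mathbf{W}^{\mathrm{out}}
\tanh(\mathbf{x}^{\mathrm{M1}}_t) + \mathbf{b}^{\mathrm{out}}$. The
stimulus is three-dimensional: target $x$, $y$ coordinates, and a go
channel that is 1 up to the go cue and 0 afterwards. All connectivity is
dense. The dynamics contain no noise term, so a trial is a deterministic
function of its stimulus — trial-to-trial variability in training comes
only from target identity and go timing.

Design choices the dynamics leave open, and the defaults taken here:

* **Initial state.** Trials start from rest, $\mathbf{x}_0 = 0$
  (configurable in `simulate_network()`); the model statement is silent on
  this and a rest state is the simplest assumption for an instructed-delay
  trial.
* **Initialization.** Random initialization is implied but not specified;
  `init_params()` draws recurrent and feedforward weights i.i.d. Gaussian
  with s.d. $g/\sqrt{N}$ ($g = 1$, spectral radius $\approx 1$ by the
  circular law), input weights with s.d. $0.1$, readout with s.d.
  $1/\sqrt{N}$, zero bias.
* **"Activity" for metrics** means the tanh rates, matching the rate terms
  in the dynamics and in the rate regularizer, not the raw states.
* **Stimulus timing.** The target coordinates are present from $t = 0$
  (target information is not gated by a separate onset event); only the go
  channel has a time course. This is the simplest scheme consistent with a
  stimulus that "signals the target location", and it makes the delay-period
  activity target-specific, as in instructed-delay recordings.

## Synthetic reaching corpus

The original training corpus — pooled recorded hand trajectories — is not
publicly available, so `generate_trial_set()` emulates it:

* 8 targets uniformly spaced on a circle (unit radius; physical scale is
  absorbed by the linear readout);
* variable instructed delay, uniform on 0.5–1.5 s;
* after the go cue, a 150 ms reaction time followed by a 700 ms
  minimum-jerk reach — smooth, bell-shaped speed profiles matching primate
  kinematics (`minimum_jerk_profile()`);
* 4 s trials at 10 ms resolution, split 90/10 into train/test.

What this generator does *not* emulate: curvature and idiosyncrasies of
individual reaches, reaction-time variability, online corrections, or
feedback-driven control. Passing tests therefore show that the *modelling
pipeline* reproduces the qualitative phenomena on clean kinematics; they do
not certify behaviour on recorded data.

Metric evaluations use a separate canonical set (`make_eval_set()`): one
trial per target with a shared 1.0 s go time. Because the dynamics are
deterministic, this single trial per target equals the average of any
number of identically timed trials, implementing exact trial averaging;
the canonical go also guarantees that the ±600 ms go-aligned analysis
window always fits.

## Training objective

`train_network()` minimizes, with Adam (learning rate $10^{-4}$,
$\beta_1 = 0.9$, $\beta_2 = 0.999$) and global gradient-norm clipping at
0.2:

$$
L = \frac{1}{B(T-50)\,2}\sum_{b}^{B}\sum_{t=50}^{T}\sum_{d=x,y}
 \left(x^{\mathrm{out},d}_{t,b} - x^{\mathrm{target},d}_{t,b}\right)^2
 + E^{\mathrm{weights}} + E^{\mathrm{rates}}
$$

with $E^{\mathrm{weights}} = \alpha \sum_W \lVert W\rVert_2$ (unsquared
Frobenius norms of the eight weight matrices, bias excluded;
$\alpha = 10^{-3}$) and $E^{\mathrm{rates}}$ the mean squared tanh rate of
all three modules scaled by $\beta = 0.8$. The first 50 steps are excluded
from the error so early transients are unconstrained. "500 training
trials" (de-novo) and "100 trials" (adaptation) are read as optimizer
updates, each computed on a batch of $B = 80$ trials drawn with
replacement from the training split — the batch size appears inside the
loss normalizer, which supports this reading; the alternative
(single-trial updates) is one configuration flag away. Gradients are
computed by backpropagation through time in compiled code; a
finite-difference oracle in the test suite verifies them. Training runs in
single precision by default (metrics always in double); the first Adam
steps agree with the double-precision path to ~1e-4, and all downstream
claims are tolerance-based.

## Adaptation tasks

* `apply_vr(ts, angle)` rotates every target trajectory counter-clockwise
  by `angle` degrees, leaving stimuli untouched: the network must produce
  rotated reaches to the same cues. Clockwise and counter-clockwise
  sessions are equivalent by symmetry, so only one sign is simulated.
* `apply_reassociation(ts, perm)` permutes which cue each reach direction
  carries, leaving trajectories untouched. Permutations default to
  uniformly drawn derangements (`random_derangement()`), so every cue is
  reassigned.
* `input_remap(params, perm, targets)` implements adaptation purely by
  re-pointing input patterns: the 2-D cue channels of both input matrices
  are composed with the linear map sending each reassigned cue position
  back to its required direction. The map lives in the parameters, so no
  per-trial bookkeeping is needed; it is exact when the permutation acts
  on the cue ring as a rotation/reflection (for arbitrary permutations the
  per-trial equivalent — reassociating the evaluation set with the inverse
  permutation — produces identical activity, and is the provided
  alternative). Because input patterns are only re-assigned, never
  reshaped, activity patterns permute across cues and the neuron-by-neuron
  covariance is exactly preserved — the mechanism behind the reassociation
  fingerprint.
* `add_synaptic_fluctuation(result, factor)` adds i.i.d. Gaussian noise to
  every plastic group with s.d. `factor` (default 10) times the s.d. of
  that group's learned change — unstructured, full-rank noise against
  which the low-dimensional learned changes are tested. No connections are
  added or removed.

## Measuring learning signatures

All activity metrics compare a baseline epoch with a late-adaptation
epoch, both evaluated on canonical-go trials and a ±600 ms go-aligned
window (121 bins at 10 ms; inclusive endpoints — the off-by-one choice is
immaterial to medians but fixed). Trials are grouped by the *presented
cue*: for VR, cue and reach direction coincide; for reassociation,
grouping by cue is what lets a pure input re-assignment appear as a large
activity change with exactly zero covariance change.

* **Activity change** (`activity_change()`): median over neurons, bins and
  cues of $|\mathrm{PSTH}^{\mathrm{late}} - \mathrm{PSTH}^{\mathrm{base}}|
  / \sigma^{\mathrm{base}}$, with $\sigma$ the baseline per-neuron s.d.
  across time and cues. Neurons with $\sigma < 10^{-9}$ are excluded from
  the median (division undefined); the count is reported as an attribute.
* **Covariance change** (`covariance_change()`): 1 minus the Pearson
  correlation between corresponding entries of the two epochs'
  neuron-by-neuron covariance matrices (all $N^2$ entries; upper-triangle
  only as an option — the symmetric duplication affects both epochs
  identically).
* **Weight change** (`weight_change()`): median over entries of
  $|\Delta W| / |W^{\mathrm{base}}|$. The denominator is the element-wise
  absolute value — relative magnitudes must be positive for a percentage
  to be meaningful — floored at machine epsilon times the matrix norm;
  the median is robust to the few near-zero-denominator entries. One
  summary value per parameter group.
* **Dimensionality** (`participation_ratio()`):
  $(\sum_i k_i)^2 / \sum_i k_i^2$ over the singular values of a
  weight-change matrix; 1 for rank-1, $n$ for the identity, $\approx
  0.72\,n$ for an i.i.d. Gaussian matrix.
* **Behaviour**: windowed trajectory RMSE (`trajectory_rmse()`, same
  window as the loss) and the signed angular error of the initial reach
  direction (`angular_error()`), measured where the trajectory first
  exceeds a quarter of the target radius from the origin.

Model rates are not smoothed (the Gaussian smoothing in the experimental
pipeline applies to recorded spikes, which are out of scope here). The
choice of rates over states for covariance is switchable but rates are the
default, as they are what downstream areas read out.

## Scale profiles and what was run

`scale_profile("full")` mirrors the study conditions: $N = 400$ units per
module, $T = 400$ steps (4 s), 2238 trials, 500 de-novo + 100 adaptation
updates, $n = 10$ initializations. De-novo training at this scale is an
hours-long single-CPU computation, so the package's routine runs — the
test suite and `scripts/acceptance.R` — use `scale_profile("reduced")`:
$N = 150$, $T = 200$ (2 s trials; delays capped at 1.1 s so reaction and
movement fit), 320 trials, 300 + 100 updates, 3 initializations. The
reduced profile preserves every qualitative contrast the package tests;
thresholds quoted in the tests are stated at this profile.

At the reduced profile the pipeline reproduces: de-novo learning of all
eight reaches; restoration of behaviour after a 30° VR under both
hypotheses; covariance changes that are small at 30° and grow with
rotation angle, with the M1 covariance change growing at least as fast as
PMd's under local plasticity; the reassociation dissociation (large
activity change with *exactly* preserved covariance under the input
remap, altered covariance under local learning); adaptation weight
changes of ~0.5–2% per group (vs several to tens of percent during de-novo
training) organized in a low-dimensional pattern; and the lifting of the
weight-change participation ratio above half of full rank by simulated
synaptic fluctuation.

Two qualitative signatures do **not** reproduce at this scale, and the
corresponding test expectations are asserted as stated and allowed to
fail rather than re-tuning the fixed training constants to force them:

* Under `H_input` the M1 module's activity change exceeds PMd's (the
  expected ordering is PMd ≥ M1, as in the upstream-learning account),
  robustly across seeds. In this implementation the behaviour-forced
  component of the M1 change — the frozen readout must emit 30°-rotated
  trajectories, so M1 rates must reorganize regardless of where
  plasticity sits — dominates the median, and changes grow, rather than
  shrink, down the hierarchy (the trained recurrent matrices sit slightly
  above unit spectral radius, so each module mildly amplifies its
  afferent change).
* Ten-fold synaptic fluctuation degrades behaviour here instead of
  leaving it unchanged: the learned changes have s.d. ~1.6% of the
  weight scale, so the injected noise perturbs each plastic matrix by
  ~16% of its element scale and the evaluated RMSE rises several-fold,
  mostly through delay-period drift of the held output. The induced
  per-neuron current perturbation scales as
  `factor · (relative change) · gain · r_rms`, independent of `N`, so
  this is not simply a small-network artifact; robustness of this kind
  appears to require a less critical operating regime than gain-1
  initialization produces. Weaker initial coupling (gain 0.2–0.5) does
  give noise-robust networks, but they fail to learn the task within the
  reduced profile's update budget, so the documented default is kept.

## Numerical notes and limitations

* Stability requires $0 < dt/\tau \le 1$; the default ratio is 0.2.
  Non-finite states abort with the offending step index.
* Plasticity masking is exact: unmasked groups are returned bit-identical,
  which the tests assert with `identical()`.
* All randomness (trial sampling, initialization, batches, derangements,
  fluctuations) flows through explicit integer seeds; experiment campaigns
  derive per-seed streams by fixed offsets so adding seeds never changes
  existing ones.
* The model omits feedback (visual/proprioceptive), trial-by-trial
  learning dynamics, spiking, Dale's law and sparse connectivity; it
  addresses the slow component of adaptation between baseline and late
  epochs only.
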