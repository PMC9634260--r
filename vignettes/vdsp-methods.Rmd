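---
title: "Voltage-dependent synaptic plasticity: model, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voltage-dependent synaptic plasticity: model, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdsp)
```

## The problem

Spike-timing-dependent plasticity (STDP) is the standard local, unsupervised
learning rule for spiking neural networks, but it needs per-synapse spike
times or decaying traces to be stored and fetched at every update, and its
exponential window has a fixed time scale that must be re-tuned whenever the
input firing rates change. Voltage-dependent synaptic plasticity (VDSP)
replaces both requirements with a quantity the neuron already has: the
presynaptic membrane potential. The update fires only on postsynaptic
spikes, reads `v_pre` at that instant, and needs no extra state.

This package implements the full pipeline around that idea: clock-driven
LIF/ALIF neuron simulation, the VDSP rule, the analytic bridge between
membrane potential and spike timing that justifies it, a trace-based STDP
baseline, rate/Poisson image encoders, a two-layer winner-take-all (WTA)
network with a compiled simulation core, unsupervised training with post-hoc
neuron labelling, and a synthetic multi-class pattern generator so every
experiment runs without downloads.

## Neuron model

Membrane dynamics follow the leaky integrate-and-fire equation
$$\tau_m \frac{dv}{dt} = -(v - v_{rest}) + g I + b,$$
integrated with the *exact exponential* (zero-order-hold) update
$v' = E + (v - E)\,e^{-dt/\tau_m}$, $E = gI + b + v_{rest}$, rather than
forward Euler: the classification experiments run at the coarse `dt = 5` ms
(equal to the refractory period), where Euler is visibly inaccurate, while
the analytic experiments use `dt = 0.01`–`0.05` ms. Threshold crossings are
detected at the end of the step; the spike time is the step's timestamp, the
membrane is reset to `v_reset` and held there for `t_ref`. Output neurons
are adaptive (ALIF): each spike increments an adaptation current `n` by
`inc_n` (subtracted from the drive), and `n` decays with `tau_n`
($\tau_n\,dn/dt = -n$).

For constant supra-threshold drive the inter-spike interval has the closed
form `t_ref + tau_m * log((E - v_reset)/(E - v_th))`
([`closed_form_isi()`]); it is the independent oracle against which the
simulator is validated (agreement within `2*dt`). Sub-threshold drive
returns `Inf` ("never fires").

Reference parameter set (used throughout unless stated): input layer
`tau_m = 30` ms, `v_th = 1` V, `v_reset = -1` V, `v_rest = 0`, `t_ref = 5`
ms, `bias = 0.5`; output layer identical except `v_reset = 0`, `bias = 0`,
`inc_n = 0.01`, `tau_n = 1` s. Distinct resting and reset potentials are
essential: they let the rule tell an *inactive* neuron (sitting at its
positive biased equilibrium) from one that *fired recently* (pinned at the
negative reset).

## The VDSP rule

On each postsynaptic spike, every incoming synapse is updated from the
presynaptic potential and current weight:
$$dW = \begin{cases}
(W_{max} - W)\,(e^{-V_{pre}} - 1)\,lr, & V_{pre} < 0\\[2pt]
-W\,(e^{V_{pre}} - 1)\,lr, & V_{pre} > 0.
\end{cases}$$
A negative `V_pre` means the presynaptic neuron fired recently
(potentiation); a positive one means it is charging toward threshold, about
to fire (depression). `V_pre = 0` returns exactly zero — the rule is
undefined there but both one-sided limits vanish. The multiplicative
factors `(W_max - W)` and `W` soft-bound the weight: provided
`lr * (exp(|v_reset|) - 1) <= 1` (checked at configuration time,
`lr <= 0.58` for `v_reset = -1`), iterated updates never leave
`[0, W_max]` and **no clipping is ever applied**.

The learning rate is the rule's single tunable. The default is
`lr = 5e-2`, the value quoted for reproducing the reference classification
results; reported optima vary with the output population size (larger
populations tolerate larger rates), so `vdsp_params()` exposes it.

### Why the rule reproduces STDP under constant drive

With constant drive `I > v_th` and no refractory period the membrane is
invertible: `v(t) = I + c e^{-t/tau_m}` gives
$$|\Delta t| = \tau_m \min\left\{\left|\ln\frac{v_{th}-I}{v-I}\right|,
\left|\ln\frac{v_{reset}-I}{v-I}\right|\right\},$$
the distance to the nearest presynaptic spike
(`delta_t_from_voltage()`). Substituting into the exponential STDP window
(for `v_th = 1`, `v_reset = -1`) yields a closed form in `v` alone
(`stdp_window_from_voltage()`), with branch point `v = I - sqrt(I^2 - 1)`
where the distances to the previous and next spike coincide. When
`tau_m = tau_STDP` the two expressions are algebraically identical; the
test suite checks agreement to `1e-12` and validates the inversion against
simulation (1000 random observation times, three drive levels, deviation
below `2*dt`). The same machinery does *not* extend to Poisson drive, where
the membrane trajectory is not invertible.

Because `tau_m` sets the window's time scale *through the input current*,
stronger drive compresses the window: `vdsp_window_scan()` +
`window_halfwidth()` measure this empirically (half-widths strictly
decreasing over `I in {1.5, 2, 3, 5}`). With a presynaptic refractory
period the scan shows a plateau over `delta_t in (0, t_ref]` where the
membrane is pinned at reset — an artifact worth knowing about, not a bug.

## STDP baseline

The comparison rule is pair-based exponential STDP in the two-trace
formulation: per-neuron traces decay with `tau_plus`/`tau_minus` and are
incremented on their neuron's spikes; potentiation reads the presynaptic
trace on postsynaptic spikes, depression reads the postsynaptic trace on
presynaptic spikes, both soft-bounded. Updates read the traces *before* the
same step's increments, so a spike never acts on itself; for isolated pairs
the trace model reproduces the exponential window exactly on the grid.

Pure pair-based STDP never touches synapses of silent inputs. In a WTA
network over images with a large zero background this is fatal: background
weights keep their random initial values, no neuron can lose the
competition it won first, and the network stays at chance. Competitive
unsupervised STDP formulations therefore subtract a target trace value in
the post-spike update; `stdp_params(x_tar = ...)` implements this as
`a_plus * ((w_max - w) x_pre - x_tar * w)`. The default is `x_tar = 0`
(pure pair rule, used by the window-equivalence contracts); the
frequency-robustness experiment enables `x_tar = 0.2` so the baseline is a
functioning competitor rather than a strawman.

## Network and simulation loop

The classification network is `n_in` input LIF neurons (one per pixel,
pixel intensity mapped to constant current, `drive = pixel/255`) fully
connected to `n_out` ALIF outputs, weights initialized i.i.d. uniform on
`[0, 1]`. Lateral inhibition is WTA by membrane clamping: when an output
fires, all other outputs are clamped to 0 V for 10 ms (clamping overrides
refractoriness; both timers run concurrently). Samples are presented for
350 ms back-to-back with **no state reset** between samples.

Per step, in fixed order: input update → output update (driven by the
synaptic current as of the end of the *previous* step) → winner selection →
synaptic filter update → plasticity. Three choices here were genuinely
open:

* **One-step synaptic transmission delay.** An input spike can excite the
  output layer only from the next step onward. Without the delay, a strong
  volley fires the output in the same step as its causal inputs, which are
  then read at their high pre-reset potentials and *depressed* — learning
  inverts. With the delay, the causal inputs sit at `v_reset` when the
  postsynaptic spike occurs and are potentiated, and an input firing in the
  same step as the post spike (i.e. just after it) is correctly read as
  "about to fire" and depressed. Reference clock-driven simulators behave
  the same way.
* **Synaptic current model.** The layer-to-layer current is not specified
  by the model; we use an exponential low-pass (`syn_tau = 5` ms) of the
  weighted input spike vector in which one spike through weight `w` raises
  the postsynaptic current by `syn_gain * w`. The default `syn_gain = 0.5`
  sets the operating point: a typical foreground volley (20–40 active
  pixels at mean initial weight 0.5) must already drive an *untrained*
  output past threshold (`v_th = 1`), otherwise the unsupervised loop never
  starts firing and nothing is learned; much larger gains push the drive so
  far above threshold that the adaptation current (steady scale ~0.2)
  cannot influence the competition. This is the principal free choice of
  the implementation and is exposed in `network_config()`.
* **Winner uniqueness.** At `dt = 5` ms several outputs can cross
  threshold in one step; the winner is the largest pre-reset potential,
  ties to the lowest index, and only the winner's spike is emitted —
  at most one output spike per step, by construction. Losers are clamped
  whether or not they crossed. The winner itself is not clamped (only
  refractory).

The VDSP update in the loop reads the presynaptic potential at the end of
the step *before* any same-step presynaptic reset, per the causality
argument above.

The per-step loop is implemented twice: a pure-R reference
(`network_step()`), which is the behavioral contract, and a compiled core
(Rcpp) used by `run_sample()`/`train_network()`. The test suite drives both
over identical inputs (both rules, both encoders) and requires bit-identical
states, weights and spike counts.

## Training, labelling, evaluation

Training is a single shuffled pass (per epoch) with learning on; labels are
never used. Afterwards weights are frozen and the training set is presented
again: each output neuron is labelled with the class during which it spiked
most (ties to the lowest class id; zero-spike neurons are flagged *dead*
and labelled class 1 by the tie-break). Prediction sums spike counts over
neurons per label and takes the argmax — the cumulative rule, used for all
network sizes. Diagnostics include the confusion matrix, the weight
mid-band fraction (share of weights in `(0.2, 0.8)`; uniform random weights
score 0.6, training drives it down as the distribution grows bimodal) and
receptive-field purity (fraction of non-dead neurons whose weight vector
has maximal cosine similarity with their assigned class's prototype).

Two properties deserve caveats. Because state carries across samples,
label-pass spike totals are only *approximately* invariant to presentation
order: a handful of boundary spikes can move, so the tests assert label
stability of active neurons rather than exact count equality. And an
*untrained* network is itself well above chance on the synthetic task —
random weight vectors are random projections, and the prototypes are far
apart — so the chance-level null used in the tests scores the trained
network against label-shuffled ground truth instead.

## Synthetic data

`synthetic_spec()` describes the study conditions: 5 classes of 10×10
prototypes with 20–40% foreground pixels at intensity 255 on an exactly
zero background, pairwise Hamming separation of at least 25% of pixels,
per-pixel flip noise `flip_prob = 0.1` (foreground drops to 0, background
jumps to 255), 3000 training and 1000 test samples, balanced and shuffled,
fully reproducible from the seed. The generator mimics the structural
assumptions the pipeline relies on — a sparse bright foreground over a
large zero background, so the input-bias/background-depression mechanism is
exercised — but *not* other features of real handwritten digits: correlated
(stroke-like) pixels, intensity gradients, within-class shape variability,
or class overlap. Passing the synthetic task therefore validates the
learning machinery, not digit-level accuracy figures; the IDX reader
(`read_idx_dataset()`) accepts the standard handwritten-digit distribution
files for users who have them.

## Frequency-robustness protocol

The experiment scales all input currents by `{0.5, 1, 2, 4}`, disables
output adaptation, keeps each rule's parameters fixed across scales, and
sets the presentation duration dynamically to ten times the brightest
pixel's closed-form inter-spike interval (rounded up to a multiple of
`dt`) — at most ten spikes per pixel per image. The full-scale pixel
current at scale 1 is 2 (not 1): with the standard input bias of 0.5 a base
of 1 would leave the brightest pixel's equilibrium exactly at threshold at
scale 0.5, a degenerate condition; base 2 spans equilibria `{1.5, 2.5,
4.5, 8.5}`, matching the supra-threshold range of the window scans. The
summary statistic is the range (max − min) of mean accuracy across scales,
compared one-sidedly between VDSP and STDP: VDSP's window follows the input
frequency, STDP's fixed 20 ms window does not.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 1000 observation times per
drive level for the inversion oracle (`dt = 0.01` ms); 1000-point grids for
the algebraic identities; 10^5 fuzzed triples and 10^4-step iterated
sequences for the rule properties; window scans at `dt = 0.05` ms with
`t_ref = 2` ms on a 0.25 ms grid; the full 3000/1000 synthetic task with 30
output neurons and five seeds; and the robustness matrix (2 rules × 4
scales × 5 seeds) at 10 output neurons. Constant-current runs are exactly
deterministic given the configuration and seed (verified bit-for-bit);
Poisson and noise paths consume the R RNG in a documented order so they are
reproducible under `set.seed()`.

Degenerate inputs are handled explicitly: sub-threshold drive returns
`Inf` from the ISI oracle and flags robustness scales as degenerate;
zero-spike neurons are flagged dead, all-zero count vectors predict class 1
with a low-confidence flag; `NaN` in any state vector aborts with a
diagnostic.

## Limitations

* The voltage/spike-time equivalence holds only for constant drive; under
  Poisson input VDSP is a probabilistic approximation (the package
  supports the mode but makes no analytic claim).
* Synaptic transmission is a single filtered current with a one-step
  delay; conductance-based synapses, per-synapse delays and event-driven
  simulation are out of scope.
* The WTA clamp is an idealization of lateral inhibition — no inhibitory
  neurons are modeled.
* Synthetic-task accuracies are not comparable to digit-benchmark
  accuracies (the synthetic classes are far better separated).
* Absolute weight scales interact with `syn_gain`; networks with very
  different input sizes may need the operating-point reasoning above
  re-applied.
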