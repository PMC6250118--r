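---
title: "Competitive activity-maximization learning in recurrent spiking networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive activity-maximization learning in recurrent spiking networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`feelnet` simulates a recurrent spiking neural network of leaky
integrate-and-fire (LIF) neurons trained entirely by local, rate-based
plasticity rules — the FEELING family of rules, derived from the premise
that every neuron competitively maximizes its own firing activity. This
vignette documents the model, the numerical choices, the calibration of the
default experiment, and — importantly — what the desk-scale synthetic task
does and does not demonstrate.

## The model

### Neurons

Hidden and output units are LIF neurons integrated by explicit Euler at
`dt = 1` ms:

$$\tau_m \frac{dV_j}{dt} = -V_j(t) + I_j(t), \qquad \tau_m = 20\ \mathrm{ms}.$$

A neuron whose potential reaches its threshold fires, resets `V` to 0, and
is refractory for `tau_ref = 2` ms (the spiking step plus a countdown; the
simulated inter-spike interval under constant current matches the closed
form $\tau_{ref} + \tau_m \log(I/(I-V_{thr}))$ to within one `dt`, which
the test suite verifies at `dt = 0.01` ms). Refractory neurons clamp `V`
at 0 and receive no current.

The threshold is adaptive — a homeostat that equalizes competition:

$$\frac{dV_{th,j}}{dt} = \mathrm{inc}\cdot\delta(t - t_j) - \frac{V_{th,j}}{\tau_{th}},
\qquad \tau_{th} = 50\ \mathrm{ms}.$$

The per-spike increment couples a base constant `delta_V_th = 0.1` to the
layer size `N`. Both readings of that coupling are implemented;
`th_increment_mode = "multiply"` (`inc = delta_V_th * N`) is the default.
The alternative `inc = delta_V_th / N` yields increments of order 1e-3
against input currents of order 10, so the homeostat never engages and
every layer saturates at its refractory-limited maximal rate; under the
multiplicative reading the steady firing rate is approximately
`I / (inc * tau_th)`, which keeps all layers in a stable, informative
regime across network sizes. The threshold starts at `V_th_init` rather
than 0 so a freshly built network neither fires in a synchronous avalanche
at the first stimulus nor stays silent; the default experiment sets it near
the homeostatic equilibrium of its layer.

### Activity traces

Every neuron (including the membrane-less Poisson input units) carries two
exponential moving averages of its spike train: the fast *instant activity*
`a` (`tau_a = 15` ms) and the slow *average activity* `theta`
(`tau_theta = 150` ms). For a Bernoulli(p)-per-step spike train both
converge to `p/dt`. All plasticity rules act on the contrast `a - theta`:
a neuron (or pixel) is "interesting" when it is currently more active than
its own recent history. Input-layer traces use the same time constants as
the other layers.

### Currents

The input current of a neuron is the weighted sum of pre-synaptic instant
activities, one term per connection type, each scaled by a balancing
coefficient:

- feed-forward (input→hidden, hidden→output), weights in `[0, 1]`;
- reciprocal (output→hidden), weights in `[0, 1]`, initialized to 0;
- lateral inhibitory within the hidden and output layers, weights in
  `[-1, 0]`, initialized to -1 with a structurally zero diagonal.

During supervised presentations a constant teacher current
(`I_supervised = 30`) is injected into the output neuron of the true class,
for the stimulus window only.

### Plasticity

All four rules are event-driven: they apply at spike moments, and the
passive decay term is accumulated lazily between those moments
(`exp(-elapsed/tau)`, `tau = 10` s), which is exactly equivalent to dense
per-step integration (verified to 0.1% in the tests). At a spike of the
gating neuron:

- **feed-forward** (rate `alpha = 0.1`): `w_ij += alpha (a_i - theta_i)` —
  the spiking post-neuron strengthens inputs that are above their own
  average, and weakens the rest;
- **reciprocal** (`beta = 0.3`): `w_kj += beta (a_j - theta_j) w_jk` — a
  spiking output neuron feeds back onto hidden neurons that are active and
  forward-connected to it (the forward weight is read after the same
  step's feed-forward update);
- **output lateral** (`gamma = 0.1`): `w_kk' -= gamma (a_k - theta_k)` at
  spikes of `k'` — above-average rivals strengthen their inhibition onto
  the spiker;
- **hidden lateral** (`eta = 0.15`): `w_jj' += eta (a_j - theta_j)(a_j' -
  theta_j')` at spikes of `j`, updating `j`'s outgoing row — co-active
  pairs relax toward 0 (cooperation), discordant pairs deepen toward -1.

Weights clamp hard at their bounds. A rate-based BCM rule is provided as a
config-selectable alternative for the feed-forward connections, for
rule-comparison experiments only.

### The resting state of lateral inhibition

The one place this implementation deliberately departs from a literal
reading of the rule equations is the target of the lateral decay term. With
inhibitory weights decaying toward 0, any neuron that fires regularly
erodes its outgoing inhibition by roughly 10% per simulated second, while
the discordance term that would recharge it is an order of magnitude too
small at any achievable trace level (silent rivals have near-zero
`theta`). We verified this directly: a hand-constructed converged network
(perfect families, 100% accuracy) loses all cross-family inhibition within
~300 presentations and falls to ~80% accuracy. Lateral groups therefore
decay toward their resting value of **-1** — competition is the default
state and cooperation must be actively maintained by co-firing — under
which the same hand-built network is a stable fixed point of the learning
dynamics. `network_config(lateral_decay_target = 0)` restores the literal
behavior. Excitatory weights decay toward 0 as written (unused connections
are forgotten).

## Stimuli and readout

Images are rate-coded: each pixel spikes independently per step with
probability `(intensity/255) * rate_max * dt / 1000`, capped at
`rate_max = 250` Hz, for `T_input = 100` ms, followed by `T_silence = 100`
ms of empty input during which currents, traces and thresholds relax (no
state reset between images). The predicted class is the argmax over output
neurons of the window-mean instant activity in the 50–100 ms interval of
the stimulus; ties break to the lowest class index. An alternative readout
from the adaptive thresholds (which track activity) is available via
`present_image(readout = "threshold")`.

Evaluation freezes everything: plasticity *and* decay are suspended, the
full dynamic state is snapshotted and restored, and the evaluation draws
its Poisson encodings from a private seeded stream — so test passes leave
the network bit-identical and are exactly reproducible.

## The synthetic task and what it shows

The default generator produces a five-class task of 16×16 images: each
class is a fixed random binary prototype with 25% active pixels, and every
sample flips each pixel with probability 0.05 and jitters active-pixel
intensity multiplicatively in `[0.8, 1]`. 200 training and 100 test images
per class. These sizes make a full train-and-evaluate cycle run in minutes
on one CPU while exercising the whole architecture.

What it does *not* emulate: intra-class variability with shared structure.
Every sample of a class is a noisy copy of one prototype, so a single
hidden neuron can represent a class perfectly, and nearest-prototype
classification is essentially error-free. Passing the desk-scale
experiments therefore demonstrates that the rules discover and stabilize a
class code, not that they handle the feature diversity of handwritten
digits; the MNIST pipeline (`read_idx()` + the same training functions) is
provided for full-scale runs, which take hours.

## Calibration of the default experiment

The balancing coefficients exist because each current type lives on a
different natural scale; they were set once by a pilot-run recipe — match
the mean absolute current of each type, then scale each layer's total
drive so the homeostatic rate equation `r = I/(inc * tau_th)` puts it in
the intended regime — and then frozen. The frozen defaults for the
synthetic task (256-30-5 network) are:

| coefficient | value | role |
|---|---|---|
| `c_ff_hidden` | 1.5 | weak bottom-up drive: hidden firing is sparse and selective |
| `c_lat_hidden` | 150 | strong competition: a class's neurons suppress the rest |
| `c_rec` | 400 | the teacher-driven reciprocal loop dominates hidden selection |
| `c_ff_output` | 2 | output drive below the teacher scale |
| `c_lat_output` | 30 | the teacher-driven output silences its rivals |
| `V_th_init` | 5 | near the homeostatic equilibrium; prevents onset avalanches |

The mechanism this operating point implements: during supervised training
the teacher makes exactly one output fire; its reciprocal weights grow
toward whichever hidden neurons happen to respond to that class (seeded by
the random initial hidden→output weights), and the resulting feedback
current — large against the deliberately weak feed-forward drive — selects
a small per-class group of hidden neurons whose input weights then imprint
the class pixels. Lateral inhibition keeps the groups disjoint. At
evaluation the learned feed-forward pathway activates the right group, and
the reciprocal loop sharpens its firing.

Two honest limitations of this operating point, both consequences of the
task's lack of intra-class diversity:

- **Families are narrow.** One to two hidden neurons per class capture the
  code (narrow "families"); most hidden neurons remain uncommitted
  singletons in the lateral-weight graph, so hierarchical family
  clustering (`cluster_families()`) recovers the class partition only
  weakly (adjusted Rand index ~0.05 at the accuracy-optimal defaults,
  ~0.5–0.7 at family-friendly settings whose accuracy is then unreliable).
  With nothing forcing feature-sharing, distributed multi-neuron families
  carry no coding advantage here, unlike on handwritten digits.
- **The reciprocal lesion is nearly harmless.** Because the adaptive
  threshold decays within a few `tau_th`, the feed-forward pathway
  re-ignites by itself inside the 100 ms stimulus window, and the task's
  margins are wide; zeroing the reciprocal weights after training
  typically leaves accuracy unchanged instead of halving it. The forward
  and reciprocal weight matrices are nonetheless near-perfectly correlated
  (r ≈ 1), confirming that the feedback wires onto exactly the forward
  structure.

## Numerical and design choices

- Explicit Euler at `dt = 1` ms; a fine-`dt` mode exists for oracle tests.
- Step order: input traces → currents → membrane/spikes → thresholds →
  traces → plasticity (feed-forward, then reciprocal, then lateral), then
  the clock advances — one step is a pure function of the previous state.
- Multiple simultaneous post-synaptic spikes are processed in index order;
  the touched slices are disjoint, so order does not matter.
- The hidden lateral matrix is directed (`w[j, j']` = `j`'s outgoing
  inhibition); clustering collapses direction by the element-wise minimum
  (strongest inhibition wins) and keeps edges strictly above the cutoff.
- Plasticity stays enabled during the silent window (the rules are
  spike-gated, so silence contributes only decay);
  `learn_in_silence = FALSE` freezes it.
- Presentation order is a single seeded shuffle; all randomness derives
  from one run seed through labeled component streams, so toggling one
  randomized component does not shift another's draws, and identical
  configurations reproduce bit-identical learning curves.
- Degenerate inputs raise errors rather than warn: non-binary spike
  vectors, out-of-range intensities or labels, non-monotone decay clocks,
  misshapen weight matrices, unknown configuration keys.

## Problem sizes used by the test suite

The acceptance tests train the default five-class task for 1000 supervised
presentations on five seeds (accuracy, family clustering, lesion and
correlation analyses reuse these networks), run the
partial-vs-unsupervised comparison for 250 presentations per mode (50
supervised then 200 unsupervised in the partial arm; at longer horizons
the unsupervised drift documented above erases both arms), and
verify the engine-level properties (trace fixed point, LIF interval
oracle, decay equivalence, bound preservation) on small dedicated
fixtures. The whole suite completes in roughly ten minutes on one CPU.
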