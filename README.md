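# feelnet

Clock-driven simulation of recurrent **spiking neural networks** trained by
local, rate-based plasticity rules derived from a single premise: every
neuron competitively maximizes its own firing activity (the FEELING family
of rules). The package is aimed at computational-neuroscience work on
local learning rules — it provides the full model (LIF neurons with
adaptive thresholds, feed-forward / reciprocal / lateral-inhibitory
connections, event-driven weight decay), the training protocols
(supervised teacher currents, partially-unsupervised, unsupervised), and
the post-hoc structure analyses (hierarchical neuron-family clustering,
receptive-field products, forward/reciprocal correlation, lesion
experiments), all testable end-to-end on a built-in synthetic image task
and applicable to MNIST via the included IDX reader.

## The model in brief

Membrane dynamics (explicit Euler, `dt = 1` ms), with an adaptive
threshold implementing firing-rate homeostasis:

$$\tau_m \dot V_j = -V_j + I_j,\qquad
  \dot V_{th,j} = \mathrm{inc}\,\delta(t-t_j) - V_{th,j}/\tau_{th},$$

and input currents as weighted sums of pre-synaptic *instant activities*
(fast EMAs of the spike trains, `tau_a`), balanced per connection type.
Learning acts on the contrast between the fast and slow activity traces,
at spike moments, with lazy exponential weight decay in between:

| connection | update at a spike | bounds |
|---|---|---|
| feed-forward | `w_ij += alpha (a_i - theta_i)` | `[0, 1]` |
| reciprocal (output→hidden) | `w_kj += beta (a_j - theta_j) w_jk` | `[0, 1]` |
| output lateral | `w_kk' -= gamma (a_k - theta_k)` | `[-1, 0]` |
| hidden lateral | `w_jj' += eta (a_j - theta_j)(a_j' - theta_j')` | `[-1, 0]` |

Cooperating (co-active) hidden neurons relax their mutual inhibition
toward 0 and form *families* that jointly encode a class; discordant pairs
stay maximally inhibitory. The `vignettes/feelnet-methods.Rmd` vignette
documents every parameter, the calibration of the defaults, and the known
limitations of the desk-scale task.

## Worked example

Train the default supervised experiment (five prototype classes, 16×16
pixels, a 256-30-5 network) and inspect the learned structure:

```r
library(feelnet)

cfg  <- default_config(seed = 42)
obj  <- config_objects(cfg)
data <- obj$make_data()
net  <- build_network(obj$network_config)

sch <- train_schedule("supervised", n_train_total = 500,
                      eval_every = 100, n_eval = 100)
fit <- train(net, data, sch, obj$protocol, verbose = TRUE)
#>   [supervised] 100 images seen: accuracy 1.000
#>   [supervised] 200 images seen: accuracy 1.000
#>   ...
#>   [supervised] 500 images seen: accuracy 1.000

forward_reciprocal_correlation(net$groups$ff_hidden_out$W,
                               net$groups$reciprocal$W)
#> [1] 1

cluster_families(net$groups$lateral_hidden$W)
#> <family_tree over 30 neurons, 21 cutoff levels>
#>  cutoff components
#>   -1.00          1
#>   -0.95         26
#>   ...
#>    0.00         30
```

The learning curve shows the teacher-driven network solving the
prototype task within the first hundred presentations (the task is
deliberately easy; chance is 0.2). The forward and reciprocal weight
matrices between hidden and output layers end up perfectly correlated —
output neurons feed back onto exactly the hidden neurons that drive them.
The family tree shows the pruning profile of the hidden lateral weights:
at this operating point each class is encoded by one or two strongly
cooperating neurons, so most hidden units remain singleton nodes (see the
vignette for why, and for settings that trade accuracy for broader
families).

Other entry points: `present_image()` / `evaluate()` for single
presentations and frozen-weight evaluation, `lesion_reciprocal()` for
feedback-lesion experiments, `receptive_field_product()` for per-class
input maps, `read_idx()` / `write_idx()` for MNIST-format data,
`save_network()` / `load_network()` for JSON checkpoints, and
`run_experiment()` (or `inst/cli/feelnet-cli.R` from a shell) for
config-file-driven runs: `train`, `evaluate`, `ablate` (the four
connectivity architectures), `cluster`, `visualize`, `synth-data`, each
writing a reproducible run manifest.

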