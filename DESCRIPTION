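Package: feelnet
Title: Recurrent Spiking Neural Networks Trained by Competitive
    Activity-Maximization Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clock-driven simulator for recurrent spiking neural networks of
    leaky integrate-and-fire neurons with adaptive firing thresholds, trained
    by local rate-based plasticity rules derived from the principle that each
    neuron competitively maximizes its own activity (the FEELING family of
    rules). Provides feed-forward, reciprocal and lateral-inhibitory
    connections with event-driven exponential weight decay, Poisson rate
    coding of images, supervised, partially-unsupervised and unsupervised
    training protocols with an argmax rate readout, a synthetic
    class-prototype image generator for desk-scale experiments, an MNIST IDX
    reader, and post-hoc analysis tools such as hierarchical family clustering
    of hidden neurons by lateral-weight pruning, receptive-field products,
    forward/reciprocal weight correlation, and lesion experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    mclust,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
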