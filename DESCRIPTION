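Package: retinattn
Title: Attention-Based Decoding and Interpretability for Retinal Population Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates retinal ganglion cell population responses to full-field
    flash and fractional-Brownian-motion moving-ball stimuli, decodes the
    stimuli with a spike-tokenized latent cross-attention encoder-decoder
    network trained by hand-rolled backpropagation, and analyzes the trained
    model's attention: spike-level relevance weights, Shannon attention
    entropy, Kolmogorov-Smirnov head divergence, per-unit importance scores,
    attention-guided ablation against random controls, cross-seed consensus
    subsets with physiological characterization, and decoder-side
    entropy-stimulus coupling with directional decomposition. Includes flash
    physiology indices (polarity bias, sustain index, latency, mean rate) and
    a ridge optimal-linear-estimator decoding baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    pracma,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
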