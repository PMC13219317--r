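# retinattn

Attention-based decoding and interpretability for retinal population spike
trains.

Retinal ganglion cells (RGCs) encode the visual scene in parallel spike
trains. Modern transformer decoders reconstruct the stimulus from those
trains with high accuracy, but their value for neuroscience depends on
whether their internal attention is interpretable: does the model's
allocation of attention over spikes and units recover real population-coding
structure? `retinattn` builds the full test bed for that question in R,
with synthetic recordings standing in for multielectrode-array data:

- **Synthetic retina** — full-field flash protocols (3 s ON / 3 s OFF,
  10 trials) and a moving ball following fractional Brownian motion
  (Hurst exponent H = 0.9, mean speed 232 px/s on a 400 x 400 px field);
  populations of ON / OFF / ON-OFF units with controlled kinetics,
  latencies, firing rates and Gaussian receptive fields, spiking as
  inhomogeneous Poisson processes (thinning; continuous spike times).
- **Flash physiology** — the standard light-response indices per unit:
  polarity bias `fBR = (f_ON - f_OFF) / (f_ON + f_OFF)`, sustain index
  `Si = (f_pref - f̄) / (f_pref + f̄)`, onset-to-peak latency, mean rate.
- **Spike-tokenized attention decoder** — every spike becomes one token
  (learned unit embedding + sinusoidal encoding of continuous spike time
  within a 1-s context window); a cross-attention block compresses the
  tokens into L learned latents, a self-attention stack refines them, and a
  decoder cross-attention block queries them from output-timestamp tokens
  to reconstruct the stimulus (flash intensity, or ball x/y). Forward pass,
  analytic backpropagation and AdamW are implemented in base R matrix code
  and verified against numerical gradients.
- **Interpretability stack** — latent-averaged spike weights
  `w̄ = (1/L) Σ_j a_jk` and count-normalized weights `ŵ = w̄ N_i`; Shannon
  attention entropy `E(h,i) = -Σ w̄ ln w̄` per head at 1 Hz; pairwise
  Kolmogorov-Smirnov head divergence; per-unit importance `I(u)` (per-spike
  attention averaged over heads and windows); attention-guided ablation
  against random controls; cross-seed top-K consensus sets with K-S
  physiological characterization; decoder-side entropy and its coupling to
  the stimulus, including the rectified (+X, -X, +Y, -Y) directional
  decomposition.
- **Baseline** — ridge optimal linear estimator (alpha = 0.1) on binned
  rates, sharing the decoder's temporal-block splits.

## Worked example

```r
library(retinattn)

# simulate a flash session and recover unit physiology
fcfg  <- flash_config()                      # 3 s ON / 3 s OFF, 10 trials
stim  <- generate_flash(fcfg)
pop   <- generate_population(n_units = 40, rng_seed = 11)
spk   <- simulate_spikes(stim, pop, rng_seed = 12)
phys  <- light_features(spk, fcfg)
head(phys, 3)
#   unit_id        fbr sustain_index latency_s mean_rate_hz
# 1       1 -0.6250000     0.7587373     0.075     3.566667
# 2       2 -0.2941176     0.4505495     0.275     8.333333
# 3       3  0.7391304     0.5952144     0.175    10.150000

# train the attention decoder and evaluate on held-out temporal blocks
cfg   <- model_config()                      # desk-scale profile
wins  <- make_windows(spk, stim, cfg)
split <- split_windows(length(wins))
mod   <- init_decoder(cfg, pop, out_dim = 1, rng_seed = 1)
mod   <- train_decoder(mod, wins,
                       train_config(epochs = 40, lr = 1e-3, rng_seed = 2),
                       split = split)
evaluate_r2(mod, wins, split$test)$r2
# [1] 0.9991085
```

Unit 1 is OFF-dominated and fairly transient (`fbr = -0.63`,
`sustain_index = 0.76`, 75 ms latency), unit 2 responds to both phases
with an OFF bias, and unit 3 is an ON cell; their mean rates span
3.6-10.2 Hz. The trained decoder reconstructs the held-out intensity
trace almost perfectly (R² = 0.999); `fit_ole()` on the same session gives the linear
reference, and `collect_encoder_attention()` / `unit_importance()` /
`ablation_experiment()` take the analysis from decoding to attention-based
interpretability.

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` ... `06_decoder_attention.R`) that runs the complete study
at desk scale and writes its tables under `results/`.

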