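# Shared fixtures, built once per test run.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fx <- new.env(parent = emptyenv())

fixtures <- function() {
  if (is.null(.fx$f)) .fx$f <- make_fixtures()
  .fx$f
}

# A regular deterministic spike train: one spike at the centre of every
# `bin`-wide slot over [0, total); constant rate 1/bin Hz with exactly one
# spike per PSTH bin.
regular_train <- function(total, bin = 0.05, unit_id = 1L) {
  tt <- seq(bin / 2, total - bin / 2, by = bin)
  df <- data.frame(unit_id = unit_id, time_s = tt, session_id = "S1")
  class(df) <- c("spike_events", "data.frame")
  df
}

# Spikes at given within-trial times, replicated across trials.
trial_spikes <- function(times_in_trial, fcfg, unit_id = 1L) {
  period <- fcfg$on_duration + fcfg$off_duration
  tt <- as.vector(outer(times_in_trial, (seq_len(fcfg$n_trials) - 1) * period,
                        "+"))
  df <- data.frame(unit_id = rep(unit_id, length(tt)), time_s = sort(tt),
                   session_id = rep("S1", length(tt)))
  class(df) <- c("spike_events", "data.frame")
  df
}

# A tiny decoder + window set on the miniature flash fixture, for
# shape/invariance tests (untrained).
tiny_model_setup <- function(out_dim = 1) {
  f <- fixtures()$flash
  cfg <- model_config(latent_dim = 16L, n_latents = 4L, depth = 1L,
                      n_heads = 2L, head_dim = 8L, ffn_mult = 2L,
                      dropout = 0, n_out_tokens = 6L)
  wins <- make_windows(f$spikes, f$stim, cfg)
  model <- init_decoder(cfg, f$pop, out_dim = out_dim, rng_seed = 5L)
  list(cfg = cfg, wins = wins, model = model, fixture = f)
}
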