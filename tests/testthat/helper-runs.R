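# Trained-model fixtures shared across test files. Each is built once per
# test run (a few minutes of CPU total) and cached. Seeds are fixed
# constants; problem sizes are the desk-scale study conditions described in
# the methods vignette.

.runs <- new.env(parent = emptyenv())

# Flash session: 40-unit population under the canonical 3 s ON / 3 s OFF,
# 10-trial protocol; scaled-profile decoder trained 40 epochs.
flash_run <- function() {
  if (!is.null(.runs$flash)) return(.runs$flash)
  fcfg <- flash_config()
  stim <- generate_flash(fcfg)
  pop <- generate_population(n_units = 40, rng_seed = 11)
  spk <- simulate_spikes(stim, pop, rng_seed = 12)
  cfg <- model_config()
  wins <- make_windows(spk, stim, cfg)
  split <- split_windows(length(wins))
  model <- init_decoder(cfg, pop, out_dim = 1, rng_seed = 1)
  model <- train_decoder(model, wins,
                         train_config(epochs = 40, lr = 1e-3, rng_seed = 2),
                         split = split)
  .runs$flash <- list(fcfg = fcfg, stim = stim, pop = pop, spk = spk,
                      cfg = cfg, wins = wins, split = split, model = model,
                      r2 = evaluate_r2(model, wins, split$test)$r2)
  .runs$flash
}

# Ball session with a planted 20% informative subpopulation: 200 units, 40
# stimulus-driven; 20 s fBm trajectory (H = 0.9) repeated 10 times; decoder
# trained 60 epochs. Also carries the ridge OLE baseline on the identical
# split, the importance ranking over all windows, and the ablation curves.
ball_run <- function() {
  if (!is.null(.runs$ball)) return(.runs$ball)
  bcfg <- ball_config(n_trials = 10, rng_seed = 21)
  stim <- generate_ball_trajectory(bcfg)
  pop <- generate_population(n_units = 200, n_informative = 40,
                             rng_seed = 41)
  spk <- simulate_spikes(stim, pop, rng_seed = 42)
  cfg <- model_config()
  wins <- make_windows(spk, stim, cfg)
  split <- split_windows(length(wins))
  ole <- fit_ole(spk, stim, cfg, split = split)
  model <- init_decoder(cfg, pop, out_dim = 2, rng_seed = 1)
  model <- train_decoder(model, wins,
                         train_config(epochs = 60, lr = 1e-3, rng_seed = 101),
                         split = split)
  attn <- collect_encoder_attention(model, wins)
  wts <- spike_weights(attn)
  imp <- unit_importance(wts, unit_ids = pop$unit_id)
  abl <- ablation_experiment(model, wins, split$test, imp,
                             strategy = "both", n_random_iters = 20,
                             step_size = 20, rng_seed = 3)
  .runs$ball <- list(bcfg = bcfg, stim = stim, pop = pop, spk = spk,
                     cfg = cfg, wins = wins, split = split, model = model,
                     ole = ole, weights = wts, importance = imp,
                     ablation = abl,
                     truth = pop$unit_id[pop$informative_gain > 0],
                     r2 = evaluate_r2(model, wins, split$test)$r2)
  .runs$ball
}

# Fine-tuning pair on a held-out session: a new (curated, fully responsive)
# retina shown the same stimulus movie. From-scratch training for 40 epochs
# vs staged fine-tuning of the ball_run core for 20 epochs total
# (10 embeddings-only warmup + 10 full).
finetune_run <- function() {
  if (!is.null(.runs$ft)) return(.runs$ft)
  pre <- ball_run()
  stim <- generate_ball_trajectory(ball_config(n_trials = 10, rng_seed = 21))
  pop <- generate_population(n_units = 120, rng_seed = 141)
  spk <- simulate_spikes(stim, pop, rng_seed = 142)
  cfg <- model_config()
  wins <- make_windows(spk, stim, cfg)
  split <- split_windows(length(wins))
  scratch_epochs <- 40L
  scratch <- init_decoder(cfg, pop, out_dim = 2, rng_seed = 5)
  scratch <- train_decoder(scratch, wins,
                           train_config(epochs = scratch_epochs, lr = 1e-3,
                                        rng_seed = 6),
                           split = split)
  ft <- finetune_decoder(pre$model, wins, pop,
                         train_config(epochs = 10, lr = 1e-3, rng_seed = 7),
                         split = split, warmup_epochs = 10)
  .runs$ft <- list(wins = wins, split = split,
                   scratch = scratch, ft = ft,
                   scratch_epochs = scratch_epochs,
                   ft_epochs = nrow(ft$curve) + nrow(ft$warmup_curve),
                   scratch_r2 = evaluate_r2(scratch, wins, split$test)$r2,
                   ft_r2 = evaluate_r2(ft, wins, split$test)$r2)
  .runs$ft
}
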