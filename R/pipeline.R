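#' Experiment configuration
#'
#' Bundles the simulator, model and training settings for an end-to-end
#' multi-seed experiment. Seeds for the independent training runs are
#' `base_seed + run index`.
#'
#' @param stimulus `"flash"` or `"ball"`
#' @param n_units population size
#' @param n_informative stimulus-driven units (default all)
#' @param stim_config a [flash_config()] or [ball_config()] (default by
#'   stimulus type)
#' @param model_cfg a [model_config()]
#' @param train_cfg a [train_config()]
#' @param n_seeds independent training runs (>= 2 for consensus)
#' @param ablation_threshold R-squared level defining the per-seed top-K
#' @param consensus_fraction minimum fraction of seeds for consensus
#' @param ablation_step units removed per ablation step
#' @param n_random_iters random ablation orders per seed
#' @param base_seed base for all derived seeds
#' @param out_dir optional directory for CSV artifacts
#' @return an `experiment_config` list
#' @export
experiment_config <- function(stimulus = c("flash", "ball"),
                              n_units = 60, n_informative = n_units,
                              stim_config = NULL,
                              model_cfg = model_config(),
                              train_cfg = train_config(),
                              n_seeds = 2, ablation_threshold = 0.5,
                              consensus_fraction = 0.5,
                              ablation_step = 5, n_random_iters = 5,
                              base_seed = 1L, out_dir = NULL) {
  stimulus <- match.arg(stimulus)
  if (is.null(stim_config))
    stim_config <- if (stimulus == "flash") flash_config() else ball_config()
  structure(list(stimulus = stimulus, n_units = n_units,
                 n_informative = n_informative, stim_config = stim_config,
                 model_cfg = model_cfg, train_cfg = train_cfg,
                 n_seeds = as.integer(n_seeds),
                 ablation_threshold = ablation_threshold,
                 consensus_fraction = consensus_fraction,
                 ablation_step = ablation_step,
                 n_random_iters = n_random_iters,
                 base_seed = as.integer(base_seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Run a full simulate-train-analyze experiment
#'
#' Executes the whole stack: stimulus simulation, population generation,
#' spike simulation, flash physiology (always computed from a companion
#' flash session on the same population), one decoder training run per seed,
#' encoder attention analysis (weights, entropy, head divergence, unit
#' importance), attention-guided vs random ablation, per-seed top-K and
#' cross-seed consensus, physiological comparison, and decoder attention
#' coupling. With fewer than 2 seeds the consensus stage is skipped with a
#' warning.
#'
#' @param config an [experiment_config()]
#' @param verbose print stage progress
#' @return an `experiment_report` list; if `config$out_dir` is set the main
#'   tables are also written there as CSV
#' @export
run_experiment <- function(config, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  bs <- config$base_seed
  say("simulating stimuli and population")
  stim <- if (config$stimulus == "flash") generate_flash(config$stim_config)
          else generate_ball_trajectory(config$stim_config)
  pop <- generate_population(config$n_units, config$n_informative,
                             rng_seed = child_seed(bs, 1))
  spikes <- simulate_spikes(stim, pop, rng_seed = child_seed(bs, 2))
  # physiology always measured under the flash protocol
  fcfg <- if (config$stimulus == "flash") config$stim_config else flash_config()
  flash_pop <- pop
  flash_pop$informative_gain <- 1
  flash_stim <- if (config$stimulus == "flash") stim else generate_flash(fcfg)
  flash_spikes <- if (config$stimulus == "flash") spikes else
    simulate_spikes(flash_stim, flash_pop, rng_seed = child_seed(bs, 3))
  physio <- light_features(flash_spikes, fcfg)

  out_dim <- if (config$stimulus == "flash") 1L else 2L
  windows <- make_windows(spikes, stim, config$model_cfg)
  split <- split_windows(length(windows), config$train_cfg$split)
  say("training ", config$n_seeds, " seed(s)")
  seeds <- bs + seq_len(config$n_seeds)
  runs <- lapply(seeds, function(sd) {
    tcfg <- config$train_cfg
    tcfg$rng_seed <- sd
    model <- init_decoder(config$model_cfg, pop, out_dim = out_dim,
                          rng_seed = sd)
    model <- train_decoder(model, windows, tcfg, split = split)
    test_r2 <- evaluate_r2(model, windows, split$test)$r2
    say("  seed ", sd, " test R2 ", round(test_r2, 3))
    attn <- collect_encoder_attention(model, windows, split$test)
    wts <- spike_weights(attn)
    ent <- encoder_entropy(wts)
    imp <- unit_importance(wts, unit_ids = pop$unit_id)
    abl <- ablation_experiment(model, windows, split$test, imp,
                               strategy = "both",
                               n_random_iters = config$n_random_iters,
                               step_size = config$ablation_step,
                               rng_seed = sd)
    att_curve <- abl[abl$strategy == "attention", ]
    tk <- topk_at_threshold(att_curve, config$ablation_threshold,
                            n_units = config$n_units)
    list(seed = sd, model = model, test_r2 = test_r2, entropy = ent,
         divergence = head_divergence(ent), importance = imp,
         ablation = abl, K = tk$K, crossed = tk$crossed,
         topk = imp$unit_id[seq_len(max(tk$K, 1))])
  })

  consensus <- NULL
  phys_tests <- NULL
  if (config$n_seeds >= 2) {
    say("consensus and physiology")
    consensus <- consensus_units(lapply(runs, `[[`, "topk"),
                                 config$consensus_fraction)
    if (nrow(consensus) > 0)
      phys_tests <- compare_physiology(physio, consensus$unit_id)$tests
  } else {
    warning("n_seeds < 2: consensus stage skipped")
  }

  say("decoder attention analysis")
  dec_attn <- collect_decoder_attention(runs[[1]]$model, windows, split$test)
  dec_ent <- decoder_entropy(dec_attn)
  coupling <- if (config$stimulus == "flash") {
    flash_coupling(dec_ent, stim)
  } else {
    directional_coupling(dec_ent, directional_decompose(stim))
  }

  report <- list(config = config, seeds = seeds,
                 roster = pop, physiology = physio,
                 per_seed = lapply(runs, function(r)
                   r[setdiff(names(r), "model")]),
                 models = lapply(runs, `[[`, "model"),
                 test_r2 = vapply(runs, `[[`, numeric(1), "test_r2"),
                 consensus = consensus, physiology_tests = phys_tests,
                 decoder_entropy = dec_ent, coupling = coupling,
                 split = split)
  class(report) <- "experiment_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write the main report tables as CSV
#'
#' @param report an `experiment_report`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name),
                                           row.names = FALSE)
  w(data.frame(seed = report$seeds, test_r2 = report$test_r2),
    "test_r2.csv")
  w(report$physiology, "physiology.csv")
  for (i in seq_along(report$per_seed)) {
    r <- report$per_seed[[i]]
    w(r$entropy, sprintf("encoder_entropy_seed%d.csv", r$seed))
    w(r$importance, sprintf("importance_seed%d.csv", r$seed))
    w(r$ablation, sprintf("ablation_seed%d.csv", r$seed))
  }
  if (!is.null(report$consensus)) w(report$consensus, "consensus_units.csv")
  if (!is.null(report$physiology_tests))
    w(report$physiology_tests, "physiology_tests.csv")
  w(report$decoder_entropy, "decoder_entropy.csv")
  w(report$coupling, "coupling.csv")
  invisible(dir)
}

#' Deterministic miniature fixtures for unit tests
#'
#' Small hand-checkable objects: a 3-unit / 2-window attention toy whose
#' per-unit importance can be verified by direct summation, a miniature
#' flash session with planted rates, and a miniature ball session.
#'
#' @param profile `"tiny"` (the only profile)
#' @return named list of fixtures
#' @export
make_fixtures <- function(profile = "tiny") {
  # toy spike-weight object: H = 1 head, 1 window, units A=1 (2 spikes,
  # wbar 0.4 each) and B=2 (1 spike, wbar 0.2)
  toy_weights <- structure(list(list(
    wbar = matrix(c(0.4, 0.4, 0.2), nrow = 1),
    what = matrix(c(0.4, 0.4, 0.2) * 3, nrow = 1),
    unit_id = c(1, 1, 2), time_s = c(0.1, 0.5, 0.9), t_end = 1, n = 3L
  )), class = "spike_weights", n_heads = 1L)

  fcfg <- flash_config(n_trials = 3)
  flash_stim <- generate_flash(fcfg)
  flash_pop <- generate_population(n_units = 6, rng_seed = 101L)
  flash_spk <- simulate_spikes(flash_stim, flash_pop, rng_seed = 102L)

  bcfg <- ball_config(duration = 10, n_trials = 1, rng_seed = 103L)
  ball_stim <- generate_ball_trajectory(bcfg)
  ball_pop <- generate_population(n_units = 6, rng_seed = 104L)
  ball_spk <- simulate_spikes(ball_stim, ball_pop, rng_seed = 105L)

  list(toy_weights = toy_weights,
       flash = list(cfg = fcfg, stim = flash_stim, pop = flash_pop,
                    spikes = flash_spk),
       ball = list(cfg = bcfg, stim = ball_stim, pop = ball_pop,
                   spikes = ball_spk))
}

#' Read / write an experiment configuration as YAML
#'
#' @param config an `experiment_config`
#' @param path file path
#' @return `read_experiment_yaml` returns an `experiment_config`
#' @export
write_experiment_yaml <- function(config, path) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_experiment_yaml
#' @export
read_experiment_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  stim_cfg <- if (y$stimulus == "flash") do.call(flash_config, y$stim_config)
              else do.call(ball_config, y$stim_config)
  experiment_config(stimulus = y$stimulus, n_units = y$n_units,
                    n_informative = y$n_informative, stim_config = stim_cfg,
                    model_cfg = do.call(model_config,
                                        y$model_cfg[setdiff(names(y$model_cfg),
                                                            "profile")]),
                    train_cfg = do.call(train_config, y$train_cfg),
                    n_seeds = y$n_seeds,
                    ablation_threshold = y$ablation_threshold,
                    consensus_fraction = y$consensus_fraction,
                    ablation_step = y$ablation_step,
                    n_random_iters = y$n_random_iters,
                    base_seed = y$base_seed,
                    out_dir = y$out_dir)
}
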