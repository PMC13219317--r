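#' Generate a ground-truth-labeled synthetic RGC population
#'
#' Draws a cohort of retinal ganglion cell models from mixtures over polarity
#' (ON / OFF / ON-OFF), response kinetics (a `sustain` parameter in `[0, 1]`
#' mapping to the adaptation time constant), response latency, heterogeneous
#' baseline and peak firing rates, and spatial Gaussian receptive fields.
#' Exactly `n_informative` units carry stimulus drive (`informative_gain = 1`);
#' the remainder fire at baseline only, giving a planted uninformative
#' subpopulation whose recovery downstream analyses can be scored against.
#'
#' @param n_units number of units
#' @param n_informative number of stimulus-driven units (`<= n_units`);
#'   defaults to all units
#' @param mixture named list of distribution settings:
#'   `polarity_probs` (ON, OFF, ON-OFF), `sustain_range`, `latency_range`
#'   (s), `baseline_meanlog`/`baseline_sdlog` (log-Hz), `peak_gain_meanlog`/
#'   `peak_gain_sdlog` (log-Hz above baseline), `rf_sigma_range` (px)
#' @param field_size field size in pixels for receptive-field placement
#' @param rng_seed integer seed
#' @return data.frame of class `unit_roster`, one row per unit
#' @export
generate_population <- function(n_units = 400,
                                n_informative = n_units,
                                mixture = default_mixture(),
                                field_size = c(400, 400),
                                rng_seed = 1L) {
  stop_if_not(n_units >= 1, "n_units must be >= 1")
  stop_if_not(n_informative <= n_units, "n_informative must be <= n_units")
  stop_if_not(length(mixture$polarity_probs) == 3 &&
                sum(mixture$polarity_probs) > 0,
              "mixture$polarity_probs must be 3 nonnegative weights")
  with_seed(rng_seed, {
    polarity <- sample(c("ON", "OFF", "ON-OFF"), n_units, replace = TRUE,
                       prob = mixture$polarity_probs)
    sustain <- stats::runif(n_units, mixture$sustain_range[1],
                            mixture$sustain_range[2])
    latency <- stats::runif(n_units, mixture$latency_range[1],
                            mixture$latency_range[2])
    baseline <- stats::rlnorm(n_units, mixture$baseline_meanlog,
                              mixture$baseline_sdlog)
    peak <- baseline + stats::rlnorm(n_units, mixture$peak_gain_meanlog,
                                     mixture$peak_gain_sdlog)
    rf_x <- stats::runif(n_units, 0, field_size[1])
    rf_y <- stats::runif(n_units, 0, field_size[2])
    rf_sigma <- stats::runif(n_units, mixture$rf_sigma_range[1],
                             mixture$rf_sigma_range[2])
    informative <- rep(0, n_units)
    informative[sample.int(n_units, n_informative)] <- 1
  })
  out <- data.frame(
    unit_id = seq_len(n_units),
    polarity = polarity,
    polarity_mix = 0.5,          # ON-weight of the ON-OFF response
    sustain = sustain,
    latency_s = latency,
    baseline_hz = baseline,
    peak_hz = peak,
    rf_x = rf_x, rf_y = rf_y, rf_sigma = rf_sigma,
    informative_gain = informative,
    stringsAsFactors = FALSE
  )
  class(out) <- c("unit_roster", "data.frame")
  attr(out, "rng_seed") <- as.integer(rng_seed)
  attr(out, "field_size") <- field_size
  out
}

#' Default response-property mixture for [generate_population()]
#'
#' Polarity 40/40/20 (ON/OFF/ON-OFF), kinetics uniform between fully
#' transient and fully sustained, latencies 50-300 ms, log-normal spontaneous
#' rates around 1 Hz and evoked gains around 30 Hz (typical for curated,
#' light-responsive mouse RGCs, whose spontaneous activity is low relative to
#' evoked transients), receptive-field radii 20-40 px (~80-160 um at the
#' 4 um/px display calibration, matching mouse RGC centre sizes).
#' @return named list of mixture settings
#' @export
default_mixture <- function() {
  list(polarity_probs = c(0.4, 0.4, 0.2),
       sustain_range = c(0, 1),
       latency_range = c(0.05, 0.3),
       baseline_meanlog = log(1), baseline_sdlog = 0.6,
       peak_gain_meanlog = log(30), peak_gain_sdlog = 0.5,
       rf_sigma_range = c(20, 40))
}

# Per-unit firing-rate function on the stimulus time grid (Hz).
# Flash: polarity-gated adaptation kernel
#   k(t) = sustain + (1 - sustain) * exp(-t / 80 ms),
# i.e. a transient component decaying with an 80 ms time constant riding on a
# sustained plateau; sustain = 1 gives a constant response over the phase,
# sustain = 0 a purely transient one. Shifted by latency and gated to the
# unit's own phase. Ball: Gaussian receptive field evaluated at the ball
# position, low-pass filtered with the unit's kinetics and shifted by
# latency. Both are scaled to peak at peak_hz on top of baseline_hz.
unit_rate <- function(unit, stimulus) {
  t <- stimulus$t_s
  dt <- 1 / attr(stimulus, "frame_rate")
  type <- attr(stimulus, "stim_type")
  gain <- unit$informative_gain * (unit$peak_hz - unit$baseline_hz)
  if (type == "flash") {
    cfg <- attr(stimulus, "config")
    period <- cfg$on_duration + cfg$off_duration
    phase <- t %% period
    drive <- numeric(length(t))
    comp <- function(onset, dur, weight) {
      s <- pmin(pmax(unit$sustain, 0), 1)
      tt <- phase - onset - unit$latency_s
      in_phase <- phase >= onset & phase < onset + dur
      k <- s + (1 - s) * exp(-tt / 0.08)
      weight * ifelse(in_phase & tt >= 0, k, 0)
    }
    if (unit$polarity == "ON") {
      drive <- comp(0, cfg$on_duration, 1)
    } else if (unit$polarity == "OFF") {
      drive <- comp(cfg$on_duration, cfg$off_duration, 1)
    } else {
      drive <- comp(0, cfg$on_duration, unit$polarity_mix) +
        comp(cfg$on_duration, cfg$off_duration, 1 - unit$polarity_mix)
    }
  } else if (type == "ball") {
    d2 <- (stimulus$x_px - unit$rf_x)^2 + (stimulus$y_px - unit$rf_y)^2
    g <- exp(-d2 / (2 * unit$rf_sigma^2))
    tau <- 0.03 + 0.2 * unit$sustain
    a <- exp(-dt / tau)
    g <- as.numeric(stats::filter(g * (1 - a), a, method = "recursive"))
    shift <- round(unit$latency_s / dt)
    if (shift > 0) g <- c(rep(0, shift), g[seq_len(length(g) - shift)])
    drive <- g  # in [0, 1]: unit fires at peak_hz only when the ball crosses
                # its receptive-field centre

  } else {
    stop("unknown stimulus type: ", type)
  }
  lam <- unit$baseline_hz + gain * drive
  if (any(lam < 0)) {
    warning("negative instantaneous rate clamped to 0 for unit ",
            unit$unit_id)
    lam[lam < 0] <- 0
  }
  lam
}

#' Simulate continuous-time spikes by inhomogeneous-Poisson thinning
#'
#' Each unit's rate function \eqn{\lambda_u(t)} is evaluated on the stimulus
#' frame grid; candidate spikes are drawn from a homogeneous Poisson process
#' at \eqn{\max_t \lambda_u(t)} and accepted with probability
#' \eqn{\lambda_u(t)/\max \lambda_u} (linearly interpolated between frames),
#' yielding continuous spike times with sub-frame jitter. Deterministic given
#' `rng_seed`.
#'
#' @param stimulus a trace from [generate_flash()] or
#'   [generate_ball_trajectory()]
#' @param units a `unit_roster` from [generate_population()]
#' @param rng_seed integer seed
#' @param session_id session label stored with every event
#' @return data.frame of class `spike_events` with columns
#'   `unit_id`, `time_s`, `session_id`, sorted by unit then time; the roster
#'   and stimulus metadata ride along as attributes.
#' @export
simulate_spikes <- function(stimulus, units, rng_seed = 1L,
                            session_id = "S1") {
  t_grid <- stimulus$t_s
  total <- t_grid[length(t_grid)] + 1 / attr(stimulus, "frame_rate")
  events <- with_seed(rng_seed, {
    lapply(seq_len(nrow(units)), function(j) {
      u <- units[j, ]
      lam <- unit_rate(u, stimulus)
      lam_max <- max(lam)
      if (lam_max <= 0) return(numeric(0))
      n_cand <- stats::rpois(1, lam_max * total)
      if (n_cand == 0) return(numeric(0))
      tc <- sort(stats::runif(n_cand, 0, total))
      lam_t <- stats::approx(t_grid, lam, xout = tc, rule = 2)$y
      tc[stats::runif(n_cand) < lam_t / lam_max]
    })
  })
  n_per <- lengths(events)
  out <- data.frame(
    unit_id = rep(units$unit_id, n_per),
    time_s = unlist(events),
    session_id = session_id,
    stringsAsFactors = FALSE
  )
  class(out) <- c("spike_events", "data.frame")
  attr(out, "roster") <- units
  attr(out, "duration") <- total
  attr(out, "stim_type") <- attr(stimulus, "stim_type")
  attr(out, "rng_seed") <- as.integer(rng_seed)
  out
}

#' Write / read spike events as CSV
#'
#' Columns `unit_id,time_s,session_id`, times in seconds with 6 decimals.
#' @param spikes a `spike_events` data.frame
#' @param path file path
#' @return `read_spike_csv` returns a plain data.frame of events
#' @export
write_spike_csv <- function(spikes, path) {
  df <- data.frame(unit_id = spikes$unit_id,
                   time_s = sprintf("%.6f", spikes$time_s),
                   session_id = spikes$session_id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$time_s <- as.numeric(df$time_s)
  class(df) <- c("spike_events", "data.frame")
  df
}
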