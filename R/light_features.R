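#' Trial-averaged PSTH for every unit under a flash protocol
#'
#' Spike times are folded by the trial period (ON + OFF duration) and binned;
#' the histogram is converted to a rate in Hz by dividing by
#' `n_trials * bin`.
#'
#' @param spikes a `spike_events` data.frame
#' @param flash_cfg the [flash_config()] the spikes were recorded under
#' @param bin bin width in seconds (default 50 ms); must not exceed the
#'   shorter phase
#' @param unit_ids units to include (default: roster if present, else all
#'   unit ids appearing in `spikes`)
#' @return matrix of rates (units x bins) with `unit_id` rownames; bin
#'   centers (s, relative to trial onset) as the `bin_centers` attribute
#' @export
compute_psth <- function(spikes, flash_cfg, bin = 0.05, unit_ids = NULL) {
  period <- flash_cfg$on_duration + flash_cfg$off_duration
  stop_if_not(bin <= min(flash_cfg$on_duration, flash_cfg$off_duration),
              "bin must not exceed the phase duration")
  if (is.null(unit_ids)) {
    roster <- attr(spikes, "roster")
    unit_ids <- if (!is.null(roster)) roster$unit_id else sort(unique(spikes$unit_id))
  }
  n_bins <- round(period / bin)
  breaks <- seq(0, period, length.out = n_bins + 1)
  psth <- matrix(0, nrow = length(unit_ids), ncol = n_bins,
                 dimnames = list(unit_ids, NULL))
  folded <- spikes$time_s %% period
  for (i in seq_along(unit_ids)) {
    tt <- folded[spikes$unit_id == unit_ids[i]]
    if (length(tt)) {
      h <- graphics::hist(tt, breaks = breaks, plot = FALSE,
                          right = FALSE)$counts  # bins are [lo, hi)
      psth[i, ] <- h / (flash_cfg$n_trials * bin)
    }
  }
  attr(psth, "bin_centers") <- (breaks[-1] + breaks[-length(breaks)]) / 2
  attr(psth, "bin") <- bin
  attr(psth, "flash_cfg") <- flash_cfg
  psth
}

# logical masks over PSTH bins for the ON and OFF phases
phase_masks <- function(psth) {
  cfg <- attr(psth, "flash_cfg")
  centers <- attr(psth, "bin_centers")
  list(on = centers < cfg$on_duration, off = centers >= cfg$on_duration)
}

#' Flash bias response (polarity index)
#'
#' `fbr = (fON - fOFF) / (fON + fOFF)` where `fON`, `fOFF` are the peak
#' trial-averaged PSTH rates within the ON and OFF phases: +1 for a pure ON
#' unit, -1 for a pure OFF unit, 0 for a balanced ON-OFF unit. Silent units
#' (no spikes in either phase) are undefined and returned as `NA`.
#'
#' @param psth matrix from [compute_psth()]
#' @return named numeric vector of fbr values (one per unit, `NA` if silent)
#' @export
compute_fbr <- function(psth) {
  m <- phase_masks(psth)
  f_on <- apply(psth[, m$on, drop = FALSE], 1, max)
  f_off <- apply(psth[, m$off, drop = FALSE], 1, max)
  out <- ifelse(f_on + f_off > 0, (f_on - f_off) / (f_on + f_off), NA_real_)
  names(out) <- rownames(psth)
  out
}

# index of the preferred phase: the phase containing the global PSTH peak
# (ties broken toward ON), per unit
preferred_phase <- function(psth) {
  m <- phase_masks(psth)
  p_on <- apply(psth[, m$on, drop = FALSE], 1, max)
  p_off <- apply(psth[, m$off, drop = FALSE], 1, max)
  ifelse(p_on >= p_off, "on", "off")
}

#' Sustain index
#'
#' `Si = (f_pref - fbar) / (f_pref + fbar)` with both terms expressed as
#' firing rates: `f_pref` is the peak trial-averaged PSTH rate in the
#' preferred phase (the phase holding the global PSTH peak, ties to ON) and
#' `fbar` is the mean rate over the entire flash sequence. A constant-rate
#' unit gives exactly 0 (pure sustained); a response concentrated in a single
#' bin approaches 1 (pure transient). Values below 0 (phase peak below the
#' overall mean) are possible and reported unclamped. Silent units are `NA`.
#'
#' @param psth matrix from [compute_psth()]
#' @param spikes the `spike_events` the PSTH was computed from (for the
#'   whole-sequence mean rate)
#' @return named numeric vector of sustain indices
#' @export
compute_sustain_index <- function(psth, spikes) {
  cfg <- attr(psth, "flash_cfg")
  m <- phase_masks(psth)
  pref <- preferred_phase(psth)
  f_pref <- vapply(seq_len(nrow(psth)), function(i) {
    mask <- if (pref[i] == "on") m$on else m$off
    max(psth[i, mask])
  }, numeric(1))
  total <- cfg$n_trials * (cfg$on_duration + cfg$off_duration)
  counts <- table(factor(spikes$unit_id, levels = rownames(psth)))
  fbar <- as.numeric(counts) / total
  out <- ifelse(f_pref + fbar > 0, (f_pref - fbar) / (f_pref + fbar), NA_real_)
  names(out) <- rownames(psth)
  out
}

#' Response latency
#'
#' Time from the onset of the preferred phase to the peak of the
#' trial-averaged PSTH, reported at the peak-bin centre; ties are broken to
#' the earliest bin. Flat (silent) PSTHs give `NA`.
#'
#' @param psth matrix from [compute_psth()]
#' @return named numeric vector of latencies in seconds
#' @export
compute_latency <- function(psth) {
  cfg <- attr(psth, "flash_cfg")
  centers <- attr(psth, "bin_centers")
  m <- phase_masks(psth)
  pref <- preferred_phase(psth)
  out <- vapply(seq_len(nrow(psth)), function(i) {
    mask <- if (pref[i] == "on") m$on else m$off
    onset <- if (pref[i] == "on") 0 else cfg$on_duration
    v <- psth[i, mask]
    if (max(v) <= 0) return(NA_real_)
    centers[mask][which.max(v)] - onset
  }, numeric(1))
  names(out) <- rownames(psth)
  out
}

#' Mean firing rate
#'
#' Total spike count divided by the total stimulus duration.
#'
#' @param spikes a `spike_events` data.frame
#' @param duration total stimulus duration in seconds
#' @param unit_ids units to report (default: roster or observed ids)
#' @return named numeric vector of rates in Hz
#' @export
compute_mean_rate <- function(spikes, duration, unit_ids = NULL) {
  stop_if_not(duration > 0, "duration must be positive")
  if (is.null(unit_ids)) {
    roster <- attr(spikes, "roster")
    unit_ids <- if (!is.null(roster)) roster$unit_id else sort(unique(spikes$unit_id))
  }
  counts <- table(factor(spikes$unit_id, levels = unit_ids))
  out <- as.numeric(counts) / duration
  names(out) <- unit_ids
  out
}

#' All flash physiology indices for a recording
#'
#' Convenience wrapper computing the PSTH and the four light-response
#' features (polarity bias, sustain index, latency, mean rate) for every
#' unit.
#'
#' @inheritParams compute_psth
#' @return data.frame of class `unit_physiology` with columns `unit_id`,
#'   `fbr`, `sustain_index`, `latency_s`, `mean_rate_hz`; the PSTH matrix is
#'   attached as an attribute
#' @export
light_features <- function(spikes, flash_cfg, bin = 0.05, unit_ids = NULL) {
  psth <- compute_psth(spikes, flash_cfg, bin = bin, unit_ids = unit_ids)
  total <- flash_cfg$n_trials * (flash_cfg$on_duration + flash_cfg$off_duration)
  out <- data.frame(
    unit_id = as.integer(rownames(psth)),
    fbr = unname(compute_fbr(psth)),
    sustain_index = unname(compute_sustain_index(psth, spikes)),
    latency_s = unname(compute_latency(psth)),
    mean_rate_hz = unname(compute_mean_rate(spikes, total,
                                            unit_ids = rownames(psth)))
  )
  class(out) <- c("unit_physiology", "data.frame")
  attr(out, "psth") <- psth
  out
}

#' Write physiology indices as CSV
#' @param physio a `unit_physiology` data.frame
#' @param path file path
#' @export
write_physiology_csv <- function(physio, path) {
  utils::write.csv(as.data.frame(physio), path, row.names = FALSE)
  invisible(path)
}
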