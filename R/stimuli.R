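#' Full-field flash stimulus configuration
#'
#' The default protocol is a 3-s ON / 3-s OFF full-field flash repeated for
#' 10 trials, the standard luminance-step protocol used to classify retinal
#' ganglion cells into ON / OFF / ON-OFF types.
#'
#' @param on_duration seconds of the ON phase (> 0)
#' @param off_duration seconds of the OFF phase (> 0)
#' @param n_trials number of ON/OFF repetitions (>= 1)
#' @param frame_rate display sampling rate in Hz
#' @param on_intensity,off_intensity normalized luminance in `[0, 1]`
#' @return a `flash_config` list
#' @export
flash_config <- function(on_duration = 3, off_duration = 3, n_trials = 10,
                         frame_rate = 60, on_intensity = 1, off_intensity = 0) {
  stop_if_not(on_duration > 0 && off_duration > 0,
              "flash phase durations must be positive")
  stop_if_not(n_trials >= 1, "n_trials must be >= 1")
  stop_if_not(frame_rate > 0, "frame_rate must be positive")
  structure(list(on_duration = on_duration, off_duration = off_duration,
                 n_trials = as.integer(n_trials), frame_rate = frame_rate,
                 on_intensity = on_intensity, off_intensity = off_intensity),
            class = "flash_config")
}

#' Moving-ball stimulus configuration
#'
#' A ball moving over a square pixel field along a fractional Brownian motion
#' (fBm) trajectory. The persistence of the motion is set by the Hurst
#' exponent (default 0.9, strongly persistent) and the increments are rescaled
#' so the realized mean speed matches `target_mean_speed` (default
#' 232 px/s).
#'
#' @param hurst Hurst exponent in (0, 1)
#' @param duration seconds per trial
#' @param n_trials repetitions of the same trajectory
#' @param frame_rate frames per second
#' @param field_size length-2 field size in pixels (x, y)
#' @param target_mean_speed mean frame-to-frame speed in px/s
#' @param ball_size ellipsoid axes in pixels (metadata only)
#' @param rng_seed integer seed controlling the trajectory
#' @return a `ball_config` list
#' @export
ball_config <- function(hurst = 0.9, duration = 20, n_trials = 10,
                        frame_rate = 60, field_size = c(400, 400),
                        target_mean_speed = 232, ball_size = c(28.0, 36.6),
                        rng_seed = 1L) {
  stop_if_not(hurst > 0 && hurst < 1, "hurst must be in (0, 1)")
  stop_if_not(duration > 0, "duration must be positive")
  stop_if_not(n_trials >= 1, "n_trials must be >= 1")
  structure(list(hurst = hurst, duration = duration,
                 n_trials = as.integer(n_trials), frame_rate = frame_rate,
                 field_size = field_size, target_mean_speed = target_mean_speed,
                 ball_size = ball_size, rng_seed = as.integer(rng_seed)),
            class = "ball_config")
}

#' Generate the full-field flash intensity trace
#'
#' @param config a [flash_config()]
#' @return a data.frame with columns `t_s`, `value`, carrying stimulus
#'   metadata as attributes (`stim_type`, `frame_rate`, `trial_duration`,
#'   `n_trials`, `config`)
#' @examples
#' tr <- generate_flash(flash_config())
#' nrow(tr)  # 60 s x 60 Hz = 3600 samples
#' @export
generate_flash <- function(config = flash_config()) {
  period <- config$on_duration + config$off_duration
  total <- config$n_trials * period
  n <- round(total * config$frame_rate)
  t <- (seq_len(n) - 1) / config$frame_rate
  phase <- t %% period
  value <- ifelse(phase < config$on_duration,
                  config$on_intensity, config$off_intensity)
  out <- data.frame(t_s = t, value = value)
  attr(out, "stim_type") <- "flash"
  attr(out, "frame_rate") <- config$frame_rate
  attr(out, "trial_duration") <- period
  attr(out, "n_trials") <- config$n_trials
  attr(out, "config") <- config
  out
}

# Exact synthesis of fractional Gaussian noise by circulant embedding
# (Davies-Harte). Returns n increments with unit variance and the fGn
# autocovariance for Hurst exponent H; O(n log n) via FFT.
fgn_davies_harte <- function(n, H) {
  k <- 0:n
  g <- 0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
  # first row of the 2n circulant embedding
  r <- c(g[1:n], g[n + 1], g[n:2][seq_len(n - 1)])
  lam <- Re(stats::fft(r))
  lam[lam < 0 & lam > -1e-8] <- 0
  stop_if_not(all(lam >= 0), "circulant embedding not nonnegative definite")
  m <- 2 * n
  w <- complex(length.out = m)
  w[1] <- sqrt(lam[1] / m) * stats::rnorm(1)
  w[n + 1] <- sqrt(lam[n + 1] / m) * stats::rnorm(1)
  a <- stats::rnorm(n - 1)
  b <- stats::rnorm(n - 1)
  w[2:n] <- sqrt(lam[2:n] / (2 * m)) * complex(real = a, imaginary = b)
  w[m:(n + 2)] <- Conj(w[2:n])
  Re(stats::fft(w))[1:n]
}

# Fold a coordinate into [lo, hi] with reflecting boundaries.
reflect_fold <- function(x, lo, hi) {
  r <- hi - lo
  y <- (x - lo) %% (2 * r)
  lo + ifelse(y > r, 2 * r - y, y)
}

#' Generate a moving-ball trajectory by fractional Brownian motion
#'
#' Two independent fBm paths (one per axis) are synthesized from exact
#' fractional Gaussian noise, their increments rescaled so the mean
#' frame-to-frame speed matches the configured target, and the path is kept
#' inside the field by reflecting at the borders. With `n_trials > 1` the same
#' trajectory is tiled so the returned trace covers the whole session.
#'
#' @param config a [ball_config()]
#' @return data.frame with columns `t_s`, `x_px`, `y_px`; attributes as in
#'   [generate_flash()], plus `realized_speed` (px/s, single trial, before
#'   tiling).
#' @export
generate_ball_trajectory <- function(config = ball_config()) {
  n_frames <- round(config$duration * config$frame_rate)
  stop_if_not(n_frames >= 3, "trajectory needs at least 3 frames")
  with_seed(config$rng_seed, {
    dx <- fgn_davies_harte(n_frames - 1, config$hurst)
    dy <- fgn_davies_harte(n_frames - 1, config$hurst)
  })
  step_target <- config$target_mean_speed / config$frame_rate
  sc <- step_target / mean(sqrt(dx^2 + dy^2))
  dx <- dx * sc
  dy <- dy * sc
  x_raw <- config$field_size[1] / 2 + cumsum(c(0, dx))
  y_raw <- config$field_size[2] / 2 + cumsum(c(0, dy))
  x <- reflect_fold(x_raw, 0, config$field_size[1])
  y <- reflect_fold(y_raw, 0, config$field_size[2])
  speed <- mean(sqrt(diff(x)^2 + diff(y)^2)) * config$frame_rate
  xs <- rep(x, config$n_trials)
  ys <- rep(y, config$n_trials)
  t <- (seq_along(xs) - 1) / config$frame_rate
  out <- data.frame(t_s = t, x_px = xs, y_px = ys)
  attr(out, "stim_type") <- "ball"
  attr(out, "frame_rate") <- config$frame_rate
  attr(out, "trial_duration") <- config$duration
  attr(out, "n_trials") <- config$n_trials
  attr(out, "realized_speed") <- speed
  attr(out, "config") <- config
  out
}

#' Rescaled-range (R/S) Hurst exponent estimate
#'
#' Corrected rescaled-range estimate of the Hurst exponent of an increment
#' series, computed with [pracma::hurstexp()]'s Anis-Lloyd/Peters
#' small-sample-corrected statistic (`Hal`), which removes the finite-size
#' bias of the naive R/S slope.
#'
#' @param x increment series (e.g. per-frame displacements on one axis)
#' @return estimated Hurst exponent (scalar)
#' @export
hurst_rs <- function(x) {
  stop_if_not(length(x) >= 32, "series too short for R/S estimation")
  pracma::hurstexp(x, display = FALSE)$Hal
}

#' Write / read a stimulus trace as CSV
#'
#' Columns are `t_s,value` for flash traces and `t_s,x_px,y_px` for ball
#' trajectories.
#' @param trace a stimulus trace data.frame
#' @param path file path
#' @return `read_stimulus_csv` returns the data.frame (without simulation
#'   metadata attributes)
#' @export
write_stimulus_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_csv
#' @export
read_stimulus_csv <- function(path) {
  utils::read.csv(path)
}
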