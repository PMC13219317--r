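fake_dec_set <- function(D_lists, t_outs) {
  recs <- lapply(seq_along(D_lists), function(i)
    list(D = D_lists[[i]], t_out = t_outs[[i]]))
  structure(recs, class = "decoder_attention_set",
            n_heads = length(D_lists[[1]]),
            n_latents = ncol(D_lists[[1]][[1]]))
}

test_that("decoder entropy hits its exact bounds and hand values", {
  L <- 64
  uniform <- matrix(1 / L, 2, L)
  one_hot <- matrix(0, 2, L); one_hot[, 5] <- 1
  half <- matrix(0, 2, L); half[, 1:2] <- 0.5
  ent <- decoder_entropy(fake_dec_set(list(list(uniform, one_hot, half)),
                                      list(c(0.5, 1))))
  expect_equal(ent$E_nats[ent$head == 1], rep(log(64), 2), tolerance = 1e-12)
  expect_equal(ent$E_nats[ent$head == 2], rep(0, 2))
  expect_equal(ent$E_nats[ent$head == 3], rep(log(2), 2), tolerance = 1e-12)
})

test_that("flash coupling recovers exact and null correlations", {
  stim <- generate_flash(flash_config())
  # entropy that is an affine function of -intensity: r = -1
  tt <- seq(0.05, 59.95, by = 0.1)
  intens <- stats::approx(stim$t_s, stim$value, xout = tt)$y
  ent <- data.frame(t_s = tt, head = 1, E_nats = 3 - 2 * intens)
  expect_equal(flash_coupling(ent, stim)$r, -1, tolerance = 1e-12)
  # independent white noise: |r| < 0.1 at n >= 1000
  set.seed(9)
  ent2 <- data.frame(t_s = rep(tt, 2), head = rep(1:2, each = length(tt)),
                     E_nats = rnorm(2 * length(tt)))
  r2 <- flash_coupling(ent2, stim)$r
  expect_true(all(abs(r2) < 0.1))
  # zero-variance entropy flagged
  flat <- data.frame(t_s = tt, head = 1, E_nats = 1)
  expect_warning(res <- flash_coupling(flat, stim), "zero-variance")
  expect_true(is.na(res$r))
})

test_that("directional decomposition rectifies displacements exactly", {
  tr <- data.frame(t_s = 0:2, x_px = c(0, 2, -1), y_px = c(0, -1, 3))
  d <- directional_decompose(tr)
  expect_equal(d$plus_x, c(2, 0))
  expect_equal(d$minus_x, c(0, 3))
  expect_equal(d$plus_y, c(0, 4))
  expect_equal(d$minus_y, c(1, 0))
  expect_true(all(d$plus_x >= 0 & d$minus_x >= 0))
  # identity on a generated trajectory
  ball <- generate_ball_trajectory(ball_config(duration = 5, n_trials = 1,
                                               rng_seed = 3))
  dd <- directional_decompose(ball)
  expect_equal(dd$plus_x - dd$minus_x, diff(ball$x_px), tolerance = 1e-12)
  expect_equal(dd$plus_y - dd$minus_y, diff(ball$y_px), tolerance = 1e-12)
  # strictly increasing x: -X identically zero
  mono <- data.frame(t_s = 0:5, x_px = 0:5, y_px = rep(1, 6))
  dm <- directional_decompose(mono)
  expect_true(all(dm$minus_x == 0))
  expect_error(directional_decompose(mono[1, ]), "2 frames")
  # position mode rectifies mean-centred coordinates
  dp <- directional_decompose(mono, mode = "position")
  expect_equal(dp$plus_x - dp$minus_x, mono$x_px - mean(mono$x_px))
})

test_that("directional coupling recovers planted couplings and nulls", {
  ball <- generate_ball_trajectory(ball_config(duration = 20, n_trials = 1,
                                               rng_seed = 4))
  d <- directional_decompose(ball)
  # head 1 entropy affine in -(+X): r(+X) = -1; head 2 coupled to -Y
  ent <- rbind(
    data.frame(t_s = d$t_s, head = 1, E_nats = 2 - 3 * d$plus_x),
    data.frame(t_s = d$t_s, head = 2, E_nats = 1 - 0.5 * d$minus_y)
  )
  cp <- directional_coupling(ent, d)
  expect_equal(cp$r[cp$head == 1 & cp$component == "+X"], -1,
               tolerance = 1e-10)
  h2 <- cp[cp$head == 2, ]
  expect_equal(h2$component[which.max(abs(h2$r))], "-Y")
  # independent entropy: all four |r| small at n >= 1000
  set.seed(10)
  ent0 <- data.frame(t_s = d$t_s, head = 1, E_nats = rnorm(nrow(d)))
  cp0 <- directional_coupling(ent0, d)
  expect_true(all(abs(cp0$r) < 0.1))
  # static axis flagged as constant
  flat <- d
  flat$plus_y <- 0
  expect_warning(directional_coupling(ent0, flat), "constant")
})

test_that("correlation agrees with the direct covariance formula", {
  set.seed(11)
  x <- rnorm(500)
  y <- 0.3 * x + rnorm(500)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(stats::cor(x, y), direct, tolerance = 1e-12)
})
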