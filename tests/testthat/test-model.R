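test_that("tokenization yields one token per spike with continuous times", {
  f <- fixtures()$flash
  win <- tokenize(f$spikes, 0, 1, f$pop$unit_id)
  n_in <- sum(f$spikes$time_s >= 0 & f$spikes$time_s < 1)
  expect_equal(win$n, n_in)
  expect_true(all(win$t_rel >= 0 & win$t_rel < 1))
  expect_true(!is.unsorted(win$t_rel))

  # two spikes of one unit at different times: same embedding row,
  # different time encoding
  enc <- retinattn:::time_encoding(c(0.2, 0.7), 16)
  expect_false(isTRUE(all.equal(enc[1, ], enc[2, ])))

  # unknown unit is rejected
  bad <- f$spikes
  bad$unit_id[1] <- 999L
  bad$time_s[1] <- 0.5
  expect_error(tokenize(bad, 0, 1, f$pop$unit_id), "roster")
})

test_that("forward pass has softmax rows and the documented shapes", {
  s <- tiny_model_setup()
  win <- s$wins[[1]]
  fw <- forward_window(s$model, win, capture = TRUE)
  H <- s$cfg$n_heads
  expect_length(fw$enc_attn, H)
  expect_length(fw$dec_attn, H)
  for (h in seq_len(H)) {
    A <- fw$enc_attn[[h]]
    D <- fw$dec_attn[[h]]
    expect_equal(dim(A), c(s$cfg$n_latents, win$n))
    expect_equal(dim(D), c(s$cfg$n_out_tokens, s$cfg$n_latents))
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-5)
    expect_equal(rowSums(D), rep(1, nrow(D)), tolerance = 1e-5)
  }
  expect_true(all(is.finite(fw$pred)))
  expect_equal(dim(fw$pred), c(s$cfg$n_out_tokens, 1))
})

test_that("predictions are invariant to spike-token order", {
  s <- tiny_model_setup()
  win <- s$wins[[2]]
  fw1 <- forward_window(s$model, win)
  perm <- sample(win$n)
  win2 <- win
  win2$unit_idx <- win$unit_idx[perm]
  win2$t_rel <- win$t_rel[perm]
  fw2 <- forward_window(s$model, win2)
  expect_equal(fw1$pred, fw2$pred, tolerance = 1e-10)
})

test_that("empty windows are rejected and skipped with a warning", {
  s <- tiny_model_setup()
  win <- s$wins[[1]]
  win$unit_idx <- integer(0)
  win$t_rel <- numeric(0)
  expect_error(forward_window(s$model, win), "empty")

  f <- fixtures()$flash
  sparse <- f$spikes[f$spikes$time_s < 2, ]
  class(sparse) <- c("spike_events", "data.frame")
  attr(sparse, "roster") <- f$pop
  expect_warning(make_windows(sparse, f$stim, s$cfg), "empty window")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  cfg <- model_config(latent_dim = 8L, n_latents = 3L, depth = 1L,
                      n_heads = 2L, head_dim = 4L, ffn_mult = 2L,
                      dropout = 0, n_out_tokens = 4L)
  model <- init_decoder(cfg, roster = 1:5, out_dim = 2, rng_seed = 3)
  win <- list(unit_idx = c(1L, 2L, 2L, 4L, 5L, 3L), t_rel = runif(6),
              t_start = 0, n = 6L, targets = matrix(rnorm(8), 4, 2),
              session_idx = 1L)
  lg <- retinattn:::window_loss_grad(model, win, train = TRUE)
  grads <- retinattn:::backward_window(model, lg$cache, lg$dpred, list())
  eps <- 1e-5
  for (k in names(model$params)) {
    pk <- model$params[[k]]
    probe <- sample(length(pk), min(length(pk), 4))
    for (i in probe) {
      m2 <- model
      m2$params[[k]][i] <- pk[i] + eps
      lp <- retinattn:::window_loss_grad(m2, win, train = FALSE)$loss
      m2$params[[k]][i] <- pk[i] - eps
      lm <- retinattn:::window_loss_grad(m2, win, train = FALSE)$loss
      num <- (lp - lm) / (2 * eps)
      ana <- if (is.null(grads[[k]])) 0 else grads[[k]][i]
      expect_equal(ana, num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", k, i))
    }
  }
})

test_that("model configs validate and expose both profiles", {
  paper <- model_config("paper")
  expect_equal(paper$latent_dim, 128L)
  expect_equal(paper$n_latents, 64L)
  expect_equal(paper$depth, 6L)
  expect_equal(paper$n_heads, 8L)
  expect_equal(paper$head_dim, 64L)
  expect_equal(paper$dropout, 0.3)
  scaled <- model_config()
  expect_equal(scaled$latent_dim, 64L)
  expect_error(model_config(latent_dim = 7L), "even")
  expect_error(model_config(bogus = 1), "unknown")
})
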