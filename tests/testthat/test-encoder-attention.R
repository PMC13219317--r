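# Hand-built attention sets for oracle checks ------------------------------

fake_attn_set <- function(A_lists, unit_ids, times = NULL, t_end = NULL) {
  recs <- lapply(seq_along(A_lists), function(i) {
    n <- ncol(A_lists[[i]][[1]])
    list(A = A_lists[[i]], unit_id = unit_ids[[i]],
         time_s = times[[i]] %||% seq(0, 1, length.out = n),
         t_end = t_end[[i]] %||% i, n = n)
  })
  structure(recs, class = "encoder_attention_set",
            n_heads = length(A_lists[[1]]),
            n_latents = nrow(A_lists[[1]][[1]]))
}

rand_row_stochastic <- function(L, n) {
  m <- matrix(stats::rexp(L * n), L, n)
  m / rowSums(m)
}

test_that("spike weights match brute-force column means and normalizations", {
  set.seed(4)
  L <- 4; n <- 5
  A <- rand_row_stochastic(L, n)
  attn <- fake_attn_set(list(list(A)), list(rep(1:5)))
  w <- spike_weights(attn)
  # oracle: direct summation over latent rows
  brute <- vapply(seq_len(n), function(k) sum(A[, k]) / L, numeric(1))
  expect_equal(as.vector(w[[1]]$wbar), brute, tolerance = 1e-12)
  expect_equal(sum(w[[1]]$wbar), 1, tolerance = 1e-10)
  expect_equal(mean(w[[1]]$what), 1, tolerance = 1e-10)

  # uniform attention: wbar = 1/N, what = 1
  Au <- matrix(1 / n, L, n)
  wu <- spike_weights(fake_attn_set(list(list(Au)), list(1:5)))
  expect_equal(as.vector(wu[[1]]$wbar), rep(1 / n, n))
  expect_equal(as.vector(wu[[1]]$what), rep(1, n))

  # all latents attend spike 3 only
  Ah <- matrix(0, L, n); Ah[, 3] <- 1
  wh <- spike_weights(fake_attn_set(list(list(Ah)), list(1:5)))
  expect_equal(as.vector(wh[[1]]$wbar), c(0, 0, 1, 0, 0))
  expect_equal(wh[[1]]$what[3], n)
})

test_that("attention entropy hits its exact bounds and hand values", {
  L <- 3
  one_hot <- matrix(0, L, 4); one_hot[, 2] <- 1
  uniform <- matrix(1 / 100, L, 100)
  mixed <- matrix(rep(c(0.5, 0.25, 0.25), each = L), L, 3)
  attn <- fake_attn_set(list(list(one_hot), list(uniform), list(mixed)),
                        list(1:4, 1:100, 1:3))
  ent <- encoder_entropy(spike_weights(attn))
  expect_equal(ent$E_nats[1], 0)
  expect_equal(ent$E_nats[2], log(100), tolerance = 1e-12)
  expect_equal(ent$E_nats[3], 1.0397, tolerance = 1e-4)  # -sum p ln p by hand
  # bounds 0 <= E <= ln N on random matrices
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:50, 1)
    A <- rand_row_stochastic(4, n)
    e <- encoder_entropy(spike_weights(fake_attn_set(list(list(A)),
                                                     list(seq_len(n)))))
    expect_true(all(e$E_nats >= 0 & e$E_nats <= log(n) + 1e-12))
  }
})

test_that("K-S head divergence separates distinct heads only", {
  set.seed(6)
  # two heads with identical entropy distributions vs one shifted
  ent <- data.frame(
    t_s = rep(1:100, 3),
    head = rep(1:3, each = 100),
    E_nats = c(rnorm(100), rnorm(100, 5), rnorm(100))
  )
  div <- head_divergence(ent)
  expect_true(is.na(div$D[1, 1]))
  expect_equal(div$D, t(div$D))
  expect_lt(div$p[1, 2], 1e-9)         # N(0,1) vs N(5,1), n = 100
  expect_gt(div$p[1, 3], 0.05)         # same distribution
  expect_true(all(div$p_bonferroni >= div$p, na.rm = TRUE))
  # identical samples: D = 0, p = 1
  same <- data.frame(t_s = rep(1:3, 2), head = rep(1:2, each = 3),
                     E_nats = rep(c(1, 2, 3), 2))
  div2 <- head_divergence(same)
  expect_equal(div2$D[1, 2], 0)
  expect_equal(div2$p[1, 2], 1)
})

test_that("unit importance matches the hand-worked toy and brute force", {
  toy <- fixtures()$toy_weights
  imp <- unit_importance(toy)
  expect_equal(imp$importance[imp$unit_id == 1], 0.4)
  expect_equal(imp$importance[imp$unit_id == 2], 0.2)
  expect_equal(imp$rank[imp$unit_id == 1], 1)

  # brute-force oracle on a 3-unit, 2-head, 2-window toy: direct triple sum
  set.seed(7)
  units_w1 <- c(1, 1, 2, 3)
  units_w2 <- c(2, 3, 3)
  A1 <- list(rand_row_stochastic(3, 4), rand_row_stochastic(3, 4))
  A2 <- list(rand_row_stochastic(3, 3), rand_row_stochastic(3, 3))
  attn <- fake_attn_set(list(A1, A2), list(units_w1, units_w2))
  w <- spike_weights(attn)
  imp2 <- unit_importance(w)
  brute <- function(u) {
    per_win <- c()
    for (wi in list(list(A = A1, units = units_w1),
                    list(A = A2, units = units_w2))) {
      ks <- which(wi$units == u)
      if (!length(ks)) next
      per_head <- vapply(wi$A, function(A)
        mean(colMeans(A)[ks]), numeric(1))
      per_win <- c(per_win, mean(per_head))
    }
    mean(per_win)
  }
  for (u in 1:3)
    expect_equal(imp2$importance[imp2$unit_id == u], brute(u),
                 tolerance = 1e-12)

  # uniform attention: equally active units share identical importance
  Au <- matrix(1 / 4, 3, 4)
  wu <- spike_weights(fake_attn_set(list(list(Au)), list(c(1, 1, 2, 2))))
  iu <- unit_importance(wu)
  expect_equal(iu$importance[1], iu$importance[2])

  # a unit hogging all attention in every window ranks first
  Ah <- matrix(0, 3, 4); Ah[, 1] <- 0.97; Ah[, -1] <- 0.01
  wh <- spike_weights(fake_attn_set(list(list(Ah)), list(c(9, 1, 1, 2))))
  ih <- unit_importance(wh)
  expect_equal(ih$unit_id[1], 9)
})

test_that("importance is independent of a unit's total firing rate", {
  # two units receiving identical per-spike attention get identical I(u)
  # even when one fires twice as often: the score is a per-spike average
  A <- matrix(rep(c(0.2, 0.2, 0.2, 0.2, 0.2), each = 3), 3, 5)
  w <- spike_weights(fake_attn_set(list(list(A)), list(c(1, 1, 1, 2, 2))))
  i <- unit_importance(w)
  expect_equal(i$importance[i$unit_id == 1], i$importance[i$unit_id == 2],
               tolerance = 1e-12)
  expect_equal(i$n_spikes[i$unit_id == 1], 3)
  # scaling the number of spikes with attention mass held per-spike across
  # two windows: averages across windows are unchanged
  A1 <- matrix(rep(c(0.5, 0.5), each = 2), 2, 2)        # 2 spikes of unit 1
  A2 <- matrix(rep(rep(0.25, 4), each = 2), 2, 4)       # 4 spikes of unit 1
  wd <- spike_weights(fake_attn_set(list(list(A1), list(A2)),
                                    list(c(1, 1), c(1, 1, 1, 1))))
  id <- unit_importance(wd)
  # per-window per-spike means are 0.5 and 0.25; I(u) is their average and
  # equals the brute-force triple-sum evaluation
  expect_equal(id$importance[1], mean(c(0.5, 0.25)), tolerance = 1e-12)
})

test_that("top-K extraction follows the first-crossing rule", {
  curve <- data.frame(n_removed = 1:4, r2 = c(0.9, 0.6, 0.45, 0.2))
  expect_equal(topk_at_threshold(curve)$K, 3)
  high <- data.frame(n_removed = 0:3, r2 = c(0.9, 0.8, 0.7, 0.6))
  res <- topk_at_threshold(high, n_units = 40)
  expect_equal(res$K, 40)
  expect_false(res$crossed)
  low <- data.frame(n_removed = 0:2, r2 = c(0.4, 0.3, 0.2))
  res2 <- topk_at_threshold(low)
  expect_equal(res2$K, 0)
  expect_true(res2$crossed)
})

test_that("consensus keeps units present in at least half the seeds", {
  lists <- list(c(1, 2, 3), c(1, 2, 4), c(1, 5, 6), c(1, 2, 7),
                c(8, 9, 10), c(11, 12, 13), c(14, 15, 16), c(17, 18, 19))
  cons <- consensus_units(lists)          # 8 seeds, need >= 4
  expect_true(1 %in% cons$unit_id)        # in 4 of 8: included
  expect_false(2 %in% cons$unit_id)       # in 3 of 8: excluded
  ident <- consensus_units(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_setequal(ident$unit_id, c(1, 2))
  expect_warning(consensus_units(list(1, 2, 3, 4)), "empty")
  expect_error(consensus_units(list(1)), "two seeds")
})

test_that("physiological K-S comparison behaves at both extremes", {
  set.seed(8)
  n <- 120
  physio <- data.frame(
    unit_id = 1:n,
    fbr = runif(n, -1, 1),
    sustain_index = runif(n),
    latency_s = runif(n, 0, 0.3),
    mean_rate_hz = c(rlnorm(n / 2, log(3), 0.3), rlnorm(n / 2, log(15), 0.3))
  )
  # subset == population: D = 0, p = 1 everywhere
  all_cmp <- compare_physiology(physio, physio$unit_id)
  expect_true(all(all_cmp$tests$D == 0))
  expect_true(all(all_cmp$tests$p == 1))
  # planted high-rate subset differs in firing rate
  high <- compare_physiology(physio, (n / 2 + 1):n)
  rate_row <- high$tests[high$tests$feature == "mean_rate_hz", ]
  expect_lt(rate_row$p, 0.05)
  # two hand-listed identical samples: D = 0
  tiny <- data.frame(unit_id = 1:2, fbr = c(0, 1), sustain_index = c(0, 1),
                     latency_s = c(0, 1), mean_rate_hz = c(0, 1))
  expect_warning(res <- compare_physiology(tiny, 1:2), "smaller than 5")
  expect_true(all(res$tests$D == 0))
  # KDE grids returned on request
  kd <- compare_physiology(physio, 1:20, kde = TRUE)
  expect_named(kd$kde, c("sustain_index", "latency_s", "mean_rate_hz"))
  expect_equal(dim(kd$kde$latency_s$z), c(50, 50))
})
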