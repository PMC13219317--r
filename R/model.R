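#' Model architecture configuration
#'
#' Architecture of the spike-tokenized latent-attention encoder--decoder:
#' spikes in a 1-s context window become tokens (unit embedding + sinusoidal
#' encoding of continuous spike time), a cross-attention block compresses them
#' into `n_latents` latent tokens, a stack of `depth` self-attention blocks
#' refines the latents, and a decoder cross-attention block queries them from
#' `n_out_tokens` output-timestamp tokens that an MLP head maps to the
#' stimulus features.
#'
#' Two profiles are provided: `"scaled"` (the default desk-scale profile:
#' latent dimension 64, 32 latents, depth 2, 4 heads, dropout 0.1) and
#' `"paper"` (latent dimension 128, 64 latents, depth 6, 8 heads of head
#' dimension 64, dropout 0.3).
#'
#' @param profile `"scaled"` or `"paper"`
#' @param ... overrides for individual fields (`latent_dim`, `n_latents`,
#'   `depth`, `n_heads`, `head_dim`, `ffn_mult`, `dropout`,
#'   `context_window`, `n_out_tokens`)
#' @return a `model_config` list
#' @export
model_config <- function(profile = c("scaled", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "paper") {
    list(latent_dim = 128L, n_latents = 64L, depth = 6L, n_heads = 8L,
         head_dim = 64L, ffn_mult = 4L, dropout = 0.3,
         context_window = 1, n_out_tokens = 30L)
  } else {
    list(latent_dim = 64L, n_latents = 32L, depth = 2L, n_heads = 4L,
         head_dim = 16L, ffn_mult = 2L, dropout = 0.1,
         context_window = 1, n_out_tokens = 30L)
  }
  dots <- list(...)
  stop_if_not(all(names(dots) %in% names(cfg)),
              "unknown model_config field in ...")
  cfg[names(dots)] <- dots
  stop_if_not(cfg$latent_dim %% 2 == 0, "latent_dim must be even")
  stop_if_not(all(unlist(cfg[c("latent_dim", "n_latents", "depth", "n_heads",
                               "head_dim", "ffn_mult", "n_out_tokens")]) > 0) ||
                cfg$depth >= 0, "config fields must be positive")
  cfg$profile <- profile
  structure(cfg, class = "model_config")
}

# Sinusoidal encoding of continuous within-window time (t in [0, 1)).
# Frequencies span half a cycle per window down to ~8 ms resolution so that
# sub-bin spike timing stays distinguishable.
time_encoding <- function(t_rel, d) {
  nf <- d / 2
  freqs <- 2^seq(log2(0.5), log2(64), length.out = nf)
  ang <- 2 * pi * outer(t_rel, freqs)
  enc <- matrix(0, length(t_rel), d)
  enc[, seq(1, d, by = 2)] <- sin(ang)
  enc[, seq(2, d, by = 2)] <- cos(ang)
  enc
}

# Gaussian-error linear unit and row softmax -------------------------------

gelu <- function(x) x * stats::pnorm(x)

softmax_rows <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)      # length-nrow vector recycles along rows
  e / rowSums(e)
}

# parameter initialization --------------------------------------------------

rand_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

attn_params <- function(d, inner, hd, prefix, cross) {
  p <- list()
  p[[paste0(prefix, ".lnq_g")]] <- rep(1, d)
  p[[paste0(prefix, ".lnq_b")]] <- rep(0, d)
  if (cross) {
    p[[paste0(prefix, ".lnkv_g")]] <- rep(1, d)
    p[[paste0(prefix, ".lnkv_b")]] <- rep(0, d)
  }
  p[[paste0(prefix, ".Wq")]] <- rand_mat(d, inner, 1 / sqrt(d))
  p[[paste0(prefix, ".Wk")]] <- rand_mat(d, inner, 1 / sqrt(d))
  p[[paste0(prefix, ".Wv")]] <- rand_mat(d, inner, 1 / sqrt(d))
  p[[paste0(prefix, ".Wo")]] <- rand_mat(inner, d, 0.5 / sqrt(inner))
  p[[paste0(prefix, ".ln2_g")]] <- rep(1, d)
  p[[paste0(prefix, ".ln2_b")]] <- rep(0, d)
  p[[paste0(prefix, ".W1")]] <- rand_mat(d, hd, 1 / sqrt(d))
  p[[paste0(prefix, ".b1")]] <- rep(0, hd)
  p[[paste0(prefix, ".W2")]] <- rand_mat(hd, d, 0.5 / sqrt(hd))
  p[[paste0(prefix, ".b2")]] <- rep(0, d)
  p
}

#' Initialize a spike decoder
#'
#' @param cfg a [model_config()]
#' @param roster `unit_roster` (or vector of unit ids) defining the unit
#'   embedding table
#' @param sessions character vector of session ids
#' @param out_dim output dimensionality (1 for flash intensity, 2 for ball
#'   x/y)
#' @param rng_seed integer seed for weight initialization
#' @return a `spike_decoder` object (untrained)
#' @export
init_decoder <- function(cfg, roster, sessions = "S1", out_dim = 1,
                         rng_seed = 1L) {
  unit_ids <- if (is.data.frame(roster)) roster$unit_id else roster
  d <- cfg$latent_dim
  inner <- cfg$n_heads * cfg$head_dim
  hd <- cfg$ffn_mult * d
  params <- with_seed(rng_seed, {
    p <- list(
      U = rand_mat(length(unit_ids), d, 0.5),
      S = rand_mat(length(sessions), d, 0.5),
      Z0 = rand_mat(cfg$n_latents, d, 1)
    )
    p <- c(p, attn_params(d, inner, hd, "enc", cross = TRUE))
    for (t in seq_len(cfg$depth))
      p <- c(p, attn_params(d, inner, hd, paste0("self", t), cross = FALSE))
    p <- c(p, attn_params(d, inner, hd, "dec", cross = TRUE))
    p$head.ln_g <- rep(1, d)
    p$head.ln_b <- rep(0, d)
    p$head.W1 <- rand_mat(d, d, 1 / sqrt(d))
    p$head.b1 <- rep(0, d)
    p$head.W2 <- rand_mat(d, out_dim, 1 / sqrt(d))
    p$head.b2 <- rep(0, out_dim)
    p
  })
  structure(list(params = params, cfg = cfg,
                 unit_ids = unit_ids, sessions = sessions,
                 out_dim = out_dim,
                 target_center = rep(0, out_dim),
                 target_scale = rep(1, out_dim),
                 rng_seed = as.integer(rng_seed)),
            class = "spike_decoder")
}

# layer building blocks ------------------------------------------------------

ln_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  istd <- 1 / sqrt(rowMeans(xc^2) + 1e-5)
  xh <- xc * istd
  y <- sweep(xh, 2, g, "*")
  y <- sweep(y, 2, b, "+")
  list(y = y, xh = xh, istd = istd, g = g)
}

ln_bwd <- function(dy, c) {
  dg <- colSums(dy * c$xh)
  db <- colSums(dy)
  dxh <- sweep(dy, 2, c$g, "*")
  m1 <- rowMeans(dxh)
  m2 <- rowMeans(dxh * c$xh)
  dx <- (dxh - m1 - c$xh * m2) * c$istd
  list(dx = dx, dg = dg, db = db)
}

mha_fwd <- function(Q, K, V, H, dh) {
  scale <- 1 / sqrt(dh)
  O <- matrix(0, nrow(Q), ncol(Q))
  A <- vector("list", H)
  for (h in seq_len(H)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    A[[h]] <- softmax_rows(tcrossprod(Q[, idx, drop = FALSE],
                                      K[, idx, drop = FALSE]) * scale)
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  list(O = O, A = A)
}

mha_bwd <- function(dO, Q, K, V, A, H, dh) {
  scale <- 1 / sqrt(dh)
  dQ <- matrix(0, nrow(Q), ncol(Q))
  dK <- matrix(0, nrow(K), ncol(K))
  dV <- matrix(0, nrow(V), ncol(V))
  for (h in seq_len(H)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    dOh <- dO[, idx, drop = FALSE]
    Ah <- A[[h]]
    dV[, idx] <- crossprod(Ah, dOh)
    dA <- tcrossprod(dOh, V[, idx, drop = FALSE])
    dS <- Ah * (dA - rowSums(Ah * dA))
    dQ[, idx] <- dS %*% K[, idx, drop = FALSE] * scale
    dK[, idx] <- crossprod(dS, Q[, idx, drop = FALSE]) * scale
  }
  list(dQ = dQ, dK = dK, dV = dV)
}

drop_mask <- function(nr, nc, p) {
  if (p <= 0) NULL
  else matrix(stats::rbinom(nr * nc, 1, 1 - p) / (1 - p), nr, nc)
}

# Attention + FFN block. `Xq` provides the queries; `Xkv` the keys/values
# (for self-attention Xkv is NULL and queries/keys/values share one
# normalization of Xq). Returns the block output, the per-head attention
# matrices, and (if keep) the cache for backprop.
block_fwd <- function(p, prefix, Xq, Xkv, cfg, train = FALSE, keep = FALSE) {
  g <- function(nm) p[[paste0(prefix, ".", nm)]]
  cross <- !is.null(Xkv)
  c1 <- ln_fwd(Xq, g("lnq_g"), g("lnq_b"))
  c2 <- if (cross) ln_fwd(Xkv, g("lnkv_g"), g("lnkv_b")) else c1
  Q <- c1$y %*% g("Wq")
  K <- c2$y %*% g("Wk")
  V <- c2$y %*% g("Wv")
  mh <- mha_fwd(Q, K, V, cfg$n_heads, cfg$head_dim)
  B <- mh$O %*% g("Wo")
  mb <- if (train) drop_mask(nrow(B), ncol(B), cfg$dropout) else NULL
  if (!is.null(mb)) B <- B * mb
  X1 <- Xq + B
  c3 <- ln_fwd(X1, g("ln2_g"), g("ln2_b"))
  Hpre <- sweep(c3$y %*% g("W1"), 2, g("b1"), "+")
  Pn <- stats::pnorm(Hpre)
  G <- Hpre * Pn
  mf <- if (train) drop_mask(nrow(G), ncol(G), cfg$dropout) else NULL
  Gd <- if (!is.null(mf)) G * mf else G
  Fo <- sweep(Gd %*% g("W2"), 2, g("b2"), "+")
  out <- X1 + Fo
  cache <- NULL
  if (keep) cache <- list(c1 = c1, c2 = c2, Q = Q, K = K, V = V, mh = mh,
                          mb = mb, X1 = X1, c3 = c3, Hpre = Hpre, Pn = Pn,
                          G = G, mf = mf, Gd = Gd, cross = cross)
  list(out = out, A = mh$A, cache = cache)
}

block_bwd <- function(p, prefix, dout, cache, cfg, grads) {
  g <- function(nm) p[[paste0(prefix, ".", nm)]]
  nm <- function(x) paste0(prefix, ".", x)
  add <- function(key, val) {
    grads[[key]] <<- if (is.null(grads[[key]])) val else grads[[key]] + val
  }
  # FFN
  dFo <- dout
  add(nm("b2"), colSums(dFo))
  add(nm("W2"), crossprod(cache$Gd, dFo))
  dGd <- tcrossprod(dFo, g("W2"))
  dG <- if (!is.null(cache$mf)) dGd * cache$mf else dGd
  dHpre <- dG * (cache$Pn + cache$Hpre * stats::dnorm(cache$Hpre))
  add(nm("b1"), colSums(dHpre))
  add(nm("W1"), crossprod(cache$c3$y, dHpre))
  dc3y <- tcrossprod(dHpre, g("W1"))
  l3 <- ln_bwd(dc3y, cache$c3)
  add(nm("ln2_g"), l3$dg)
  add(nm("ln2_b"), l3$db)
  dX1 <- dout + l3$dx
  # attention branch
  dB <- if (!is.null(cache$mb)) dX1 * cache$mb else dX1
  add(nm("Wo"), crossprod(cache$mh$O, dB))
  dO <- tcrossprod(dB, g("Wo"))
  mm <- mha_bwd(dO, cache$Q, cache$K, cache$V, cache$mh$A,
                cfg$n_heads, cfg$head_dim)
  add(nm("Wq"), crossprod(cache$c1$y, mm$dQ))
  add(nm("Wk"), crossprod(cache$c2$y, mm$dK))
  add(nm("Wv"), crossprod(cache$c2$y, mm$dV))
  dc1y <- tcrossprod(mm$dQ, g("Wq"))
  dc2y <- tcrossprod(mm$dK, g("Wk")) + tcrossprod(mm$dV, g("Wv"))
  if (cache$cross) {
    l1 <- ln_bwd(dc1y, cache$c1)
    l2 <- ln_bwd(dc2y, cache$c2)
    add(nm("lnq_g"), l1$dg)
    add(nm("lnq_b"), l1$db)
    add(nm("lnkv_g"), l2$dg)
    add(nm("lnkv_b"), l2$db)
    dXq <- dX1 + l1$dx
    dXkv <- l2$dx
  } else {
    l1 <- ln_bwd(dc1y + dc2y, cache$c1)
    add(nm("lnq_g"), l1$dg)
    add(nm("lnq_b"), l1$db)
    dXq <- dX1 + l1$dx
    dXkv <- NULL
  }
  list(dXq = dXq, dXkv = dXkv, grads = grads)
}

#' Forward pass on one context window
#'
#' Runs the encoder--decoder on the spike tokens of a single 1-s context
#' window and returns predictions on the output grid; optionally captures the
#' post-softmax encoder attention matrices `A_h` (`n_latents x N` per head)
#' and decoder attention matrices `D_h` (`n_out_tokens x n_latents`),
#' evaluated without dropout.
#'
#' @param model a `spike_decoder`
#' @param window a context window from [make_windows()] (needs `unit_idx`,
#'   `t_rel`, and optionally `session_idx`)
#' @param capture logical; also return attention matrices
#' @param train logical; apply dropout and keep the backprop cache
#' @return list with `pred` (`n_out_tokens x out_dim`, on the original target
#'   scale unless `train`), and `enc_attn` / `dec_attn` lists when `capture`
#' @export
forward_window <- function(model, window, capture = FALSE, train = FALSE) {
  p <- model$params
  cfg <- model$cfg
  d <- cfg$latent_dim
  n <- length(window$unit_idx)
  stop_if_not(n > 0, "empty window: no spike tokens")
  stop_if_not(all(window$unit_idx >= 1 & window$unit_idx <= nrow(p$U)),
              "unknown unit index in window")
  X <- p$U[window$unit_idx, , drop = FALSE] + time_encoding(window$t_rel, d)
  enc <- block_fwd(p, "enc", p$Z0, X, cfg, train = train, keep = train)
  Z <- enc$out
  selfs <- vector("list", cfg$depth)
  for (t in seq_len(cfg$depth)) {
    sb <- block_fwd(p, paste0("self", t), Z, NULL, cfg,
                    train = train, keep = train)
    selfs[[t]] <- sb
    Z <- sb$out
  }
  m <- cfg$n_out_tokens
  t_out <- (seq_len(m) - 0.5) / m
  sess <- window$session_idx %||% 1L
  Y0 <- time_encoding(t_out, d) +
    matrix(p$S[sess, ], m, d, byrow = TRUE)
  dec <- block_fwd(p, "dec", Y0, Z, cfg, train = train, keep = train)
  ch <- ln_fwd(dec$out, p$head.ln_g, p$head.ln_b)
  Hpre <- sweep(ch$y %*% p$head.W1, 2, p$head.b1, "+")
  Pn <- stats::pnorm(Hpre)
  G <- Hpre * Pn
  pred <- sweep(G %*% p$head.W2, 2, p$head.b2, "+")
  out <- list(pred_scaled = pred,
              pred = sweep(sweep(pred, 2, model$target_scale, "*"),
                           2, model$target_center, "+"),
              t_out = window$t_start + t_out * cfg$context_window)
  if (capture) {
    out$enc_attn <- enc$A
    out$dec_attn <- dec$A
  }
  if (train) {
    out$cache <- list(X = X, enc = enc$cache, selfs = lapply(selfs, `[[`, "cache"),
                      Y0 = Y0, dec = dec$cache, ch = ch, Hpre = Hpre, Pn = Pn,
                      G = G, sess = sess, unit_idx = window$unit_idx)
  }
  out
}

# Backward pass for one window given d(loss)/d(pred_scaled); accumulates into
# `grads` (a named list paralleling params).
backward_window <- function(model, cache, dpred, grads) {
  p <- model$params
  cfg <- model$cfg
  add <- function(key, val) {
    grads[[key]] <- if (is.null(grads[[key]])) val else grads[[key]] + val
    grads
  }
  grads <- add("head.b2", colSums(dpred))
  grads <- add("head.W2", crossprod(cache$G, dpred))
  dG <- tcrossprod(dpred, p$head.W2)
  dHpre <- dG * (cache$Pn + cache$Hpre * stats::dnorm(cache$Hpre))
  grads <- add("head.b1", colSums(dHpre))
  grads <- add("head.W1", crossprod(cache$ch$y, dHpre))
  lh <- ln_bwd(tcrossprod(dHpre, p$head.W1), cache$ch)
  grads <- add("head.ln_g", lh$dg)
  grads <- add("head.ln_b", lh$db)
  bd <- block_bwd(p, "dec", lh$dx, cache$dec, cfg, grads)
  grads <- bd$grads
  # decoder queries: session embedding (time encoding is fixed)
  gS <- grads$S %||% matrix(0, nrow(p$S), ncol(p$S))
  gS[cache$sess, ] <- gS[cache$sess, ] + colSums(bd$dXq)
  grads$S <- gS
  dZ <- bd$dXkv
  for (t in rev(seq_len(cfg$depth))) {
    sb <- block_bwd(p, paste0("self", t), dZ, cache$selfs[[t]], cfg, grads)
    grads <- sb$grads
    dZ <- sb$dXq
  }
  be <- block_bwd(p, "enc", dZ, cache$enc, cfg, grads)
  grads <- be$grads
  grads <- add("Z0", be$dXq)
  dX <- be$dXkv
  gU <- grads$U %||% matrix(0, nrow(p$U), ncol(p$U))
  agg <- rowsum(dX, group = cache$unit_idx)
  rows <- as.integer(rownames(agg))
  gU[rows, ] <- gU[rows, ] + agg
  grads$U <- gU
  grads
}
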