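#' Training configuration
#'
#' AdamW on mean-squared error with the learning rate decayed by a factor of
#' 10 across the final 25% of epochs; 70/10/20 train/validation/test split on
#' non-overlapping temporal blocks.
#'
#' @param epochs training epochs (100 for single sessions at paper scale)
#' @param batch_size windows per gradient step
#' @param lr initial learning rate
#' @param weight_decay decoupled weight decay (weight matrices only)
#' @param split train/validation/test fractions, must sum to 1
#' @param rng_seed seed for initialization, dropout and batch order
#' @return a `train_config` list
#' @export
train_config <- function(epochs = 30, batch_size = 16, lr = 1e-4,
                         weight_decay = 1e-2, split = c(0.7, 0.1, 0.2),
                         rng_seed = 1L) {
  stop_if_not(abs(sum(split) - 1) < 1e-8, "split fractions must sum to 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, split = split,
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Tokenize spikes falling into one context window
#'
#' One token per spike event: the unit-embedding index plus the continuous
#' spike time relative to the window start. Token count equals spike count.
#'
#' @param spikes `spike_events` data.frame
#' @param t_start window start (s)
#' @param width window width (s)
#' @param unit_ids roster ids defining the embedding row for each unit
#' @return list with `unit_idx`, `t_rel` (in `[0,1)`), `unit_id`, `time_s`,
#'   `t_start`, `n`
#' @export
tokenize <- function(spikes, t_start, width = 1, unit_ids) {
  sel <- spikes$time_s >= t_start & spikes$time_s < t_start + width
  uid <- spikes$unit_id[sel]
  idx <- match(uid, unit_ids)
  stop_if_not(!anyNA(idx), "spike from a unit not in the roster")
  tt <- spikes$time_s[sel]
  ord <- order(tt)
  list(unit_idx = idx[ord], t_rel = (tt[ord] - t_start) / width,
       unit_id = uid[ord], time_s = tt[ord], t_start = t_start,
       n = length(ord))
}

#' Cut a recording into non-overlapping context windows with targets
#'
#' Windows tile the recording with stride equal to the window length.
#' Targets are the stimulus features sampled (by linear interpolation) at
#' `n_out_tokens` timestamps per window. Windows without spikes are dropped
#' with a warning.
#'
#' @param spikes `spike_events`
#' @param stimulus stimulus trace ([generate_flash()] /
#'   [generate_ball_trajectory()])
#' @param cfg [model_config()] (window length and output grid)
#' @param unit_ids roster ids (default: the roster attached to `spikes`)
#' @param session_idx session embedding row for these windows
#' @return list of windows; each has token fields plus `targets`
#'   (`n_out_tokens x out_dim`)
#' @export
make_windows <- function(spikes, stimulus, cfg, unit_ids = NULL,
                         session_idx = 1L) {
  if (is.null(unit_ids)) unit_ids <- attr(spikes, "roster")$unit_id
  stop_if_not(!is.null(unit_ids), "unit_ids required (no roster attached)")
  total <- max(stimulus$t_s) + 1 / attr(stimulus, "frame_rate")
  w <- cfg$context_window
  starts <- seq(0, total - w + 1e-9, by = w)
  ycols <- setdiff(names(stimulus), "t_s")
  out <- list()
  dropped <- 0
  for (s in starts) {
    win <- tokenize(spikes, s, w, unit_ids)
    if (win$n == 0) { dropped <- dropped + 1; next }
    t_out <- s + (seq_len(cfg$n_out_tokens) - 0.5) / cfg$n_out_tokens * w
    targ <- vapply(ycols, function(cl)
      stats::approx(stimulus$t_s, stimulus[[cl]], xout = t_out, rule = 2)$y,
      numeric(cfg$n_out_tokens))
    win$targets <- matrix(targ, nrow = cfg$n_out_tokens)
    win$session_idx <- session_idx
    out[[length(out) + 1]] <- win
  }
  if (dropped > 0)
    warning(dropped, " empty window(s) skipped")
  out
}

#' Split windows into train/validation/test by temporal blocks
#'
#' The window sequence is cut into 10 contiguous temporal blocks which are
#' assigned 7/1/2 to train/validation/test in a fixed interleaved pattern, so
#' every split sees all stimulus phases and no context window spans a split
#' boundary.
#'
#' @param n_windows number of windows
#' @param split fractions (currently the canonical 0.7/0.1/0.2 pattern)
#' @return list of index vectors `train`, `val`, `test`
#' @export
split_windows <- function(n_windows, split = c(0.7, 0.1, 0.2)) {
  stop_if_not(n_windows >= 10, "need at least 10 windows to split")
  pattern <- c("train", "train", "train", "val", "train",
               "train", "test", "train", "train", "test")
  block <- pmin(floor((seq_len(n_windows) - 1) / (n_windows / 10)) + 1, 10)
  lab <- pattern[block]
  list(train = which(lab == "train"), val = which(lab == "val"),
       test = which(lab == "test"))
}

# flat-parameter helpers -----------------------------------------------------

zero_like <- function(params) lapply(params, function(x) x * 0)

# decoupled weight decay applies to weight matrices but not to embeddings,
# latents, layer-norm parameters or biases
wd_mask <- function(params) {
  nms <- names(params)
  vapply(seq_along(params), function(i) {
    is.matrix(params[[i]]) && !(nms[i] %in% c("U", "S", "Z0"))
  }, logical(1))
}

adamw_step <- function(params, grads, state, lr, wd, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  decay <- wd_mask(params)
  for (k in names(params)) {
    gk <- grads[[k]]
    if (is.null(gk)) next
    state$m[[k]] <- 0.9 * state$m[[k]] + 0.1 * gk
    state$v[[k]] <- 0.999 * state$v[[k]] + 0.001 * gk^2
    upd <- (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
    params[[k]] <- params[[k]] - lr * upd -
      (if (decay[[match(k, names(params))]]) lr * wd * params[[k]] else 0)
  }
  list(params = params, state = state)
}

lr_at_epoch <- function(ep, epochs, lr0) {
  decay_start <- ceiling(0.75 * epochs)
  if (ep <= decay_start || epochs == decay_start) return(lr0)
  frac <- (ep - decay_start) / (epochs - decay_start)
  lr0 * 0.1^frac
}

window_loss_grad <- function(model, win, train = TRUE) {
  fw <- forward_window(model, win, train = train)
  targ <- sweep(sweep(win$targets, 2, model$target_center, "-"),
                2, model$target_scale, "/")
  err <- fw$pred_scaled - targ
  loss <- mean(err^2)
  list(loss = loss, dpred = 2 * err / length(err), cache = fw$cache)
}

#' Train a spike decoder
#'
#' Minimizes the mean squared error between the reconstructed and true
#' stimulus with AdamW, tracking train/validation losses per epoch and
#' keeping the parameters of the best validation epoch. Targets are
#' standardized internally using training-split statistics; predictions are
#' returned on the original scale. Aborts on non-finite loss.
#'
#' @param model an initialized (or pretrained) `spike_decoder`
#' @param windows list from [make_windows()]
#' @param tcfg a [train_config()]
#' @param split index list from [split_windows()] (computed if `NULL`)
#' @param trainable optional character vector restricting updates to matching
#'   parameter names (e.g. `c("U", "S")` to fine-tune embeddings only)
#' @param verbose print per-epoch progress
#' @return the trained `spike_decoder`, with a `curve` data.frame
#'   (`epoch, lr, train_loss, val_loss`) and the `split` attached
#' @export
train_decoder <- function(model, windows, tcfg = train_config(),
                          split = NULL, trainable = NULL, verbose = FALSE) {
  if (is.null(split)) split <- split_windows(length(windows), tcfg$split)
  stop_if_not(length(split$train) > 0 && length(split$val) > 0,
              "empty train or validation split")
  targ_all <- do.call(rbind, lapply(windows[split$train], `[[`, "targets"))
  model$target_center <- colMeans(targ_all)
  sds <- apply(targ_all, 2, stats::sd)
  model$target_scale <- ifelse(sds > 0, sds, 1)

  state <- list(m = zero_like(model$params), v = zero_like(model$params), t = 0)
  keep <- if (is.null(trainable)) names(model$params) else
    names(model$params)[Reduce(`|`, lapply(trainable, function(p)
      startsWith(names(model$params), p)))]
  curve <- data.frame(epoch = integer(), lr = numeric(),
                      train_loss = numeric(), val_loss = numeric())
  best_val <- Inf
  best_params <- model$params
  with_seed(tcfg$rng_seed, {
    for (ep in seq_len(tcfg$epochs)) {
      lr <- lr_at_epoch(ep, tcfg$epochs, tcfg$lr)
      ord <- sample(split$train)
      ep_loss <- 0
      nb <- 0
      for (b0 in seq(1, length(ord), by = tcfg$batch_size)) {
        idx <- ord[b0:min(b0 + tcfg$batch_size - 1, length(ord))]
        grads <- list()
        bl <- 0
        for (i in idx) {
          lg <- window_loss_grad(model, windows[[i]])
          stop_if_not(is.finite(lg$loss),
                      "non-finite training loss; aborting")
          bl <- bl + lg$loss
          grads <- backward_window(model, lg$cache, lg$dpred, grads)
        }
        grads <- lapply(grads, function(x) x / length(idx))
        grads <- grads[intersect(names(grads), keep)]
        st <- adamw_step(model$params, grads, state, lr, tcfg$weight_decay)
        model$params <- st$params
        state <- st$state
        ep_loss <- ep_loss + bl / length(idx)
        nb <- nb + 1
      }
      val_loss <- mean(vapply(split$val, function(i)
        window_loss_grad(model, windows[[i]], train = FALSE)$loss, numeric(1)))
      curve <- rbind(curve, data.frame(epoch = ep, lr = lr,
                                       train_loss = ep_loss / nb,
                                       val_loss = val_loss))
      if (val_loss < best_val) {
        best_val <- val_loss
        best_params <- model$params
      }
      if (verbose) message(sprintf("epoch %3d lr %.2e train %.4f val %.4f",
                                   ep, lr, ep_loss / nb, val_loss))
    }
  })
  model$params <- best_params
  model$curve <- curve
  model$split <- split
  model$tcfg <- tcfg
  model
}

#' Coefficient of determination on a set of windows
#'
#' Predictions and targets are concatenated across windows; R-squared is
#' `1 - SS_res / SS_tot` per output dimension and averaged (for the ball,
#' the mean of the x and y values). A zero-variance target gives `NA` with a
#' warning.
#'
#' @param model trained `spike_decoder`
#' @param windows list of windows
#' @param idx window indices to evaluate (default: all)
#' @param drop_units roster embedding-row indices whose tokens are removed at
#'   inference (ablation); windows left empty are skipped
#' @return list with `r2` (mean) and `per_dim`
#' @export
evaluate_r2 <- function(model, windows, idx = seq_along(windows),
                        drop_units = integer(0)) {
  preds <- list()
  targs <- list()
  for (i in idx) {
    win <- windows[[i]]
    if (length(drop_units)) {
      keep <- !(win$unit_idx %in% drop_units)
      if (!any(keep)) next
      win$unit_idx <- win$unit_idx[keep]
      win$t_rel <- win$t_rel[keep]
      win$n <- sum(keep)
    }
    preds[[length(preds) + 1]] <- forward_window(model, win)$pred
    targs[[length(targs) + 1]] <- win$targets
  }
  if (!length(preds)) return(list(r2 = NA_real_, per_dim = NA_real_))
  per_dim <- r2_score(do.call(rbind, preds), do.call(rbind, targs))
  list(r2 = mean(per_dim), per_dim = per_dim)
}

#' Coefficient of determination per output dimension
#'
#' `1 - SS_res / SS_tot` columnwise; a zero-variance target column gives
#' `NA` with a warning.
#'
#' @param pred,targ matrices of identical shape (rows = samples)
#' @return numeric vector, one value per column
#' @export
r2_score <- function(pred, targ) {
  pred <- as.matrix(pred)
  targ <- as.matrix(targ)
  stop_if_not(all(dim(pred) == dim(targ)), "shape mismatch")
  vapply(seq_len(ncol(targ)), function(j) {
    sst <- sum((targ[, j] - mean(targ[, j]))^2)
    if (sst == 0) {
      warning("zero-variance target dimension ", j)
      return(NA_real_)
    }
    1 - sum((pred[, j] - targ[, j])^2) / sst
  }, numeric(1))
}

#' Fine-tune a pretrained decoder on a new session
#'
#' The attention/FFN core is carried over; the unit-embedding table is
#' re-initialized for the new roster and a fresh session embedding is added.
#' With `warmup_epochs > 0` the run is staged: the freshly initialized
#' embeddings are first adapted alone (core frozen, learning rate
#' `warmup_lr`, default 3x the main rate) before the whole model is trained
#' -- random embeddings otherwise corrupt the pretrained core during the
#' first updates. With `embeddings_only = TRUE` the core stays frozen
#' throughout.
#'
#' @param pretrained trained `spike_decoder`
#' @param windows windows of the new session
#' @param roster roster of the new session
#' @param tcfg [train_config()] for the main fine-tuning stage
#' @param split optional precomputed split
#' @param embeddings_only freeze the core for the whole run
#' @param warmup_epochs embeddings-only epochs before the main stage
#' @param warmup_lr learning rate of the warmup stage
#' @return fine-tuned `spike_decoder`; `curve` holds the main-stage curve and
#'   `warmup_curve` the warmup stage
#' @export
finetune_decoder <- function(pretrained, windows, roster,
                             tcfg = train_config(), split = NULL,
                             embeddings_only = FALSE, warmup_epochs = 0,
                             warmup_lr = 3 * tcfg$lr) {
  unit_ids <- if (is.data.frame(roster)) roster$unit_id else roster
  model <- pretrained
  d <- model$cfg$latent_dim
  model$params$U <- with_seed(tcfg$rng_seed,
                              rand_mat(length(unit_ids), d, 0.5))
  model$params$S <- with_seed(child_seed(tcfg$rng_seed, 1),
                              rand_mat(1, d, 0.5))
  model$unit_ids <- unit_ids
  model$sessions <- "finetune"
  model$curve <- NULL
  warm <- NULL
  if (warmup_epochs > 0) {
    wcfg <- tcfg
    wcfg$epochs <- as.integer(warmup_epochs)
    wcfg$lr <- warmup_lr
    model <- train_decoder(model, windows, wcfg, split = split,
                           trainable = c("U", "S"))
    warm <- model$curve
  }
  model <- train_decoder(model, windows, tcfg, split = split,
                         trainable = if (embeddings_only) c("U", "S") else NULL)
  model$warmup_curve <- warm
  model
}

#' Ridge optimal linear estimator baseline
#'
#' Classical linear decoding baseline: spike counts per unit on the output
#' time grid (lightly smoothed with a short causal boxcar) are mapped to the
#' stimulus features by closed-form ridge regression with regularization
#' `alpha` on standardized features. Uses the same temporal-block split as
#' the attention decoder.
#'
#' @param spikes `spike_events`
#' @param stimulus stimulus trace
#' @param cfg [model_config()] (defines the output grid and window length)
#' @param alpha ridge penalty (default 0.1)
#' @param smooth_bins causal boxcar width in bins (default 5)
#' @param split window split from [split_windows()] (computed if `NULL`)
#' @param unit_ids roster ids
#' @return list with `r2` (test), `per_dim`, `beta`, `split`
#' @export
fit_ole <- function(spikes, stimulus, cfg, alpha = 0.1, smooth_bins = 5,
                    split = NULL, unit_ids = NULL) {
  stop_if_not(alpha > 0, "alpha must be positive (0 can be singular)")
  if (is.null(unit_ids)) unit_ids <- attr(spikes, "roster")$unit_id
  total <- max(stimulus$t_s) + 1 / attr(stimulus, "frame_rate")
  w <- cfg$context_window
  n_win <- floor(total / w + 1e-9)
  m <- cfg$n_out_tokens
  dt <- w / m
  edges <- seq(0, n_win * w, by = dt)
  nb <- length(edges) - 1
  X <- matrix(0, nb, length(unit_ids))
  for (j in seq_along(unit_ids)) {
    tt <- spikes$time_s[spikes$unit_id == unit_ids[j]]
    tt <- tt[tt < n_win * w]
    if (length(tt))
      X[, j] <- graphics::hist(tt, breaks = edges, plot = FALSE)$counts
  }
  if (smooth_bins > 1)
    X <- apply(X, 2, function(col)
      as.numeric(stats::filter(col, rep(1 / smooth_bins, smooth_bins),
                               sides = 1)))
  X[is.na(X)] <- 0
  t_mid <- (edges[-1] + edges[-length(edges)]) / 2
  ycols <- setdiff(names(stimulus), "t_s")
  Y <- vapply(ycols, function(cl)
    stats::approx(stimulus$t_s, stimulus[[cl]], xout = t_mid, rule = 2)$y,
    numeric(nb))
  Y <- matrix(Y, nrow = nb)
  if (is.null(split)) split <- split_windows(n_win)
  rows_of <- function(wins) unlist(lapply(wins, function(i)
    ((i - 1) * m + 1):(i * m)))
  tr <- rows_of(split$train)
  te <- rows_of(split$test)
  mu <- colMeans(X[tr, , drop = FALSE])
  sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  ymu <- colMeans(Y[tr, , drop = FALSE])
  Yc <- sweep(Y, 2, ymu, "-")
  XtX <- crossprod(Xs[tr, , drop = FALSE])
  beta <- solve(XtX + alpha * diag(ncol(Xs)),
                crossprod(Xs[tr, , drop = FALSE], Yc[tr, , drop = FALSE]))
  P <- Xs[te, , drop = FALSE] %*% beta
  per_dim <- r2_score(P, Yc[te, , drop = FALSE])
  list(r2 = mean(per_dim), per_dim = per_dim, beta = beta, split = split,
       alpha = alpha)
}
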