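#' Collect decoder cross-attention over a set of windows
#'
#' Captures the post-softmax decoder attention matrices `D_h`
#' (`n_out_tokens x n_latents` per head) -- the weights with which each
#' output timestamp queries the latent tokens -- for the given windows, in
#' evaluation mode.
#'
#' @param model trained `spike_decoder`
#' @param windows list from [make_windows()]
#' @param idx window indices (default all)
#' @return object of class `decoder_attention_set`: per-window records
#'   (`D` = list of H matrices, `t_out` = output timestamps)
#' @export
collect_decoder_attention <- function(model, windows, idx = seq_along(windows)) {
  recs <- lapply(idx, function(i) {
    fw <- forward_window(model, windows[[i]], capture = TRUE)
    list(D = fw$dec_attn, t_out = fw$t_out)
  })
  structure(recs, class = "decoder_attention_set",
            n_heads = model$cfg$n_heads, n_latents = model$cfg$n_latents)
}

#' Shannon entropy of decoder attention per head and output token
#'
#' `E(h, m) = -sum_j d_mj ln d_mj` in nats over each row of `D_h`,
#' measuring the uncertainty of latent selection at each output timestamp;
#' computed at the sampling rate of the reconstructed stimulus and bounded
#' by `[0, ln L]`.
#'
#' @param attn a `decoder_attention_set`
#' @return data.frame with columns `t_s`, `head`, `E_nats`
#' @export
decoder_entropy <- function(attn) {
  do.call(rbind, lapply(attn, function(rec) {
    do.call(rbind, lapply(seq_along(rec$D), function(h) {
      e <- apply(rec$D[[h]], 1, function(p) {
        p <- p[p > 0]
        -sum(p * log(p))
      })
      data.frame(t_s = rec$t_out, head = h, E_nats = e)
    }))
  }))
}

#' Correlation between decoder entropy and flash intensity
#'
#' Pearson correlation, per head, between the decoder entropy trace and the
#' light intensity profile resampled onto the entropy timestamps.
#'
#' @param entropy data.frame from [decoder_entropy()]
#' @param stimulus flash trace from [generate_flash()]
#' @return data.frame `head`, `r`; `r` is `NA` (with a warning) if either
#'   trace has zero variance
#' @export
flash_coupling <- function(entropy, stimulus) {
  heads <- sort(unique(entropy$head))
  out <- lapply(heads, function(h) {
    e <- entropy[entropy$head == h, ]
    x <- stats::approx(stimulus$t_s, stimulus$value, xout = e$t_s,
                       rule = 2)$y
    r <- if (stats::sd(x) == 0 || stats::sd(e$E_nats) == 0) {
      warning("zero-variance trace for head ", h)
      NA_real_
    } else stats::cor(e$E_nats, x)
    data.frame(head = h, r = r)
  })
  do.call(rbind, out)
}

#' Rectified Cartesian decomposition of a trajectory
#'
#' Splits the per-frame displacement of a 2-D trajectory into four
#' nonnegative traces: `+X = max(dx, 0)`, `-X = max(-dx, 0)` and likewise
#' for y, so `(+X) - (-X)` reconstructs `dx` exactly. With
#' `mode = "position"` the rectification is applied to the position relative
#' to the trajectory mean instead of to displacements.
#'
#' @param trajectory ball trace with columns `t_s`, `x_px`, `y_px`
#' @param mode `"displacement"` (default) or `"position"`
#' @return data.frame `t_s`, `plus_x`, `minus_x`, `plus_y`, `minus_y`
#'   (displacement mode has one fewer row than the input, timestamped at the
#'   later frame of each pair)
#' @export
directional_decompose <- function(trajectory,
                                  mode = c("displacement", "position")) {
  mode <- match.arg(mode)
  stop_if_not(nrow(trajectory) >= 2, "trajectory needs at least 2 frames")
  if (mode == "displacement") {
    dx <- diff(trajectory$x_px)
    dy <- diff(trajectory$y_px)
    data.frame(t_s = trajectory$t_s[-1],
               plus_x = pmax(dx, 0), minus_x = pmax(-dx, 0),
               plus_y = pmax(dy, 0), minus_y = pmax(-dy, 0))
  } else {
    cx <- trajectory$x_px - mean(trajectory$x_px)
    cy <- trajectory$y_px - mean(trajectory$y_px)
    data.frame(t_s = trajectory$t_s,
               plus_x = pmax(cx, 0), minus_x = pmax(-cx, 0),
               plus_y = pmax(cy, 0), minus_y = pmax(-cy, 0))
  }
}

#' Directional coupling between decoder entropy and ball motion
#'
#' Per head, the Pearson correlation between the entropy trace and each of
#' the four rectified motion components resampled onto the entropy
#' timestamps, assembled into a positive-direction vector `(r_+X, r_+Y)`
#' and a negative-direction vector `(r_-X, r_-Y)`.
#'
#' @param entropy data.frame from [decoder_entropy()]
#' @param decomp data.frame from [directional_decompose()]
#' @return data.frame `head`, `component` (`+X`, `-X`, `+Y`, `-Y`), `r`;
#'   components with a constant trace give `NA` with a warning
#' @export
directional_coupling <- function(entropy, decomp) {
  comps <- c("+X" = "plus_x", "-X" = "minus_x",
             "+Y" = "plus_y", "-Y" = "minus_y")
  heads <- sort(unique(entropy$head))
  out <- list()
  for (h in heads) {
    e <- entropy[entropy$head == h, ]
    for (k in seq_along(comps)) {
      x <- stats::approx(decomp$t_s, decomp[[comps[k]]], xout = e$t_s,
                         rule = 2)$y
      r <- if (stats::sd(x) == 0 || stats::sd(e$E_nats) == 0) {
        warning("constant component ", names(comps)[k], " for head ", h)
        NA_real_
      } else stats::cor(e$E_nats, x)
      out[[length(out) + 1]] <- data.frame(head = h,
                                           component = names(comps)[k],
                                           r = r)
    }
  }
  do.call(rbind, out)
}
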