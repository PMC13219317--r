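#' Collect encoder cross-attention over a set of windows
#'
#' Runs the trained model in evaluation mode (no dropout) over the given
#' windows and captures the post-softmax encoder cross-attention matrices
#' `A_h` (`n_latents x N_i` per head) together with the token-to-(unit, time)
#' index. Attention is read from the single spike-level cross-attention
#' block; latent self-attention is not unit-attributable and is not
#' collected.
#'
#' @param model trained `spike_decoder`
#' @param windows list from [make_windows()]
#' @param idx window indices (default all)
#' @return object of class `encoder_attention_set`: a list of per-window
#'   records (`A` = list of H matrices, `unit_id`, `time_s`, `t_end`, `n`)
#'   with `n_heads`/`n_latents` attributes
#' @export
collect_encoder_attention <- function(model, windows, idx = seq_along(windows)) {
  recs <- lapply(idx, function(i) {
    win <- windows[[i]]
    fw <- forward_window(model, win, capture = TRUE)
    list(A = fw$enc_attn, unit_id = win$unit_id, time_s = win$time_s,
         t_end = win$t_start + model$cfg$context_window, n = win$n)
  })
  structure(recs, class = "encoder_attention_set",
            n_heads = model$cfg$n_heads, n_latents = model$cfg$n_latents)
}

#' Latent-averaged and count-normalized spike attention weights
#'
#' For each head and window, collapses the latent dimension of the attention
#' matrix by averaging over the `L` latent rows, giving a probability vector
#' `wbar` over the window's spikes (sums to 1); `what = wbar * N_i` is the
#' count-normalized weight (mean 1), comparable across windows with
#' different spike densities.
#'
#' @param attn an `encoder_attention_set` (or a single window's record)
#' @return object of class `spike_weights`: per-window records with `wbar`
#'   and `what` (`H x N_i` matrices), `unit_id`, `time_s`, `t_end`
#' @export
spike_weights <- function(attn) {
  single <- !inherits(attn, "encoder_attention_set")
  recs <- if (single) list(attn) else attn
  H <- if (single) length(attn$A) else attr(attn, "n_heads")
  out <- lapply(recs, function(rec) {
    if (rec$n == 0) return(NULL)
    wbar <- do.call(rbind, lapply(rec$A, colMeans))
    list(wbar = wbar, what = wbar * rec$n, unit_id = rec$unit_id,
         time_s = rec$time_s, t_end = rec$t_end, n = rec$n)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  structure(out, class = "spike_weights", n_heads = H)
}

#' Shannon entropy of encoder attention per head and window
#'
#' `E(h, i) = -sum_k wbar ln wbar` in nats (`0 ln 0 := 0`), one value per
#' head per context window, timestamped at the window end -- a time-varying
#' focus metric at 1 Hz resolution for 1-s windows. Bounded by `[0, ln N_i]`.
#'
#' @param weights a `spike_weights` object
#' @return data.frame with columns `t_s`, `head`, `E_nats`, `n_spikes`
#' @export
encoder_entropy <- function(weights) {
  do.call(rbind, lapply(weights, function(rec) {
    e <- apply(rec$wbar, 1, function(p) {
      p <- p[p > 0]
      -sum(p * log(p))
    })
    data.frame(t_s = rec$t_end, head = seq_along(e), E_nats = e,
               n_spikes = rec$n)
  }))
}

#' Pairwise Kolmogorov-Smirnov divergence between attention heads
#'
#' Two-sample K-S tests between the entropy distributions of every pair of
#' heads. Returns the D statistic and raw p-value matrices (symmetric,
#' diagonal `NA`) plus Bonferroni-adjusted p-values over the
#' `H (H - 1) / 2` comparisons.
#'
#' @param entropy data.frame from [encoder_entropy()] (or
#'   [decoder_entropy()])
#' @return list with matrices `D`, `p`, `p_bonferroni`
#' @export
head_divergence <- function(entropy) {
  heads <- sort(unique(entropy$head))
  H <- length(heads)
  stop_if_not(H >= 2, "need at least two heads")
  stop_if_not(min(table(entropy$head)) >= 2,
              "need at least two windows per head")
  D <- matrix(NA_real_, H, H, dimnames = list(heads, heads))
  P <- D
  for (a in seq_len(H - 1)) for (b in (a + 1):H) {
    x <- entropy$E_nats[entropy$head == heads[a]]
    y <- entropy$E_nats[entropy$head == heads[b]]
    kt <- suppressWarnings(stats::ks.test(x, y))
    D[a, b] <- D[b, a] <- unname(kt$statistic)
    P[a, b] <- P[b, a] <- kt$p.value
  }
  n_comp <- H * (H - 1) / 2
  list(D = D, p = P, p_bonferroni = pmin(P * n_comp, 1))
}

#' Per-unit attention importance score
#'
#' `I(u)` is the per-spike attention a unit receives, averaged across heads
#' and across the context windows in which the unit fired: the mean of
#' `wbar` over the unit's spikes in each window, averaged over heads and
#' spike-containing windows. Being a per-spike average, it is independent of
#' the unit's total firing rate. Units with no spikes anywhere get `NA` and
#' are ranked last; ties are broken by unit id.
#'
#' @param weights a `spike_weights` object
#' @param unit_ids full roster ids (so silent units are reported); default:
#'   units observed in the weights
#' @return data.frame of class `importance_ranking`: `unit_id`, `importance`,
#'   `rank`, `n_windows`, `n_spikes`, sorted by rank
#' @export
unit_importance <- function(weights, unit_ids = NULL) {
  per_win <- do.call(rbind, lapply(weights, function(rec) {
    ph <- rowsum(t(rec$wbar), group = rec$unit_id)   # units x H sums
    cnt <- as.numeric(table(rec$unit_id)[rownames(ph)])
    data.frame(unit_id = as.numeric(rownames(ph)),
               contrib = unname(rowMeans(ph / cnt)), # heads x per-spike mean
               spikes = cnt)
  }))
  if (is.null(unit_ids)) unit_ids <- sort(unique(per_win$unit_id))
  by_unit <- split(per_win, factor(per_win$unit_id, levels = unit_ids))
  imp <- data.frame(
    unit_id = unit_ids,
    importance = vapply(by_unit, function(d)
      if (nrow(d)) mean(d$contrib) else NA_real_, numeric(1)),
    n_windows = vapply(by_unit, nrow, integer(1)),
    n_spikes = vapply(by_unit, function(d) sum(d$spikes), numeric(1))
  )
  if (anyNA(imp$importance))
    message(sum(is.na(imp$importance)), " unit(s) with no spikes ranked last")
  ord <- order(-imp$importance, imp$unit_id, na.last = TRUE)
  imp <- imp[ord, ]
  imp$rank <- seq_len(nrow(imp))
  rownames(imp) <- NULL
  class(imp) <- c("importance_ranking", "data.frame")
  imp
}

#' Attention-guided and random ablation curves
#'
#' Units are removed cumulatively at inference (their spike tokens dropped;
#' no retraining) and the model re-evaluated on the test windows after each
#' removal step. `strategy = "attention"` removes in descending importance
#' order; `strategy = "random"` repeats the procedure for `n_random_iters`
#' independent random orders.
#'
#' @param model trained `spike_decoder`
#' @param windows all windows
#' @param test_idx indices of test windows
#' @param ranking an `importance_ranking` (attention order); required for the
#'   attention strategy
#' @param strategy `"attention"`, `"random"`, or `"both"`
#' @param n_random_iters random orders (default 20)
#' @param step_size units removed per step (default 1)
#' @param rng_seed seed for the random orders
#' @return data.frame of class `ablation_curves`: `strategy`, `iter`
#'   (`NA` for attention), `step`, `n_removed`, `r2`
#' @export
ablation_experiment <- function(model, windows, test_idx, ranking = NULL,
                                strategy = c("both", "attention", "random"),
                                n_random_iters = 20, step_size = 1,
                                rng_seed = 1L) {
  strategy <- match.arg(strategy)
  n_units <- length(model$unit_ids)
  steps <- unique(c(seq(0, n_units - 1, by = step_size)))
  curve_for <- function(order_idx, strat, iter) {
    r2s <- vapply(steps, function(k) {
      evaluate_r2(model, windows, test_idx,
                  drop_units = if (k > 0) order_idx[seq_len(k)] else integer(0))$r2
    }, numeric(1))
    data.frame(strategy = strat, iter = iter, step = seq_along(steps) - 1,
               n_removed = steps, r2 = r2s)
  }
  out <- list()
  if (strategy %in% c("both", "attention")) {
    stop_if_not(!is.null(ranking), "attention strategy needs a ranking")
    ord <- match(ranking$unit_id, model$unit_ids)
    out[[length(out) + 1]] <- curve_for(ord, "attention", NA_integer_)
  }
  if (strategy %in% c("both", "random")) {
    rnd <- with_seed(rng_seed, lapply(seq_len(n_random_iters),
                                      function(i) sample(n_units)))
    for (i in seq_len(n_random_iters))
      out[[length(out) + 1]] <- curve_for(rnd[[i]], "random", i)
  }
  res <- do.call(rbind, out)
  class(res) <- c("ablation_curves", "data.frame")
  res
}

#' Number of top-ranked units needed to halve decoding performance
#'
#' The smallest cumulative removal count at which the ablation curve first
#' drops to or below `threshold` (default R-squared 0.5). If the curve never
#' crosses, `K` equals the total unit count and `crossed = FALSE`; if the
#' unablated model is already at or below threshold, `K = 0`.
#'
#' @param curve one ablation curve (data.frame with `n_removed`, `r2`)
#' @param threshold R-squared threshold
#' @param n_units total units (for the never-crossed sentinel; default: max
#'   `n_removed` + 1)
#' @return list with `K` and `crossed`
#' @export
topk_at_threshold <- function(curve, threshold = 0.5, n_units = NULL) {
  curve <- curve[order(curve$n_removed), ]
  hit <- which(curve$r2 <= threshold)
  if (!length(hit)) {
    return(list(K = n_units %||% (max(curve$n_removed) + 1), crossed = FALSE))
  }
  list(K = curve$n_removed[hit[1]], crossed = TRUE)
}

#' Cross-seed consensus set of top-attended units
#'
#' Units appearing in the per-seed top-K lists of at least
#' `ceiling(min_fraction * n_seeds)` seeds.
#'
#' @param topk_lists list (one element per seed) of unit-id vectors
#' @param min_fraction minimum fraction of seeds (default 0.5)
#' @return data.frame `unit_id`, `n_seeds` (membership count), consensus
#'   members only; empty (with a warning) if no unit qualifies
#' @export
consensus_units <- function(topk_lists, min_fraction = 0.5) {
  stop_if_not(length(topk_lists) >= 2, "need at least two seeds for consensus")
  counts <- table(unlist(lapply(topk_lists, unique)))
  need <- ceiling(min_fraction * length(topk_lists))
  keep <- counts[counts >= need]
  if (!length(keep)) warning("empty consensus set")
  out <- data.frame(unit_id = as.numeric(names(keep)),
                    n_seeds = as.numeric(keep))
  out[order(-out$n_seeds, out$unit_id), , drop = FALSE]
}

#' Physiological comparison of a consensus subset against the population
#'
#' Two-sample K-S tests on each light-response feature (polarity bias,
#' sustain index, latency, mean rate) between a unit subset and the global
#' population, optionally between two subsets, plus 2-D kernel density
#' summaries of each feature against the polarity bias.
#'
#' @param physio `unit_physiology` data.frame for the whole population
#' @param subset_ids unit ids of the (first) subset
#' @param subset2_ids optional second subset for a subset-vs-subset row
#' @param kde compute 2-D KDE grids (feature vs `fbr`) via
#'   [MASS::kde2d()]
#' @return list with `tests` (data.frame `comparison`, `feature`, `D`, `p`)
#'   and `kde` (named list of KDE grids or `NULL`)
#' @export
compare_physiology <- function(physio, subset_ids, subset2_ids = NULL,
                               kde = FALSE) {
  feats <- c("fbr", "sustain_index", "latency_s", "mean_rate_hz")
  stop_if_not(length(subset_ids) > 0, "empty subset")
  if (length(subset_ids) < 5)
    warning("subset smaller than 5 units; K-S tests are weak")
  groups <- list(subset = physio[physio$unit_id %in% subset_ids, ],
                 all = physio)
  rows <- list()
  run_ks <- function(a, b, label) {
    for (f in feats) {
      x <- stats::na.omit(a[[f]])
      y <- stats::na.omit(b[[f]])
      kt <- suppressWarnings(stats::ks.test(x, y))
      rows[[length(rows) + 1]] <<- data.frame(
        comparison = label, feature = f,
        D = unname(kt$statistic), p = kt$p.value)
    }
  }
  run_ks(groups$subset, groups$all, "subset_vs_all")
  if (!is.null(subset2_ids)) {
    g2 <- physio[physio$unit_id %in% subset2_ids, ]
    run_ks(g2, groups$all, "subset2_vs_all")
    run_ks(groups$subset, g2, "subset_vs_subset2")
  }
  kdes <- NULL
  if (kde) {
    kdes <- lapply(setdiff(feats, "fbr"), function(f) {
      ok <- stats::complete.cases(physio$fbr, physio[[f]])
      MASS::kde2d(physio$fbr[ok], physio[[f]][ok], n = 50)
    })
    names(kdes) <- setdiff(feats, "fbr")
  }
  list(tests = do.call(rbind, rows), kde = kdes)
}
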