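#!/usr/bin/env Rscript
# Stage 4 -- encoder attention analysis.
#
# From the trained ball and flash decoders: latent-averaged spike weights,
# per-head entropy traces at 1 Hz, pairwise Kolmogorov-Smirnov head
# divergence, and the per-unit importance ranking. Writes
# results/encoder_entropy_*.csv, results/head_divergence_*.csv and
# results/importance_ball.csv.

library(retinattn)

dec <- readRDS("scratch/decoders.rds")

analyze <- function(model, wins, label) {
  attn <- collect_encoder_attention(model, wins)
  wts <- spike_weights(attn)
  ent <- encoder_entropy(wts)
  write.csv(ent, sprintf("results/encoder_entropy_%s.csv", label),
            row.names = FALSE)
  div <- head_divergence(ent)
  dmat <- as.data.frame(div$D)
  dmat$head <- rownames(div$D)
  write.csv(dmat, sprintf("results/head_divergence_D_%s.csv", label),
            row.names = FALSE)
  pmat <- as.data.frame(div$p)
  pmat$head <- rownames(div$p)
  write.csv(pmat, sprintf("results/head_divergence_p_%s.csv", label),
            row.names = FALSE)
  n_sig <- sum(div$p[upper.tri(div$p)] < 0.05)
  cat(sprintf("%s: %d/%d head pairs diverge (raw p < 0.05); entropy %0.2f-%0.2f nats\n",
              label, n_sig, sum(upper.tri(div$p)), min(ent$E_nats),
              max(ent$E_nats)))
  wts
}

wts_flash <- analyze(dec$flash$model, dec$flash$wins, "flash")
wts_ball <- analyze(dec$ball$models[[1]], dec$ball$wins, "ball")

# color-coded raster export: one row per (spike, head) with the
# count-normalized attention weight as the color value
raster <- function(wts, label) {
  df <- do.call(rbind, lapply(wts, function(rec) {
    data.frame(t_s = rep(rec$time_s, each = nrow(rec$what)),
               unit_id = rep(rec$unit_id, each = nrow(rec$what)),
               head = rep(seq_len(nrow(rec$what)), times = rec$n),
               weight = as.vector(rec$what))
  }))
  write.csv(df, sprintf("results/raster_weights_%s.csv", label),
            row.names = FALSE)
}
raster(wts_flash, "flash")

imp <- unit_importance(wts_ball, unit_ids = dec$ball$pop$unit_id)
imp$informative <- imp$unit_id %in%
  dec$ball$pop$unit_id[dec$ball$pop$informative_gain > 0]
write.csv(imp, "results/importance_ball.csv", row.names = FALSE)
n_inf <- sum(imp$informative)
cat(sprintf("importance ranking: precision@%d against planted labels = %.2f\n",
            n_inf, mean(imp$informative[seq_len(n_inf)])))
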