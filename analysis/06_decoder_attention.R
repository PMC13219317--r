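#!/usr/bin/env Rscript
# Stage 6 -- decoder attention and stimulus coupling.
#
# Decoder-side entropy traces at the output sampling rate, their Pearson
# coupling with the flash intensity profile, and the directional
# (rectified +X/-X/+Y/-Y displacement) coupling vectors for the ball.
# Writes results/decoder_entropy_*.csv and results/coupling.csv.

library(retinattn)

dec <- readRDS("scratch/decoders.rds")

fent <- decoder_entropy(collect_decoder_attention(dec$flash$model,
                                                  dec$flash$wins))
write.csv(fent, "results/decoder_entropy_flash.csv", row.names = FALSE)
fc <- flash_coupling(fent, dec$flash$stim)
fc$stimulus <- "flash"
fc$component <- "intensity"

bent <- decoder_entropy(collect_decoder_attention(dec$ball$models[[1]],
                                                  dec$ball$wins))
write.csv(bent, "results/decoder_entropy_ball.csv", row.names = FALSE)
dd <- directional_decompose(dec$ball$stim)
bc <- directional_coupling(bent, dd)
bc$stimulus <- "ball"

coupling <- rbind(fc[, c("stimulus", "head", "component", "r")],
                  bc[, c("stimulus", "head", "component", "r")])
write.csv(coupling, "results/coupling.csv", row.names = FALSE)

# heatmap export for a representative window: one matrix CSV per head,
# latents on columns, output timestamps on rows (transpose for plotting
# with latents vertical)
rep_win <- collect_decoder_attention(dec$ball$models[[1]], dec$ball$wins,
                                     dec$ball$split$test[1])
for (h in seq_along(rep_win[[1]]$D))
  write.csv(rep_win[[1]]$D[[h]],
            sprintf("results/decoder_attention_ball_head%d.csv", h),
            row.names = FALSE)

cat("flash intensity coupling per head:\n")
print(fc[, c("head", "r")], row.names = FALSE)
cat("\nball directional coupling (per head, rectified displacement):\n")
print(reshape(bc[, c("head", "component", "r")], idvar = "head",
              timevar = "component", direction = "wide"), row.names = FALSE)
best <- bc[as.logical(ave(abs(bc$r), bc$head,
                          FUN = function(x) x == max(x))), ]
cat("\nstrongest component per head:\n")
print(best, row.names = FALSE)
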