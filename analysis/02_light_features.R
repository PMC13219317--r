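#!/usr/bin/env Rscript
# Stage 2 -- flash physiology indices for every unit.
#
# Computes the polarity bias (fBR), sustain index, latency and mean firing
# rate from the flash-session PSTHs of the ball-session population (all
# units made light-responsive for the characterization protocol, as after
# experimental curation), and writes results/physiology.csv.

library(retinattn)

stopifnot(file.exists("results/data/ball_roster.csv"))
pop <- read.csv("results/data/ball_roster.csv")
class(pop) <- c("unit_roster", "data.frame")

fcfg <- flash_config()
stim <- generate_flash(fcfg)
pop_flash <- pop
pop_flash$informative_gain <- 1   # characterization drives every unit
spk <- simulate_spikes(stim, pop_flash, rng_seed = 13,
                       session_id = "ball01_flashchar")
phys <- light_features(spk, fcfg)
write_physiology_csv(phys, "results/physiology.csv")

cat(sprintf("%d units characterized\n", nrow(phys)))
cat(sprintf("polarity: %d ON (fBR>0.3), %d OFF (fBR<-0.3), %d ON-OFF\n",
            sum(phys$fbr > 0.3, na.rm = TRUE),
            sum(phys$fbr < -0.3, na.rm = TRUE),
            sum(abs(phys$fbr) <= 0.3, na.rm = TRUE)))
cat(sprintf("sustain index: median %.2f (IQR %.2f-%.2f)\n",
            median(phys$sustain_index, na.rm = TRUE),
            quantile(phys$sustain_index, 0.25, na.rm = TRUE),
            quantile(phys$sustain_index, 0.75, na.rm = TRUE)))
cat(sprintf("latency: median %.0f ms; mean rate: median %.1f Hz\n",
            1000 * median(phys$latency_s, na.rm = TRUE),
            median(phys$mean_rate_hz, na.rm = TRUE)))
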