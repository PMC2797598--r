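#!/usr/bin/env Rscript
# Fit piecewise-linear segments to the simulated asynchronous profiles from
# 01_simulate_profiles.R, convert slopes to fork velocities, flag stall
# segments and quantify the head-on speed decrease.

library(replifork)
map <- bsub_genome_map("HT")
Mbp_deg <- map$genome_length_bp / 360 / 1e6
doubling <- c(Min = 44, CAA = 55)
bounds <- list(
  Min = list(right = 94 * Mbp_deg, left = numeric(0)),
  CAA = list(right = c(13, 40, 80, 94) * Mbp_deg, left = numeric(0)))

all_fits <- list()
for (medium in c("Min", "CAA")) {
  p <- read_profile(sprintf("results/profile_HT_%s.tsv", medium))
  fits <- fit_segments(p, map, boundaries = bounds[[medium]])
  fits <- stall_segments(fits, fold_threshold = 2)
  fits <- velocity_table(fits, doubling[[medium]])
  fits$medium <- medium
  all_fits[[medium]] <- fits
}
tab <- do.call(rbind, all_fits)
utils::write.table(format(tab, digits = 4), "results/segment_fits.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

min_fits <- all_fits$Min
a_ho <- min_fits[min_fits$replichore == "right", ][1, ]
a_cd <- min_fits[min_fits$replichore == "right", ][2, ]
cat(sprintf(paste0(
  "Min medium: head-on slope %.3f, co-directional %.3f per Mbp\n",
  "  => %.1f%% fork-speed decrease in the head-on region (vs same arm),\n",
  "     %.1f%% vs the left replichore (slope %.3f).\n"),
  a_ho$slope, a_cd$slope, percent_speed_change(a_ho, a_cd),
  percent_speed_change(a_ho, min_fits[min_fits$replichore == "left", ][1, ]),
  min_fits[min_fits$replichore == "left", "slope"][1]))
caa <- all_fits$CAA[all_fits$CAA$replichore == "right", ]
cat(sprintf(
  "CAA medium: stall-flagged segments: %s (slope %.2f per Mbp, v = %.1f kb/min)\n",
  paste(which(caa$stall), collapse = ","),
  caa$slope[caa$stall][1], caa$velocity_kb_min[caa$stall][1]))
cat("Wrote results/segment_fits.tsv\n")

# automated changepoint search on the CAA right arm, no boundaries supplied
p_caa <- read_profile("results/profile_HT_CAA.tsv")
cp <- detect_changepoints(p_caa, map, "right")
cat("Changepoints detected on the CAA right replichore (Mbp from oriC):",
    paste(sprintf("%.2f", cp), collapse = ", "), "\n")
cat("rRNA landmark positions (Mbp):",
    paste(sprintf("%.2f", c(13, 40, 80, 94) * Mbp_deg), collapse = ", "), "\n")
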