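#!/usr/bin/env Rscript
# Synchronized-release analysis: simulate 30-minute release profiles of the
# HT strain (half the population initiating), with and without shutting off
# transcription 4 minutes after release, then estimate the initiation
# fraction and per-arm fork fronts from the tracks.

library(replifork)
dir.create("results", showWarnings = FALSE)
map <- bsub_genome_map("HT")
pos <- seq(500, map$genome_length_bp - 500, by = 1000)

# untreated: left arm unimpeded (front 0.68 Mbp at 30 min), inverted right
# arm slowed by head-on transcription (front 0.56 Mbp)
v_untr <- velocity_profile(left = replichore_velocity(680 / 30),
                           right = replichore_velocity(560 / 30))
sched_untr <- velocity_schedule(0, 30, list(v_untr))
# rifampicin at 4 min: the right arm speeds up afterwards so that its front
# reaches 0.72 Mbp; the left arm is already co-directional and keeps its speed
v_rif <- velocity_profile(left = replichore_velocity(680 / 30),
                          right = replichore_velocity((720 - 4 * 560 / 30) / 26))
sched_rif <- velocity_schedule(c(0, 4), c(4, 30), list(v_untr, v_rif))

rows <- list()
for (arm_cfg in list(list(sched = sched_untr, label = "untreated"),
                     list(sched = sched_rif, label = "rifampicin"))) {
  p <- sample_sync_profile(arm_cfg$sched, f_init = 0.5, elapsed_min = 30,
                           map = map, probe_positions = pos, noise_sd = 0.1,
                           seed = 42)
  for (arm in c("left", "right")) {
    est <- estimate_fork_position(p, map, arm, window = 200)
    rows[[length(rows) + 1]] <- data.frame(
      treatment = arm_cfg$label, replichore = arm,
      fork_Mbp = est$fork_position_Mbp,
      predicted_Mbp = predicted_fork_position(arm_cfg$sched, 30, arm),
      f_init = est$f)
  }
}
tab <- do.call(rbind, rows)
utils::write.table(format(tab, digits = 3), "results/sync_estimates.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(tab, digits = 3)
rt <- tab[tab$replichore == "right", ]
cat(sprintf(paste0(
  "\nEstimated initiation fraction ~%.0f%%. On the inverted right arm the\n",
  "fork reaches %.2f Mbp untreated vs %.2f Mbp when transcription is shut\n",
  "off at 4 min: the slowdown is transcription-dependent.\n"),
  100 * mean(tab$f_init), rt$fork_Mbp[rt$treatment == "untreated"],
  rt$fork_Mbp[rt$treatment == "rifampicin"]))
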