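# shared fixtures: built in code, no files
wt_map <- bsub_genome_map("wt")
L_BS <- wt_map$genome_length_bp

# evenly spaced probes on the right replichore, 1 kb spacing over `span_Mbp`
right_arm_probes <- function(span_Mbp = 2, spacing_bp = 1000) {
  seq(spacing_bp / 2, span_Mbp * 1e6, by = spacing_bp)
}

# uniform-velocity schedule placing the fork front at `front_Mbp` after 30 min
uniform_schedule <- function(front_Mbp, elapsed = 30) {
  velocity_schedule(0, elapsed, list(
    velocity_profile(replichore_velocity(front_Mbp * 1e3 / elapsed))))
}
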