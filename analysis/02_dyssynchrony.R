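#!/usr/bin/env Rscript
# Dyssynchrony analysis of the simulated patient: per-segment area-change
# curves over the cardiac cycle and time-to-peak contraction, written as
# CSV plus a bullseye SVG.

suppressMessages(library(crtarget))
stopifnot(file.exists("results/patient/endo/manifest.json"))

endo <- read_mesh_sequence("results/patient/endo/manifest.json")
frame <- endo$frame
aha <- assign_aha(endo$seq$frames[[1]], frame, 16L)

strains <- compute_strains(endo$seq, frame, measures = "area")
curves <- aggregate_segments(strains, aha)
ttp <- time_to_peak(curves)

write_segment_curves(curves, "results/curves")
write_ttp(ttp, "results/time_to_peak.csv")
render_bullseye <- crtarget:::render_bullseye
render_bullseye("results/bullseye_ttp.svg", targets = integer(), ttp = ttp)

latest <- ttp[order(-ttp$ttp), ][1:3, ]
message("latest mechanically activating segments (time to peak, % RR):")
for (i in 1:3)
  message(sprintf("  segment %2d (%s): %g%%%s", latest$segment[i],
                  aha_segment_names()[latest$segment[i]], latest$ttp[i],
                  if (latest$low_amplitude[i]) " [low amplitude]" else ""))
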