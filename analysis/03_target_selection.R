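#!/usr/bin/env Rscript
# Apply the eligibility rules: exclude septal segments, visible or
# inferred scar (wall thinning < 6 mm, hypoattenuation, akinesis) and
# minimal-strain segments; rank the rest by descending time to peak.

suppressMessages(library(crtarget))
stopifnot(file.exists("results/time_to_peak.csv"))

truth <- jsonlite::read_json("results/patient/truth.json",
                             simplifyVector = TRUE)
ttp <- utils::read.csv("results/time_to_peak.csv")
class(ttp) <- c("ttp_map", "data.frame")

features <- data.frame(segment = 1:16,
                       visible_scar = 1:16 %in% truth$scar_segments,
                       wall_thickness = truth$wall_thickness,
                       peak_area_change = ttp$peak,
                       attenuation = truth$attenuation)
scar <- infer_scar(features)
report <- select_targets(ttp, scar)
write_target_report(report, "results/target_report.json")
utils::write.csv(report$table, "results/target_table.csv", row.names = FALSE)

print(report)
truth_best <- which(truth$ttp == max(truth$ttp[setdiff(
  setdiff(1:16, aha_septal_segments()), truth$scar_segments)]))
message(sprintf("ground-truth latest eligible segment: %s",
                paste(truth_best, collapse = "/")))
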