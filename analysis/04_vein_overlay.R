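#!/usr/bin/env Rscript
# Coronary-vein matching and C-arm overlays: generate the synthetic venous
# tree, map branches to the AHA segments they subtend, pick the branch for
# the chosen target (with bullseye-adjacency fallback), and render the
# three standard venography views (RAO30 / PA / LAO30) as SVG.

suppressMessages(library(crtarget))
stopifnot(file.exists("results/target_report.json"))

endo <- read_mesh_sequence("results/patient/endo/manifest.json")
epi <- read_mesh_sequence("results/patient/epi/manifest.json")
frame <- endo$frame
tr <- jsonlite::read_json("results/target_report.json", simplifyVector = TRUE)
report <- structure(list(targets = tr$targets, ranking = tr$ranking,
                         table = tr$table, reason = tr$reason),
                    class = "target_report")

veins <- generate_vein_tree(epi$seq$frames[[1]], frame, report$targets)
write_vein_tree(veins, "results/veins.json")

aha_epi <- assign_aha(epi$seq$frames[[1]], frame, 16L)
sub <- vein_subtension(veins, epi$seq$frames[[1]], aha_epi)
for (b in sub)
  message(sprintf("branch %-26s subtends segments: %s", b$label,
                  paste(b$subtended, collapse = " ")))

choice <- pick_target_vein(report, sub)
jsonlite::write_json(unclass(choice), "results/vein_choice.json",
                     auto_unbox = TRUE, digits = NA, null = "null")
message(sprintf("chosen vein: %s via segment %s%s", choice$branch,
                choice$segment,
                if (isTRUE(choice$fallback)) " (adjacency fallback)" else ""))

aha_endo <- assign_aha(endo$seq$frames[[1]], frame, 16L)
paths <- render_overlay_views(endo$seq$frames[[1]], aha_endo, report, veins,
                              "results/overlay")
message("overlays written: ", paste(basename(paths), collapse = ", "))
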