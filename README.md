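# crtarget

Cardiac resynchronization therapy (CRT) fails in roughly a third of
patients, and a major determinant of response is *where* the left
ventricular (LV) pacing lead ends up. `crtarget` implements, as a tested
desk-scale analysis, a CT-guided targeting pipeline for LV lead
placement: endocardial wall motion is tracked on a dynamic LV surface
mesh over the cardiac cycle (0–100% RR in 5% increments), regional
contraction is summarized on the AHA 16-segment model, the **latest
mechanically activating** segments outside scar are selected as pacing
targets, coronary-vein branches are matched to the segments they
subtend, and overlays are projected into standard C-arm fluoroscopy
views. Acute hemodynamic response and remodeling statistics close the
loop. It is aimed at researchers in cardiac image analysis who want a
transparent, fully synthetic-testable reference implementation of the
targeting logic.

## The method in brief

For a vertex-corresponded endocardial mesh sequence with end-diastolic
reference, the package computes per vertex and phase the Lagrangian
measures

- local area change `(A − A₀)/A₀` of the one-ring neighborhood,
- circumferential and longitudinal engineering strain `√C_cc − 1`,
  `√C_ll − 1`, from a least-squares fit of the in-plane metric `C` to
  the one-ring edge lengths (exactly rigid-motion invariant),

aggregates them per AHA segment, and takes the **time to peak
contraction** per segment as the phase of the most negative area change.
Target selection excludes septal segments (2, 3, 8, 9, 14), visible
scar, inferred scar (wall thinning < 6 mm, optional hypoattenuation,
akinesis: peak |area change| < 0.05) and ranks the remainder by
descending time to peak. The acute hemodynamic response at a pacing site
is `AHR = 100·(dP/dt_max^BiV − dP/dt_max^base)/dP/dt_max^base`, with
`AHR > 10 %` a positive response; 2×2 comparisons use a two-sided exact
test (minimum-likelihood rule). A seeded synthetic generator (contracting
prolate-spheroid LV with per-segment activation delays, scar, an
epicardial venous tree, and paired hemodynamic cohorts) grounds every
stage in known truth.

## Worked example

```r
library(crtarget)

truth <- default_motion_truth(scar_segments = c(4L, 10L))  # latest: segment 5 at 65% RR
lv    <- generate_lv_sequence(synth_config(noise_sd = 0.3, seed = 20), truth)

strains <- compute_strains(lv$endo, lv$frame, measures = "area")
curves  <- aggregate_segments(strains, lv$aha)
ttp     <- time_to_peak(curves)

feats  <- data.frame(segment = 1:16,
                     visible_scar = 1:16 %in% truth$scar_segments,
                     wall_thickness = truth$wall_thickness,
                     peak_area_change = ttp$peak,
                     attenuation = truth$attenuation)
report <- select_targets(ttp, infer_scar(feats))
print(report)
```

```
target segment(s): 5 (basal inferolateral)
ranking: 5 > 11 > 6 > 16 > 12 > 15 > 13 > 7 > 1
excluded: 2[septal] 3[septal] 4[scar_visible;scar_thinning;akinetic;low_strain]
          8[septal] 9[septal] 10[scar_visible;scar_thinning;akinetic;low_strain] 14[septal]
```

The pipeline recovered the ground-truth latest eligible segment (5,
basal inferolateral, peak contraction at 65% RR); both scar segments
were excluded by three independent rules each, and the septum never
enters the ranking. Matching the synthetic venous tree and rendering the
three venography views:

```r
veins <- generate_vein_tree(lv$epi$frames[[1]], lv$frame, report$targets)
sub   <- vein_subtension(veins, lv$epi$frames[[1]],
                         assign_aha(lv$epi$frames[[1]], lv$frame), max_dist = 10)
pick_target_vein(report, sub)     # -> posterolateral branch, via segment 5
render_overlay_views(lv$endo$frames[[1]], lv$aha, report, veins, "overlay")
# -> overlay_PA.svg, overlay_RAO30.svg, overlay_LAO30.svg
```

And the hemodynamic outcome statistics from the study's printed counts
(10/12 = 83.3% of target-site vs 3/12 = 25.0% of nontarget-site
pacing positions with AHR > 10%):

```r
fisher_exact_2x2(matrix(c(10, 2, 3, 9), 2, byrow = TRUE))$p   # 0.0123
fisher_exact_2x2(matrix(c(4, 4, 5, 2), 2, byrow = TRUE))$p    # 0.6084
```

The numbered scripts under `analysis/` run these stages as a workflow
(`01_simulate_patient.R` … `05_hemodynamics.R`), writing their tables,
meshes and SVG overlays under `results/`. `run_pipeline()` performs the
whole chain in one call with a single YAML-serializable config and a
provenance manifest; a fixed config + seed reproduces every output file
byte for byte.

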