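---
title: "CT-guided CRT lead targeting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT-guided CRT lead targeting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtarget)
```

`crtarget` reconstructs a CT-guided workflow for choosing the left
ventricular (LV) pacing site in cardiac resynchronization therapy: find
the latest mechanically activating myocardium that is not scar, check
which coronary vein can reach it, and verify acutely (dP/dt~max~) and at
six months (LV end-systolic volume) that pacing there was worthwhile.
This vignette explains the models behind each stage, the tunable
parameters and their defaults, what the synthetic data generator does and
does not emulate, and the design decisions taken where the problem was
genuinely open.

## Coordinate conventions and the AHA model

All geometry lives in patient-space millimetres. The LV frame consists
of the long axis (unit vector, base → apex), the apex and basal-centroid
landmarks, and a septal direction orthogonal to the long axis that fixes
the circumferential origin. `fit_lv_frame()` takes the long axis from an
area-weighted principal component analysis of the surface (area
weighting removes the pole-density bias of structured meshes) and
orients it by picking the pointier extremity as apex; a mesh whose first
two principal extents differ by less than 15% has no identifiable long
axis and is rejected. The septal direction cannot be inferred from an
isolated endocardial surface — no right ventricle is in view — so it is
metadata: ground truth for synthetic meshes, user-supplied for real
ones.

Segments follow the standard AHA numbering: equal longitudinal thirds of
the apex-to-base extent (basal / mid / apical), six 60° sectors on the
basal and mid rings, four 90° sectors apically, with angle 0 at the
mid-septum increasing towards the anterior wall; in 17-segment mode the
most apical 15% becomes the apical cap. Strain bullseyes use the
16-segment model, scar polar maps the 17-segment variant, mirroring how
the two models are used in practice. Exact sector-boundary ties go to
the lower segment id, deterministically. Faces are attributed to
segments by majority vertex label, so segment areas always sum exactly
to the total surface area.

## Strain and time to peak contraction

Motion is Lagrangian with the end-diastolic frame (phase 0) as
reference; one cardiac cycle is 20 frames at 0–95% RR in 5% steps
(100% ≡ 0%). Three measures are computed per vertex:

* **Local area change** — the one-ring face area relative to reference,
  `(A − A₀)/A₀`. This is the default "contraction" scalar: it needs no
  direction field and is well defined everywhere except at degenerate
  rings.
* **Circumferential and longitudinal strain** — reference one-ring edges
  are expressed by their in-plane components in the local
  (circumferential, longitudinal) basis; deformed edges are projected
  onto the *deformed* tangent plane; and a symmetric 2×2 metric `C` is
  fit by least squares to the squared in-plane lengths. The engineering
  strains are `√C_cc − 1` and `√C_ll − 1`. Because only lengths of
  co-rotating projections enter, rigid motions give exactly zero strain
  (machine precision), uniform scaling by *s* gives exactly `s − 1`, and
  anisotropic scaling of a cylinder separates exactly into its
  components — the classical idealized verification problems.

Vertices are flagged and excluded from segment means where the long axis
is parallel to the surface normal (the apex tip), where a reference edge
has zero length, or where the metric fit is rank-deficient. Segment
curves are unweighted means over unflagged vertices (the segment-total
area variant is available via `area_mode`). Time to peak contraction is
the phase of the most negative value of the chosen measure, ties broken
to the earliest phase and flagged; a segment whose peak |area change|
is below the akinesis threshold (default 0.05) is flagged
`low_amplitude`.

A measurement caveat documented deliberately: one-ring neighbourhoods
(and majority-attributed faces) straddle segment boundaries, so each
segment's curve mixes a little of its neighbours' motion. On synthetic
wavefront activation patterns this shifts the noiseless grid argmin by
one 5% step for roughly 5% of segments at the default resolution;
isolated-delay and uniform patterns are recovered exactly. This is a
property of local surface measures, not of the noise model, and it is
the main reason target selection occasionally returns the second-ranked
segment (see below).

## The synthetic left ventricle

The generator is first-class, tested code; it defines the study
conditions for every property test.

* **Geometry** — prolate half-spheroid, long axis 80 mm, basal radius
  25 mm (a dilated LV), closed by a flat basal cap; default resolution
  20 rings × 30 circumferential samples (≈ 600 vertices, 4–6 mm edges,
  comparable to a decimated clinical endocardial mesh). The epicardium
  is the endocardium offset outward along vertex normals by the
  per-segment wall thickness (default 10 mm; scarred segments 4 mm).
* **Contraction** — each vertex moves radially towards the long axis,
  scaled by a raised-cosine pulse that peaks exactly at its segment's
  time to peak. The pulse half-width is `min(d, 100 − d, 25)` % RR:
  contraction occupies about half the cycle, matching systolic
  (isovolumic + ejection) duration at heart-failure heart rates, and the
  waveform is continuous across the 100% ≡ 0% wrap. Peak amplitude
  defaults to 0.12 (≈ 12–24% local area reduction depending on surface
  orientation); scar segments get 0.015, guaranteed below the akinesis
  threshold (the generator satisfies the scar-inference rules by
  construction). With `blend_iters > 0` the per-segment motion is mixed
  smoothly across boundaries through diffused membership weights; the
  default is 0 because any blending occasionally moves the noiseless
  grid argmin, and exact noiseless recovery is the property the strain
  stage is validated against. The smooth variant is used when exercising
  surface tracking, whose closest-point correspondence is blind to
  sliding at a motion discontinuity.
* **Activation patterns** — `random_motion_truth()` draws a spatially
  coherent wavefront, as in left-bundle-branch-block or right-ventricular
  pacing: earliest at the septum (25% RR), delay growing with angular
  distance towards a latest direction drawn uniformly on the free wall
  (150–270°), basal segments 5% later than apical ones, and 10% of
  segments jittered ±5% RR. Independent per-segment delays were
  rejected as unphysiological — no dyssynchronous ventricle scatters
  near-ties across the wall.
* **Noise** — isotropic Gaussian on vertex positions, σ = 0.3 mm
  (sub-voxel for modern CT), independent per frame, added last.
* **Hemodynamics** — per patient one target-site and one nontarget-site
  AHR drawn from N(14.4, 7.4²) and N(6.9, 5.9²) percent (the published
  group statistics), baseline dP/dt~max~ from N(900, 150²) mmHg/s
  truncated positive by redrawing, and the biventricular value
  back-computed so the stored AHR is exact.
* **Veins** — a CS trunk ring near the base plus branches descending
  along epicardial meridians (points 1 mm off the surface), at least one
  branch over every requested target segment, padded with standard
  anterior-interventricular / posterolateral branches; labels follow the
  branch's circumferential position.

What the generator does **not** emulate: CT image formation (contrast,
beam hardening, dual energy), papillary muscles and trabeculation,
through-wall (transmural) strain, absolute-time effects of the scanner's
66 ms temporal resolution (everything lives on the 5% RR grid), atrial
or right-ventricular anatomy, and respiratory/patient motion. Passing
tests therefore demonstrate the correctness of the *analysis logic*
under controlled conditions, not segmentation robustness on clinical
images.

## Cavity tracking

The voxel route exists so that the pipeline can consume binary
blood-pool volumes: `voxelize()` fills voxels whose centres are inside a
closed surface (z-ray parity with an irrational sub-voxel grid offset to
dodge degenerate hits), `segment_cavity()` keeps the 6-connected
component containing a seed, and `extract_surface()` runs marching
tetrahedra at the 0.5 level on a box-mollified field (one 3×3×3 pass by
default; more passes erode high-curvature regions). A voxelized 20 mm
sphere at 1 mm spacing recovers its volume to ~0.6% and its surface area
to ~0.3%.

`track_sequence()` replaces the proprietary deformable registration of
clinical platforms with a transparent two-stage scheme: rigid iterative
closest point (centroid + Procrustes, so rigid motions are recovered
exactly), then per-vertex closest-point displacement, Laplacian-smoothed
(10 iterations, weight 0.5 by default) and finally reprojected onto the
target surface — smoothing regularizes the tangential distribution of
correspondence but must not pull vertices off the surface, which would
fake local area change. Known limitations, stated rather than hidden:
closest-point correspondence cannot observe tangential sliding (the
aperture problem), and the sharp apex erodes under voxelization and
mollification, so the voxel route is validated segment-wise on the basal
and mid rings only; apical segments from the voxel route should not be
trusted at 1 mm spacing. The pipeline bypasses tracking when
correspondence-true meshes are supplied (the manifest carries the flag).

## Target selection and vein matching

Septal segments (2, 3, 8, 9, 14) are always excluded — septal pacing is
not a CRT target and septal "late activation" on a surface measure is
unreliable. Scar is inferred if any rule fires: visible scar label,
wall thickness < 6 mm, attenuation below a threshold (off unless
attenuation is supplied), or peak |area change| < 0.05. Eligible
segments are ranked by descending time to peak; ties break by larger
peak contraction, then lower segment id. The full ranking is retained so
that vein fallback has ordered alternatives.

A vein branch *subtends* a segment when at least 5 mm of its arc runs
within 10 mm of epicardial vertices carrying that segment's label (both
thresholds configurable; subtension is monotone in the distance gate).
The branch for the chosen target is the one subtending it with the
largest arc, tributaries preferred over the CS trunk; failing that, the
branch with the largest arc over a bullseye-adjacent, non-septal
segment is used and flagged as a fallback; failing that, the report says
so machine-readably.

C-arm projection is orthographic: patient coordinates (x = left,
y = anterior, z = cranial) are expressed in the detector frame by the
inverse C-arm rotation `Rx(−cran) · Rz(−raolao)` and the depth
coordinate is dropped, so PA (0°, 0°) drops exactly the
anterior–posterior axis and LAO 90° is a left-lateral view.
Perspective (cone-beam) geometry is an extension point; vendor
source-detector distances are not public. Overlays are deterministic
SVG (fixed `%.4f` formatting): mesh silhouette, target-segment outline,
vein polylines, plus a 16-segment bullseye sidecar.

## Hemodynamics and statistics

`ahr()` is the percent change of dP/dt~max~ from baseline to
biventricular pacing; a site responds if its mean AHR exceeds 10%
(strict `>` by default with a `strict = FALSE` switch to `≥` — both
operator conventions appear in the literature for this cutoff, and the
same switch exists for the 15% LV end-systolic volume remodeling
threshold). The two-sided exact test for 2×2 tables uses the
minimum-likelihood rule — the sum of hypergeometric probabilities of all
tables, margins fixed, whose point probability does not exceed the
observed one (relative slack 10⁻⁷) — which reproduces the printed
p-values .012 (10/12 vs 3/12 responders) and .608 (4/8 vs 5/7
remodeling by etiology); the doubling rule would not necessarily.
Paired target-vs-nontarget comparisons wrap the standard paired t and
Wilcoxon signed-rank tests, with degenerate inputs (zero-variance
differences) flagged instead of erroring mid-pipeline.

Because the study's per-patient raw values are not printed, cohort-level
claims are covered by property-style simulation: at the published group
parameters with 12 pairs, strictly more target than nontarget sites are
classified responders in ≈ 97.7% of cohorts — that figure is a
mathematical consequence of the two binomials involved
(P(T > N) = 0.977, ties 0.015), and the acceptance script reports the
simulated rate rather than asserting an unattainable higher one.

## Problem sizes and determinism

The test suite and acceptance script use the default 600-vertex LV at 20
phases; the property tests run 100 synthetic patients for recovery and
selection, 50 seeded venous trees, and 1000 hemodynamic cohorts, all in
a few minutes total. Every generator consumes an explicit seed and every
pipeline output (JSON, CSV, SVG, PLY) is byte-stable under a fixed
config + seed; the run directory carries a provenance manifest with the
config checksum. The exact-test implementation is verified against
brute-force enumeration over all margins up to n = 30 and against the
standard library implementation on random tables.
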