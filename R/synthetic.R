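#' Ground-truth motion and tissue description for the synthetic LV
#'
#' Holds, per AHA segment (16-segment model), the phase of peak contraction
#' (time-to-peak, percent RR on the 5% grid), the peak contraction
#' amplitude (fraction of local area lost at peak; positive magnitude),
#' the scar set, per-segment wall thickness (mm) and an HU-like
#' attenuation scalar. Scar segments are constrained by construction to
#' satisfy the downstream scar-inference thresholds: their amplitude is
#' below the akinesis threshold and their thickness below the thinning
#' threshold (closure property).
#'
#' @param ttp named or positional numeric vector of 16 time-to-peak values
#'   (percent RR, multiples of 5 in \[0, 95\]).
#' @param amplitude peak contraction amplitude per segment (fraction,
#'   e.g. 0.12 means roughly 12--24% local area reduction at peak
#'   depending on surface orientation).
#' @param scar_segments integer vector of scarred AHA ids (may be empty).
#' @param wall_thickness per-segment thickness in mm.
#' @param attenuation per-segment HU-like value.
#' @param scar_amplitude,scar_thickness,scar_attenuation values imposed on
#'   scar segments (defaults keep them under the 0.05 akinesis / 6 mm
#'   thinning thresholds).
#' @return An object of class `motion_truth`.
#' @export
motion_truth <- function(ttp, amplitude = rep(0.12, 16),
                         scar_segments = integer(),
                         wall_thickness = rep(10, 16),
                         attenuation = rep(90, 16),
                         scar_amplitude = 0.015,
                         scar_thickness = 4,
                         scar_attenuation = 35) {
  ttp <- as.numeric(ttp)
  if (length(ttp) != 16L) stop("ttp must have 16 values")
  if (any(ttp < 0 | ttp > 95 | ttp %% 5 != 0))
    stop("time-to-peak values must lie on the 5% grid in [0, 95]")
  amplitude <- rep_len(as.numeric(amplitude), 16L)
  wall_thickness <- rep_len(as.numeric(wall_thickness), 16L)
  attenuation <- rep_len(as.numeric(attenuation), 16L)
  scar_segments <- sort(unique(as.integer(scar_segments)))
  if (length(scar_segments) && (min(scar_segments) < 1 || max(scar_segments) > 16))
    stop("scar segments must be AHA ids in 1..16")
  amplitude[scar_segments] <- scar_amplitude
  wall_thickness[scar_segments] <- scar_thickness
  attenuation[scar_segments] <- scar_attenuation
  structure(list(ttp = ttp, amplitude = amplitude,
                 scar_segments = scar_segments,
                 wall_thickness = wall_thickness, attenuation = attenuation),
            class = "motion_truth")
}

#' @rdname motion_truth
#' @details `default_motion_truth()` is a plausible dyssynchronous LV:
#' early septal activation, progressively later free-wall activation with
#' the latest segment basal inferolateral (segment 5) at 65% RR.
#' `random_motion_truth()` draws per-segment delays uniformly from
#' \{25, 30, ..., 70\}% RR and optionally scars random non-septal segments.
#' @export
default_motion_truth <- function(scar_segments = integer()) {
  ttp <- c(40, 25, 25, 45, 65, 55,   # basal ring
           40, 25, 30, 45, 60, 55,   # mid ring
           35, 30, 40, 50)           # apical
  motion_truth(ttp, scar_segments = scar_segments)
}

#' @rdname motion_truth
#' @param seed RNG seed.
#' @param n_scar number of scar segments to draw (from non-septal ids).
#' @details `random_motion_truth()` draws a spatially coherent activation
#' wavefront, as in left-bundle-branch-block or right-ventricular-paced
#' dyssynchrony: the septum activates earliest and the delay grows with
#' circumferential distance towards a randomly placed latest-activation
#' direction on the free wall (lateral to inferior), plus small on-grid
#' per-segment jitter. Independent per-segment delays would scatter
#' near-ties all over the wall, which no dyssynchronous ventricle does.
#' @export
random_motion_truth <- function(seed = 1L, n_scar = 0L) {
  set.seed(seed)
  # circumferential centre angle (deg) of each segment, angle 0 mid-septum
  centres <- c(90, 30, 330, 270, 210, 150,   # basal
               90, 30, 330, 270, 210, 150,   # mid
               90, 0, 270, 180)              # apical
  theta_late <- stats::runif(1, 150, 270)    # latest direction on free wall
  t_early <- 25
  t_late <- sample(seq(55, 70, by = 5), 1)
  dang <- abs(centres - theta_late)
  dang <- pmin(dang, 360 - dang)
  delay <- t_late - (t_late - t_early) * dang / 180
  # apex-to-base component: latest activation is typically basal
  delay <- delay + rep(c(5, 0, -5), c(6, 6, 4))
  # occasional local deviation from the smooth wavefront
  delay <- delay + sample(c(-5, 0, 5), 16, replace = TRUE,
                          prob = c(0.05, 0.9, 0.05))
  ttp <- pmin(pmax(5 * round(delay / 5), 15), 85)
  scar <- integer()
  if (n_scar > 0) {
    pool <- setdiff(1:16, aha_septal_segments())
    scar <- sample(pool, n_scar)
  }
  motion_truth(ttp, scar_segments = scar)
}

#' Synthetic LV generator configuration
#'
#' @param n_rings,n_phi mesh resolution of the prolate half-spheroid.
#' @param phases cardiac phases (percent RR, 5% grid; default 20 frames).
#' @param length_mm,basal_radius_mm long-axis length and basal radius of
#'   the end-diastolic endocardium (typical dilated-LV scale).
#' @param noise_sd isotropic Gaussian positional noise, mm (sub-voxel for
#'   submillimetre CT; default 0.3).
#' @param blend_iters smoothing passes applied to the per-segment motion
#'   weights so the displacement field blends smoothly across segment
#'   boundaries (a real myocardium has no motion discontinuities). The
#'   default 0 keeps the motion piecewise-constant by segment, which makes
#'   noiseless time-to-peak recovery exact on the 5% grid; use 1-2 when a
#'   spatially smooth surface matters more than grid-exact delays (e.g.
#'   when exercising surface tracking).
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_rings = 20L, n_phi = 30L,
                         phases = seq(0, 95, by = 5),
                         length_mm = 80, basal_radius_mm = 25,
                         noise_sd = 0.3, blend_iters = 0L, seed = 1L) {
  if (any(phases %% 5 != 0) || phases[1] != 0 || any(phases < 0 | phases > 95))
    stop("phases must be multiples of 5 in [0, 95] starting at 0")
  structure(list(n_rings = as.integer(n_rings), n_phi = as.integer(n_phi),
                 phases = as.numeric(phases), length_mm = length_mm,
                 basal_radius_mm = basal_radius_mm,
                 noise_sd = noise_sd, blend_iters = as.integer(blend_iters),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# raised-cosine contraction pulse: 0 at phase 0, peak value 1 exactly at
# the delay d, half-width min(d, 100 - d, 25) so the waveform is
# periodic-continuous across the 100% == 0% wrap; the 25% RR half-width
# makes the contraction span about half the cycle, matching systolic
# (isovolumic + ejection) duration at heart-failure heart rates
contraction_pulse <- function(phase, delay, max_halfwidth = 25) {
  n <- max(length(phase), length(delay))
  phase <- rep_len(phase, n); delay <- rep_len(delay, n)
  w <- pmin(delay, 100 - delay, max_halfwidth)
  dx <- abs(phase - delay)
  out <- numeric(n)
  inside <- w > 0 & dx < w
  out[inside] <- 0.5 * (1 + cos(pi * dx[inside] / w[inside]))
  out
}

#' Generate a dynamic synthetic LV (endocardium + epicardium)
#'
#' Builds an end-diastolic prolate half-spheroid endocardium, assigns AHA
#' labels in the ground-truth frame, and contracts each vertex radially
#' towards the long axis with a raised-cosine pulse peaking exactly at its
#' segment's true time-to-peak; with `blend_iters > 0` the per-segment
#' motion is mixed smoothly across segment boundaries. Scar segments
#' receive the truth's (small) scar amplitude. The epicardium is the
#' endocardium offset outward along vertex normals by the per-segment
#' wall thickness and is animated with the same motion model. Isotropic
#' Gaussian positional noise is added last, to every frame. Vertex
#' correspondence is exact by construction.
#'
#' @param cfg a [synth_config()].
#' @param truth a [motion_truth()].
#' @return List with `endo` and `epi` [mesh_sequence()]s, the ground-truth
#'   `frame` ([lv_frame()]), the `aha` map of the reference endocardium,
#'   and `truth` echoed back.
#' @export
generate_lv_sequence <- function(cfg = synth_config(),
                                 truth = default_motion_truth()) {
  set.seed(cfg$seed)
  endo0 <- mesh_prolate_lv(cfg$length_mm, cfg$basal_radius_mm,
                           cfg$n_rings, cfg$n_phi)
  frame <- lv_frame(apex = c(0, 0, -cfg$length_mm),
                    base_centroid = c(0, 0, 0),
                    long_axis = c(0, 0, -1), septal_dir = c(1, 0, 0))
  aha <- assign_aha(endo0, frame, 16L)
  nrm <- vertex_normals(endo0)
  epi0 <- phase_mesh(endo0$vertices +
                       nrm * truth$wall_thickness[aha$vertex_labels],
                     endo0$faces, 0)

  # per-vertex segment-membership weights, diffused across the mesh so the
  # displacement field is smooth at segment boundaries (rows sum to 1)
  W <- matrix(0, nrow(endo0$vertices), 16L)
  W[cbind(seq_len(nrow(W)), aha$vertex_labels)] <- 1
  if (cfg$blend_iters > 0) {
    nb <- vertex_one_rings(endo0)$neighbours
    for (it in seq_len(cfg$blend_iters)) {
      avg <- W
      for (v in seq_len(nrow(W)))
        if (length(nb[[v]])) avg[v, ] <- colMeans(W[nb[[v]], , drop = FALSE])
      W <- 0.5 * W + 0.5 * avg
    }
  }

  animate <- function(mesh0) {
    xy <- mesh0$vertices[, 1:2]
    lapply(cfg$phases, function(p) {
      seg_pulse <- truth$amplitude * contraction_pulse(p, truth$ttp)
      s <- 1 - drop(W %*% seg_pulse)
      v <- mesh0$vertices
      v[, 1:2] <- xy * s
      if (cfg$noise_sd > 0)
        v <- v + matrix(stats::rnorm(length(v), sd = cfg$noise_sd), ncol = 3)
      phase_mesh(v, mesh0$faces, p)
    })
  }
  endo <- mesh_sequence(animate(endo0), correspondence = TRUE, layer = "endo")
  epi <- mesh_sequence(animate(epi0), correspondence = TRUE, layer = "epi")
  list(endo = endo, epi = epi, frame = frame, aha = aha, truth = truth)
}

#' Generate a synthetic coronary venous tree on the epicardium
#'
#' Emits a coronary-sinus (CS) trunk polyline circling the base just
#' outside the epicardial surface plus branch polylines running
#' apex-wards along epicardial meridians, with at least one branch
#' overlying each requested target segment. Additional standard branches
#' (anterior interventricular, posterolateral) are added so the tree has
#' 2--4 branches. Branch labels follow the branch's circumferential
#' position (anterior_interventricular / lateral / posterolateral / other).
#'
#' @param epi reference (phase 0) epicardial [phase_mesh()].
#' @param frame the [lv_frame()].
#' @param target_segments AHA ids (1..16) each of which must be subtended
#'   by at least one branch; may be empty (CS trunk only).
#' @param surface_offset radial offset of vein points off the epicardium, mm.
#' @param step_mm approximate spacing of polyline points, mm.
#' @return An object of class `vein_tree`: list of branches, each with a
#'   `label` and an ordered k x 3 `points` polyline (mm).
#' @export
generate_vein_tree <- function(epi, frame, target_segments = integer(),
                               surface_offset = 1, step_mm = 3) {
  target_segments <- as.integer(target_segments)
  if (length(target_segments) &&
      (min(target_segments) < 1 || max(target_segments) > 16))
    stop("unreachable segment requested: ids must be in 1..16")
  co <- lv_coordinates(epi, frame)
  nrm <- vertex_normals(epi)
  # nearest epicardial vertex to a requested (t, theta), offset outward
  surf_point <- function(t, theta) {
    dth <- pmin(abs(co$theta - theta), 360 - abs(co$theta - theta)) / 180
    d2 <- (co$t - t)^2 + dth^2
    i <- which.min(d2)
    epi$vertices[i, ] + surface_offset * nrm[i, ]
  }
  # CS trunk: ring near the base
  trunk_theta <- seq(0, 350, by = 10)
  trunk <- t(vapply(trunk_theta, function(th) surf_point(0.92, th),
                    numeric(3)))
  branches <- list(list(label = "CS", points = trunk))

  seg_centre <- function(seg) {
    sel <- which(assign_aha(epi, frame, 16L)$vertex_labels == seg)
    th <- co$theta[sel]
    # circular mean of the segment's vertex angles
    (atan2(mean(sin(th * pi / 180)), mean(cos(th * pi / 180))) * 180 / pi) %% 360
  }
  ring_of <- function(seg) if (seg <= 6) "basal" else if (seg <= 12) "mid" else "apical"
  t_reach <- c(basal = 0.55, mid = 0.3, apical = 0.1)

  label_for <- function(theta) {
    if (theta < 60 || theta >= 300) "anterior_interventricular"
    else if (theta < 180 && theta >= 120) "lateral"
    else if (theta >= 180 && theta < 270) "posterolateral"
    else "other"
  }
  add_branch <- function(theta, t_lo) {
    n_pts <- max(2L, ceiling((0.9 - t_lo) * 60 / step_mm * 2))
    ts <- seq(0.9, t_lo, length.out = n_pts)
    pts <- t(vapply(ts, function(t) surf_point(t, theta), numeric(3)))
    branches[[length(branches) + 1L]] <<-
      list(label = label_for(theta), points = pts)
  }
  covered <- numeric()
  for (seg in target_segments) {
    th <- seg_centre(seg)
    add_branch(th, t_reach[[ring_of(seg)]])
    covered <- c(covered, th)
  }
  # pad with standard branches away from already-covered angles
  for (th in c(330, 215, 150)) {
    if (length(branches) - 1L >= max(2L, length(target_segments))) break
    if (!length(covered) ||
        all(pmin(abs(covered - th), 360 - abs(covered - th)) > 40))
      add_branch(th, 0.3)
  }
  structure(list(branches = branches), class = "vein_tree")
}

#' @export
print.vein_tree <- function(x, ...) {
  cat(sprintf("vein_tree: %d branches (%s)\n", length(x$branches),
              paste(vapply(x$branches, `[[`, character(1), "label"),
                    collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic hemodynamic cohort
#'
#' Per patient, one target-site and one nontarget-site acute hemodynamic
#' response (AHR, percent change in dP/dt_max from baseline to
#' biventricular pacing) drawn from two normal distributions; defaults are
#' the observed target / nontarget group statistics (14.4 +/- 7.4% vs
#' 6.9 +/- 5.9%). Baseline dP/dt_max is normal(900, 150) mmHg/s truncated
#' positive (redrawn if non-positive); the biventricular value is
#' back-computed so the stored AHR is exact.
#'
#' @param n_patients number of patients (one paired site couple each).
#' @param mu_target,mu_nontarget mean AHR (%) at target / nontarget sites.
#' @param sigma AHR standard deviation(s), length 1 or 2
#'   (target, nontarget).
#' @param baseline_mean,baseline_sd baseline dP/dt_max distribution
#'   (mmHg/s).
#' @param seed RNG seed.
#' @return data.frame with one row per pacing site: `patient`, `site`
#'   (`"target"`/`"nontarget"`), `is_target`, `baseline`, `biv`, `ahr`.
#' @export
generate_hemo_cohort <- function(n_patients = 12L,
                                 mu_target = 14.4, mu_nontarget = 6.9,
                                 sigma = c(7.4, 5.9),
                                 baseline_mean = 900, baseline_sd = 150,
                                 seed = 1L) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  sigma <- rep_len(sigma, 2L)
  if (any(sigma < 0)) stop("sigma must be non-negative")
  set.seed(seed)
  draw_baseline <- function(n) {
    b <- stats::rnorm(n, baseline_mean, baseline_sd)
    while (any(b <= 0))                       # truncate positive by redraw
      b[b <= 0] <- stats::rnorm(sum(b <= 0), baseline_mean, baseline_sd)
    b
  }
  ahr_t <- stats::rnorm(n_patients, mu_target, sigma[1])
  ahr_n <- stats::rnorm(n_patients, mu_nontarget, sigma[2])
  base <- draw_baseline(2L * n_patients)
  out <- data.frame(
    patient = rep(seq_len(n_patients), 2L),
    site = rep(c("target", "nontarget"), each = n_patients),
    is_target = rep(c(TRUE, FALSE), each = n_patients),
    baseline = base,
    ahr = c(ahr_t, ahr_n))
  out$biv <- out$baseline * (1 + out$ahr / 100)
  out[order(out$patient, -out$is_target),
      c("patient", "site", "is_target", "baseline", "biv", "ahr")]
}
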