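# Independent oracles used across the suite; deliberately kept free of the
# package's own computational paths.

# Fisher two-sided p by brute-force enumeration over all admissible tables
# with the observed margins, point probability from the factorial formula.
fisher_bruteforce <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  ptab <- function(a) {
    b <- r1 - a; c3 <- c1 - a; d <- r2 - c3
    if (min(b, c3, d) < 0) return(0)
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
          lfactorial(n - c1) - lfactorial(n) - lfactorial(a) -
          lfactorial(b) - lfactorial(c3) - lfactorial(d))
  }
  probs <- vapply(0:min(r1, c1), ptab, numeric(1))
  p_obs <- ptab(tab[1, 1])
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# rotation matrix about an arbitrary unit axis (Rodrigues), independent of
# the package's axis-specific rotation helpers
rot_axis_angle <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
              byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# even-odd point-in-polygon test for 2D overlay checks
point_in_polygon <- function(pt, poly) {
  n <- nrow(poly); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2]) &&
        pt[1] < (poly[j, 1] - poly[i, 1]) * (pt[2] - poly[i, 2]) /
          (poly[j, 2] - poly[i, 2]) + poly[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

# canonical ground-truth frame of the synthetic LV
truth_frame <- function(length_mm = 80) {
  lv_frame(c(0, 0, -length_mm), c(0, 0, 0), c(0, 0, -1), c(1, 0, 0))
}

# latest eligible (non-septal, non-scar) segments of a motion truth,
# computed directly from the truth delays
truth_latest_eligible <- function(truth) {
  elig <- setdiff(setdiff(1:16, aha_septal_segments()), truth$scar_segments)
  elig[truth$ttp[elig] == max(truth$ttp[elig])]
}

# run the dyssynchrony stage on one synthetic patient and return the
# time-to-peak map plus objects needed downstream
run_dyssynchrony <- function(truth, seed, noise_sd = 0.3,
                             n_rings = 20L, n_phi = 30L) {
  lv <- generate_lv_sequence(
    synth_config(n_rings = n_rings, n_phi = n_phi, noise_sd = noise_sd,
                 seed = seed), truth)
  st <- compute_strains(lv$endo, lv$frame, measures = "area")
  cv <- aggregate_segments(st, lv$aha)
  list(lv = lv, curves = cv, ttp = time_to_peak(cv))
}

# scar feature table as the pipeline assembles it
features_from_truth <- function(truth, ttp) {
  data.frame(segment = 1:16,
             visible_scar = 1:16 %in% truth$scar_segments,
             wall_thickness = truth$wall_thickness,
             peak_area_change = ttp$peak[match(1:16, ttp$segment)],
             attenuation = truth$attenuation)
}
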