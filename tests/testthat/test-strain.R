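cyl_frame <- lv_frame(c(0, 0, -60), c(0, 0, 0), c(0, 0, -1), c(1, 0, 0))

test_that("local directions are orthonormal and follow cylinder symmetry", {
  cyl <- mesh_cylinder()
  d <- local_directions(cyl, cyl_frame)
  # interior vertices only: the open tube's rim normals are one-sided
  ok <- !d$flagged & cyl$vertices[, 3] < -2 & cyl$vertices[, 3] > -58
  expect_true(all(abs(rowSums(d$circ[ok, ] * d$long[ok, ])) < 1e-10))
  expect_true(all(abs(rowSums(d$circ[ok, ]^2) - 1) < 1e-10))
  # longitudinal direction parallel to the axis on a cylinder
  expect_true(all(abs(abs(d$long[ok, 3]) - 1) < 1e-10))
  expect_true(all(abs(d$circ[ok, 3]) < 1e-10))
  # circumferential vectors tangent to the circles (orthogonal to radius)
  rad <- cbind(cyl$vertices[ok, 1:2] / 20, 0)
  expect_true(all(abs(rowSums(d$circ[ok, ] * rad)) < 1e-10))
})

test_that("local directions co-rotate with a rigid motion", {
  cyl <- mesh_cylinder(n_z = 10L, n_phi = 24L)
  d0 <- local_directions(cyl, cyl_frame)
  R <- rot_axis_angle(c(1, -0.4, 0.2), 29)
  cr <- phase_mesh(cyl$vertices %*% t(R), cyl$faces, 0)
  frr <- lv_frame(drop(R %*% cyl_frame$apex), drop(R %*% cyl_frame$base_centroid),
                  drop(R %*% cyl_frame$long_axis), drop(R %*% cyl_frame$septal_dir))
  dr <- local_directions(cr, frr)
  ok <- !d0$flagged & !dr$flagged
  expect_lt(max(abs(dr$circ[ok, ] - d0$circ[ok, ] %*% t(R))), 1e-9)
  expect_lt(max(abs(dr$long[ok, ] - d0$long[ok, ] %*% t(R))), 1e-9)
})

test_that("rigid motion produces zero strain to machine precision", {
  cyl <- mesh_cylinder()
  R <- rot_axis_angle(c(0.2, 1, 0.7), 41)
  rg <- phase_mesh(cyl$vertices %*% t(R) + rep(c(3, -7, 2), each = nrow(cyl$vertices)),
                   cyl$faces, 5)
  st <- compute_strains(mesh_sequence(list(cyl, rg)), cyl_frame)
  ok <- !st$flagged
  expect_lt(max(abs(st$circ[ok, 2])), 1e-9)
  expect_lt(max(abs(st$long[ok, 2])), 1e-9)
  expect_lt(max(abs(st$area[ok, 2])), 1e-9)
  # reference frame strain is identically zero
  expect_true(all(abs(st$area[ok, 1]) < 1e-12))
  expect_true(all(abs(st$circ[ok, 1]) < 1e-12))
})

test_that("uniform scaling matches the engineering-strain closed form", {
  cyl <- mesh_cylinder()
  sc <- phase_mesh(cyl$vertices * 1.1, cyl$faces, 5)
  st <- compute_strains(mesh_sequence(list(cyl, sc)), cyl_frame)
  ok <- !st$flagged
  expect_lt(max(abs(st$circ[ok, 2] - 0.1)), 1e-6)
  expect_lt(max(abs(st$long[ok, 2] - 0.1)), 1e-6)
  expect_lt(max(abs(st$area[ok, 2] - 0.21)), 1e-6)
})

test_that("anisotropic cylinder scaling separates the strain components", {
  cyl <- mesh_cylinder()
  an <- phase_mesh(cbind(cyl$vertices[, 1] * 1.2, cyl$vertices[, 2] * 1.2,
                         cyl$vertices[, 3]), cyl$faces, 5)
  st <- compute_strains(mesh_sequence(list(cyl, an)), cyl_frame)
  ok <- !st$flagged
  expect_lt(max(abs(st$circ[ok, 2] - 0.2)), 1e-6)
  expect_lt(max(abs(st$long[ok, 2])), 1e-6)
})

test_that("apex-tip vertices are flagged and excluded from aggregation", {
  m <- mesh_prolate_lv(n_rings = 12L, n_phi = 18L)
  fr <- truth_frame()
  d <- local_directions(m, fr)
  apex_vertex <- which.min(m$vertices[, 3])
  expect_true(d$flagged[apex_vertex])
  st <- compute_strains(mesh_sequence(list(m, phase_mesh(m$vertices * 1.05, m$faces, 5))), fr)
  aha <- assign_aha(m, fr, 16L)
  cv <- aggregate_segments(st, aha)
  expect_true(all(is.finite(cv$area)))
})

test_that("segment aggregation reproduces hand-computable means", {
  # two-segment fixture: known per-vertex values split over two labels
  vals <- matrix(c(rep(1, 4), rep(3, 6)), ncol = 1)
  strains <- structure(list(area = cbind(vals, vals * 2),
                            phases = c(0, 5), flagged = rep(FALSE, 10)),
                       class = "vertex_strains")
  aha <- structure(list(n_segments = 2L,
                        vertex_labels = c(rep(1L, 4), rep(2L, 6))),
                   class = "aha_map")
  cv <- aggregate_segments(strains, aha)
  expect_equal(unname(cv$area[, 1]), c(1, 3))
  expect_equal(unname(cv$area[, 2]), c(2, 6))
  # identical values give that value in every segment
  strains$area[] <- 0.4
  expect_true(all(aggregate_segments(strains, aha)$area == 0.4))
})

test_that("time to peak handles ties, flats, and unique minima", {
  phases <- seq(0, 95, 5)
  mk <- function(v) structure(list(area = matrix(v, nrow = 1), phases = phases),
                              class = "segment_curves")
  unique_min <- -0.2 * exp(-((phases - 40) / 12)^2)
  tp <- time_to_peak(mk(unique_min))
  expect_equal(tp$ttp, 40)
  expect_false(tp$low_amplitude)
  flat <- rep(0, 20)
  tpf <- time_to_peak(mk(flat))
  expect_equal(tpf$ttp, 0)
  expect_true(tpf$low_amplitude)
  two_min <- rep(0, 20); two_min[c(8, 12)] <- -0.3
  tpt <- time_to_peak(mk(two_min))
  expect_equal(tpt$ttp, phases[8])   # earliest of the tied minima
  expect_true(tpt$tie)
})

test_that("segment-total area mode agrees with vertex mean on smooth motion", {
  truth <- default_motion_truth()
  lv <- generate_lv_sequence(synth_config(noise_sd = 0, n_rings = 16L,
                                          n_phi = 24L), truth)
  st <- compute_strains(lv$endo, lv$frame, measures = "area")
  cv_v <- aggregate_segments(st, lv$aha)
  cv_t <- aggregate_segments(st, lv$aha, seq = lv$endo,
                             area_mode = "segment_total")
  expect_equal(time_to_peak(cv_t)$ttp, time_to_peak(cv_v)$ttp)
})
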