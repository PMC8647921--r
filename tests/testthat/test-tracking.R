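test_that("voxelization recovers analytic volume and refines with spacing", {
  sp <- mesh_sphere(20, 32, 48)
  vol1 <- voxelize(sp, 1)
  vtrue <- 4 / 3 * pi * 20^3
  err1 <- abs(sum(vol1$data) * 1 - vtrue) / vtrue
  expect_lt(err1, 0.03)
  vol2 <- voxelize(sp, 2)
  err2 <- abs(sum(vol2$data) * 8 - vtrue) / vtrue
  expect_lt(err1, err2)            # halving the spacing reduces the error
})

test_that("voxelization rejects open meshes and out-of-grid meshes", {
  expect_error(voxelize(mesh_cylinder(), 2), "closed")
  sp <- mesh_sphere(20, 16, 24)
  expect_error(voxelize(sp, 1, origin = c(100, 100, 100), dims = c(10L, 10L, 10L)),
               "outside")
})

test_that("cavity segmentation keeps only the seeded component", {
  a <- array(0L, c(30, 30, 30))
  a[5:12, 5:12, 5:12] <- 1L       # cavity A
  a[20:26, 20:26, 20:26] <- 1L    # cavity B
  a[16, 16, 16] <- 1L             # speckle
  vol <- binary_volume(a, c(1, 1, 1), c(0, 0, 0))
  segA <- segment_cavity(vol, c(7, 7, 7))
  expect_equal(sum(segA$data), 8^3)
  expect_equal(sum(segA$data[20:26, 20:26, 20:26]), 0)
  # noiseless single-cavity volume is unchanged
  clean <- binary_volume(a * 0 + (a & (seq_len(30) < 15)[slice.index(a, 1)]),
                         c(1, 1, 1))
  seg1 <- segment_cavity(clean, c(7, 7, 7))
  expect_identical(seg1$data, clean$data)
  expect_error(segment_cavity(vol, c(1, 1, 1)), "not foreground")
})

test_that("isosurface extraction is closed and metrically accurate", {
  sp <- mesh_sphere(20, 32, 48)
  vol <- voxelize(sp, 1)
  surf <- extract_surface(vol)
  expect_true(crtarget:::is_closed_mesh(surf))
  atrue <- 4 * pi * 400
  expect_lt(abs(sum(face_areas(surf)) - atrue) / atrue, 0.05)
  expect_lt(mean_surface_distance(surf, sp), 1)    # < voxel spacing
  # single voxel still yields a valid closed surface
  a <- array(0L, c(3, 3, 3)); a[2, 2, 2] <- 1L
  s1 <- extract_surface(binary_volume(a))
  expect_true(crtarget:::is_closed_mesh(s1))
  expect_error(extract_surface(binary_volume(array(0L, c(4, 4, 4)))), "empty")
})

test_that("tracking recovers rigid translations to sub-0.1 mm", {
  lv <- generate_lv_sequence(synth_config(noise_sd = 0, n_rings = 14L,
                                          n_phi = 20L), default_motion_truth())
  ref <- lv$endo$frames[[1]]
  tgt <- phase_mesh(ref$vertices + rep(c(5, 0, 0), each = nrow(ref$vertices)),
                    ref$faces, 5)
  seqt <- track_sequence(ref, list(tgt))
  disp <- seqt$frames[[2]]$vertices - ref$vertices
  expect_lt(max(abs(sweep(disp, 2, c(5, 0, 0)))), 0.1)
  # identical target gives zero displacement
  seqi <- track_sequence(ref, list(phase_mesh(ref$vertices, ref$faces, 5)))
  expect_lt(max(abs(seqi$frames[[2]]$vertices - ref$vertices)), 1e-9)
})

test_that("tracking errors out beyond the gate distance", {
  # a grossly mismatched target shape leaves residuals no rigid alignment
  # can absorb (a pure translation would be recovered by the ICP stage)
  m <- mesh_prolate_lv(n_rings = 8L, n_phi = 12L)
  blob <- mesh_sphere(4, 10, 14)
  far <- phase_mesh(blob$vertices, blob$faces, 5)
  expect_error(track_sequence(m, list(far), gate_mm = 10), "gate")
})

test_that("tracked contraction reproduces downstream time-to-peak", {
  # blended (spatially smooth) motion: closest-point correspondence cannot
  # see sliding across a motion discontinuity, and real surfaces have none
  truth <- default_motion_truth()
  lv <- generate_lv_sequence(synth_config(noise_sd = 0, blend_iters = 2L),
                             truth)
  tracked <- track_sequence(lv$endo$frames[[1]], lv$endo$frames[-1])
  st <- compute_strains(tracked, lv$frame, measures = "area")
  tp <- time_to_peak(aggregate_segments(st, lv$aha))
  expect_true(all(abs(tp$ttp - truth$ttp) <= 5))
})

test_that("voxelize-extract-track agrees with true correspondence", {
  # one mid-systolic phase: segment-mean area change from the tracked
  # isosurface matches the corresponded ground truth on the basal and mid
  # rings; apical segments are excluded (the sharp apex erodes under
  # voxelization and isosurface mollification at 1 mm voxels)
  truth <- default_motion_truth()
  cfg <- synth_config(noise_sd = 0, blend_iters = 2L, phases = c(0, 40))
  lv <- generate_lv_sequence(cfg, truth)
  vol <- voxelize(lv$endo$frames[[2]], 1)
  vol$phase <- 40
  tracked <- track_sequence(lv$endo$frames[[1]], list(vol))
  cv_t <- aggregate_segments(compute_strains(tracked, lv$frame, "area"), lv$aha)
  cv_c <- aggregate_segments(compute_strains(lv$endo, lv$frame, "area"), lv$aha)
  expect_lt(max(abs(cv_t$area[1:12, 2] - cv_c$area[1:12, 2]), na.rm = TRUE),
            0.1)
})
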