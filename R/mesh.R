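#' Triangulated surface mesh at one cardiac phase
#'
#' A `phase_mesh` is the basic surface container of the package: a vertex
#' matrix in patient-space millimetres, a triangle index matrix and the
#' cardiac phase the surface belongs to. One cardiac cycle is sampled at
#' 0--95% of the RR interval in 5% increments (20 frames; 100% is the same
#' frame as 0%).
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param phase cardiac phase in percent RR; must lie on the 5% grid
#'   \{0, 5, ..., 95\}.
#' @return An object of class `phase_mesh`.
#' @export
phase_mesh <- function(vertices, faces, phase = 0) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("faces index vertices outside 1..n")
  check_phase(phase)
  structure(list(vertices = vertices, faces = faces, phase = phase),
            class = "phase_mesh")
}

check_phase <- function(phase) {
  if (length(phase) != 1L || is.na(phase) || phase < 0 || phase > 95 ||
      phase %% 5 != 0)
    stop("phase must be a single value in {0, 5, ..., 95}")
  invisible(phase)
}

#' @export
print.phase_mesh <- function(x, ...) {
  cat(sprintf("phase_mesh: %d vertices, %d faces, phase %g%% RR\n",
              nrow(x$vertices), nrow(x$faces), x$phase))
  invisible(x)
}

#' Vertex-corresponded mesh sequence over the cardiac cycle
#'
#' All frames share the vertex count and face list; when `correspondence`
#' is `TRUE`, vertex i denotes the same material point in every frame and
#' frame 1 (phase 0) is the end-diastolic reference used for Lagrangian
#' strain.
#'
#' @param frames list of [phase_mesh()] objects ordered by phase.
#' @param correspondence logical; vertex i is the same material point in
#'   every frame.
#' @param layer `"endo"` or `"epi"`.
#' @return An object of class `mesh_sequence`.
#' @export
mesh_sequence <- function(frames, correspondence = TRUE,
                          layer = c("endo", "epi")) {
  layer <- match.arg(layer)
  if (!length(frames)) stop("empty frame list")
  if (!all(vapply(frames, inherits, logical(1), "phase_mesh")))
    stop("all frames must be phase_mesh objects")
  nv <- nrow(frames[[1]]$vertices)
  f0 <- frames[[1]]$faces
  for (fr in frames) {
    if (nrow(fr$vertices) != nv || !identical(fr$faces, f0))
      stop("all frames must share vertex count and face list")
  }
  phases <- vapply(frames, `[[`, numeric(1), "phase")
  if (is.unsorted(phases, strictly = TRUE))
    stop("frames must be in strictly increasing phase order")
  if (phases[1] != 0) stop("frame 1 must be the end-diastolic phase 0")
  structure(list(frames = frames, correspondence = correspondence,
                 layer = layer, phases = phases),
            class = "mesh_sequence")
}

#' @export
print.mesh_sequence <- function(x, ...) {
  cat(sprintf("mesh_sequence (%s): %d frames, %d vertices, correspondence=%s\n",
              x$layer, length(x$frames), nrow(x$frames[[1]]$vertices),
              x$correspondence))
  invisible(x)
}

#' @rdname mesh_faces
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Face and vertex quantities of a triangle mesh
#'
#' `face_areas` returns the area (mm^2) of every triangle; `vertex_normals`
#' returns area-weighted, unit-length outward vertex normals;
#' `vertex_one_rings` returns, per vertex, the indices of its one-ring
#' neighbours and incident faces.
#'
#' @param mesh a [phase_mesh()].
#' @return See the individual descriptions.
#' @name mesh_faces
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])  # 2*area-weighted
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], f[, k], reorder = FALSE)
      idx <- as.integer(rownames(acc))
      n[idx, d] <- n[idx, d] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' @rdname mesh_faces
#' @export
vertex_one_rings <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  ed <- rbind(ed, ed[, 2:1])
  key <- (ed[, 1] - 1) * as.double(nv) + ed[, 2]
  ed <- ed[!duplicated(key), , drop = FALSE]
  nb <- split(ed[, 2], ed[, 1])
  fid <- split(rep(seq_len(nrow(f)), 3), as.vector(f))
  neighbours <- vector("list", nv)
  faces <- vector("list", nv)
  neighbours[as.integer(names(nb))] <- nb
  faces[as.integer(names(fid))] <- fid
  list(neighbours = neighbours, faces = faces)
}

#' Synthetic analytic test surfaces
#'
#' Closed UV-sphere, open cylinder tube, and half-ellipsoid LV meshes used
#' throughout the package and its tests. The LV mesh is a prolate
#' half-spheroid (apex at z = -length_mm, base plane at z = 0) closed by a
#' flat basal cap, which makes it a closed orientable surface suitable for
#' voxelization.
#'
#' @param radius,n_theta,n_phi sphere radius (mm) and angular resolution.
#' @return A [phase_mesh()].
#' @name test_surfaces
#' @export
mesh_sphere <- function(radius = 1, n_theta = 32L, n_phi = 48L) {
  th <- seq(0, pi, length.out = n_theta + 2L)[2:(n_theta + 1L)]
  ph <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  g <- expand.grid(ph = ph, th = th)
  v <- cbind(radius * sin(g$th) * cos(g$ph),
             radius * sin(g$th) * sin(g$ph),
             radius * cos(g$th))
  north <- nrow(v) + 1L; south <- nrow(v) + 2L
  v <- rbind(v, c(0, 0, radius), c(0, 0, -radius))
  idx <- function(i, j) (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  f <- list()
  f[[1]] <- cbind(north, idx(1, 1:n_phi), idx(1, 2:(n_phi + 1)))
  for (i in seq_len(n_theta - 1L)) {
    j <- 1:n_phi
    f[[length(f) + 1L]] <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
    f[[length(f) + 1L]] <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  }
  f[[length(f) + 1L]] <- cbind(south, idx(n_theta, 2:(n_phi + 1)),
                               idx(n_theta, 1:n_phi))
  phase_mesh(v, do.call(rbind, f), 0)
}

#' @rdname test_surfaces
#' @param length_mm,n_z axial length (mm) and number of axial rings.
#' @export
mesh_cylinder <- function(radius = 20, length_mm = 60, n_z = 20L,
                          n_phi = 36L) {
  z <- seq(0, -length_mm, length.out = n_z)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  g <- expand.grid(ph = ph, z = z)
  v <- cbind(radius * cos(g$ph), radius * sin(g$ph), g$z)
  idx <- function(i, j) (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  f <- list()
  for (i in seq_len(n_z - 1L)) {
    j <- 1:n_phi
    f[[length(f) + 1L]] <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
    f[[length(f) + 1L]] <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  }
  phase_mesh(v, do.call(rbind, f), 0)
}

#' @rdname test_surfaces
#' @param basal_radius_mm equatorial (basal) radius of the half-spheroid.
#' @param n_rings number of latitude rings between apex and base.
#' @param cap close the base with a flat triangulated cap (default `TRUE`).
#' @export
mesh_prolate_lv <- function(length_mm = 80, basal_radius_mm = 25,
                            n_rings = 24L, n_phi = 36L, cap = TRUE) {
  u <- seq(0, pi / 2, length.out = n_rings + 1L)[-1L]  # apex pole handled apart
  ph <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  g <- expand.grid(ph = ph, u = u)
  v <- cbind(basal_radius_mm * sin(g$u) * cos(g$ph),
             basal_radius_mm * sin(g$u) * sin(g$ph),
             -length_mm * cos(g$u))
  apex <- nrow(v) + 1L
  v <- rbind(v, c(0, 0, -length_mm))
  idx <- function(i, j) (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  f <- list()
  f[[1]] <- cbind(apex, idx(1, 2:(n_phi + 1)), idx(1, 1:n_phi))
  for (i in seq_len(n_rings - 1L)) {
    j <- 1:n_phi
    f[[length(f) + 1L]] <- cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j + 1L))
    f[[length(f) + 1L]] <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i + 1L, j))
  }
  if (cap) {
    centre <- nrow(v) + 1L
    v <- rbind(v, c(0, 0, 0))
    f[[length(f) + 1L]] <- cbind(centre, idx(n_rings, 1:n_phi),
                                 idx(n_rings, 2:(n_phi + 1)))
  }
  phase_mesh(v, do.call(rbind, f), 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

apply_rigid <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  phase_mesh(mesh$vertices %*% t(R) + rep(t, each = nrow(mesh$vertices)),
             mesh$faces, mesh$phase)
}
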