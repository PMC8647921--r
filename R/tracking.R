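#' Binary voxel volume
#'
#' @param data 3D array of 0/1 (logical or integer).
#' @param spacing mm per axis, length 3, positive.
#' @param origin world coordinate (mm) of the centre of voxel (1,1,1).
#' @return Object of class `binary_volume`.
#' @export
binary_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- array(as.integer(data != 0), dim = dim(data))
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  cat(sprintf("binary_volume: %s voxels, spacing (%g, %g, %g) mm, %d foreground\n",
              paste(dim(x$data), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3], sum(x$data)))
  invisible(x)
}

#' Voxelize a closed surface mesh
#'
#' A voxel is foreground iff its centre lies inside the surface, decided
#' by z-ray parity: for every (x, y) voxel column, the z values where the
#' column's ray crosses the surface are collected and voxels between
#' consecutive crossing pairs are filled. The sampling grid is offset by
#' an irrational sub-voxel amount to avoid rays passing exactly through
#' mesh edges or vertices; columns with an odd crossing count (a residual
#' degeneracy) raise an error asking for a different spacing.
#'
#' @param mesh a closed [phase_mesh()].
#' @param spacing voxel edge length(s), mm.
#' @param origin,dims optional fixed grid (centre of voxel (1,1,1) and
#'   array dimensions); the mesh must fit inside, otherwise an error is
#'   raised. By default the grid is fitted to the mesh with a one-voxel
#'   margin.
#' @return A [binary_volume()].
#' @export
voxelize <- function(mesh, spacing = 1, origin = NULL, dims = NULL) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  v <- mesh$vertices; f <- mesh$faces
  auto_grid <- is.null(origin)
  if (!is_closed_mesh(mesh)) stop("voxelize requires a closed mesh")
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  if (is.null(origin)) {
    # irrational, axis-distinct offsets dodge exact edge/vertex ray hits;
    # attempt > 1 reshifts the grid after a degenerate-ray failure
    shift <- attr(mesh, "voxelize_attempt") %||% 1
    origin <- lo - spacing * (1 + 1e-3 * shift * sqrt(c(2, 3, 5)))
    dims <- ceiling((hi - origin) / spacing) + 2L
  } else {
    if (is.null(dims)) stop("dims must accompany origin")
    gmax <- origin + (dims - 1) * spacing
    if (any(lo < origin - spacing / 2) || any(hi > gmax + spacing / 2))
      stop("mesh lies (partly) outside the fixed voxel grid")
  }
  dims <- as.integer(dims)
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]

  # per-column z crossings, accumulated triangle by triangle
  crossings <- vector("list", dims[1] * dims[2])
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  for (tr in seq_len(nrow(f))) {
    a <- p1[tr, ]; b <- p2[tr, ]; c3 <- p3[tr, ]
    xi <- which(xs >= min(a[1], b[1], c3[1]) & xs <= max(a[1], b[1], c3[1]))
    yi <- which(ys >= min(a[2], b[2], c3[2]) & ys <= max(a[2], b[2], c3[2]))
    if (!length(xi) || !length(yi)) next
    d <- (b[2] - c3[2]) * (a[1] - c3[1]) + (c3[1] - b[1]) * (a[2] - c3[2])
    if (d == 0) next                       # triangle vertical in z: no area in xy
    for (ix in xi) {
      px <- xs[ix]
      w1 <- ((b[2] - c3[2]) * (px - c3[1]) + (c3[1] - b[1]) * (ys[yi] - c3[2])) / d
      w2 <- ((c3[2] - a[2]) * (px - c3[1]) + (a[1] - c3[1]) * (ys[yi] - c3[2])) / d
      w3 <- 1 - w1 - w2
      ok <- w1 >= 0 & w2 >= 0 & w3 >= 0
      if (!any(ok)) next
      zhit <- w1[ok] * a[3] + w2[ok] * b[3] + w3[ok] * c3[3]
      cols <- (yi[ok] - 1L) * dims[1] + ix
      for (k in seq_along(cols))
        crossings[[cols[k]]] <- c(crossings[[cols[k]]], zhit[k])
    }
  }
  vol <- array(0L, dims)
  for (col in which(lengths(crossings) > 0)) {
    z <- sort(crossings[[col]])
    # collapse near-duplicate hits (ray grazing a shared edge)
    if (length(z) > 1) z <- z[c(TRUE, diff(z) > 1e-6 * spacing[3])]
    if (length(z) %% 2 != 0) {
      attempt <- (attr(mesh, "voxelize_attempt") %||% 1) + 1
      if (!auto_grid || attempt > 4) stop("degenerate ray crossings persist")
      attr(mesh, "voxelize_attempt") <- attempt
      return(voxelize(mesh, spacing))
    }
    ix <- (col - 1L) %% dims[1] + 1L
    iy <- (col - 1L) %/% dims[1] + 1L
    for (k in seq(1, length(z), by = 2)) {
      zi <- which(zs > z[k] & zs < z[k + 1])
      if (length(zi)) vol[ix, iy, zi] <- 1L
    }
  }
  binary_volume(vol, spacing, origin)
}

is_closed_mesh <- function(mesh) {
  f <- mesh$faces
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  all(table(key) == 2L)
}

#' Keep the connected cavity containing a seed point
#'
#' 6-connected flood fill from the seed; all other foreground components
#' are removed (speckle / second-cavity suppression).
#'
#' @param vol a [binary_volume()].
#' @param seed_point 3D point in mm; its voxel must be foreground.
#' @return A [binary_volume()] containing only the seed's component.
#' @export
segment_cavity <- function(vol, seed_point) {
  d <- dim(vol$data)
  ijk <- round((as.numeric(seed_point) - vol$origin) / vol$spacing) + 1L
  if (any(ijk < 1L) || any(ijk > d))
    stop("seed point outside the volume")
  if (vol$data[ijk[1], ijk[2], ijk[3]] != 1L)
    stop("seed point is not foreground")
  lin <- function(i, j, k) (k - 1L) * d[1] * d[2] + (j - 1L) * d[1] + i
  fg <- vol$data == 1L
  visited <- array(FALSE, d)
  frontier <- lin(ijk[1], ijk[2], ijk[3])
  visited[frontier] <- TRUE
  offs <- c(-1L, 1L, -d[1], d[1], -d[1] * d[2], d[1] * d[2])
  # precomputed border masks forbid wrap-around steps
  idx_i <- slice.index(visited, 1); idx_j <- slice.index(visited, 2)
  idx_k <- slice.index(visited, 3)
  while (length(frontier)) {
    nxt <- integer()
    for (o in seq_along(offs)) {
      cand <- frontier + offs[o]
      src_ok <- switch(o,
                       idx_i[frontier] > 1L, idx_i[frontier] < d[1],
                       idx_j[frontier] > 1L, idx_j[frontier] < d[2],
                       idx_k[frontier] > 1L, idx_k[frontier] < d[3])
      cand <- cand[src_ok]
      cand <- cand[fg[cand] & !visited[cand]]
      if (length(cand)) {
        visited[cand] <- TRUE
        nxt <- c(nxt, cand)
      }
    }
    frontier <- unique(nxt)
  }
  out <- array(0L, d)
  out[visited & fg] <- 1L
  binary_volume(out, vol$spacing, vol$origin)
}

# 6-tetrahedra decomposition of the unit cube, consistent across cells
# (all tets share the main diagonal 1-8); corners numbered 1..8 as
# (i,j,k) offsets in binary order x fastest
tet_table <- function() {
  list(c(1L, 2L, 4L, 8L), c(1L, 4L, 3L, 8L), c(1L, 3L, 7L, 8L),
       c(1L, 7L, 5L, 8L), c(1L, 5L, 6L, 8L), c(1L, 6L, 2L, 8L))
}

#' Extract a closed isosurface from a binary volume
#'
#' Marching tetrahedra at the 0.5 level. The binary volume is first
#' mollified with a separable 3x3x3 box filter after zero-padding,
#' which turns the staircase voxel boundary into a smooth scalar field
#' whose 0.5 level set tracks the true surface to sub-voxel accuracy;
#' isosurface vertices are placed by linear interpolation along cell
#' edges. Shared edge keys weld vertices, so the result is a closed
#' triangulated surface in mm coordinates.
#'
#' @param vol a non-empty [binary_volume()].
#' @param smooth_passes box-filter passes applied before extraction
#'   (default 1; 0 gives the raw staircase field, more passes erode
#'   high-curvature regions).
#' @return A [phase_mesh()].
#' @export
extract_surface <- function(vol, smooth_passes = 1L) {
  if (sum(vol$data) == 0) stop("empty volume")
  pad <- 2L + smooth_passes
  d0 <- dim(vol$data)
  d <- d0 + 2L * pad
  f <- array(0, d)
  f[pad + seq_len(d0[1]), pad + seq_len(d0[2]), pad + seq_len(d0[3])] <-
    vol$data
  box1 <- function(a, dim_i) {
    up <- function(x, s) {
      idx <- pmin(pmax(seq_len(dim(a)[dim_i]) + s, 1L), dim(a)[dim_i])
      switch(dim_i, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
             a[, , idx, drop = FALSE])
    }
    (up(a, -1L) + a + up(a, 1L)) / 3
  }
  for (pass in seq_len(smooth_passes))
    for (ax in 1:3) f <- box1(f, ax)

  origin <- vol$origin - pad * vol$spacing
  level <- 0.5
  # grid point linear index helpers
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  corner_off <- c(0L,                       # (0,0,0)
                  1L,                       # (1,0,0)
                  nx,                       # (0,1,0)
                  nx + 1L,                  # (1,1,0)
                  nx * ny,                  # (0,0,1)
                  nx * ny + 1L,
                  nx * ny + nx,
                  nx * ny + nx + 1L)
  # cells with any sign change over their 8 corners (bounding the level set)
  above <- f > level
  corner_count <- Reduce(`+`, lapply(0:7, function(b) {
    dx <- bitwAnd(b, 1L); dy <- bitwAnd(bitwShiftR(b, 1L), 1L)
    dz <- bitwAnd(bitwShiftR(b, 2L), 1L)
    above[seq_len(nx - 1L) + dx, seq_len(ny - 1L) + dy,
          seq_len(nz - 1L) + dz]
  }))
  cells <- which(corner_count > 0L & corner_count < 8L)
  if (!length(cells)) {
    # tiny structures can be mollified entirely below the level; fall back
    # to less smoothing rather than fail
    if (smooth_passes > 0L)
      return(extract_surface(vol, smooth_passes = smooth_passes - 1L))
    stop("no isosurface at level 0.5")
  }
  ci <- arrayInd(cells, d - 1L)
  base <- (ci[, 3] - 1L) * nx * ny + (ci[, 2] - 1L) * nx + ci[, 1]

  tets <- tet_table()
  tri_i <- list(); tri_j <- list()          # triangle corners as grid-edge pairs
  for (tet in tets) {
    g <- vapply(tet, function(c8) base + corner_off[c8], numeric(length(base)))
    vals <- matrix(f[g], ncol = 4L)
    inside <- vals > level
    code <- inside[, 1] + 2L * inside[, 2] + 4L * inside[, 3] + 8L * inside[, 4]
    for (cd in setdiff(unique(code), c(0L, 15L))) {
      rows <- which(code == cd)
      ins <- which(bitwAnd(cd, c(1L, 2L, 4L, 8L)) > 0)
      outs <- setdiff(1:4, ins)
      if (length(ins) == 1L || length(ins) == 3L) {
        ap <- if (length(ins) == 1L) ins else outs
        others <- setdiff(1:4, ap)
        e <- lapply(others, function(o) cbind(g[rows, ap], g[rows, o]))
        # consistent orientation not required downstream; emit one triangle
        tri_i[[length(tri_i) + 1L]] <- cbind(e[[1]][, 1], e[[2]][, 1], e[[3]][, 1])
        tri_j[[length(tri_j) + 1L]] <- cbind(e[[1]][, 2], e[[2]][, 2], e[[3]][, 2])
      } else {                              # 2 in / 2 out: quad -> 2 triangles
        i1 <- ins[1]; i2 <- ins[2]; o1 <- outs[1]; o2 <- outs[2]
        e11 <- cbind(g[rows, i1], g[rows, o1]); e12 <- cbind(g[rows, i1], g[rows, o2])
        e21 <- cbind(g[rows, i2], g[rows, o1]); e22 <- cbind(g[rows, i2], g[rows, o2])
        tri_i[[length(tri_i) + 1L]] <- cbind(e11[, 1], e12[, 1], e21[, 1])
        tri_j[[length(tri_j) + 1L]] <- cbind(e11[, 2], e12[, 2], e21[, 2])
        tri_i[[length(tri_i) + 1L]] <- cbind(e21[, 1], e12[, 1], e22[, 1])
        tri_j[[length(tri_j) + 1L]] <- cbind(e21[, 2], e12[, 2], e22[, 2])
      }
    }
  }
  A <- do.call(rbind, tri_i)                # grid index inside-end per corner
  B <- do.call(rbind, tri_j)                # grid index outside-end
  ekey <- paste(pmin(A, B), pmax(A, B))
  uk <- !duplicated(as.vector(ekey))
  ua <- as.vector(A)[uk]; ub <- as.vector(B)[uk]
  vid <- match(as.vector(ekey), as.vector(ekey)[uk])
  faces <- matrix(vid, ncol = 3L)
  # interpolated positions on the unique edges
  frac <- (level - f[ua]) / (f[ub] - f[ua])
  pa <- (arrayInd(ua, d) - 1L) * rep(vol$spacing, each = length(ua))
  pb <- (arrayInd(ub, d) - 1L) * rep(vol$spacing, each = length(ub))
  verts <- pa + frac * (pb - pa)
  verts <- sweep(verts, 2, origin, "+")
  # drop degenerate (repeated-vertex) triangles produced by grazing tets
  good <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  phase_mesh(verts, faces[good, , drop = FALSE], vol_phase(vol))
}

vol_phase <- function(vol) if (!is.null(vol$phase)) vol$phase else 0

#' Mean point-to-surface distance between meshes
#'
#' Mean distance from the vertices of `a` to the triangulated surface of
#' `b` (closest point on the candidate triangles around the nearest
#' vertex).
#'
#' @param a,b [phase_mesh()] objects.
#' @return Mean distance in mm.
#' @export
mean_surface_distance <- function(a, b) {
  cp <- closest_points_on_surface(a$vertices, b)
  mean(cp$dist)
}

# closest point on mesh surface for each query point: nearest vertex, then
# exact point-triangle projection over that vertex's incident faces
closest_points_on_surface <- function(points, mesh) {
  rings <- vertex_one_rings(mesh)
  nn <- nearest_vertex(points, mesh$vertices)
  out <- matrix(0, nrow(points), 3)
  dist <- numeric(nrow(points))
  v <- mesh$vertices; f <- mesh$faces
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    cand <- rings$faces[[nn$index[i]]]
    best <- v[nn$index[i], ]; bd <- nn$dist[i]
    for (fc in cand) {
      q <- closest_point_triangle(p, v[f[fc, 1], ], v[f[fc, 2], ], v[f[fc, 3], ])
      d <- sqrt(sum((p - q)^2))
      if (d < bd) { bd <- d; best <- q }
    }
    out[i, ] <- best; dist[i] <- bd
  }
  list(point = out, dist = dist)
}

# standard closest-point-on-triangle (Ericson), barycentric clamping
closest_point_triangle <- function(p, a, b, c3) {
  ab <- b - a; ac <- c3 - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + ab * d1 / (d1 - d3))
  cp <- p - c3
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c3)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + ac * d2 / (d2 - d6))
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(b + (c3 - b) * w)
  }
  den <- va + vb + vc
  a + ab * (vb / den) + ac * (vc / den)
}

#' Track a reference surface through the cardiac cycle
#'
#' Establishes vertex correspondence from the end-diastolic reference to
#' each later phase in two stages: a rigid iterative-closest-point (ICP)
#' alignment (centroid shift + Procrustes rotation, iterated), then a
#' non-rigid refinement in which each vertex moves to its closest point
#' on the target surface and the resulting displacement field is
#' regularized by Laplacian smoothing (neighbour averaging). Targets may
#' be meshes or binary volumes (isosurfaced first). An error is raised
#' when surfaces are farther apart than the gate distance.
#'
#' @param ref end-diastolic reference [phase_mesh()].
#' @param targets list of [phase_mesh()] or [binary_volume()] objects for
#'   the remaining phases (in increasing phase order).
#' @param gate_mm maximum admissible residual distance (default 10).
#' @param icp_iters rigid ICP iterations (default 20).
#' @param smooth_iters,smooth_weight Laplacian smoothing of the
#'   displacement field (default 10 iterations, weight 0.5).
#' @param phases optional phase (percent RR) per target, used when targets
#'   do not carry one (e.g. binary volumes).
#' @return A corresponded [mesh_sequence()] whose first frame is `ref`.
#' @export
track_sequence <- function(ref, targets, gate_mm = 10, icp_iters = 20L,
                           smooth_iters = 10L, smooth_weight = 0.5,
                           phases = NULL) {
  frames <- list(ref)
  rings <- vertex_one_rings(ref)
  nb <- rings$neighbours
  for (ti in seq_along(targets)) {
    tg <- targets[[ti]]
    if (inherits(tg, "binary_volume")) tg <- extract_surface(tg)
    if (!is.null(phases)) tg$phase <- phases[ti]
    tv <- tg$vertices
    # --- rigid ICP ---
    tv_c <- colMeans(tv)
    cur <- sweep(ref$vertices, 2, colMeans(ref$vertices) - tv_c)
    for (it in seq_len(icp_iters)) {
      nn <- nearest_vertex(cur, tv)
      q <- tv[nn$index, , drop = FALSE]
      mc <- colMeans(cur); mq <- colMeans(q)
      H <- crossprod(sweep(cur, 2, mc), sweep(q, 2, mq))
      sv <- svd(H)
      Rstep <- sv$v %*% diag(c(1, 1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
      new <- sweep(sweep(cur, 2, mc) %*% t(Rstep), 2, mq, "+")
      if (max(abs(new - cur)) < 1e-10) { cur <- new; break }
      cur <- new
    }
    # --- non-rigid refinement ---
    cp <- closest_points_on_surface(cur, tg)
    if (stats::median(cp$dist) > gate_mm)
      stop(sprintf("tracking gate exceeded (median residual %.1f mm)",
                   stats::median(cp$dist)))
    disp <- cp$point - cur
    for (it in seq_len(smooth_iters)) {
      avg <- disp
      for (vtx in seq_len(nrow(disp))) {
        nbv <- nb[[vtx]]
        if (length(nbv))
          avg[vtx, ] <- colMeans(disp[nbv, , drop = FALSE])
      }
      disp <- (1 - smooth_weight) * disp + smooth_weight * avg
    }
    # reproject onto the target surface: smoothing regularizes the
    # tangential distribution of the correspondence but must not pull
    # vertices off the surface (that would fake local area change)
    cp2 <- closest_points_on_surface(cur + disp, tg)
    frames[[length(frames) + 1L]] <-
      phase_mesh(cp2$point, ref$faces, tg$phase)
  }
  mesh_sequence(frames, correspondence = TRUE, layer = "endo")
}
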