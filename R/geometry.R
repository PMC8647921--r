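#' LV anatomical coordinate frame
#'
#' Houses the coordinate conventions used by the AHA segment assignment:
#' the long axis (unit vector pointing base to apex), the apex and basal
#' centroid landmarks, and the septal direction that fixes the
#' circumferential origin. `septal_dir` is re-orthogonalized against the
#' long axis on construction.
#'
#' @param apex,base_centroid 3D points (mm).
#' @param long_axis unit vector from base to apex.
#' @param septal_dir unit vector orthogonal to `long_axis` pointing at the
#'   mid-septum (circumferential angle 0).
#' @return An object of class `lv_frame`.
#' @export
lv_frame <- function(apex, base_centroid, long_axis = NULL,
                     septal_dir = c(1, 0, 0)) {
  apex <- as.numeric(apex); base_centroid <- as.numeric(base_centroid)
  if (isTRUE(all.equal(apex, base_centroid)))
    stop("degenerate frame: apex equals base centroid")
  if (is.null(long_axis)) long_axis <- apex - base_centroid
  long_axis <- long_axis / sqrt(sum(long_axis^2))
  septal_dir <- septal_dir - sum(septal_dir * long_axis) * long_axis
  ns <- sqrt(sum(septal_dir^2))
  if (ns < 1e-8) stop("septal_dir is parallel to the long axis")
  septal_dir <- septal_dir / ns
  structure(list(apex = apex, base_centroid = base_centroid,
                 long_axis = long_axis, septal_dir = septal_dir),
            class = "lv_frame")
}

#' @export
print.lv_frame <- function(x, ...) {
  cat(sprintf(
    "lv_frame: apex (%.1f, %.1f, %.1f), long axis (%.2f, %.2f, %.2f)\n",
    x$apex[1], x$apex[2], x$apex[3],
    x$long_axis[1], x$long_axis[2], x$long_axis[3]))
  invisible(x)
}

#' Fit the LV frame to a mesh
#'
#' The long axis is the principal axis of the vertex cloud, oriented
#' base-to-apex by picking as apex the extremity with the smaller
#' cross-sectional radius (the LV tapers towards the apex). The apex
#' landmark is the extreme vertex along that axis and the basal centroid is
#' the centroid of the 5% of vertices nearest the base. The septal
#' direction cannot be inferred from a bare endocardial surface: it is
#' taken from `septal_dir` (synthetic meshes carry it as ground-truth
#' metadata; for real meshes it must be supplied), defaulting to the +x
#' axis projected orthogonal to the long axis.
#'
#' @param mesh a [phase_mesh()].
#' @param septal_dir approximate mid-septal direction (projected orthogonal
#'   to the fitted long axis).
#' @param min_elongation minimum ratio of first to second principal
#'   standard deviation below which the mesh is considered degenerate
#'   (no identifiable long axis).
#' @return An [lv_frame()].
#' @export
fit_lv_frame <- function(mesh, septal_dir = c(1, 0, 0),
                         min_elongation = 1.15) {
  v <- mesh$vertices
  # area-weighted covariance removes the sampling bias of structured grids
  # (a UV sphere is vertex-dense at the poles but isotropic by area)
  w <- rep(1, nrow(v))
  if (nrow(mesh$faces)) {
    fa <- face_areas(mesh)
    w <- numeric(nrow(v))
    for (k in 1:3) {
      acc <- rowsum(fa, mesh$faces[, k], reorder = FALSE)
      idx <- as.integer(rownames(acc))
      w[idx] <- w[idx] + acc[, 1] / 3
    }
    w[w == 0] <- min(w[w > 0])
  }
  ctr <- colSums(v * w) / sum(w)
  vc <- sweep(v, 2, ctr)
  eg <- eigen(crossprod(vc * sqrt(w)) / sum(w), symmetric = TRUE)
  sdvs <- sqrt(pmax(eg$values, 0))
  if (sdvs[3] < 1e-9 * sdvs[1]) stop("degenerate (coplanar) mesh")
  if (sdvs[1] / sdvs[2] < min_elongation)
    stop("no identifiable long axis: mesh is not elongated")
  ax <- eg$vectors[, 1]
  s <- drop(vc %*% ax)
  # apex = the pointier extremity: compare mean off-axis radius in the two
  # terminal 20% slabs
  r2 <- rowSums(vc^2) - s^2
  hi <- s > stats::quantile(s, 0.8); lo <- s < stats::quantile(s, 0.2)
  if (mean(r2[hi]) >= mean(r2[lo])) {  # apex is the pointier end
    ax <- -ax; s <- -s
  }
  apex <- v[which.max(s), ]
  base_centroid <- colMeans(v[s < stats::quantile(s, 0.05), , drop = FALSE])
  lv_frame(apex, base_centroid, long_axis = ax, septal_dir = septal_dir)
}

#' AHA segment names, septal set and bullseye adjacency
#'
#' Constants of the standard AHA 16/17-segment left-ventricular model:
#' segment display names, the septal subset of the 16-segment model
#' (segments 2, 3, 8, 9, 14), and the bullseye adjacency table (segments
#' sharing a boundary on the polar plot: circumferential ring neighbours
#' plus radial neighbours between rings).
#'
#' @name aha_model
#' @export
aha_segment_names <- function() {
  c("basal anterior", "basal anteroseptal", "basal inferoseptal",
    "basal inferior", "basal inferolateral", "basal anterolateral",
    "mid anterior", "mid anteroseptal", "mid inferoseptal",
    "mid inferior", "mid inferolateral", "mid anterolateral",
    "apical anterior", "apical septal", "apical inferior", "apical lateral",
    "apex")
}

#' @rdname aha_model
#' @export
aha_septal_segments <- function() c(2L, 3L, 8L, 9L, 14L)

#' @rdname aha_model
#' @export
aha_adjacency <- function() {
  ring_b <- c(2L, 1L, 6L, 5L, 4L, 3L)      # basal ring in circumferential order
  ring_m <- ring_b + 6L
  ring_a <- c(14L, 13L, 16L, 15L)
  adj <- vector("list", 17L)
  add <- function(a, b) {
    adj[[a]] <<- union(adj[[a]], b)
    adj[[b]] <<- union(adj[[b]], a)
  }
  link_ring <- function(r) for (i in seq_along(r)) add(r[i], r[i %% length(r) + 1L])
  link_ring(ring_b); link_ring(ring_m); link_ring(ring_a)
  for (i in 1:6) add(i, i + 6L)            # basal <-> mid, same sector
  # mid <-> apical by angular overlap of 60 deg vs 90 deg sectors
  for (p in list(c(13L, 7L), c(13L, 8L), c(13L, 12L),
                 c(14L, 8L), c(14L, 9L),
                 c(15L, 9L), c(15L, 10L), c(15L, 11L),
                 c(16L, 11L), c(16L, 12L)))
    add(p[1], p[2])
  for (a in ring_a) add(17L, a)
  lapply(adj, sort)
}

# circumferential angle (deg, [0, 360)) and normalized long-axis coordinate
# t (0 = apex, 1 = base) of each vertex in the frame's coordinates
lv_coordinates <- function(mesh, frame) {
  up <- -frame$long_axis                    # apex -> base
  e1 <- frame$septal_dir
  e2 <- vec_cross(e1, frame$long_axis)      # anterior direction
  h <- sum((frame$base_centroid - frame$apex) * up)
  rel <- sweep(mesh$vertices, 2, frame$apex)
  t <- pmin(pmax(drop(rel %*% up) / h, 0), 1)
  radial <- rel - outer(drop(rel %*% up), up)
  theta <- (atan2(drop(radial %*% e2), drop(radial %*% e1)) * 180 / pi) %% 360
  list(t = t, theta = theta, r = sqrt(rowSums(radial^2)))
}

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# sector lookup tables: segment id as a function of the circumferential
# angle, per ring; angle 0 at mid-septum, increasing towards the anterior
# wall, 60 deg sectors on the basal/mid rings and 90 deg (offset 45) apically
seg_from_angle <- function(theta, ring) {
  if (ring == "basal" || ring == "mid") {
    tab <- c(2L, 1L, 6L, 5L, 4L, 3L)
    k <- pmin(floor(theta / 60) + 1L, 6L)
    out <- tab[k]
    if (ring == "mid") out <- out + 6L
    # boundary tie-break: lower segment id wins on exact sector boundaries
    on_b <- theta %% 60 == 0
    if (any(on_b)) {
      k2 <- (floor(theta[on_b] / 60) - 1L) %% 6L + 1L
      alt <- tab[k2]
      if (ring == "mid") alt <- alt + 6L
      out[on_b] <- pmin(out[on_b], alt)
    }
    out
  } else {
    tab <- c(14L, 13L, 16L, 15L)
    shifted <- (theta + 45) %% 360
    k <- pmin(floor(shifted / 90) + 1L, 4L)
    out <- tab[k]
    on_b <- shifted %% 90 == 0
    if (any(on_b)) {
      k2 <- (floor(shifted[on_b] / 90) - 1L) %% 4L + 1L
      out[on_b] <- pmin(out[on_b], tab[k2])
    }
    out
  }
}

#' Assign AHA segment labels to mesh vertices
#'
#' Vertices are binned longitudinally into equal thirds of the apex-to-base
#' long-axis extent (basal, mid, apical), and circumferentially from the
#' septal direction into 6/6/4 sectors following the standard AHA 2002
#' numbering (1 basal anterior ... 16 apical lateral). In 17-segment mode
#' the most apical 15% of the long-axis extent becomes the apical cap
#' (segment 17). Exact boundary ties go to the lower segment number.
#'
#' @param mesh a [phase_mesh()].
#' @param frame an [lv_frame()].
#' @param n_segments 16 (strain bullseyes) or 17 (scar polar maps).
#' @return An object of class `aha_map`: list with `n_segments` and
#'   integer `vertex_labels` (one label per vertex).
#' @export
assign_aha <- function(mesh, frame, n_segments = 16L) {
  if (!n_segments %in% c(16L, 17L)) stop("n_segments must be 16 or 17")
  co <- lv_coordinates(mesh, frame)
  lab <- integer(nrow(mesh$vertices))
  basal <- co$t >= 2 / 3
  mid <- co$t >= 1 / 3 & !basal
  apical <- !basal & !mid
  lab[basal] <- seg_from_angle(co$theta[basal], "basal")
  lab[mid] <- seg_from_angle(co$theta[mid], "mid")
  lab[apical] <- seg_from_angle(co$theta[apical], "apical")
  if (n_segments == 17L) lab[co$t < 0.15] <- 17L
  structure(list(n_segments = as.integer(n_segments), vertex_labels = lab),
            class = "aha_map")
}

#' @export
print.aha_map <- function(x, ...) {
  cat(sprintf("aha_map: %d-segment model, %d vertices\n",
              x$n_segments, length(x$vertex_labels)))
  print(table(x$vertex_labels))
  invisible(x)
}

# per-face segment label: majority vote over the three vertex labels,
# ties resolved to the lowest segment id
face_labels <- function(mesh, aha) {
  fl <- matrix(aha$vertex_labels[mesh$faces], ncol = 3)
  apply(fl, 1, function(r) {
    tb <- table(r)
    as.integer(names(tb)[which.max(tb)][1])  # table() names sorted ascending
  })
}

#' Surface area of an AHA segment
#'
#' Sum of the areas of the faces attributed to a segment; a face is
#' attributed by the majority label of its three vertices (ties to the
#' lowest segment id), so segment areas always sum exactly to the total
#' mesh area.
#'
#' @param mesh a [phase_mesh()].
#' @param aha an `aha_map` from [assign_aha()].
#' @param segment_id segment id in 1..n_segments.
#' @return Area in mm^2 (0 with a warning for an empty segment).
#' @export
segment_surface_area <- function(mesh, aha, segment_id) {
  if (!segment_id %in% seq_len(aha$n_segments)) stop("invalid segment id")
  fl <- face_labels(mesh, aha)
  sel <- fl == segment_id
  if (!any(sel)) {
    warning(sprintf("segment %d has no attributed faces", segment_id))
    return(0)
  }
  sum(face_areas(mesh)[sel])
}
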