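#' Map vein branches to the AHA segments they subtend
#'
#' Each polyline edge is assigned to the AHA segment of the epicardial
#' vertex nearest its midpoint, provided that vertex lies within
#' `max_dist`; a branch subtends a segment when the assigned arc length
#' exceeds `min_arc_mm`. Subtension is monotone in `max_dist` (a larger
#' gate can only add arc length).
#'
#' @param veins a `vein_tree`.
#' @param epi epicardial reference [phase_mesh()] in the same space.
#' @param aha `aha_map` of the epicardial mesh.
#' @param max_dist maximum point-to-surface distance, mm (default 10).
#' @param min_arc_mm minimum subtended arc length, mm (default 5).
#' @return List of class `vein_subtension`, one element per branch:
#'   `label`, `arc_mm` (named vector, mm of arc per segment) and
#'   `subtended` (segment ids). Branches entirely beyond `max_dist` get an
#'   empty set with a warning.
#' @export
vein_subtension <- function(veins, epi, aha, max_dist = 10, min_arc_mm = 5) {
  v <- epi$vertices
  res <- lapply(veins$branches, function(br) {
    p <- br$points
    if (nrow(p) < 2L) stop("vein polyline needs at least 2 points")
    mid <- (p[-1, , drop = FALSE] + p[-nrow(p), , drop = FALSE]) / 2
    len <- sqrt(rowSums((p[-1, , drop = FALSE] -
                           p[-nrow(p), , drop = FALSE])^2))
    nn <- nearest_vertex(mid, v)
    keep <- nn$dist <= max_dist
    if (!any(keep)) {
      warning(sprintf("branch '%s' lies entirely beyond %g mm", br$label,
                      max_dist))
      return(list(label = br$label, arc_mm = numeric(), subtended = integer()))
    }
    seg <- aha$vertex_labels[nn$index[keep]]
    arc <- tapply(len[keep], seg, sum)
    arc <- stats::setNames(as.numeric(arc), names(arc))
    list(label = br$label, arc_mm = arc,
         subtended = sort(as.integer(names(arc)[arc >= min_arc_mm])))
  })
  structure(res, class = "vein_subtension")
}

# exact nearest vertex, vectorized over the reference set per query
# (meshes here are a few thousand vertices; no spatial index needed)
nearest_vertex <- function(points, vertices) {
  idx <- integer(nrow(points)); d <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    dd <- (vertices[, 1] - points[i, 1])^2 +
      (vertices[, 2] - points[i, 2])^2 + (vertices[, 3] - points[i, 3])^2
    idx[i] <- which.min(dd)
    d[i] <- sqrt(dd[idx[i]])
  }
  list(index = idx, dist = d)
}

#' Pick the vein branch for the target segment
#'
#' Selects the branch subtending the top-ranked target segment (largest
#' subtended arc wins among several; tributary branches are preferred
#' over the CS trunk itself, which is not a lead destination). When no
#' branch subtends the target,
#' the fallback searches the bullseye-adjacent segments of the target
#' (see [aha_adjacency()]), excluding septal segments, and returns the
#' branch with the largest arc over those, flagged as a fallback.
#'
#' @param report a `target_report` from [select_targets()].
#' @param subtension a `vein_subtension`.
#' @return List of class `vein_choice`: `branch` (label or `NA`),
#'   `segment` (the segment through which the branch was matched),
#'   `fallback` (logical), `reason` (when no branch found).
#' @export
pick_target_vein <- function(report, subtension) {
  if (!length(subtension)) stop("empty vein tree")
  if (!length(report$targets))
    return(structure(list(branch = NA_character_, segment = NA_integer_,
                          fallback = FALSE, reason = "no_target_segment"),
                     class = "vein_choice"))
  target <- report$targets[1]
  labels <- vapply(subtension, `[[`, character(1), "label")
  arc_for <- function(seg) vapply(subtension, function(b) {
    a <- b$arc_mm[as.character(seg)]
    if (seg %in% b$subtended && !is.na(a)) a else 0
  }, numeric(1))
  direct <- arc_for(target)
  # a lead is delivered into a tributary, not the CS trunk itself
  if (any(direct[labels != "CS"] > 0)) direct[labels == "CS"] <- 0
  if (any(direct > 0)) {
    i <- which.max(direct)
    return(structure(list(branch = subtension[[i]]$label, segment = target,
                          fallback = FALSE, reason = NULL),
                     class = "vein_choice"))
  }
  adj <- setdiff(aha_adjacency()[[target]], aha_septal_segments())
  best <- list(arc = 0, i = NA_integer_, seg = NA_integer_)
  for (seg in adj) {
    a <- arc_for(seg)
    if (any(a[labels != "CS"] > 0)) a[labels == "CS"] <- 0
    if (max(a) > best$arc)
      best <- list(arc = max(a), i = which.max(a), seg = seg)
  }
  if (!is.na(best$i))
    return(structure(list(branch = subtension[[best$i]]$label,
                          segment = best$seg, fallback = TRUE, reason = NULL),
                     class = "vein_choice"))
  structure(list(branch = NA_character_, segment = NA_integer_,
                 fallback = FALSE, reason = "no_vein_near_target"),
            class = "vein_choice")
}

#' C-arm fluoroscopic view
#'
#' @param rao_lao_angle degrees about the patient's cranio-caudal axis:
#'   RAO negative, LAO positive, 0 = postero-anterior (PA).
#' @param cran_caud_angle degrees about the patient's lateral axis
#'   (cranial positive), default 0.
#' @return Object of class `carm_view`.
#' @export
carm_view <- function(rao_lao_angle = 0, cran_caud_angle = 0) {
  if (abs(rao_lao_angle) > 90 || abs(cran_caud_angle) > 90)
    stop("C-arm angles must lie in [-90, 90] degrees")
  structure(list(rao_lao_angle = rao_lao_angle,
                 cran_caud_angle = cran_caud_angle), class = "carm_view")
}

#' @rdname carm_view
#' @param name `"PA"`, `"RAO30"` or `"LAO30"`.
#' @export
standard_views <- function(name = c("PA", "RAO30", "LAO30")) {
  name <- match.arg(name)
  switch(name,
         PA = carm_view(0, 0),
         RAO30 = carm_view(-30, 0),
         LAO30 = carm_view(30, 0))
}

# rotation matrices about patient axes; coordinates are x = patient left,
# y = anterior, z = cranial
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
}
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
}

#' Orthographic C-arm projection
#'
#' Expresses patient coordinates (x = patient left, y = anterior,
#' z = cranial, mm) in the detector frame — the patient frame rotated by
#' the RAO/LAO angle about the cranio-caudal axis, then by the
#' cranial/caudal angle about the lateral axis — and drops the detector's
#' depth (anterior-posterior at PA) coordinate. Equivalently the points
#' are rotated by the inverse C-arm rotation, `Rx(-cran) Rz(-raolao)`. At
#' PA (0, 0) the projection drops exactly the patient y coordinate; at
#' LAO 90 the horizontal detector axis is the patient's anterior (+y)
#' axis (a left-lateral view). Orthographic by design; in-plane distances
#' are preserved for points in the view plane.
#'
#' @param points n x 3 matrix (mm).
#' @param view a [carm_view()].
#' @return n x 2 matrix: horizontal and vertical detector coordinates.
#' @export
project_carm <- function(points, view) {
  points <- matrix(as.numeric(points), ncol = 3)
  R <- rot_x(-view$cran_caud_angle) %*% rot_z(-view$rao_lao_angle)
  p <- points %*% t(R)
  p[, c(1, 3), drop = FALSE]
}

# boundary polyline(s) of the faces belonging to one segment: edges used
# by exactly one face of the segment
segment_outline_edges <- function(mesh, aha, segment_id) {
  fl <- face_labels(mesh, aha)
  f <- mesh$faces[fl == segment_id, , drop = FALSE]
  if (!nrow(f)) return(matrix(integer(), 0, 2))
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  ed[key %in% names(which(table(key) == 1L)), , drop = FALSE]
}

svg_num <- function(x) sprintf("%.4f", x)

svg_polyline <- function(p2, colour, width, fill = "none", closed = FALSE) {
  pts <- paste(svg_num(p2[, 1]), svg_num(p2[, 2]), sep = ",", collapse = " ")
  tag <- if (closed) "polygon" else "polyline"
  sprintf('<%s points="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
          tag, pts, fill, colour, svg_num(width))
}

#' Render a fluoroscopy-style overlay scene as SVG
#'
#' Projects the LV mesh (wireframe silhouette), the target-segment
#' outline(s) and the vein polylines into one C-arm view and writes a
#' deterministic SVG (fixed number formatting; identical input gives a
#' byte-identical file). A bullseye sidecar SVG showing the 16-segment
#' polar plot with the target highlighted can be written alongside.
#'
#' @param mesh endocardial reference [phase_mesh()].
#' @param aha `aha_map` for `mesh`.
#' @param report `target_report` (may have no target: the overlay is then
#'   written without a target layer, with a warning).
#' @param veins `vein_tree` or `NULL`.
#' @param view a [carm_view()].
#' @param file output SVG path.
#' @param bullseye_file optional path for the bullseye sidecar SVG.
#' @param ttp optional `ttp_map` used to annotate the bullseye.
#' @return Invisibly, the main SVG path.
#' @export
render_overlay <- function(mesh, aha, report, veins, view, file,
                           bullseye_file = NULL, ttp = NULL) {
  p2 <- project_carm(mesh$vertices, view)
  p2[, 2] <- -p2[, 2]                      # SVG y grows downward
  allpts <- p2
  vein2 <- list()
  if (!is.null(veins)) {
    vein2 <- lapply(veins$branches, function(br) {
      q <- project_carm(br$points, view); q[, 2] <- -q[, 2]; q
    })
    allpts <- rbind(allpts, do.call(rbind, vein2))
  }
  pad <- 5
  xr <- range(allpts[, 1]); yr <- range(allpts[, 2])
  lines_out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" viewBox="%s %s %s %s">',
    svg_num(xr[1] - pad), svg_num(yr[1] - pad),
    svg_num(diff(xr) + 2 * pad), svg_num(diff(yr) + 2 * pad)))
  hull <- grDevices::chull(p2)
  lines_out <- c(lines_out,
                 svg_polyline(p2[hull, , drop = FALSE], "#888888", 0.5,
                              closed = TRUE))
  if (length(report$targets)) {
    for (tg in report$targets) {
      ed <- segment_outline_edges(mesh, aha, tg)
      for (i in seq_len(nrow(ed)))
        lines_out <- c(lines_out,
                       svg_polyline(p2[ed[i, ], , drop = FALSE],
                                    "#d62728", 1.2))
    }
  } else {
    warning("no target segment: overlay written without target layer")
  }
  for (q in vein2)
    lines_out <- c(lines_out, svg_polyline(q, "#1f77b4", 1.0))
  lines_out <- c(lines_out, "</svg>")
  writeLines(lines_out, file)
  if (!is.null(bullseye_file))
    render_bullseye(bullseye_file, targets = report$targets, ttp = ttp)
  invisible(file)
}

#' @rdname render_overlay
#' @param views named list of [carm_view()]s (default the three standard
#'   venography views); one SVG per view is written next to `file_stem`.
#' @param file_stem path stem; files are `<stem>_<view>.svg`.
#' @export
render_overlay_views <- function(mesh, aha, report, veins, file_stem,
                                 views = list(PA = standard_views("PA"),
                                              RAO30 = standard_views("RAO30"),
                                              LAO30 = standard_views("LAO30"))) {
  paths <- character()
  for (nm in names(views)) {
    f <- paste0(file_stem, "_", nm, ".svg")
    suppressWarnings(render_overlay(mesh, aha, report, veins, views[[nm]], f))
    paths <- c(paths, f)
  }
  paths
}

# 16-segment polar plot: basal outer ring, mid, apical inner ring of 4
render_bullseye <- function(file, targets = integer(), ttp = NULL) {
  seg_arc <- function(r0, r1, a0, a1, colour, label_txt, cx = 0, cy = 0) {
    th <- seq(a0, a1, length.out = 24) * pi / 180
    outer_arc <- cbind(cx + r1 * sin(th), cy - r1 * cos(th))
    inner_arc <- cbind(cx + r0 * sin(rev(th)), cy - r0 * cos(rev(th)))
    pts <- rbind(outer_arc, inner_arc)
    poly <- svg_polyline(pts, "#333333", 0.4, fill = colour, closed = TRUE)
    am <- (a0 + a1) / 2 * pi / 180; rm <- (r0 + r1) / 2
    lab <- sprintf(
      '<text x="%s" y="%s" font-size="5" text-anchor="middle">%s</text>',
      svg_num(cx + rm * sin(am)), svg_num(cy - rm * cos(am) + 1.8), label_txt)
    c(poly, lab)
  }
  # bullseye convention: septum drawn to the left, anterior up; our
  # circumferential angle theta (0 = mid-septum, increasing anterior) maps
  # to plot angle -90 - theta... fixed offsets per ring below
  ring <- function(segs, r0, r1, offset) {
    out <- character()
    n <- length(segs)
    for (i in seq_along(segs)) {
      a0 <- offset + (i - 1) * 360 / n
      a1 <- offset + i * 360 / n
      s <- segs[i]
      colour <- if (s %in% targets) "#f4a582" else "#f7f7f7"
      txt <- if (!is.null(ttp)) sprintf("%d:%g", s, ttp$ttp[ttp$segment == s])
      else sprintf("%d", s)
      out <- c(out, seg_arc(r0, r1, a0, a1, colour, txt))
    }
    out
  }
  body <- c(
    ring(c(1, 6, 5, 4, 3, 2), 34, 50, -90),   # basal, seg 1 centred anterior
    ring(c(7, 12, 11, 10, 9, 8), 18, 34, -90),
    ring(c(13, 16, 15, 14), 2, 18, -45))
  writeLines(c('<svg xmlns="http://www.w3.org/2000/svg" viewBox="-55 -55 110 110">',
               body, "</svg>"), file)
  invisible(file)
}
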