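#' Per-vertex circumferential and longitudinal directions
#'
#' At each vertex the longitudinal direction is the projection of the LV
#' long axis onto the local tangent plane and the circumferential
#' direction is `normal x longitudinal`; both are unit length and the
#' triple (circ, long, normal) is an orthonormal basis. Vertices where the
#' long axis is (near-)parallel to the surface normal (the apex tip) are
#' flagged and excluded from directional strain.
#'
#' @param mesh a [phase_mesh()] (normally the end-diastolic reference).
#' @param frame an [lv_frame()].
#' @param tol flag threshold on the tangential norm of the long axis.
#' @return List with n x 3 matrices `circ`, `long`, `normal` and a logical
#'   `flagged` vector.
#' @export
local_directions <- function(mesh, frame, tol = 1e-6) {
  n <- vertex_normals(mesh)
  ax <- frame$long_axis
  lt <- matrix(ax, nrow(n), 3, byrow = TRUE) - outer(drop(n %*% ax), ax)
  len <- sqrt(rowSums(lt^2))
  flagged <- len < tol
  len[flagged] <- 1
  lg <- lt / len
  circ <- cbind(n[, 2] * lg[, 3] - n[, 3] * lg[, 2],
                n[, 3] * lg[, 1] - n[, 1] * lg[, 3],
                n[, 1] * lg[, 2] - n[, 2] * lg[, 1])
  list(circ = circ, long = lg, normal = n, flagged = flagged)
}

#' Lagrangian strain and local area change on a corresponded sequence
#'
#' For every vertex and phase, the deformation is measured on the one-ring
#' neighbourhood relative to the end-diastolic reference (frame 1):
#'
#' * **local area change** `(A - A0)/A0` of the one-ring face area;
#' * **circumferential / longitudinal strain**: reference edges are
#'   expressed by their in-plane components in the local (circ, long)
#'   basis, deformed edges are projected onto the deformed tangent plane,
#'   and a symmetric 2x2 metric `C` is fit by least squares to the squared
#'   in-plane deformed lengths (`|e|^2 = e0' C e0` over the one-ring
#'   edges). The engineering strains are `sqrt(C_cc) - 1` and
#'   `sqrt(C_ll) - 1`; fitting squared lengths of co-rotating projections
#'   makes the measure exactly invariant to rigid motion.
#'
#' Vertices are flagged (and excluded from segment means) at the apex tip,
#' where an edge has zero reference length, or where the one-ring metric
#' fit is rank-deficient.
#'
#' @param seq a [mesh_sequence()] with `correspondence = TRUE`.
#' @param frame an [lv_frame()].
#' @param measures subset of `c("area", "circ", "long")`; directional
#'   strain is costlier and may be skipped.
#' @return Object of class `vertex_strains`: list of n x P matrices
#'   (`area`, and if requested `circ`, `long`), `phases`, and logical
#'   `flagged` (length n).
#' @export
compute_strains <- function(seq, frame, measures = c("area", "circ", "long")) {
  if (!isTRUE(seq$correspondence))
    stop("strain requires a vertex-corresponded sequence")
  measures <- match.arg(measures, c("area", "circ", "long"),
                        several.ok = TRUE)
  ref <- seq$frames[[1]]
  nv <- nrow(ref$vertices)
  P <- length(seq$frames)
  rings <- vertex_one_rings(ref)
  flagged <- logical(nv)

  out <- list(phases = seq$phases)

  if ("area" %in% measures) {
    fa_by_frame <- vapply(seq$frames, face_areas,
                          numeric(nrow(ref$faces)))      # m x P
    ring_area <- function(fa) {
      vapply(rings$faces, function(fi)
        if (length(fi)) sum(fa[fi]) else NA_real_, numeric(1))
    }
    A <- apply(fa_by_frame, 2, ring_area)                # n x P
    A0 <- A[, 1]
    bad <- !is.finite(A0) | A0 <= 0
    flagged <- flagged | bad
    A0[bad] <- 1
    out$area <- sweep(A, 1, A0, "/") - 1
    out$area[bad, ] <- NA_real_
  }

  if (any(c("circ", "long") %in% measures)) {
    dirs <- local_directions(ref, frame)
    flagged <- flagged | dirs$flagged
    circ <- matrix(NA_real_, nv, P)
    long <- matrix(NA_real_, nv, P)
    # edge endpoints per vertex, flattened for vectorized length updates
    nb <- rings$neighbours
    deg <- lengths(nb)
    vi <- rep(seq_len(nv), deg)
    vj <- unlist(nb, use.names = FALSE)
    e0 <- ref$vertices[vj, , drop = FALSE] - ref$vertices[vi, , drop = FALSE]
    # in-plane components of reference edges in the (circ, long) basis of
    # vertex i; the 2D metric C is fit to in-plane deformed edge lengths
    # (deformed edges are projected onto the deformed tangent plane, which
    # makes the fit exactly rigid-motion invariant)
    u1 <- rowSums(e0 * dirs$circ[vi, , drop = FALSE])
    u2 <- rowSums(e0 * dirs$long[vi, , drop = FALSE])
    # design matrix rows for the 3 unique entries of symmetric 2x2 C
    Arow <- cbind(u1^2, u2^2, 2 * u1 * u2)
    idx_by_v <- split(seq_along(vi), vi)
    qr_by_v <- vector("list", nv)
    for (v in seq_len(nv)) {
      if (flagged[v]) next
      rows <- idx_by_v[[as.character(v)]]
      if (is.null(rows) || length(rows) < 3L ||
          any(rowSums(e0[rows, , drop = FALSE]^2) == 0)) {
        flagged[v] <- TRUE
        next
      }
      qd <- qr(Arow[rows, , drop = FALSE])
      if (qd$rank < 3L) { flagged[v] <- TRUE; next }
      qr_by_v[[v]] <- qd
    }
    for (p in seq_len(P)) {
      fp <- seq$frames[[p]]
      np <- vertex_normals(fp)
      ep <- fp$vertices[vj, , drop = FALSE] - fp$vertices[vi, , drop = FALSE]
      en <- rowSums(ep * np[vi, , drop = FALSE])
      b <- rowSums(ep^2) - en^2            # squared in-plane deformed length
      for (v in seq_len(nv)) {
        if (flagged[v]) next
        rows <- idx_by_v[[as.character(v)]]
        cvec <- qr.coef(qr_by_v[[v]], b[rows])
        circ[v, p] <- sqrt(max(cvec[1], 0)) - 1
        long[v, p] <- sqrt(max(cvec[2], 0)) - 1
      }
    }
    if ("circ" %in% measures) out$circ <- circ
    if ("long" %in% measures) out$long <- long
  }

  out$flagged <- flagged
  structure(out, class = "vertex_strains")
}

#' Aggregate per-vertex strain series into AHA segment curves
#'
#' Unweighted mean over the unflagged vertices of each segment, per phase
#' and per measure. Local area change can alternatively be computed from
#' the total segment surface area per phase (`area_mode = "segment_total"`,
#' faces attributed by majority vertex label as in
#' [segment_surface_area()]; default is the vertex mean). Note that both
#' modes measure some neighbouring tissue near segment boundaries (a
#' vertex one-ring or a majority-attributed face can straddle the
#' boundary), which slightly mixes neighbouring segments' motion into a
#' segment's curve. Segments whose vertices are all flagged are flagged
#' themselves and carry `NA` curves.
#'
#' @param strains a `vertex_strains` object from [compute_strains()].
#' @param aha an `aha_map` from [assign_aha()].
#' @param seq the source [mesh_sequence()]; only needed for
#'   `area_mode = "segment_total"`.
#' @param area_mode `"vertex_mean"` or `"segment_total"`.
#' @return Object of class `segment_curves`: list of S x P matrices (one
#'   per measure, rows named by segment id), `phases`, and
#'   `flagged_segments`.
#' @export
aggregate_segments <- function(strains, aha, seq = NULL,
                               area_mode = c("vertex_mean", "segment_total")) {
  area_mode <- match.arg(area_mode)
  S <- aha$n_segments
  lab <- aha$vertex_labels
  ok <- !strains$flagged
  agg <- function(M) {
    t(vapply(seq_len(S), function(s) {
      sel <- lab == s & ok
      if (!any(sel)) return(rep(NA_real_, ncol(M)))
      colMeans(M[sel, , drop = FALSE])
    }, numeric(ncol(M))))
  }
  out <- list(phases = strains$phases)
  for (m in intersect(c("area", "circ", "long"), names(strains)))
    out[[m]] <- agg(strains[[m]])
  if (area_mode == "segment_total") {
    if (is.null(seq)) stop("segment_total area mode needs the mesh sequence")
    fl <- face_labels(seq$frames[[1]], aha)
    fa <- vapply(seq$frames, face_areas, numeric(nrow(seq$frames[[1]]$faces)))
    area <- matrix(NA_real_, S, length(strains$phases))
    for (s in seq_len(S)) {
      sel <- fl == s
      if (!any(sel)) next
      tot <- colSums(fa[sel, , drop = FALSE])
      area[s, ] <- tot / tot[1] - 1
    }
    out$area <- area
  }
  for (m in intersect(c("area", "circ", "long"), names(out)))
    rownames(out[[m]]) <- seq_len(S)
  out$flagged_segments <- which(vapply(seq_len(S), function(s)
    !any(lab == s & ok), logical(1)))
  structure(out, class = "segment_curves")
}

#' Time to peak contraction per AHA segment
#'
#' The phase of peak contraction is the phase of the most negative value
#' of the chosen measure (contraction makes strain and area change
#' negative). Ties are broken to the earliest phase and flagged; segments
#' whose peak contraction magnitude falls below the akinesis threshold are
#' flagged `low_amplitude` (an all-flat curve reports phase 0 and the
#' flag).
#'
#' @param curves a `segment_curves` object.
#' @param measure `"area"` (default: local area change), `"circ"` or
#'   `"long"`.
#' @param akinesis_threshold minimum peak |amplitude| regarded as genuine
#'   contraction (default 0.05).
#' @return data.frame of class `ttp_map`: `segment`, `ttp` (percent RR),
#'   `peak` (signed amplitude at peak), `low_amplitude`, `tie`, `flagged`.
#' @export
time_to_peak <- function(curves, measure = c("area", "circ", "long"),
                         akinesis_threshold = 0.05) {
  measure <- match.arg(measure)
  M <- curves[[measure]]
  if (is.null(M)) stop(sprintf("measure '%s' not present in curves", measure))
  S <- nrow(M)
  res <- data.frame(segment = seq_len(S), ttp = 0, peak = NA_real_,
                    low_amplitude = FALSE, tie = FALSE, flagged = FALSE)
  for (s in seq_len(S)) {
    v <- M[s, ]
    if (all(!is.finite(v))) {
      res$flagged[s] <- TRUE; res$low_amplitude[s] <- TRUE
      next
    }
    i <- which.min(v)                     # earliest phase on ties
    res$ttp[s] <- curves$phases[i]
    res$peak[s] <- v[i]
    res$tie[s] <- sum(abs(v - v[i]) < 1e-12) > 1L
    res$low_amplitude[s] <- abs(v[i]) < akinesis_threshold
  }
  class(res) <- c("ttp_map", "data.frame")
  res
}
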