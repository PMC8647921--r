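#' Read and write surface meshes as ASCII PLY or OFF
#'
#' Minimal readers/writers for the two plain-text mesh formats used by the
#' pipeline. Vertex coordinates are written with full precision
#' (`%.9g`); face indices are 0-based on disk (the formats' convention)
#' and 1-based in memory.
#'
#' @param mesh a [phase_mesh()].
#' @param file path; format chosen by extension (`.ply` / `.off`) unless
#'   `format` is given.
#' @param format `"ply"` or `"off"`.
#' @param phase phase to stamp on the mesh read back (PLY/OFF carry none).
#' @return `write_mesh` returns the path invisibly; `read_mesh` a
#'   [phase_mesh()].
#' @name mesh_io
#' @export
write_mesh <- function(mesh, file, format = c("auto", "ply", "off")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.off$", file, ignore.case = TRUE)) "off" else "ply"
  v <- mesh$vertices; f <- mesh$faces - 1L
  if (format == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property float x", "property float y", "property float z",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    body <- c(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
              sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]))
    writeLines(c(hdr, body), file)
  } else {
    writeLines(c("OFF", sprintf("%d %d 0", nrow(v), nrow(f)),
                 sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
                 sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])), file)
  }
  invisible(file)
}

#' @rdname mesh_io
#' @export
read_mesh <- function(file, phase = 0) {
  ln <- readLines(file)
  ln <- trimws(ln)
  if (identical(ln[1], "OFF")) {
    counts <- scan(text = ln[2], quiet = TRUE)
    nv <- counts[1]; nf <- counts[2]
    v <- matrix(scan(text = ln[3:(2 + nv)], quiet = TRUE), ncol = 3,
                byrow = TRUE)
    fr <- matrix(scan(text = ln[(3 + nv):(2 + nv + nf)], quiet = TRUE),
                 ncol = 4, byrow = TRUE)
    return(phase_mesh(v, fr[, 2:4] + 1L, phase))
  }
  if (!identical(ln[1], "ply")) stop("not a PLY or OFF file")
  endh <- which(ln == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", ln, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", ln, value = TRUE)[1]))
  v <- matrix(scan(text = ln[(endh + 1):(endh + nv)], quiet = TRUE),
              ncol = 3, byrow = TRUE)
  fr <- matrix(scan(text = ln[(endh + nv + 1):(endh + nv + nf)],
                    quiet = TRUE), ncol = 4, byrow = TRUE)
  phase_mesh(v, fr[, 2:4] + 1L, phase)
}

#' Read and write a mesh sequence as per-phase files plus a JSON manifest
#'
#' Each phase is one PLY file next to a manifest recording the phase list,
#' layer, correspondence flag and the LV frame metadata, so a sequence is
#' self-describing on disk.
#'
#' @param seq a [mesh_sequence()].
#' @param dir output directory (created if needed).
#' @param frame optional [lv_frame()] stored in the manifest.
#' @param stem file stem for the per-phase PLY files.
#' @return `write_mesh_sequence` returns the manifest path; `
#'   read_mesh_sequence` a list with `seq` and `frame` (or `NULL`).
#' @name sequence_io
#' @export
write_mesh_sequence <- function(seq, dir, frame = NULL, stem = "phase") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%03d.ply", stem, as.integer(seq$phases))
  for (i in seq_along(seq$frames))
    write_mesh(seq$frames[[i]], file.path(dir, files[i]))
  manifest <- list(phases = seq$phases, files = files, layer = seq$layer,
                   correspondence = seq$correspondence)
  if (!is.null(frame))
    manifest$lv_frame <- list(apex = frame$apex,
                              base_centroid = frame$base_centroid,
                              long_axis = frame$long_axis,
                              septal_dir = frame$septal_dir)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname sequence_io
#' @param manifest path to a `manifest.json`.
#' @export
read_mesh_sequence <- function(manifest) {
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  frames <- lapply(seq_along(m$files), function(i)
    read_mesh(file.path(dir, m$files[i]), phase = m$phases[i]))
  seq <- mesh_sequence(frames, correspondence = isTRUE(m$correspondence),
                       layer = m$layer)
  frame <- NULL
  if (!is.null(m$lv_frame))
    frame <- lv_frame(m$lv_frame$apex, m$lv_frame$base_centroid,
                      m$lv_frame$long_axis, m$lv_frame$septal_dir)
  list(seq = seq, frame = frame)
}

#' Read and write binary volumes as NIfTI
#'
#' @param vol a [binary_volume()].
#' @param file `.nii` or `.nii.gz` path.
#' @return `read_volume_nifti` returns a [binary_volume()].
#' @name volume_io
#' @export
write_volume_nifti <- function(vol, file) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname volume_io
#' @param origin world position of voxel (1,1,1) (NIfTI origins are not
#'   round-tripped by this minimal wrapper).
#' @export
read_volume_nifti <- function(file, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(file)
  binary_volume(array(as.integer(img > 0.5), dim = dim(img)),
                spacing = RNifti::pixdim(img)[1:3], origin = origin)
}

#' Export segment curves and time-to-peak tables
#'
#' `write_segment_curves` writes one CSV per measure (segment x phase
#' matrix, phases as columns); `write_ttp` writes the per-segment
#' time-to-peak table as CSV; `write_target_report` serializes a target
#' report (eligibility table, ranking, chosen targets) as JSON;
#' `write_vein_tree` / `read_vein_tree` store vein polylines as JSON.
#'
#' @param curves a `segment_curves`.
#' @param stem path stem; files are `<stem>_<measure>.csv`.
#' @return The written path(s), invisibly.
#' @name table_io
#' @export
write_segment_curves <- function(curves, stem) {
  paths <- character()
  for (m in intersect(c("area", "circ", "long"), names(curves))) {
    df <- data.frame(segment = seq_len(nrow(curves[[m]])), curves[[m]],
                     check.names = FALSE)
    names(df)[-1] <- sprintf("phase_%g", curves$phases)
    p <- sprintf("%s_%s.csv", stem, m)
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname table_io
#' @param ttp a `ttp_map`.
#' @param file output path.
#' @export
write_ttp <- function(ttp, file) {
  utils::write.csv(as.data.frame(ttp), file, row.names = FALSE)
  invisible(file)
}

#' @rdname table_io
#' @param report a `target_report`.
#' @export
write_target_report <- function(report, file) {
  jsonlite::write_json(
    list(targets = report$targets, ranking = report$ranking,
         reason = report$reason, table = report$table),
    file, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(file)
}

#' @rdname table_io
#' @param veins a `vein_tree`.
#' @export
write_vein_tree <- function(veins, file) {
  jsonlite::write_json(
    lapply(veins$branches, function(b)
      list(label = b$label, points = unname(b$points))),
    file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname table_io
#' @export
read_vein_tree <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  branches <- lapply(seq_len(nrow_or_len(raw)), function(i)
    list(label = raw$label[[i]], points = as.matrix(raw$points[[i]])))
  structure(list(branches = branches), class = "vein_tree")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
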