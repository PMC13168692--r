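# ASCII mesh readers/writers (OBJ, PLY, STL) and scale calibration.
#
# OBJ face groups (g/o lines) carry tagma labels; PLY and STL carry none
# (STL selections are therefore whole-body only unless a label sidecar is
# supplied).

#' Read a triangulated surface mesh
#'
#' Supports ASCII OBJ (face groups become face labels), ASCII PLY and ASCII
#' STL. Polygonal OBJ/PLY faces are fan-triangulated. Degenerate faces are
#' removed on construction.
#'
#' @param path Path to the mesh file.
#' @param format `"obj"`, `"ply"`, `"stl"` or `"auto"` (from the file
#'   extension).
#' @param labels Optional path to a label sidecar: a headered CSV with
#'   columns `face_start`, `face_end` (1-based inclusive face-index ranges)
#'   and `label`, or columns `group` and `label` to rename OBJ groups.
#' @return A `triangle_mesh` (uncalibrated).
#' @export
read_mesh <- function(path, format = c("auto", "obj", "ply", "stl"),
                      labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("mesh_format: file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("obj", "ply", "stl")) {
      stop("mesh_format: cannot infer format from extension '", format, "'",
           call. = FALSE)
    }
  }
  mesh <- switch(format,
                 obj = read_obj(path),
                 ply = read_ply(path),
                 stl = read_stl(path))
  if (!is.null(labels)) mesh <- apply_label_sidecar(mesh, labels)
  mesh
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("mesh_format: empty OBJ file", call. = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  faces <- list()
  labels <- character()
  group <- NA_character_
  for (ln in lines) {
    if (startsWith(ln, "g ") || startsWith(ln, "o ")) {
      group <- trimws(substring(ln, 3))
    } else if (startsWith(ln, "f ")) {
      parts <- strsplit(ln, "\\s+")[[1]][-1]
      # "v", "v/vt", "v//vn", "v/vt/vn" all start with the vertex index
      idx <- as.integer(vapply(strsplit(parts, "/"), `[`, "", 1))
      if (anyNA(idx)) stop("mesh_format: unparseable face line", call. = FALSE)
      idx[idx < 0] <- nrow(verts) + 1L + idx[idx < 0]
      for (k in seq_len(length(idx) - 2)) {  # fan triangulation
        faces[[length(faces) + 1L]] <- c(idx[1], idx[k + 1], idx[k + 2])
        labels <- c(labels, group)
      }
    }
  }
  if (length(faces) == 0) stop("mesh_format: OBJ has no faces", call. = FALSE)
  triangle_mesh(verts, do.call(rbind, faces),
                face_labels = if (all(is.na(labels))) NULL else labels)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply") {
    stop("mesh_format: not an ASCII PLY file", call. = FALSE)
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("mesh_format: PLY header not terminated", call. = FALSE)
  header <- trimws(lines[seq_len(end)])
  if (!any(grepl("^format ascii", header))) {
    stop("mesh_format: only ASCII PLY is supported", call. = FALSE)
  }
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) {
    stop("mesh_format: PLY header missing vertex/face elements", call. = FALSE)
  }
  body <- trimws(lines[-seq_len(end)])
  body <- body[nzchar(body)]
  vparts <- strsplit(body[seq_len(nv)], "\\s+")
  verts <- do.call(rbind, lapply(vparts, function(p) as.numeric(p[1:3])))
  faces <- list()
  for (ln in body[nv + seq_len(nf)]) {
    p <- as.integer(strsplit(ln, "\\s+")[[1]])
    cnt <- p[1]
    idx <- p[2:(1 + cnt)] + 1L  # PLY is 0-based
    for (k in seq_len(cnt - 2)) {
      faces[[length(faces) + 1L]] <- c(idx[1], idx[k + 1], idx[k + 2])
    }
  }
  triangle_mesh(verts, do.call(rbind, faces))
}

read_stl <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  if (length(lines) == 0 || !startsWith(lines[1], "solid")) {
    stop("mesh_format: only ASCII STL is supported", call. = FALSE)
  }
  vlines <- lines[startsWith(lines, "vertex")]
  if (length(vlines) == 0 || length(vlines) %% 3 != 0) {
    stop("mesh_format: STL vertex count is not a multiple of 3", call. = FALSE)
  }
  coords <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  # deduplicate identical vertices so the mesh is connected
  key <- apply(coords, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  verts <- coords[uniq, , drop = FALSE]
  remap <- match(key, key[uniq])
  faces <- matrix(remap, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

apply_label_sidecar <- function(mesh, sidecar_path) {
  sc <- utils::read.csv(sidecar_path, stringsAsFactors = FALSE)
  labels <- mesh$face_labels
  if (all(c("face_start", "face_end", "label") %in% names(sc))) {
    if (is.null(labels)) labels <- rep(NA_character_, nrow(mesh$faces))
    for (i in seq_len(nrow(sc))) {
      labels[sc$face_start[i]:sc$face_end[i]] <- sc$label[i]
    }
  } else if (all(c("group", "label") %in% names(sc))) {
    if (is.null(labels)) {
      stop("mesh_format: group sidecar needs a mesh with face groups",
           call. = FALSE)
    }
    hit <- match(labels, sc$group)
    labels[!is.na(hit)] <- sc$label[hit[!is.na(hit)]]
  } else {
    stop("mesh_format: sidecar needs (face_start, face_end, label) or ",
         "(group, label) columns", call. = FALSE)
  }
  mesh$face_labels <- labels
  mesh
}

#' Write a mesh as ASCII OBJ
#'
#' Face labels are written as OBJ groups so they round-trip through
#' [read_mesh()].
#'
#' @param mesh A `triangle_mesh`.
#' @param path Output path.
#' @param digits Significant digits for vertex coordinates.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.*g %.*g %.*g", digits, mesh$vertices[, 1],
                     digits, mesh$vertices[, 2], digits, mesh$vertices[, 3]),
             con)
  f <- mesh$faces
  labels <- mesh$face_labels
  if (is.null(labels)) {
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else {
    ord <- order(labels)
    f <- f[ord, , drop = FALSE]
    labels <- labels[ord]
    prev <- ""
    for (i in seq_len(nrow(f))) {
      if (!identical(labels[i], prev)) {
        writeLines(paste("g", labels[i]), con)
        prev <- labels[i]
      }
      writeLines(sprintf("f %d %d %d", f[i, 1], f[i, 2], f[i, 3]), con)
    }
  }
  invisible(path)
}

#' Scale-calibration record
#'
#' Captures the scalebar used to convert model units to mm: one known length
#' imaged alongside the specimens plus three verification (known, measured)
#' pairs re-checked after scaling.
#'
#' @param known_length_mm Physical scalebar length (mm).
#' @param measured_length_model_units The same length measured on the model,
#'   in model units.
#' @param verification_pairs Optional 2-column matrix/data frame of (known
#'   mm, measured model units) verification lengths; three pairs by
#'   convention.
#' @return A `calibration_record` with the derived `scale_factor`.
#' @export
calibration_record <- function(known_length_mm, measured_length_model_units,
                               verification_pairs = NULL) {
  stopifnot(known_length_mm > 0, measured_length_model_units > 0)
  if (!is.null(verification_pairs)) {
    verification_pairs <- as.matrix(verification_pairs)
    stopifnot(ncol(verification_pairs) == 2, all(verification_pairs > 0))
  }
  structure(list(known_length_mm = known_length_mm,
                 measured_length_model_units = measured_length_model_units,
                 scale_factor = known_length_mm / measured_length_model_units,
                 verification_pairs = verification_pairs),
            class = "calibration_record")
}

#' Calibrate a mesh to mm
#'
#' Scales every vertex by `known/measured` and re-checks each verification
#' pair at the new scale; any pair off by more than `tolerance` (relative)
#' aborts with the offending pairs listed.
#'
#' @param mesh An uncalibrated `triangle_mesh`.
#' @param calibration A [calibration_record()].
#' @param tolerance Relative tolerance for verification lengths (default
#'   0.02, i.e. 2%).
#' @return The calibrated mesh (`units_calibrated = TRUE`).
#' @export
apply_calibration <- function(mesh, calibration, tolerance = 0.02) {
  stopifnot(inherits(calibration, "calibration_record"))
  if (mesh$units_calibrated) {
    warning("mesh is already flagged calibrated; rescaling anyway")
  }
  s <- calibration$scale_factor
  vp <- calibration$verification_pairs
  if (!is.null(vp)) {
    scaled <- vp[, 2] * s
    rel <- abs(scaled - vp[, 1]) / vp[, 1]
    bad <- which(rel > tolerance)
    if (length(bad) > 0) {
      stop("calibration_error: verification pair(s) outside tolerance: ",
           paste(sprintf("known %.4g mm vs scaled %.4g mm (%.2f%%)",
                         vp[bad, 1], scaled[bad], 100 * rel[bad]),
                 collapse = "; "), call. = FALSE)
    }
  }
  mesh$vertices <- mesh$vertices * s
  mesh$units_calibrated <- TRUE
  mesh
}

#' Measure a labelled specimen mesh
#'
#' Produces the empirical analogue of the geometric size table: surface area
#' and volume per tagma (appendage faces excluded), the tagmata sum, and the
#' whole body including appendages. Tagma sub-meshes cut from a closed body
#' are closed by planar-fan capping before the volume integral; cap faces
#' never count toward surface area.
#'
#' @param mesh A calibrated, labelled `triangle_mesh`.
#' @param specimen_id Identifier copied into the output rows.
#' @return A size-table data frame with columns `specimen_id`, `method`
#'   (`"model_tagmata"` / `"model_whole_body"`), `scope`, `surface_area_mm2`,
#'   `volume_mm3`, `watertight`.
#' @export
measure_mesh <- function(mesh, specimen_id = "specimen") {
  if (!mesh$units_calibrated) {
    warning("mesh is not flagged calibrated; units may not be mm")
  }
  whole_rep <- watertight_report(mesh)
  rows <- list()
  if (!is.null(mesh$face_labels) &&
      any(TAGMA_LABELS %in% mesh$face_labels)) {
    sa <- vol <- numeric(0)
    for (tg in TAGMA_LABELS) {
      if (!tg %in% mesh$face_labels) next
      sub <- submesh(mesh, tg)
      area <- mesh_area(sub, labels = NULL)
      volume <- mesh_volume(sub, cap = TRUE)
      wt <- watertight_report(sub)$watertight
      rows[[tg]] <- data.frame(specimen_id = specimen_id,
                               method = "model_tagmata", scope = tg,
                               surface_area_mm2 = area, volume_mm3 = volume,
                               watertight = wt, stringsAsFactors = FALSE)
      sa <- c(sa, area); vol <- c(vol, volume)
    }
    rows$tagmata_sum <- data.frame(specimen_id = specimen_id,
                                   method = "model_tagmata",
                                   scope = "tagmata_sum",
                                   surface_area_mm2 = sum(sa),
                                   volume_mm3 = sum(vol),
                                   watertight = all(vapply(rows, function(r)
                                     r$watertight, logical(1))),
                                   stringsAsFactors = FALSE)
  }
  rows$whole_body <- data.frame(specimen_id = specimen_id,
                                method = "model_whole_body",
                                scope = "whole_body",
                                surface_area_mm2 = mesh_area(mesh),
                                volume_mm3 = mesh_volume(mesh, cap = TRUE),
                                watertight = whole_rep$watertight,
                                stringsAsFactors = FALSE)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
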