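# Triangle-mesh container and morphometric measurements.
#
# A mesh is a list: `vertices` (n x 3 numeric matrix, mm once calibrated),
# `faces` (m x 3 integer matrix of vertex indices with consistent outward
# winding), `face_labels` (character per face: head/mesosoma/metasoma/wing/
# leg/antenna/tongue/stinger/other, or NA when unlabeled) and
# `units_calibrated` (logical). Surface area is the summed triangle area
# (half cross-product magnitude); volume is the divergence-theorem signed
# tetrahedron sum, valid only on closed, consistently oriented selections.

DEGENERATE_AREA_MM2 <- 1e-12

TAGMA_LABELS <- c("head", "mesosoma", "metasoma")
APPENDAGE_LABELS <- c("wing", "leg", "antenna", "tongue", "stinger", "other")

#' Construct a triangle mesh
#'
#' Validates faces, drops degenerate (zero-area) triangles with a message,
#' and attaches optional per-face tagma/appendage labels.
#'
#' @param vertices Numeric matrix, one 3D point per row.
#' @param faces Integer matrix, one triangle (three vertex indices) per row.
#' @param face_labels Optional character vector, one label per face.
#' @param units_calibrated Logical; `TRUE` once vertices are in mm.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, face_labels = NULL,
                          units_calibrated = FALSE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) == 0 || nrow(vertices) == 0) {
    stop("mesh_format: mesh has no faces or no vertices", call. = FALSE)
  }
  if (min(faces) < 1 || max(faces) > nrow(vertices)) {
    stop("mesh_format: face indices out of range", call. = FALSE)
  }
  if (!is.null(face_labels) && length(face_labels) != nrow(faces)) {
    stop("mesh_format: face_labels length must equal the face count",
         call. = FALSE)
  }
  mesh <- structure(list(vertices = vertices, faces = faces,
                         face_labels = face_labels,
                         units_calibrated = isTRUE(units_calibrated)),
                    class = "triangle_mesh")
  areas <- mesh_face_areas(mesh)
  bad <- areas < DEGENERATE_AREA_MM2
  if (any(bad)) {
    message(sprintf("removed %d degenerate face(s)", sum(bad)))
    mesh$faces <- mesh$faces[!bad, , drop = FALSE]
    if (!is.null(mesh$face_labels)) mesh$face_labels <- mesh$face_labels[!bad]
    if (nrow(mesh$faces) == 0) {
      stop("mesh_format: all faces degenerate", call. = FALSE)
    }
  }
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  lab <- if (is.null(x$face_labels)) "unlabeled" else
    paste(sort(unique(x$face_labels)), collapse = ", ")
  cat(sprintf("<triangle_mesh> %d vertices, %d faces (%s)%s\n",
              nrow(x$vertices), nrow(x$faces), lab,
              if (x$units_calibrated) ", calibrated mm" else ""))
  invisible(x)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

mesh_face_areas <- function(mesh, faces = mesh$faces) {
  v <- mesh$vertices
  e1 <- v[faces[, 2], , drop = FALSE] - v[faces[, 1], , drop = FALSE]
  e2 <- v[faces[, 3], , drop = FALSE] - v[faces[, 1], , drop = FALSE]
  0.5 * sqrt(rowSums(cross3(e1, e2)^2))
}

select_faces <- function(mesh, labels) {
  if (is.null(labels)) return(seq_len(nrow(mesh$faces)))
  if (is.null(mesh$face_labels)) {
    warning("mesh is unlabeled; measuring the whole mesh")
    return(seq_len(nrow(mesh$faces)))
  }
  which(mesh$face_labels %in% labels)
}

#' Mesh surface area
#'
#' Sum of triangle areas over the faces passing the label filter.
#'
#' @param mesh A `triangle_mesh`.
#' @param labels Optional character vector of face labels to include;
#'   `NULL` measures every face.
#' @return Surface area (mm^2 for a calibrated mesh).
#' @export
mesh_area <- function(mesh, labels = NULL) {
  idx <- select_faces(mesh, labels)
  if (length(idx) == 0) {
    warning("empty face selection; surface area is 0")
    return(0)
  }
  sum(mesh_face_areas(mesh, mesh$faces[idx, , drop = FALSE]))
}

#' Extract a labelled submesh
#'
#' @inheritParams mesh_area
#' @return A `triangle_mesh` containing only the selected faces, with
#'   vertices re-indexed.
#' @export
submesh <- function(mesh, labels = NULL) {
  idx <- select_faces(mesh, labels)
  if (length(idx) == 0) stop("mesh_format: empty face selection", call. = FALSE)
  f <- mesh$faces[idx, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(remap[f], ncol = 3),
                face_labels = if (is.null(mesh$face_labels)) NULL else
                  mesh$face_labels[idx],
                units_calibrated = mesh$units_calibrated)
}

# Directed half-edges as a 3m x 2 matrix in face order.
half_edges <- function(faces) {
  rbind(faces[, 1:2, drop = FALSE], faces[, 2:3, drop = FALSE],
        faces[, c(3, 1), drop = FALSE])
}

undirected_key <- function(edges, n_vertices) {
  lo <- pmin(edges[, 1], edges[, 2])
  hi <- pmax(edges[, 1], edges[, 2])
  (as.numeric(lo) - 1) * n_vertices + as.numeric(hi)
}

#' Watertightness diagnostics
#'
#' Reports boundary-edge and non-manifold-edge counts, orientation
#' consistency and the Euler characteristic. For a single closed,
#' consistently oriented genus-0 surface the Euler characteristic is 2 (or
#' 2 per connected component for a composite of closed solids).
#'
#' @param mesh A `triangle_mesh`.
#' @return A list: `boundary_edges`, `non_manifold_edges`,
#'   `oriented_consistently`, `euler_characteristic`, `n_components`,
#'   `watertight` (zero boundary edges, manifold, consistent orientation).
#' @export
watertight_report <- function(mesh) {
  he <- half_edges(mesh$faces)
  nv_ref <- length(unique(as.vector(mesh$faces)))
  n <- nrow(mesh$vertices)
  ukey <- undirected_key(he, n)
  ucount <- table(ukey)
  boundary <- sum(ucount == 1)
  non_manifold <- sum(ucount > 2)
  # Orientation consistent iff no directed edge repeats (every shared
  # undirected edge is traversed once in each direction).
  dkey <- (as.numeric(he[, 1]) - 1) * n + as.numeric(he[, 2])
  oriented <- !anyDuplicated(dkey)
  euler <- nv_ref - length(ucount) + nrow(mesh$faces)
  comps <- count_components(mesh$faces, n)
  list(boundary_edges = boundary,
       non_manifold_edges = non_manifold,
       oriented_consistently = oriented,
       euler_characteristic = euler,
       n_components = comps,
       watertight = boundary == 0 && non_manifold == 0 && oriented)
}

count_components <- function(faces, n_vertices) {
  used <- sort(unique(as.vector(faces)))
  idx <- integer(n_vertices)
  idx[used] <- seq_along(used)
  parent <- seq_along(used)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  f <- matrix(idx[faces], ncol = 3)
  for (k in seq_len(nrow(f))) {
    unite(f[k, 1], f[k, 2])
    unite(f[k, 2], f[k, 3])
  }
  length(unique(vapply(seq_along(used), find, integer(1))))
}

boundary_half_edges <- function(mesh) {
  he <- half_edges(mesh$faces)
  ukey <- undirected_key(he, nrow(mesh$vertices))
  counts <- table(ukey)
  singles <- names(counts)[counts == 1]
  he[ukey %in% as.numeric(singles), , drop = FALSE]
}

# Group boundary half-edges into loops by shared vertices (union-find on the
# edge endpoints), returning a list of half-edge matrices.
boundary_loops <- function(mesh) {
  be <- boundary_half_edges(mesh)
  if (nrow(be) == 0) return(list())
  verts <- sort(unique(as.vector(be)))
  idx <- integer(max(verts))
  idx[verts] <- seq_along(verts)
  parent <- seq_along(verts)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(be))) {
    a <- find(idx[be[k, 1]]); b <- find(idx[be[k, 2]])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(idx[be[, 1]], find, integer(1))
  lapply(split(seq_len(nrow(be)), roots),
         function(rows) be[rows, , drop = FALSE])
}

#' Cap boundary loops with planar fans
#'
#' Closes each boundary loop by fanning triangles from the loop centroid,
#' oriented to match the surrounding surface. Cap faces are labelled
#' `"cap"` so they can be excluded from surface-area measurements.
#'
#' @param mesh A `triangle_mesh` with one or more boundary loops.
#' @return A closed `triangle_mesh`.
#' @export
cap_boundary_loops <- function(mesh) {
  loops <- boundary_loops(mesh)
  if (length(loops) == 0) return(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  labels <- mesh$face_labels
  if (is.null(labels)) labels <- rep(NA_character_, nrow(f))
  for (loop in loops) {
    centroid <- colMeans(v[unique(as.vector(loop)), , drop = FALSE])
    v <- rbind(v, centroid)
    ci <- nrow(v)
    # boundary half-edge (a -> b) belongs to a face; the cap triangle
    # (b, a, centroid) restores consistent outward orientation
    new_faces <- cbind(loop[, 2], loop[, 1], ci)
    f <- rbind(f, new_faces)
    labels <- c(labels, rep("cap", nrow(new_faces)))
  }
  triangle_mesh(v, f, face_labels = labels,
                units_calibrated = mesh$units_calibrated)
}

signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  sum(rowSums(a * cross3(b, c3))) / 6
}

#' Mesh volume via the divergence theorem
#'
#' Absolute value of the signed tetrahedron sum over a closed, consistently
#' oriented selection. An open selection is an error unless `cap = TRUE`, in
#' which case each boundary loop is closed with a planar fan first (the cap
#' contributes to the volume, never to surface area).
#'
#' @inheritParams mesh_area
#' @param cap Close boundary loops before integrating (default `FALSE`).
#' @return Volume (mm^3 for a calibrated mesh).
#' @export
mesh_volume <- function(mesh, labels = NULL, cap = FALSE) {
  sel <- if (is.null(labels)) mesh else submesh(mesh, labels)
  rep <- watertight_report(sel)
  if (!rep$oriented_consistently || rep$non_manifold_edges > 0) {
    stop("mesh_not_watertight: inconsistent orientation or non-manifold edges; ",
         "repair the mesh before measuring volume", call. = FALSE)
  }
  if (rep$boundary_edges > 0) {
    if (!cap) {
      stop(sprintf(
        "mesh_not_watertight: selection has %d boundary edge(s); pass cap = TRUE to close boundary loops",
        rep$boundary_edges), call. = FALSE)
    }
    sel <- cap_boundary_loops(sel)
  }
  abs(signed_volume(sel))
}

#' Rigid and similarity transforms
#'
#' @param mesh A `triangle_mesh`.
#' @param factor Uniform scale factor.
#' @return The transformed mesh.
#' @export
scale_mesh <- function(mesh, factor) {
  stopifnot(is.numeric(factor), factor > 0)
  mesh$vertices <- mesh$vertices * factor
  mesh
}

#' @rdname scale_mesh
#' @param offset Length-3 translation vector.
#' @export
translate_mesh <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, offset, "+")
  mesh
}

#' @rdname scale_mesh
#' @param yaw,pitch,roll Rotation angles in radians about z, y and x.
#' @export
rotate_mesh <- function(mesh, yaw = 0, pitch = 0, roll = 0) {
  rz <- matrix(c(cos(yaw), -sin(yaw), 0, sin(yaw), cos(yaw), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  ry <- matrix(c(cos(pitch), 0, sin(pitch), 0, 1, 0, -sin(pitch), 0,
                 cos(pitch)), 3, 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cos(roll), -sin(roll), 0, sin(roll), cos(roll)),
               3, 3, byrow = TRUE)
  mesh$vertices <- mesh$vertices %*% t(rz %*% ry %*% rx)
  mesh
}
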