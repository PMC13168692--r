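# Deterministic mesh generators with analytic ground truth.
#
# These produce the watertight fixtures the measurement code is tested
# against: icospheres, capped cylinders, cones, the cylinder+cone metasoma
# composite, and a disjoint three-solid "composite bee" whose analytic
# surface areas and volumes come from the same closed-form estimators used
# for caliper data (so cap conventions match exactly). All tessellations
# inscribe their vertices on the ideal surface, so measured area and volume
# converge to the analytic values from below as the level grows.

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto the sphere; vertices lie exactly on
#' the sphere, so mesh area and volume approach the analytic values from
#' below as `level` increases.
#'
#' @param diameter Sphere diameter (mm).
#' @param level Subdivision level (0 = icosahedron; each level quadruples
#'   the face count). Level 4 gives 5120 faces and < 0.1% volume error.
#' @param label Optional face label applied to every face.
#' @return A `triangle_mesh`.
#' @export
icosphere <- function(diameter = 1, level = 4, label = NULL) {
  stopifnot(diameter > 0, level >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(level)) {
    cache <- new.env(hash = TRUE)
    nf <- matrix(0L, nrow(f) * 4, 3)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      cache[[key]] <- nrow(v)
      nrow(v)
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(c3, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v * (diameter / 2)
  triangle_mesh(v, f,
                face_labels = if (is.null(label)) NULL else
                  rep(label, nrow(f)))
}

ring_points <- function(radius, z, n) {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  cbind(radius * cos(theta), radius * sin(theta), z)
}

# Lateral band between two same-size rings of vertex indices (counter-
# clockwise seen from +z); outward-facing winding.
band_faces <- function(bottom_idx, top_idx) {
  n <- length(bottom_idx)
  nxt <- c(2:n, 1)
  rbind(cbind(bottom_idx, bottom_idx[nxt], top_idx[nxt]),
        cbind(bottom_idx, top_idx[nxt], top_idx))
}

fan_faces <- function(ring_idx, center_idx, outward_up) {
  n <- length(ring_idx)
  nxt <- c(2:n, 1)
  if (outward_up) cbind(center_idx, ring_idx, ring_idx[nxt])
  else cbind(center_idx, ring_idx[nxt], ring_idx)
}

#' Capped cylinder, cone and metasoma composite meshes
#'
#' `cylinder_mesh` builds a closed cylinder along +z; `cone_mesh` a closed
#' cone (base cap down); `metasoma_mesh` the cylinder+cone composite with an
#' anterior cap, shared junction ring, and no junction disc. `segments` is
#' the angular resolution; vertices are inscribed so measurements converge
#' to the analytic values from below.
#'
#' @param diameter,length,height Dimensions in mm.
#' @param segments Number of angular segments.
#' @param label Optional face label for every face.
#' @return A `triangle_mesh`.
#' @export
cylinder_mesh <- function(diameter, length, segments = 64, label = NULL) {
  stopifnot(diameter > 0, length > 0, segments >= 3)
  r <- diameter / 2
  n <- segments
  v <- rbind(ring_points(r, 0, n), ring_points(r, length, n),
             c(0, 0, 0), c(0, 0, length))
  bot <- 1:n; top <- n + 1:n
  f <- rbind(band_faces(bot, top),
             fan_faces(bot, 2 * n + 1, outward_up = FALSE),
             fan_faces(top, 2 * n + 2, outward_up = TRUE))
  triangle_mesh(v, f, face_labels = if (is.null(label)) NULL else
    rep(label, nrow(f)))
}

#' @rdname cylinder_mesh
#' @export
cone_mesh <- function(diameter, height, segments = 64, label = NULL) {
  stopifnot(diameter > 0, height > 0, segments >= 3)
  r <- diameter / 2
  n <- segments
  v <- rbind(ring_points(r, 0, n), c(0, 0, height), c(0, 0, 0))
  base <- 1:n
  nxt <- c(2:n, 1)
  f <- rbind(cbind(base, base[nxt], n + 1),            # lateral, apex up
             fan_faces(base, n + 2, outward_up = FALSE))
  triangle_mesh(v, f, face_labels = if (is.null(label)) NULL else
    rep(label, nrow(f)))
}

#' @rdname cylinder_mesh
#' @param anterior_length Cylinder length (m5, mm).
#' @param posterior_length Cone height (m6, mm); zero closes the posterior
#'   end with a flat cap.
#' @export
metasoma_mesh <- function(diameter, anterior_length, posterior_length,
                          segments = 64, label = NULL) {
  stopifnot(diameter > 0, anterior_length > 0, posterior_length >= 0,
            segments >= 3)
  r <- diameter / 2
  n <- segments
  v <- rbind(ring_points(r, 0, n), ring_points(r, anterior_length, n),
             c(0, 0, 0))
  bot <- 1:n; top <- n + 1:n
  f <- rbind(band_faces(bot, top),
             fan_faces(bot, 2 * n + 1, outward_up = FALSE))  # anterior cap
  nxt <- c(2:n, 1)
  if (posterior_length > 0) {
    v <- rbind(v, c(0, 0, anterior_length + posterior_length))
    f <- rbind(f, cbind(top, top[nxt], nrow(v)))             # cone lateral
  } else {
    v <- rbind(v, c(0, 0, anterior_length))
    f <- rbind(f, fan_faces(top, nrow(v), outward_up = TRUE))  # flat cap
  }
  triangle_mesh(v, f, face_labels = if (is.null(label)) NULL else
    rep(label, nrow(f)))
}

merge_meshes <- function(meshes) {
  offs <- 0L
  vs <- list(); fs <- list(); ls <- list()
  for (m in meshes) {
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$faces + offs
    ls[[length(ls) + 1L]] <- if (is.null(m$face_labels))
      rep(NA_character_, nrow(m$faces)) else m$face_labels
    offs <- offs + nrow(m$vertices)
  }
  triangle_mesh(do.call(rbind, vs), do.call(rbind, fs),
                face_labels = unlist(ls))
}

#' Composite synthetic bee mesh
#'
#' Three disjoint closed solids — cylinder head, icosphere mesosoma,
#' cylinder+cone metasoma — placed along the x axis and labelled per tagma.
#' The solid dimensions map onto the six caliper measurements exactly as in
#' the closed-form estimators, and the returned analytic truths are computed
#' by those estimators, so formula-vs-mesh comparisons share cap
#' conventions. This is a synthetic stand-in for a photogrammetric specimen:
#' ideal solids, no appendages, no hair.
#'
#' @param measurements List/row with the six caliper measurements (see
#'   [estimate_specimen()]).
#' @param level Tessellation level: spheres use icosphere subdivision
#'   `level`, cylinders/cones use `2^level * 4` angular segments.
#' @return List: `mesh` (labelled, watertight `triangle_mesh`), `analytic`
#'   (per-tagma and summed surface areas/volumes from the closed-form
#'   estimators).
#' @export
composite_bee_mesh <- function(measurements, level = 4) {
  m <- as.list(measurements)
  segments <- 4L * 2L^level
  gap <- 2 * max(unlist(m[MEASUREMENT_COLUMNS]))
  # head cylinder: diameter = thickness (m2), axis = width (m1), both caps
  head <- cylinder_mesh(m$head_thickness_mm, m$head_width_mm,
                        segments = segments, label = "head")
  head <- translate_mesh(rotate_mesh(head, pitch = pi / 2), c(-gap, 0, 0))
  meso <- icosphere(m$mesosoma_width_mm, level = level, label = "mesosoma")
  meta <- metasoma_mesh(m$metasoma_width_mm, m$metasoma_anterior_length_mm,
                        m$metasoma_posterior_length_mm, segments = segments,
                        label = "metasoma")
  meta <- translate_mesh(rotate_mesh(meta, pitch = pi / 2), c(gap, 0, 0))
  rec <- estimate_specimen(m)
  list(mesh = merge_meshes(list(head, meso, meta)),
       analytic = list(
         head = rec$head, mesosoma = rec$mesosoma, metasoma = rec$metasoma,
         summed_surface_area_mm2 = rec$summed_surface_area_mm2,
         summed_volume_mm3 = rec$summed_volume_mm3))
}

#' Build a solid mesh with its analytic truth
#'
#' @param kind `"sphere"`, `"capped_cylinder"`, `"cone"` or
#'   `"composite_bee"`.
#' @param dimensions Named list: sphere needs `diameter`; capped_cylinder
#'   `diameter`, `length`; cone `diameter`, `height`; composite_bee the six
#'   caliper measurements.
#' @param level Tessellation level (>= 2; spheres subdivide, cylinders/cones
#'   use `4 * 2^level` angular segments).
#' @return List with `mesh` and `analytic` (`surface_area`, `volume`; per
#'   tagma for composite_bee).
#' @export
make_solid_mesh <- function(kind = c("sphere", "capped_cylinder", "cone",
                                     "composite_bee"),
                            dimensions, level = 4) {
  kind <- match.arg(kind)
  if (level < 2) stop("tessellation level must be >= 2", call. = FALSE)
  d <- as.list(dimensions)
  segments <- 4L * 2L^level
  switch(kind,
    sphere = list(mesh = icosphere(d$diameter, level = level),
                  analytic = sphere_solid(d$diameter)),
    capped_cylinder = list(
      mesh = cylinder_mesh(d$diameter, d$length, segments = segments),
      analytic = cylinder_solid(d$diameter, d$length, caps = 2L)),
    cone = list(mesh = cone_mesh(d$diameter, d$height, segments = segments),
                analytic = cone_solid(d$diameter, d$height, base_cap = TRUE)),
    composite_bee = composite_bee_mesh(d, level = level))
}

#' Smooth radial perturbation of a mesh
#'
#' Displaces each vertex radially from its connected component's centroid by
#' a smooth, seeded directional field (a sum of sinusoids of random
#' direction projections), emulating how a real body deviates from an ideal
#' solid. Topology is untouched, so a watertight input stays watertight.
#' With `normalize_volume = TRUE` the result is rescaled to the input
#' volume, in which case surface area is non-decreasing in the amplitude.
#'
#' @param mesh A watertight `triangle_mesh`.
#' @param amplitude Relative radial amplitude (must be < 0.3 to avoid
#'   self-intersection of the fan caps and component overlap).
#' @param frequency Angular frequency of the perturbation field.
#' @param seed Integer seed; the field is fully determined by it.
#' @param n_waves Number of sinusoidal components.
#' @param normalize_volume Rescale the perturbed mesh to the original
#'   volume.
#' @return The perturbed `triangle_mesh`.
#' @export
perturb_mesh <- function(mesh, amplitude, frequency = 3, seed = 1,
                         n_waves = 4, normalize_volume = FALSE) {
  if (amplitude < 0) stop("amplitude must be non-negative", call. = FALSE)
  if (amplitude >= 0.3) {
    stop("perturbation_amplitude: amplitude >= 0.3 risks self-intersection; ",
         "reduce amplitude", call. = FALSE)
  }
  if (amplitude == 0) return(mesh)
  rep0 <- watertight_report(mesh)
  if (!rep0$watertight) {
    stop("mesh_not_watertight: perturb_mesh needs a watertight input",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  dirs <- matrix(stats::rnorm(3 * n_waves), n_waves, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  amps <- stats::runif(n_waves, 0.5, 1)
  phases <- stats::runif(n_waves, 0, 2 * pi)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  comp <- vertex_components(mesh)
  v <- mesh$vertices
  vol0 <- if (normalize_volume) abs(signed_volume(mesh))
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    centroid <- colMeans(v[idx, , drop = FALSE])
    rel <- sweep(v[idx, , drop = FALSE], 2, centroid)
    rad <- sqrt(rowSums(rel^2))
    u <- rel / pmax(rad, 1e-12)
    field <- rep(0, length(idx))
    for (k in seq_len(n_waves)) {
      field <- field + amps[k] * sin(frequency * (u %*% dirs[k, ]) + phases[k])
    }
    field <- field / sum(amps)
    v[idx, ] <- sweep(rel * (1 + amplitude * as.vector(field)), 2, centroid,
                      "+")
  }
  mesh$vertices <- v
  if (normalize_volume) {
    mesh <- scale_mesh(mesh, (vol0 / abs(signed_volume(mesh)))^(1 / 3))
  }
  mesh
}

vertex_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- mesh$faces
  for (k in seq_len(nrow(f))) {
    a <- find(f[k, 1]); b <- find(f[k, 2]); c3 <- find(f[k, 3])
    if (a != b) parent[a] <- b
    b <- find(f[k, 2])
    if (b != c3) parent[b] <- c3
  }
  vapply(seq_len(n), find, integer(1))
}
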