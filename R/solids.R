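# Closed-form solid-shape estimators for bee tagmata.
#
# The classical size-estimation method treats the head as a cylinder, the
# mesosoma as a sphere, and the metasoma as a cylinder joined to a cone, and
# reads the solid dimensions off six caliper measurements:
#   m1 head width, m2 head thickness, m3 mesosoma width, m4 metasoma width,
#   m5 metasoma anterior length (tergites 1-3), m6 metasoma posterior length
#   (tergites 4-6 females / 4-7 males).
# All lengths are in mm; areas in mm^2; volumes in mm^3.

# Upper bound on plausible caliper measurements (mm); catches unit mistakes
# (e.g. values entered in micrometres or centimetres) -- bees are < 40 mm.
MAX_LENGTH_MM <- 100

assert_length_mm <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("measurement_invalid: '%s' must be a single finite number", name),
         call. = FALSE)
  }
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (!lo_ok || x >= MAX_LENGTH_MM) {
    stop(sprintf(
      "measurement_invalid: '%s' = %g mm is outside %s, %g) mm",
      name, x, if (allow_zero) "[0" else "(0", MAX_LENGTH_MM), call. = FALSE)
  }
  invisible(x)
}

solid_estimate <- function(tagma, solid_kind, surface_area_mm2, volume_mm3) {
  structure(list(tagma = tagma, solid_kind = solid_kind,
                 surface_area_mm2 = surface_area_mm2,
                 volume_mm3 = volume_mm3),
            class = "solid_estimate")
}

#' @export
print.solid_estimate <- function(x, ...) {
  cat(sprintf("<solid_estimate> %s (%s): SA = %.5g mm^2, V = %.5g mm^3\n",
              x$tagma, x$solid_kind, x$surface_area_mm2, x$volume_mm3))
  invisible(x)
}

#' Cylinder surface area and volume
#'
#' @param diameter,length Cylinder diameter and axis length (mm).
#' @param caps Number of end caps included in the surface area (0, 1 or 2).
#' @return List with `surface_area` and `volume`.
#' @keywords internal
cylinder_solid <- function(diameter, length, caps = 2L) {
  r <- diameter / 2
  list(surface_area = pi * diameter * length + caps * pi * r^2,
       volume = pi * r^2 * length)
}

sphere_solid <- function(diameter) {
  list(surface_area = pi * diameter^2, volume = pi * diameter^3 / 6)
}

cone_solid <- function(diameter, height, base_cap = FALSE) {
  r <- diameter / 2
  list(surface_area = pi * r * sqrt(r^2 + height^2) +
         if (base_cap) pi * r^2 else 0,
       volume = pi * r^2 * height / 3)
}

#' Estimate head size as a cylinder
#'
#' The head is modelled as a cylinder. Under the default convention the
#' cylinder diameter is the head thickness (m2, the smaller and more circular
#' cross-section) and the axis length is the head width (m1); set
#' `diameter = "width"` to swap. End caps are included by default.
#'
#' @param head_width_mm Width of the head at the widest point (m1).
#' @param head_thickness_mm Thickness of the head at the thickest point (m2).
#' @param diameter Which measurement is the cylinder diameter: `"thickness"`
#'   (default) or `"width"`.
#' @param caps Number of cylinder end caps counted in the surface area (0-2).
#' @return A `solid_estimate` with surface area (mm^2) and volume (mm^3).
#' @examples
#' estimate_head(3, 2)  # SA = 8*pi, V = 3*pi
#' @export
estimate_head <- function(head_width_mm, head_thickness_mm,
                          diameter = c("thickness", "width"), caps = 2L) {
  diameter <- match.arg(diameter)
  assert_length_mm(head_width_mm, "head_width_mm")
  assert_length_mm(head_thickness_mm, "head_thickness_mm")
  stopifnot(caps %in% 0:2)
  d <- if (diameter == "thickness") head_thickness_mm else head_width_mm
  l <- if (diameter == "thickness") head_width_mm else head_thickness_mm
  s <- cylinder_solid(d, l, caps = caps)
  solid_estimate("head", "cylinder", s$surface_area, s$volume)
}

#' Estimate mesosoma size as a sphere
#'
#' @param mesosoma_width_mm Lateral width of the mesosoma at the widest point
#'   (m3), taken as the sphere diameter.
#' @return A `solid_estimate`.
#' @examples
#' estimate_mesosoma(1)  # SA = pi, V = pi/6
#' @export
estimate_mesosoma <- function(mesosoma_width_mm) {
  assert_length_mm(mesosoma_width_mm, "mesosoma_width_mm")
  s <- sphere_solid(mesosoma_width_mm)
  solid_estimate("mesosoma", "sphere", s$surface_area, s$volume)
}

#' Estimate metasoma size as a cylinder plus a cone
#'
#' The metasoma is a cylinder (diameter m4, length m5) joined to a cone (base
#' diameter m4, height m6). The default surface area counts the cylinder
#' lateral surface, one anterior end cap and the cone lateral surface; the
#' disc where cylinder and cone meet is internal and never counted. With
#' `m6 = 0` the cone degenerates to a flat posterior cap and the result equals
#' a closed cylinder.
#'
#' @param metasoma_width_mm Width of the metasoma at the widest point (m4).
#' @param anterior_length_mm Tergite 1-3 span (m5), the cylinder length.
#' @param posterior_length_mm Tergite 4-6/7 span (m6), the cone height; may
#'   be zero.
#' @param anterior_cap Include the anterior end cap in the surface area
#'   (default `TRUE`).
#' @return A `solid_estimate`.
#' @examples
#' estimate_metasoma(2, 2, 0)  # degenerate cone: SA = 6*pi, V = 2*pi
#' @export
estimate_metasoma <- function(metasoma_width_mm, anterior_length_mm,
                              posterior_length_mm, anterior_cap = TRUE) {
  assert_length_mm(metasoma_width_mm, "metasoma_width_mm")
  assert_length_mm(anterior_length_mm, "anterior_length_mm")
  assert_length_mm(posterior_length_mm, "posterior_length_mm", allow_zero = TRUE)
  cyl <- cylinder_solid(metasoma_width_mm, anterior_length_mm,
                        caps = as.integer(anterior_cap))
  r <- metasoma_width_mm / 2
  con <- cone_solid(metasoma_width_mm, posterior_length_mm)
  # degenerate cone (height 0) closes the posterior end with a flat disc
  sa_cone <- if (posterior_length_mm == 0) pi * r^2 else con$surface_area
  solid_estimate("metasoma", "cylinder_plus_cone",
                 cyl$surface_area + sa_cone, cyl$volume + con$volume)
}

#' Geometric size estimate for a whole specimen
#'
#' Applies the three solid-shape estimators to one row of caliper
#' measurements and sums the per-tagma surface areas and volumes.
#'
#' @param measurements A list or one-row data frame with columns/fields
#'   `head_width_mm`, `head_thickness_mm`, `mesosoma_width_mm`,
#'   `metasoma_width_mm`, `metasoma_anterior_length_mm`,
#'   `metasoma_posterior_length_mm`, and optionally `specimen_id` and `caste`.
#' @param ... Convention flags passed to [estimate_head()] and
#'   [estimate_metasoma()] (`diameter`, `caps`, `anterior_cap`).
#' @return A `size_record` list: `specimen_id`, `method = "geometric"`,
#'   per-tagma `solid_estimate`s, and exact sums `summed_surface_area_mm2`,
#'   `summed_volume_mm3`.
#' @export
estimate_specimen <- function(measurements, ...) {
  m <- as.list(measurements)
  dots <- list(...)
  head_args <- dots[names(dots) %in% c("diameter", "caps")]
  meta_args <- dots[names(dots) %in% "anterior_cap"]
  head <- do.call(estimate_head,
                  c(list(m$head_width_mm, m$head_thickness_mm), head_args))
  meso <- estimate_mesosoma(m$mesosoma_width_mm)
  meta <- do.call(estimate_metasoma,
                  c(list(m$metasoma_width_mm, m$metasoma_anterior_length_mm,
                         m$metasoma_posterior_length_mm), meta_args))
  structure(list(
    specimen_id = if (is.null(m$specimen_id)) NA_character_ else m$specimen_id,
    caste = if (is.null(m$caste)) "worker" else m$caste,
    method = "geometric",
    head = head, mesosoma = meso, metasoma = meta,
    summed_surface_area_mm2 = head$surface_area_mm2 + meso$surface_area_mm2 +
      meta$surface_area_mm2,
    summed_volume_mm3 = head$volume_mm3 + meso$volume_mm3 + meta$volume_mm3),
    class = "size_record")
}

#' @export
print.size_record <- function(x, ...) {
  cat(sprintf("<size_record> %s (%s, method = %s)\n", x$specimen_id, x$caste,
              x$method))
  for (t in c("head", "mesosoma", "metasoma")) print(x[[t]])
  cat(sprintf("  sum: SA = %.5g mm^2, V = %.5g mm^3\n",
              x$summed_surface_area_mm2, x$summed_volume_mm3))
  invisible(x)
}

MEASUREMENT_COLUMNS <- c("head_width_mm", "head_thickness_mm",
                         "mesosoma_width_mm", "metasoma_width_mm",
                         "metasoma_anterior_length_mm",
                         "metasoma_posterior_length_mm")

#' Read a caliper-measurement table
#'
#' Comma-separated, one row per specimen, headered columns for the six linear
#' measurements in mm. A `caste` column is optional (default `"worker"`); a
#' `specimen_id` column is generated when absent.
#'
#' @param path Path to a CSV file.
#' @return A data frame of validated measurements.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("measurement_invalid: missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$specimen_id)) df$specimen_id <- sprintf("sp%02d", seq_len(nrow(df)))
  if (is.null(df$caste)) df$caste <- "worker"
  if (!all(df$caste %in% c("worker", "queen", "drone"))) {
    stop("measurement_invalid: caste must be worker, queen or drone", call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    for (cl in MEASUREMENT_COLUMNS) {
      assert_length_mm(df[[cl]][i], cl,
                       allow_zero = cl == "metasoma_posterior_length_mm")
    }
  }
  df
}

#' Geometric size estimates for a measurement table
#'
#' @param measurements Data frame as returned by [read_measurements()].
#' @param ... Convention flags passed to [estimate_specimen()].
#' @return A data frame in long "size table" form: one row per specimen x
#'   scope (head, mesosoma, metasoma, tagmata_sum) with columns
#'   `specimen_id`, `method`, `scope`, `surface_area_mm2`, `volume_mm3`.
#' @export
estimate_table <- function(measurements, ...) {
  rows <- lapply(seq_len(nrow(measurements)), function(i) {
    rec <- estimate_specimen(measurements[i, ], ...)
    size_record_rows(rec)
  })
  do.call(rbind, rows)
}

size_record_rows <- function(rec) {
  data.frame(
    specimen_id = rec$specimen_id,
    method = rec$method,
    scope = c("head", "mesosoma", "metasoma", "tagmata_sum"),
    surface_area_mm2 = c(rec$head$surface_area_mm2,
                         rec$mesosoma$surface_area_mm2,
                         rec$metasoma$surface_area_mm2,
                         rec$summed_surface_area_mm2),
    volume_mm3 = c(rec$head$volume_mm3, rec$mesosoma$volume_mm3,
                   rec$metasoma$volume_mm3, rec$summed_volume_mm3),
    stringsAsFactors = FALSE)
}
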