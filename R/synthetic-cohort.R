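# Synthetic measurement cohorts and thermal-response coefficient sets.
#
# The cohort generator emulates the statistical structure of a paired
# geometric-vs-3D-model study: n specimens drawn from a narrow log-normal
# size distribution, per-tagma "true" (model) sizes tied to an allometric
# scaling exponent, and geometric estimates produced by multiplicative
# systematic deflation plus log-normal measurement noise (size errors are
# relative, not absolute). Every injected quantity is recorded in a truth
# log.

# Baseline worker caliper measurements (mm): head width/thickness, mesosoma
# width, metasoma width, anterior and posterior lengths.
WORKER_BASELINE <- list(head_width_mm = 3.7, head_thickness_mm = 2.1,
                        mesosoma_width_mm = 4.2, metasoma_width_mm = 4.3,
                        metasoma_anterior_length_mm = 3.1,
                        metasoma_posterior_length_mm = 2.8)

# Default injected underestimation fractions of the geometric method, per
# tagma and quantity. Head and mesosoma values follow the magnitudes the
# paired study design is meant to detect; metasoma underestimation is small
# (the torpedo-shaped metasoma is well approximated by a cylinder + cone).
DEFAULT_UNDERESTIMATION <- list(
  head = c(surface_area = 0.26424, volume = 0.39298),
  mesosoma = c(surface_area = 0.44056, volume = 0.50261),
  metasoma = c(surface_area = 0.05, volume = 0.05))

#' Specification of a synthetic paired-measurement cohort
#'
#' @param n_specimens Cohort size (>= 2; default 11).
#' @param size_median Median of the specimen scale factor (1 = the baseline
#'   worker).
#' @param size_sdlog Log-scale spread of the size distribution (default
#'   0.06; honey bee workers vary little in size).
#' @param beta_true True allometric exponent of surface area on volume for
#'   the model (empirical) measurements (default 2/3, isometry).
#' @param underestimation Named list (head/mesosoma/metasoma) of named
#'   vectors `c(surface_area=, volume=)` with the geometric method's
#'   systematic underestimation fractions in [0, 1).
#' @param noise_sdlog Log-normal sd of the geometric method's multiplicative
#'   measurement noise (default 0.12, giving percent-error standard errors
#'   of a few points at n = 11).
#' @param shape_sdlog Log-normal sd of per-tagma biological shape scatter
#'   around the allometric line (default 0.04).
#' @param appendage_sa_fraction,appendage_vol_fraction Fractional increase
#'   of whole-body (wings + legs + antennae) over tagmata-sum surface area
#'   and volume (defaults 0.43627 and 0.16272).
#' @param seed Mandatory integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_specimens = 11, size_median = 1,
                        size_sdlog = 0.06, beta_true = 2 / 3,
                        underestimation = DEFAULT_UNDERESTIMATION,
                        noise_sdlog = 0.12, shape_sdlog = 0.04,
                        appendage_sa_fraction = 0.43627,
                        appendage_vol_fraction = 0.16272,
                        seed) {
  if (missing(seed)) stop("cohort_spec: seed is mandatory", call. = FALSE)
  stopifnot(n_specimens >= 2, size_median > 0, size_sdlog >= 0,
            noise_sdlog >= 0, shape_sdlog >= 0)
  for (tg in TAGMA_LABELS) {
    u <- underestimation[[tg]]
    if (is.null(u) || !all(c("surface_area", "volume") %in% names(u))) {
      stop("cohort_spec: underestimation needs surface_area and volume for ",
           tg, call. = FALSE)
    }
    if (any(u < 0 | u >= 1)) {
      stop("cohort_spec: underestimation fractions must be in [0, 1)",
           call. = FALSE)
    }
  }
  structure(list(n_specimens = n_specimens, size_median = size_median,
                 size_sdlog = size_sdlog, beta_true = beta_true,
                 underestimation = underestimation,
                 noise_sdlog = noise_sdlog, shape_sdlog = shape_sdlog,
                 appendage_sa_fraction = appendage_sa_fraction,
                 appendage_vol_fraction = appendage_vol_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a paired geometric-vs-model measurement cohort
#'
#' For each specimen a scale factor is drawn, baseline worker measurements
#' are scaled by it, and the closed-form estimators give the noiseless
#' geometric sizes. True ("model") per-tagma sizes inflate these by
#' `(1 - fraction)^-1`, carry allometric tilt `(V/V_median)^(beta - 2/3)`
#' relative tilt on surface areas, and log-normal shape scatter. Observed
#' geometric sizes deflate the true values by the injected fractions and add
#' log-normal measurement noise, so at zero noise the per-specimen percent
#' error equals the injected fraction exactly. Whole-body model rows add the
#' appendage fractions on top of the tagmata sum.
#'
#' @param spec A [cohort_spec()].
#' @return List: `measurements` (caliper table), `geometric` and `model`
#'   size tables (long form, one row per specimen x scope), `whole_body`
#'   (model_whole_body rows), and `truth` (the injected fractions, exponent
#'   and seed).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_specimens
  scale <- spec$size_median * exp(stats::rnorm(n, 0, spec$size_sdlog))
  meas <- do.call(rbind, lapply(seq_len(n), function(i) {
    m <- lapply(WORKER_BASELINE, function(x) x * scale[i])
    data.frame(specimen_id = sprintf("syn%02d", i), caste = "worker",
               as.data.frame(m), stringsAsFactors = FALSE)
  }))
  geo_clean <- estimate_table(meas)

  # allometric tilt: SA_true gains (V_rel)^(beta - 2/3) relative to the
  # geometrically similar baseline (V_rel = scale^3)
  tilt <- (scale^3)^(spec$beta_true - 2 / 3)
  model_rows <- list(); geo_rows <- list()
  for (i in seq_len(n)) {
    id <- meas$specimen_id[i]
    g <- geo_clean[geo_clean$specimen_id == id &
                     geo_clean$scope != "tagmata_sum", ]
    sa_m <- vol_m <- sa_g <- vol_g <- numeric(0)
    for (tg in TAGMA_LABELS) {
      u <- spec$underestimation[[tg]]
      base_sa <- g$surface_area_mm2[g$scope == tg]
      base_vol <- g$volume_mm3[g$scope == tg]
      true_sa <- base_sa / (1 - u[["surface_area"]]) * tilt[i] *
        exp(stats::rnorm(1, 0, spec$shape_sdlog))
      true_vol <- base_vol / (1 - u[["volume"]]) *
        exp(stats::rnorm(1, 0, spec$shape_sdlog))
      obs_sa <- true_sa * (1 - u[["surface_area"]]) *
        exp(stats::rnorm(1, 0, spec$noise_sdlog))
      obs_vol <- true_vol * (1 - u[["volume"]]) *
        exp(stats::rnorm(1, 0, spec$noise_sdlog))
      model_rows[[paste(id, tg)]] <- data.frame(
        specimen_id = id, method = "model_tagmata", scope = tg,
        surface_area_mm2 = true_sa, volume_mm3 = true_vol,
        stringsAsFactors = FALSE)
      geo_rows[[paste(id, tg)]] <- data.frame(
        specimen_id = id, method = "geometric", scope = tg,
        surface_area_mm2 = obs_sa, volume_mm3 = obs_vol,
        stringsAsFactors = FALSE)
      sa_m <- c(sa_m, true_sa); vol_m <- c(vol_m, true_vol)
      sa_g <- c(sa_g, obs_sa); vol_g <- c(vol_g, obs_vol)
    }
    model_rows[[paste(id, "sum")]] <- data.frame(
      specimen_id = id, method = "model_tagmata", scope = "tagmata_sum",
      surface_area_mm2 = sum(sa_m), volume_mm3 = sum(vol_m),
      stringsAsFactors = FALSE)
    geo_rows[[paste(id, "sum")]] <- data.frame(
      specimen_id = id, method = "geometric", scope = "tagmata_sum",
      surface_area_mm2 = sum(sa_g), volume_mm3 = sum(vol_g),
      stringsAsFactors = FALSE)
  }
  model <- do.call(rbind, c(model_rows, list(make.row.names = FALSE)))
  geometric <- do.call(rbind, c(geo_rows, list(make.row.names = FALSE)))
  sums <- model[model$scope == "tagmata_sum", ]
  whole <- data.frame(
    specimen_id = sums$specimen_id, method = "model_whole_body",
    scope = "whole_body",
    surface_area_mm2 = sums$surface_area_mm2 *
      (1 + spec$appendage_sa_fraction) *
      exp(stats::rnorm(nrow(sums), 0, spec$shape_sdlog)),
    volume_mm3 = sums$volume_mm3 * (1 + spec$appendage_vol_fraction) *
      exp(stats::rnorm(nrow(sums), 0, spec$shape_sdlog)),
    stringsAsFactors = FALSE)
  list(measurements = meas, geometric = geometric, model = model,
       whole_body = whole,
       truth = list(underestimation = spec$underestimation,
                    beta_true = spec$beta_true,
                    noise_sdlog = spec$noise_sdlog,
                    shape_sdlog = spec$shape_sdlog,
                    appendage_sa_fraction = spec$appendage_sa_fraction,
                    appendage_vol_fraction = spec$appendage_vol_fraction,
                    seed = spec$seed))
}

#' Synthetic thermal-response coefficient sets
#'
#' Linear coefficient sets (intercept + slope x air temperature) for
#' mass-specific metabolic heat, mass-specific evaporative heat loss and the
#' three tagma temperatures, explicitly synthetic: they are not the
#' empirical flight coefficients, but reproduce their qualitative shape —
#' metabolic heat declining with air temperature, evaporative loss growing,
#' and tagma temperatures above air temperature that converge toward it as
#' it rises.
#'
#' `preset = "crossover"` additionally tunes the metabolic line (pivoting at
#' 50 degrees C, by 1-D root finding at construction time) so that with the
#' default geometric tagma surface areas the fitted |Q_C| and |Q_R| lines
#' over the 20-50 degrees C grid intersect at exactly
#' `crossover_temperature`.
#'
#' @param preset `"fig6like"` (default qualitative shape) or `"crossover"`.
#' @param areas Tagma surface areas used when tuning the crossover preset
#'   (default [default_tagma_areas()]).
#' @param constants Radiative constants used when tuning.
#' @param crossover_temperature Target intersection temperature (degrees C)
#'   for the crossover preset.
#' @return A [thermal_model_set()].
#' @export
default_thermal_models <- function(preset = c("fig6like", "crossover"),
                                   areas = default_tagma_areas(),
                                   constants = radiative_constants(),
                                   crossover_temperature = 35) {
  preset <- match.arg(preset)
  base <- thermal_model_set(
    metabolic = c(intercept = 1100, slope = -12),     # mW g^-1
    evaporative = c(intercept = 130, slope = -9),     # mW g^-1, signed
    head_temp = c(intercept = 10, slope = 0.85),      # degrees C
    thorax_temp = c(intercept = 30, slope = 0.42),
    abdomen_temp = c(intercept = 4, slope = 0.93),
    body_mass_g = 0.0753,
    label = "synthetic fig6like")
  if (preset == "fig6like") return(base)

  tuned <- function(delta) {
    m <- base
    # add delta * (50 - T)/30 mW g^-1 to the metabolic line: pivots at 50 C
    m$metabolic["intercept"] <- base$metabolic[["intercept"]] + delta * 50 / 30
    m$metabolic["slope"] <- base$metabolic[["slope"]] - delta / 30
    m
  }
  objective <- function(delta) {
    b <- build_budget(tuned(delta), areas, constants)
    cx <- find_crossover(b$air_temperature_C, abs(b$Q_C_mW), abs(b$Q_R_mW))
    if (is.na(cx)) return(NA_real_)
    cx - crossover_temperature
  }
  # bracket a sign change on a coarse grid, then refine
  grid <- seq(0, -500, by = -10)
  vals <- vapply(grid, objective, numeric(1))
  ok <- which(is.finite(vals))
  flip <- ok[which(diff(sign(vals[ok])) != 0)[1]]
  if (is.na(flip)) {
    stop("could not bracket the crossover target; adjust the base preset",
         call. = FALSE)
  }
  lo <- grid[flip]; hi <- grid[ok[match(flip, ok) + 1]]
  root <- stats::uniroot(objective, lower = min(lo, hi), upper = max(lo, hi),
                         tol = 1e-10)$root
  out <- tuned(root)
  out$label <- sprintf("synthetic crossover@%g", crossover_temperature)
  out
}

#' Default geometric tagma surface areas
#'
#' Surface areas (mm^2) of the baseline worker's head, thorax (mesosoma) and
#' abdomen (metasoma) from the closed-form solid estimators; the heat-budget
#' analogue of the mean geometric surface areas.
#'
#' @param measurements Caliper measurements (default the baseline worker).
#' @return A [tagma_surface_areas()] with method `"geometric"`.
#' @export
default_tagma_areas <- function(measurements = WORKER_BASELINE) {
  rec <- estimate_specimen(measurements)
  tagma_surface_areas(head_mm2 = rec$head$surface_area_mm2,
                      thorax_mm2 = rec$mesosoma$surface_area_mm2,
                      abdomen_mm2 = rec$metasoma$surface_area_mm2,
                      method = "geometric")
}
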