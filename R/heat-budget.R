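# Steady-state heat budget: Q_M + Q_E + Q_R + Q_C = 0.
#
# Sign convention: gains positive, losses negative, so the budget is a
# literal zero sum and convective transfer is the residual
# Q_C = -Q_M - Q_E - Q_R. Longwave radiative exchange per tagma follows the
# Stefan-Boltzmann law,
#   (R_gain - R_loss)_tagma = [a*eC*sigma*Ti^4 - eS*sigma*Tx^4] * SA_tagma,
# with Ti the chamber-wall (= air) temperature and Tx the tagma temperature,
# both converted to kelvin; SA is converted mm^2 -> m^2 and the result
# W -> mW. Metabolic and evaporative routes are linear in air temperature in
# mass-specific units (mW g^-1) and scaled by body mass.

KELVIN_OFFSET <- 273.15

#' Radiative constants
#'
#' @param absorptivity Body surface absorptivity `a` (default 0.98).
#' @param emissivity_chamber Chamber-wall emissivity (borosilicate glass,
#'   default 0.90).
#' @param emissivity_surface Body-surface emissivity (default 0.98).
#' @param stefan_boltzmann Stefan-Boltzmann constant (W m^-2 K^-4, default
#'   5.67e-8).
#' @return A `radiative_constants` list.
#' @export
radiative_constants <- function(absorptivity = 0.98,
                                emissivity_chamber = 0.90,
                                emissivity_surface = 0.98,
                                stefan_boltzmann = 5.67e-8) {
  stopifnot(absorptivity > 0, absorptivity <= 1,
            emissivity_chamber > 0, emissivity_chamber <= 1,
            emissivity_surface > 0, emissivity_surface <= 1,
            stefan_boltzmann > 0)
  structure(list(absorptivity = absorptivity,
                 emissivity_chamber = emissivity_chamber,
                 emissivity_surface = emissivity_surface,
                 stefan_boltzmann = stefan_boltzmann),
            class = "radiative_constants")
}

check_linear_coef <- function(x, name) {
  if (is.null(x) || !is.numeric(x) || length(x) != 2 ||
      !all(c("intercept", "slope") %in% names(x))) {
    stop("thermal_config: '", name,
         "' needs a numeric c(intercept =, slope =)", call. = FALSE)
  }
  x[c("intercept", "slope")]
}

#' Thermal-response coefficient set
#'
#' Linear models (intercept + slope x air temperature, degrees C) for
#' mass-specific metabolic heat production and evaporative heat loss
#' (mW g^-1; evaporative values are signed, i.e. negative = loss) and for
#' head, thorax and abdomen temperature (degrees C), plus the body mass used
#' to convert mass-specific rates to absolute mW.
#'
#' @param metabolic,evaporative Named vectors `c(intercept =, slope =)` in
#'   mW g^-1 per degree C.
#' @param head_temp,thorax_temp,abdomen_temp Named vectors
#'   `c(intercept =, slope =)` in degrees C per degree C.
#' @param body_mass_g Body mass in grams (default 0.0753).
#' @param label Free-text provenance label.
#' @return A `thermal_model_set`.
#' @export
thermal_model_set <- function(metabolic, evaporative, head_temp, thorax_temp,
                              abdomen_temp, body_mass_g = 0.0753,
                              label = "unlabelled") {
  stopifnot(body_mass_g > 0)
  structure(list(metabolic = check_linear_coef(metabolic, "metabolic"),
                 evaporative = check_linear_coef(evaporative, "evaporative"),
                 head_temp = check_linear_coef(head_temp, "head_temp"),
                 thorax_temp = check_linear_coef(thorax_temp, "thorax_temp"),
                 abdomen_temp = check_linear_coef(abdomen_temp,
                                                  "abdomen_temp"),
                 body_mass_g = body_mass_g, label = label),
            class = "thermal_model_set")
}

predict_linear <- function(coef, t_air) {
  coef[["intercept"]] + coef[["slope"]] * t_air
}

#' Per-tagma surface areas for the heat budget
#'
#' @param head_mm2,thorax_mm2,abdomen_mm2 Tagma surface areas (mm^2).
#' @param method Method label carried into budget rows.
#' @return A `tagma_surface_areas` list.
#' @export
tagma_surface_areas <- function(head_mm2, thorax_mm2, abdomen_mm2,
                                method = "geometric") {
  stopifnot(head_mm2 > 0, thorax_mm2 > 0, abdomen_mm2 > 0)
  structure(list(head_mm2 = head_mm2, thorax_mm2 = thorax_mm2,
                 abdomen_mm2 = abdomen_mm2, method = method),
            class = "tagma_surface_areas")
}

#' Metabolic and evaporative heat at an air temperature
#'
#' Mass-specific linear prediction scaled by body mass. Metabolic heat is a
#' gain (positive); evaporative heat is a loss (negative under the signed
#' convention). Vectorized over `t_air`.
#'
#' @param t_air Air temperature(s), degrees C.
#' @param models A [thermal_model_set()].
#' @return Heat flux in mW.
#' @export
metabolic_heat <- function(t_air, models) {
  stopifnot(inherits(models, "thermal_model_set"))
  q <- predict_linear(models$metabolic, t_air) * models$body_mass_g
  if (any(q < 0)) {
    warning("metabolic heat is negative at some temperatures; check the ",
            "coefficient set")
  }
  q
}

#' @rdname metabolic_heat
#' @export
evaporative_heat <- function(t_air, models) {
  stopifnot(inherits(models, "thermal_model_set"))
  q <- predict_linear(models$evaporative, t_air) * models$body_mass_g
  if (any(q > 0)) {
    warning("evaporative heat is positive (a gain) at some temperatures; ",
            "check the coefficient set")
  }
  q
}

#' Predicted tagma temperatures
#'
#' @inheritParams metabolic_heat
#' @return Data frame with columns `t_air`, `head`, `thorax`, `abdomen`
#'   (degrees C). Values outside 0-60 degrees C raise a warning.
#' @export
tagma_temperatures <- function(t_air, models) {
  stopifnot(inherits(models, "thermal_model_set"))
  out <- data.frame(t_air = t_air,
                    head = predict_linear(models$head_temp, t_air),
                    thorax = predict_linear(models$thorax_temp, t_air),
                    abdomen = predict_linear(models$abdomen_temp, t_air))
  vals <- unlist(out[c("head", "thorax", "abdomen")])
  if (any(vals < 0 | vals > 60)) {
    warning("predicted tagma temperatures outside 0-60 degrees C; check the ",
            "coefficient set")
  }
  out
}

#' Net longwave radiative exchange of one tagma
#'
#' `[(a * eC * sigma * Ti^4) - (eS * sigma * Tx^4)] * SA`, with `Ti` the
#' air/chamber temperature and `Tx` the tagma temperature (both degrees C,
#' converted to kelvin internally), `SA` in mm^2 (converted to m^2) and the
#' result in mW. Exactly linear in `SA`. Vectorized.
#'
#' @param t_air,t_tagma Temperatures (degrees C, > -273.15).
#' @param sa_mm2 Tagma surface area (mm^2, >= 0).
#' @param constants A [radiative_constants()].
#' @return Net radiative flux in mW (negative = net loss).
#' @export
net_radiative_tagma <- function(t_air, t_tagma, sa_mm2,
                                constants = radiative_constants()) {
  if (any(t_air <= -KELVIN_OFFSET) || any(t_tagma <= -KELVIN_OFFSET)) {
    stop("temperature_invalid: temperatures must exceed -273.15 degrees C",
         call. = FALSE)
  }
  if (any(sa_mm2 < 0)) {
    stop("surface_area_invalid: surface area must be non-negative",
         call. = FALSE)
  }
  ti <- t_air + KELVIN_OFFSET
  tx <- t_tagma + KELVIN_OFFSET
  s <- constants$stefan_boltzmann
  flux_w_m2 <- constants$absorptivity * constants$emissivity_chamber * s *
    ti^4 - constants$emissivity_surface * s * tx^4
  flux_w_m2 * sa_mm2 * 1e-6 * 1000   # mm^2 -> m^2, W -> mW
}

#' Whole-body longwave radiative exchange
#'
#' Sums [net_radiative_tagma()] over head, thorax and abdomen at their
#' predicted temperatures. Vectorized over `t_air`.
#'
#' @inheritParams metabolic_heat
#' @param areas A [tagma_surface_areas()].
#' @param constants A [radiative_constants()].
#' @return Net whole-body radiative flux in mW.
#' @export
whole_body_radiative <- function(t_air, models, areas,
                                 constants = radiative_constants()) {
  stopifnot(inherits(areas, "tagma_surface_areas"))
  tt <- tagma_temperatures(t_air, models)
  net_radiative_tagma(t_air, tt$head, areas$head_mm2, constants) +
    net_radiative_tagma(t_air, tt$thorax, areas$thorax_mm2, constants) +
    net_radiative_tagma(t_air, tt$abdomen, areas$abdomen_mm2, constants)
}

#' Convective heat as the budget residual
#'
#' `Q_C = -Q_M - Q_E - Q_R`, so the four-route budget sums to zero exactly.
#'
#' @param q_m,q_e,q_r Metabolic, evaporative and radiative fluxes (mW,
#'   loss-negative).
#' @return Convective flux in mW.
#' @export
convective_heat <- function(q_m, q_e, q_r) {
  -q_m - q_e - q_r
}

#' Build a steady-state heat-budget table
#'
#' One row per grid temperature with the four routes (mW) and the
#' surface-area method label; `Q_C` is the residual, so every row sums to
#' zero to machine precision.
#'
#' @inheritParams whole_body_radiative
#' @param grid Air-temperature grid (default 20-50 degrees C in 5-degree
#'   steps).
#' @return Data frame: `air_temperature_C`, `Q_M_mW`, `Q_E_mW`, `Q_R_mW`,
#'   `Q_C_mW`, `method`.
#' @export
build_budget <- function(models, areas, constants = radiative_constants(),
                         grid = seq(20, 50, by = 5)) {
  stopifnot(length(grid) >= 1)
  q_m <- metabolic_heat(grid, models)
  q_e <- evaporative_heat(grid, models)
  q_r <- whole_body_radiative(grid, models, areas, constants)
  data.frame(air_temperature_C = grid, Q_M_mW = q_m, Q_E_mW = q_e,
             Q_R_mW = q_r, Q_C_mW = convective_heat(q_m, q_e, q_r),
             method = areas$method, stringsAsFactors = FALSE)
}

#' Propagate surface-area error into the budget inputs
#'
#' Inflates each tagma surface area by `(1 - fraction)^-1`, inverting a
#' known underestimation (fractions, not percentages), and relabels the
#' method.
#'
#' @param areas A [tagma_surface_areas()].
#' @param fractions Named numeric `c(head =, thorax =, abdomen =)` of
#'   underestimation fractions in [0, 1); missing names default to 0.
#' @param method Label of the corrected method (default `"3D-corrected"`).
#' @return A new `tagma_surface_areas`.
#' @export
apply_surface_correction <- function(areas, fractions,
                                     method = "3D-corrected") {
  stopifnot(inherits(areas, "tagma_surface_areas"))
  get_f <- function(nm) {
    f <- if (nm %in% names(fractions)) fractions[[nm]] else 0
    if (f < 0 || f >= 1) {
      stop("correction_invalid: fraction for ", nm, " must be in [0, 1)",
           call. = FALSE)
    }
    f
  }
  tagma_surface_areas(
    head_mm2 = corrected_size(areas$head_mm2, get_f("head")),
    thorax_mm2 = corrected_size(areas$thorax_mm2, get_f("thorax")),
    abdomen_mm2 = corrected_size(areas$abdomen_mm2, get_f("abdomen")),
    method = method)
}

#' Regress each heat route on air temperature with a method interaction
#'
#' For each route fits `Q ~ T_air * method` over the stacked budget tables,
#' reports the interaction F-test (do slopes differ between surface-area
#' methods?), per-method slopes and intercepts, and — when the interaction
#' is not significant at `alpha` — the intercept (method main-effect)
#' contrast from the additive model, the usual fallback interpretation.
#'
#' @param budgets A single stacked data frame from [build_budget()] rows of
#'   >= 2 methods, or a list of budget tables (rbound internally). All
#'   methods must share the temperature grid.
#' @param routes Route columns to model (default all four).
#' @param alpha Interaction significance threshold (default 0.05).
#' @return A `route_regressions` list keyed by route, each with `slopes`,
#'   `intercepts` (per method), `interaction_F`, `interaction_p`,
#'   `method_F`, `method_p` (additive model), `anova`, `model`.
#' @export
regress_routes <- function(budgets,
                           routes = c("Q_M_mW", "Q_E_mW", "Q_R_mW",
                                      "Q_C_mW"),
                           alpha = 0.05) {
  if (is.list(budgets) && !is.data.frame(budgets)) {
    budgets <- do.call(rbind, budgets)
  }
  methods <- unique(budgets$method)
  if (length(methods) < 2) {
    stop("regress_routes: need budgets for >= 2 methods", call. = FALSE)
  }
  grids <- split(budgets$air_temperature_C, budgets$method)
  ref <- sort(grids[[1]])
  if (!all(vapply(grids, function(g) identical(sort(g), ref), logical(1)))) {
    stop("grid_mismatch: all methods must share the temperature grid",
         call. = FALSE)
  }
  out <- list()
  for (route in routes) {
    d <- data.frame(q = budgets[[route]], t_air = budgets$air_temperature_C,
                    method = factor(budgets$method))
    full <- stats::lm(q ~ t_air * method, data = d)
    an <- stats::anova(full)
    additive <- stats::lm(q ~ t_air + method, data = d)
    an_add <- stats::anova(additive)
    per <- lapply(levels(d$method), function(mt) {
      cf <- stats::coef(stats::lm(q ~ t_air, data = d[d$method == mt, ]))
      c(intercept = unname(cf[1]), slope = unname(cf[2]))
    })
    names(per) <- levels(d$method)
    out[[route]] <- list(
      route = route,
      slopes = vapply(per, `[[`, numeric(1), "slope"),
      intercepts = vapply(per, `[[`, numeric(1), "intercept"),
      interaction_F = an["t_air:method", "F value"],
      interaction_p = an["t_air:method", "Pr(>F)"],
      interaction_significant =
        is.finite(an["t_air:method", "Pr(>F)"]) &&
        an["t_air:method", "Pr(>F)"] < alpha,
      method_F = an_add["method", "F value"],
      method_p = an_add["method", "Pr(>F)"],
      anova = an, model = full)
  }
  class(out) <- "route_regressions"
  out
}

#' @export
print.route_regressions <- function(x, ...) {
  for (r in x) {
    cat(sprintf("%s: interaction F = %.4g, p = %.4g%s\n", r$route,
                r$interaction_F, r$interaction_p,
                if (r$interaction_significant) " (slopes differ)" else
                  sprintf("; intercept shift p = %.4g", r$method_p)))
    for (mt in names(r$slopes)) {
      cat(sprintf("  %s: slope = %.4g mW/C, intercept = %.4g mW\n", mt,
                  r$slopes[mt], r$intercepts[mt]))
    }
  }
  invisible(x)
}

#' Locate the crossover of two heat-route magnitude series
#'
#' Fits a line to each series over the grid and solves for the temperature
#' where the fitted lines meet (`method = "fitted"`, matching a
#' regression-based presentation), or finds a sign change of the raw
#' difference by linear interpolation (`method = "interpolated"`). Returns
#' `NA` when the lines are parallel or the intersection falls outside the
#' grid range.
#'
#' @param grid Air temperatures (degrees C).
#' @param magnitude_a,magnitude_b Route magnitudes (e.g. `abs(Q_C)` and
#'   `abs(Q_R)`) on the grid.
#' @param method `"fitted"` (default) or `"interpolated"`.
#' @return Crossover temperature (degrees C) or `NA_real_`.
#' @export
find_crossover <- function(grid, magnitude_a, magnitude_b,
                           method = c("fitted", "interpolated")) {
  method <- match.arg(method)
  stopifnot(length(grid) == length(magnitude_a),
            length(grid) == length(magnitude_b))
  if (method == "fitted") {
    fa <- stats::coef(stats::lm(magnitude_a ~ grid))
    fb <- stats::coef(stats::lm(magnitude_b ~ grid))
    dslope <- fa[[2]] - fb[[2]]
    if (abs(dslope) < 1e-12) return(NA_real_)
    t_star <- (fb[[1]] - fa[[1]]) / dslope
    if (t_star < min(grid) || t_star > max(grid)) return(NA_real_)
    return(t_star)
  }
  d <- magnitude_a - magnitude_b
  zero <- which(d == 0)
  if (length(zero) > 0) return(grid[zero[1]])
  flips <- which(d[-1] * d[-length(d)] < 0)
  if (length(flips) == 0) return(NA_real_)
  i <- flips[1]
  grid[i] + (grid[i + 1] - grid[i]) * d[i] / (d[i] - d[i + 1])
}
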