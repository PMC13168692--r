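# End-to-end orchestration: simulate (or load) a paired cohort, compare the
# methods, fit the allometry, build and compare heat budgets, and write a
# machine-readable report bundle.

default_config <- function() {
  list(seed = 1,
       output_dir = NULL,
       cohort = list(),           # overrides for cohort_spec()
       normality_alpha = 0.05,
       correction_alpha = 0.05,
       constants = list(),        # overrides for radiative_constants()
       thermal_preset = "fig6like",
       thermal_models = NULL,     # explicit coefficient list overrides preset
       grid = seq(20, 50, by = 5),
       digits = 6)
}

#' Read a pipeline run configuration
#'
#' @param path Path to a YAML config file; keys mirror the arguments of
#'   [run_full_analysis()] (`seed`, `output_dir`, `cohort`,
#'   `normality_alpha`, `correction_alpha`, `constants`, `thermal_preset`,
#'   `thermal_models`, `grid`, `digits`).
#' @return A named list merged over the defaults.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config_error: config file not found: ", path, call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  cfg$grid <- as.numeric(cfg$grid)
  cfg
}

config_thermal_models <- function(cfg, areas, constants) {
  if (!is.null(cfg$thermal_models)) {
    tm <- cfg$thermal_models
    as_coef <- function(x) c(intercept = as.numeric(x$intercept),
                             slope = as.numeric(x$slope))
    thermal_model_set(
      metabolic = as_coef(tm$metabolic),
      evaporative = as_coef(tm$evaporative),
      head_temp = as_coef(tm$head_temp),
      thorax_temp = as_coef(tm$thorax_temp),
      abdomen_temp = as_coef(tm$abdomen_temp),
      body_mass_g = if (is.null(tm$body_mass_g)) 0.0753 else
        as.numeric(tm$body_mass_g),
      label = if (is.null(tm$label)) "config" else tm$label)
  } else {
    # the crossover preset is tuned against the surface areas actually used
    default_thermal_models(cfg$thermal_preset, areas = areas,
                           constants = constants)
  }
}

write_table <- function(df, path, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Simulates a paired measurement cohort, compares geometric estimates with
#' model measurements (percent error, mean signed error, paired tests), fits
#' the log-log allometry across the three methods, builds heat budgets under
#' the geometric surface areas and under the error-corrected
#' (`"3D-corrected"`) areas, regresses each route on air temperature with a
#' method interaction, and locates the convection/radiation crossover for
#' each method. All tables, reports and a config echo (with seed and an MD5
#' hash of the configuration) are written under `output_dir`.
#'
#' @param config A configuration list (see [read_run_config()]) or a path to
#'   a YAML config file. `seed` and `output_dir` are required.
#' @return Invisibly, a list with all intermediate results (`cohort`,
#'   `comparison`, `fractions`, `allometry`, `budgets`, `route_regressions`,
#'   `crossover`) and the written `files`.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$output_dir)) {
    stop("config_error: output_dir is required", call. = FALSE)
  }
  if (is.null(cfg$seed)) stop("config_error: seed is required", call. = FALSE)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(cfg$output_dir, name)
  files <- character(0)

  stage <- "simulate"
  res <- tryCatch({
    spec <- do.call(cohort_spec,
                    utils::modifyList(cfg$cohort, list(seed = cfg$seed)))
    cohort <- simulate_cohort(spec)
    files <- c(files,
               write_table(cohort$measurements, out("measurements.csv"),
                           cfg$digits),
               write_table(cohort$geometric, out("size_geometric.csv"),
                           cfg$digits),
               write_table(rbind(cohort$model, cohort$whole_body),
                           out("size_model.csv"), cfg$digits))

    stage <- "compare"
    comparison <- comparison_table(cohort$geometric, cohort$model,
                                   normality_alpha = cfg$normality_alpha)
    files <- c(files, write_table(comparison, out("comparison_table.csv"),
                                  cfg$digits))
    writeLines(utils::capture.output(print(comparison)),
               out("comparison_table.txt"))
    files <- c(files, out("comparison_table.txt"))
    fractions <- correction_fractions(comparison,
                                      alpha = cfg$correction_alpha)

    stage <- "allometry"
    sums_g <- cohort$geometric[cohort$geometric$scope == "tagmata_sum", ]
    sums_m <- cohort$model[cohort$model$scope == "tagmata_sum", ]
    combined <- rbind(sums_g, sums_m, cohort$whole_body)
    allom <- compare_methods(combined)
    files <- c(files, write_table(scaling_fit_table(allom),
                                  out("allometry_fits.csv"), cfg$digits))

    stage <- "budget"
    constants <- do.call(radiative_constants, cfg$constants)
    geo_sa <- sapply(TAGMA_LABELS, function(tg) {
      mean(cohort$geometric$surface_area_mm2[cohort$geometric$scope == tg])
    })
    areas_geo <- tagma_surface_areas(geo_sa[["head"]], geo_sa[["mesosoma"]],
                                     geo_sa[["metasoma"]],
                                     method = "geometric")
    models <- config_thermal_models(cfg, areas_geo, constants)
    areas_cor <- apply_surface_correction(areas_geo, fractions)
    budgets <- rbind(build_budget(models, areas_geo, constants, cfg$grid),
                     build_budget(models, areas_cor, constants, cfg$grid))
    files <- c(files, write_table(budgets, out("budget.csv"), cfg$digits))

    stage <- "route_regressions"
    # Q_M and Q_E are method-independent; only the surface-area-bearing
    # routes are compared across methods
    routes <- regress_routes(budgets, routes = c("Q_R_mW", "Q_C_mW"))
    route_df <- do.call(rbind, lapply(routes, function(r) {
      data.frame(route = r$route, method = names(r$slopes),
                 slope_mW_per_C = r$slopes, intercept_mW = r$intercepts,
                 interaction_F = r$interaction_F,
                 interaction_p = r$interaction_p,
                 method_F = r$method_F, method_p = r$method_p,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    files <- c(files, write_table(route_df, out("route_regressions.csv"),
                                  cfg$digits))
    writeLines(utils::capture.output(print(routes)),
               out("route_regressions.txt"))
    files <- c(files, out("route_regressions.txt"))

    stage <- "crossover"
    crossover <- lapply(split(budgets, budgets$method), function(b) {
      find_crossover(b$air_temperature_C, abs(b$Q_C_mW), abs(b$Q_R_mW))
    })
    jsonlite::write_json(
      list(description = "air temperature (C) where fitted |Q_C| and |Q_R| lines intersect; null if none in range",
           crossover_C = crossover, seed = cfg$seed),
      out("crossover.json"), auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(files, out("crossover.json"))

    list(cohort = cohort, comparison = comparison, fractions = fractions,
         allometry = allom, budgets = budgets, route_regressions = routes,
         crossover = crossover)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  cfg_echo <- cfg
  cfg_echo$grid <- as.numeric(cfg_echo$grid)
  jsonlite::write_json(cfg_echo, out("run_config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  cfg_hash <- unname(tools::md5sum(out("run_config.json")))
  jsonlite::write_json(list(seed = cfg$seed, config_md5 = cfg_hash,
                            files = basename(c(files, out("run_config.json")))),
                       out("run_manifest.json"), auto_unbox = TRUE)
  res$files <- c(files, out("run_config.json"), out("run_manifest.json"))
  invisible(res)
}
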