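# Stefan-Boltzmann radiative exchange, budget closure, error propagation,
# route regressions and crossover detection.

test_that("metabolic and evaporative routes scale mass-specific lines", {
  m <- thermal_model_set(metabolic = c(intercept = 500, slope = 0),
                         evaporative = c(intercept = -100, slope = 0),
                         head_temp = c(intercept = 5, slope = 1),
                         thorax_temp = c(intercept = 10, slope = 0.9),
                         abdomen_temp = c(intercept = 2, slope = 1),
                         body_mass_g = 0.0753)
  expect_equal(metabolic_heat(30, m), 500 * 0.0753)  # 37.65 mW
  # zero slope: constant across the grid
  grid <- seq(20, 50, by = 5)
  expect_equal(metabolic_heat(grid, m), rep(37.65, 7))
  # hand-evaluated line at all grid points
  m2 <- default_thermal_models()
  expect_equal(metabolic_heat(grid, m2),
               (1100 - 12 * grid) * 0.0753)
  expect_error(thermal_model_set(metabolic = c(1, 2)), "thermal_config")
})

test_that("net radiative exchange matches the hand-evaluated Stefan-Boltzmann form", {
  # Ti = Tx = 300 K, SA = 1 m^2 (1e6 mm^2):
  # 0.98 * sigma * 300^4 * (0.90 - 1) = -45.008 W
  net_mw <- net_radiative_tagma(26.85, 26.85, 1e6)
  sigma <- 5.67e-8
  expect_equal(net_mw / 1000, 0.98 * sigma * 300^4 * (0.90 - 1),
               tolerance = 1e-12)
  expect_equal(net_mw / 1000, -45.008, tolerance = 1e-4)
  gain <- 0.98 * 0.90 * sigma * 300^4
  expect_equal(gain, 405.076, tolerance = 1e-4)

  expect_equal(net_radiative_tagma(30, 40, 0), 0)
  # exactly linear in surface area
  one <- net_radiative_tagma(25, 38, 50)
  expect_equal(net_radiative_tagma(25, 38, 100), 2 * one)
  expect_error(net_radiative_tagma(-300, 20, 1), "temperature_invalid")
})

test_that("radiative sign and monotonicity properties hold", {
  # with a = eS and eC < 1, net radiation is strictly negative when
  # the body is at least as warm as the chamber
  for (ti in seq(0, 50, by = 10)) {
    for (dt in c(0, 2, 10)) {
      expect_lt(net_radiative_tagma(ti, ti + dt, 10), 0)
    }
  }
  # decreasing in body temperature at fixed air temperature
  tx <- seq(20, 50, by = 5)
  q <- net_radiative_tagma(rep(25, length(tx)), tx, 10)
  expect_true(all(diff(q) < 0))
  # increasing in air temperature at fixed body temperature
  ti <- seq(10, 40, by = 5)
  q2 <- net_radiative_tagma(ti, rep(42, length(ti)), 10)
  expect_true(all(diff(q2) > 0))
})

test_that("whole-body radiation equals the per-tagma loop", {
  models <- default_thermal_models()
  areas <- default_tagma_areas()
  grid <- seq(20, 50, by = 5)
  tt <- tagma_temperatures(grid, models)
  loop <- net_radiative_tagma(grid, tt$head, areas$head_mm2) +
    net_radiative_tagma(grid, tt$thorax, areas$thorax_mm2) +
    net_radiative_tagma(grid, tt$abdomen, areas$abdomen_mm2)
  expect_equal(whole_body_radiative(grid, models, areas), loop)

  # three identical tagmata: triple the single-tagma value
  same <- tagma_surface_areas(10, 10, 10)
  m_same <- thermal_model_set(metabolic = c(intercept = 500, slope = 0),
                              evaporative = c(intercept = -10, slope = 0),
                              head_temp = c(intercept = 5, slope = 1),
                              thorax_temp = c(intercept = 5, slope = 1),
                              abdomen_temp = c(intercept = 5, slope = 1))
  expect_equal(whole_body_radiative(30, m_same, same),
               3 * net_radiative_tagma(30, 35, 10))
})

test_that("budget closes to machine precision at every grid point", {
  expect_equal(convective_heat(10, -3, -2), -5)
  expect_equal(convective_heat(0, 0, 0), 0)
  for (preset in c("fig6like", "crossover")) {
    b <- build_budget(default_thermal_models(preset), default_tagma_areas())
    expect_equal(nrow(b), 7)
    expect_equal(b$Q_M_mW + b$Q_E_mW + b$Q_R_mW + b$Q_C_mW, rep(0, 7))
    expect_true(all(b$Q_M_mW > 0))
    expect_true(all(b$Q_E_mW <= 0))
  }
  # single-point grid
  b1 <- build_budget(default_thermal_models(), default_tagma_areas(),
                     grid = 30)
  expect_equal(nrow(b1), 1)
})

test_that("body at air temperature still loses longwave heat when eC < 1", {
  m <- thermal_model_set(metabolic = c(intercept = 500, slope = 0),
                         evaporative = c(intercept = -10, slope = 0),
                         head_temp = c(intercept = 0, slope = 1),
                         thorax_temp = c(intercept = 0, slope = 1),
                         abdomen_temp = c(intercept = 0, slope = 1))
  b <- build_budget(m, default_tagma_areas())
  expect_true(all(b$Q_R_mW < 0))
})

test_that("surface correction rescales Q_R per tagma exactly", {
  areas <- default_tagma_areas()
  frac <- c(head = 0.26424, thorax = 0.44056, abdomen = 0)
  corr <- apply_surface_correction(areas, frac)
  expect_identical(corr$method, "3D-corrected")
  expect_equal(corr$head_mm2, areas$head_mm2 / (1 - 0.26424))
  expect_equal(corr$head_mm2 / areas$head_mm2, 1.35914, tolerance = 1e-5)
  expect_equal(corr$abdomen_mm2, areas$abdomen_mm2)

  # linearity of the radiative term: corrected Q_R decomposes per tagma
  models <- default_thermal_models()
  grid <- seq(20, 50, by = 5)
  tt <- tagma_temperatures(grid, models)
  q_corr <- whole_body_radiative(grid, models, corr)
  q_manual <- net_radiative_tagma(grid, tt$head,
                                  areas$head_mm2 / (1 - 0.26424)) +
    net_radiative_tagma(grid, tt$thorax, areas$thorax_mm2 / (1 - 0.44056)) +
    net_radiative_tagma(grid, tt$abdomen, areas$abdomen_mm2)
  expect_equal(q_corr, q_manual)
  expect_error(apply_surface_correction(areas, c(head = 1)),
               "correction_invalid")

  # identity correction
  same <- apply_surface_correction(areas, c(head = 0))
  expect_equal(same$head_mm2, areas$head_mm2)
})

test_that("method differences in Q_C mirror -(differences in Q_R) exactly", {
  models <- default_thermal_models()
  geo <- default_tagma_areas()
  cor3d <- apply_surface_correction(geo, c(head = 0.26424,
                                           thorax = 0.44056, abdomen = 0))
  bg <- build_budget(models, geo)
  bc <- build_budget(models, cor3d)
  expect_equal(bc$Q_C_mW - bg$Q_C_mW, -(bc$Q_R_mW - bg$Q_R_mW))
  expect_equal(bc$Q_M_mW, bg$Q_M_mW)
  expect_equal(bc$Q_E_mW, bg$Q_E_mW)
})

test_that("route regressions recover constructed lines and flag interactions", {
  grid <- seq(20, 50, by = 5)
  mk <- function(slope, intercept, method) {
    data.frame(air_temperature_C = grid, Q_M_mW = 1, Q_E_mW = -1,
               Q_R_mW = intercept + slope * grid,
               Q_C_mW = -(1 - 1 + intercept + slope * grid),
               method = method)
  }
  b <- rbind(mk(0.3, -20, "geometric"), mk(0.5, -35, "model"))
  rr <- suppressWarnings(regress_routes(b, routes = "Q_R_mW"))  # exact lines
  expect_equal(unname(rr$Q_R_mW$slopes["geometric"]), 0.3)
  expect_equal(unname(rr$Q_R_mW$slopes["model"]), 0.5)
  expect_equal(unname(rr$Q_R_mW$intercepts["model"]), -35)
  expect_gt(rr$Q_R_mW$interaction_F, 1e6)   # exact lines: huge F
  expect_lt(rr$Q_R_mW$interaction_p, 1e-10)

  # ANOVA sum-of-squares decomposition against a brute-force oracle
  models <- default_thermal_models()
  bg <- build_budget(models, default_tagma_areas())
  bc <- build_budget(models, apply_surface_correction(
    default_tagma_areas(), c(head = 0.2, thorax = 0.3, abdomen = 0)))
  both <- rbind(bg, bc)
  rr2 <- regress_routes(both, routes = "Q_R_mW")
  an <- rr2$Q_R_mW$anova
  y <- both$Q_R_mW
  fitted_full <- fitted(rr2$Q_R_mW$model)
  ss_res <- sum((y - fitted_full)^2)
  expect_equal(an["Residuals", "Sum Sq"], ss_res)
  expect_equal(sum(an[, "Sum Sq"]), sum((y - mean(y))^2))

  # mismatched grids refuse to fit
  shifted <- bc
  shifted$air_temperature_C <- shifted$air_temperature_C + 1
  expect_error(regress_routes(rbind(bg, shifted)), "grid_mismatch")

  # identical tables under two labels: no method or interaction effect
  dup <- bg
  dup$method <- "copy"
  rr3 <- suppressWarnings(regress_routes(rbind(bg, dup), routes = "Q_R_mW"))
  expect_equal(unname(rr3$Q_R_mW$slopes["copy"]),
               unname(rr3$Q_R_mW$slopes["geometric"]))
})

test_that("crossover detection solves exact intersections and rejects parallels", {
  grid <- seq(20, 50, by = 5)
  a <- 2 * grid - 60
  b <- grid - 25
  expect_equal(find_crossover(grid, a, b), 35)
  expect_equal(find_crossover(grid, a, b, method = "interpolated"), 35)
  expect_true(is.na(find_crossover(grid, a, a + 5)))       # parallel
  expect_true(is.na(find_crossover(grid, 2 * grid, grid))) # crossing at 0, out of range
  # dominance flips exactly at the returned temperature
  mc <- default_thermal_models("crossover")
  bud <- build_budget(mc, default_tagma_areas())
  cx <- find_crossover(bud$air_temperature_C, abs(bud$Q_C_mW),
                       abs(bud$Q_R_mW))
  fa <- coef(lm(abs(bud$Q_C_mW) ~ bud$air_temperature_C))
  fb <- coef(lm(abs(bud$Q_R_mW) ~ bud$air_temperature_C))
  pred_a <- function(t) fa[[1]] + fa[[2]] * t
  pred_b <- function(t) fb[[1]] + fb[[2]] * t
  expect_gt(pred_a(cx - 1) - pred_b(cx - 1), 0)  # convection dominates below
  expect_lt(pred_a(cx + 1) - pred_b(cx + 1), 0)  # radiation dominates above
})
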