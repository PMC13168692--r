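# Synthetic-data generators: analytic solid meshes, perturbation, cohorts
# and thermal-model presets.

test_that("formula and tessellated mesh agree for every solid kind", {
  cases <- list(
    list(kind = "sphere", dims = list(diameter = 3.9)),
    list(kind = "capped_cylinder", dims = list(diameter = 1.1, length = 3.4)),
    list(kind = "cone", dims = list(diameter = 3, height = 4)))
  for (cs in cases) {
    out <- make_solid_mesh(cs$kind, cs$dims, level = 4)
    expect_lt(rel_err(mesh_area(out$mesh), out$analytic$surface_area), 0.002)
    expect_lt(rel_err(mesh_volume(out$mesh), out$analytic$volume), 0.005)
    expect_true(watertight_report(out$mesh)$watertight)
  }
  # composite metasoma solid against the metasoma estimator
  est <- estimate_metasoma(3.5, 3.0, 3.0)
  ms <- metasoma_mesh(3.5, 3.0, 3.0, segments = 64)
  expect_lt(rel_err(mesh_area(ms), est$surface_area_mm2), 0.003)
  expect_lt(rel_err(mesh_volume(ms), est$volume_mm3), 0.003)
})

test_that("mesh agreement tightens monotonically as tessellation refines", {
  est <- estimate_mesosoma(3.9)
  errs <- vapply(2:5, function(lev) {
    rel_err(mesh_area(icosphere(3.9, level = lev)), est$surface_area_mm2)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("composite bee analytic truths equal the geometric estimators", {
  w <- worker_measurements()
  out <- make_solid_mesh("composite_bee", w, level = 3)
  rec <- estimate_specimen(w)
  expect_equal(out$analytic$summed_surface_area_mm2,
               rec$summed_surface_area_mm2)
  expect_equal(out$analytic$head$volume_mm3, rec$head$volume_mm3)
  rep <- watertight_report(out$mesh)
  expect_equal(rep$boundary_edges, 0L)
  expect_equal(rep$n_components, 3L)
  # per-tagma mesh measurements approach the per-tagma analytic truths
  for (tg in c("head", "mesosoma", "metasoma")) {
    expect_lt(rel_err(mesh_area(out$mesh, tg),
                      out$analytic[[tg]]$surface_area_mm2), 0.005)
    expect_lt(rel_err(mesh_volume(out$mesh, tg),
                      out$analytic[[tg]]$volume_mm3), 0.01)
  }
})

test_that("perturbation is deterministic, closure-preserving and amplitude-monotone", {
  ic <- icosphere(2, level = 3)
  expect_identical(perturb_mesh(ic, 0), ic)
  p1 <- perturb_mesh(ic, 0.12, seed = 9)
  p2 <- perturb_mesh(ic, 0.12, seed = 9)
  expect_identical(p1$vertices, p2$vertices)
  expect_false(identical(p1$vertices,
                         perturb_mesh(ic, 0.12, seed = 10)$vertices))
  expect_true(watertight_report(p1)$watertight)
  expect_error(perturb_mesh(ic, 0.5, seed = 1), "amplitude")

  sas <- vapply(seq(0, 0.25, by = 0.05), function(a) {
    mesh_area(perturb_mesh(ic, a, seed = 9, normalize_volume = TRUE))
  }, numeric(1))
  expect_true(all(diff(sas) >= 0))

  cb <- composite_bee_mesh(worker_measurements(), level = 3)
  pb <- perturb_mesh(cb$mesh, 0.1, seed = 4)
  expect_true(watertight_report(pb)$watertight)
})

test_that("cohorts invert injected fractions exactly at zero noise", {
  frac <- list(head = c(surface_area = 0.2, volume = 0.3),
               mesosoma = c(surface_area = 0.44, volume = 0.5),
               metasoma = c(surface_area = 0.1, volume = 0.15))
  sp <- cohort_spec(n_specimens = 5, underestimation = frac,
                    noise_sdlog = 0, shape_sdlog = 0, seed = 11)
  co <- simulate_cohort(sp)
  for (tg in c("head", "mesosoma", "metasoma")) {
    g <- co$geometric[co$geometric$scope == tg, ]
    m <- co$model[co$model$scope == tg, ]
    expect_equal(percent_error(g$surface_area_mm2, m$surface_area_mm2),
                 rep(100 * frac[[tg]][["surface_area"]], 5))
    expect_equal(percent_error(g$volume_mm3, m$volume_mm3),
                 rep(100 * frac[[tg]][["volume"]], 5))
  }
  # zero fractions + zero noise: percent error identically 0
  zero <- lapply(frac, function(x) x * 0)
  co0 <- simulate_cohort(cohort_spec(n_specimens = 4,
                                     underestimation = zero,
                                     noise_sdlog = 0, shape_sdlog = 0,
                                     seed = 2))
  expect_equal(co0$geometric$surface_area_mm2, co0$model$surface_area_mm2)
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- simulate_cohort(cohort_spec(seed = 42))
  b <- simulate_cohort(cohort_spec(seed = 42))
  expect_identical(a, b)
  expect_error(cohort_spec(), "seed")
})

test_that("default thermal models satisfy the generator contract", {
  m <- default_thermal_models()
  grid <- seq(20, 50, by = 5)
  expect_true(all(metabolic_heat(grid, m) > 0))
  expect_true(all(evaporative_heat(grid, m) <= 0))
  tt <- tagma_temperatures(grid, m)
  # tagma temperatures above air, converging toward it as air warms
  for (tg in c("head", "thorax", "abdomen")) {
    expect_true(all(tt[[tg]] >= tt$t_air))
    expect_true(all(diff(tt[[tg]] - tt$t_air) < 0))
  }
})

test_that("the crossover preset intersects |Q_C| and |Q_R| at 35 C", {
  m <- default_thermal_models("crossover")
  b <- build_budget(m, default_tagma_areas())
  cx <- find_crossover(b$air_temperature_C, abs(b$Q_C_mW), abs(b$Q_R_mW))
  expect_equal(cx, 35, tolerance = 1e-6)
})
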