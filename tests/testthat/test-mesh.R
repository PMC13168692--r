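# Mesh measurement: areas, divergence-theorem volumes, watertightness,
# capping, calibration and file round-trips.

test_that("unit cube measures exactly and reports watertight", {
  cube <- unit_cube()
  expect_equal(mesh_area(cube), 6)
  expect_equal(mesh_volume(cube), 1)
  rep <- watertight_report(cube)
  expect_equal(rep$boundary_edges, 0L)
  expect_equal(rep$euler_characteristic, 2L)
  expect_true(rep$watertight)
})

test_that("icosphere volume and area converge to the analytic sphere from below", {
  truths <- sphere_solid(2)
  vols <- areas <- numeric(0)
  for (lev in 2:5) {
    ic <- icosphere(2, level = lev)
    vols <- c(vols, mesh_volume(ic))
    areas <- c(areas, mesh_area(ic))
  }
  # inscribed vertices: always below the analytic value
  expect_true(all(vols < truths$volume))
  expect_true(all(areas < truths$surface_area))
  # monotone refinement
  expect_true(all(diff(vols) > 0))
  expect_true(all(diff(areas) > 0))
  # within 0.5% (volume) and 0.2% (area) at level 4
  expect_lt(rel_err(vols[3], truths$volume), 0.005)
  expect_lt(rel_err(areas[3], truths$surface_area), 0.002)
})

test_that("open selections error without capping and integrate with it", {
  cube <- unit_cube()
  open_cube <- triangle_mesh(cube$vertices, cube$faces[1:10, ])
  rep <- watertight_report(open_cube)
  expect_equal(rep$boundary_edges, 4L)
  expect_false(rep$watertight)
  expect_error(mesh_volume(open_cube), "mesh_not_watertight")
  expect_equal(mesh_volume(open_cube, cap = TRUE), 1)
  # cap faces are labelled and excluded from external surface area
  capped <- cap_boundary_loops(open_cube)
  expect_true(watertight_report(capped)$watertight)
  expect_equal(mesh_area(capped, labels = "cap"), 1)
})

test_that("a flipped face is an error, never a silent wrong volume", {
  cube <- unit_cube()
  f <- cube$faces
  f[3, ] <- f[3, c(1, 3, 2)]
  bad <- triangle_mesh(cube$vertices, f)
  expect_false(watertight_report(bad)$oriented_consistently)
  expect_error(mesh_volume(bad), "mesh_not_watertight")
})

test_that("area partitions over labels and volume is rigid-motion invariant", {
  cb <- composite_bee_mesh(worker_measurements(), level = 3)
  mesh <- cb$mesh
  total <- mesh_area(mesh)
  parts <- vapply(c("head", "mesosoma", "metasoma"),
                  function(l) mesh_area(mesh, l), numeric(1))
  expect_equal(sum(parts), total)

  v0 <- mesh_volume(mesh)
  moved <- translate_mesh(rotate_mesh(mesh, yaw = 0.7, pitch = -0.3,
                                      roll = 1.2), c(5, -3, 11))
  expect_equal(mesh_volume(moved), v0, tolerance = 1e-10)
  expect_equal(mesh_area(moved), total, tolerance = 1e-10)
})

test_that("calibration scales area/volume quadratically/cubically and verifies", {
  cube <- unit_cube()
  cal2 <- calibration_record(2, 1, cbind(c(2, 4, 6), c(1, 2, 3)))
  scaled <- apply_calibration(cube, cal2)
  expect_true(scaled$units_calibrated)
  expect_equal(mesh_area(scaled), 6 * 4)
  expect_equal(mesh_volume(scaled), 8)

  ident <- apply_calibration(cube, calibration_record(1, 1))
  expect_equal(ident$vertices, cube$vertices)

  off <- calibration_record(2, 1, cbind(c(2, 4, 6), c(1, 2, 3.5)))
  expect_error(apply_calibration(cube, off), "calibration_error")
})

test_that("OBJ writes round-trip with labels, areas and volumes intact", {
  cb <- composite_bee_mesh(worker_measurements(), level = 3)
  path <- withr::local_tempfile(fileext = ".obj")
  write_obj(cb$mesh, path)
  back <- read_mesh(path)
  expect_setequal(unique(back$face_labels),
                  c("head", "mesosoma", "metasoma"))
  expect_equal(mesh_area(back), mesh_area(cb$mesh), tolerance = 1e-8)
  expect_equal(mesh_volume(back), mesh_volume(cb$mesh), tolerance = 1e-8)
})

test_that("PLY and STL parse, and degenerate inputs raise format errors", {
  ply <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 4", "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "3 0 2 1", "3 0 1 3", "3 0 3 2", "3 1 2 3"), ply)
  tet <- read_mesh(ply)
  expect_equal(nrow(tet$faces), 4)
  expect_equal(mesh_volume(tet), 1 / 6)

  stl <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid tet",
               "facet normal 0 0 -1", "outer loop",
               "vertex 0 0 0", "vertex 0 1 0", "vertex 1 0 0",
               "endloop", "endfacet",
               "facet normal 0 -1 0", "outer loop",
               "vertex 0 0 0", "vertex 1 0 0", "vertex 0 0 1",
               "endloop", "endfacet",
               "facet normal -1 0 0", "outer loop",
               "vertex 0 0 0", "vertex 0 0 1", "vertex 0 1 0",
               "endloop", "endfacet",
               "facet normal 1 1 1", "outer loop",
               "vertex 1 0 0", "vertex 0 1 0", "vertex 0 0 1",
               "endloop", "endfacet",
               "endsolid tet"), stl)
  tet2 <- read_mesh(stl)
  expect_equal(nrow(tet2$vertices), 4)  # shared vertices deduplicated
  expect_equal(mesh_volume(tet2), 1 / 6)

  empty <- withr::local_tempfile(fileext = ".obj")
  file.create(empty)
  expect_error(read_mesh(empty), "mesh_format")
  expect_error(read_mesh("nope.obj"), "mesh_format")
})

test_that("label sidecars attach tagma labels by face range", {
  cube <- unit_cube()
  path <- withr::local_tempfile(fileext = ".obj")
  write_obj(cube, path)
  sidecar <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(face_start = c(1, 7), face_end = c(6, 12),
                       label = c("head", "mesosoma")),
            sidecar, row.names = FALSE)
  m <- read_mesh(path, labels = sidecar)
  expect_equal(sum(m$face_labels == "head"), 6)
  expect_equal(mesh_area(m, "head") + mesh_area(m, "mesosoma"), 6)
})

test_that("measure_mesh produces per-tagma, summed and whole-body rows", {
  cb <- composite_bee_mesh(worker_measurements(), level = 3)
  mesh <- cb$mesh
  mesh$units_calibrated <- TRUE
  tab <- measure_mesh(mesh, specimen_id = "syn")
  expect_setequal(tab$scope, c("head", "mesosoma", "metasoma",
                               "tagmata_sum", "whole_body"))
  sums <- tab[tab$scope == "tagmata_sum", ]
  parts <- tab[tab$scope %in% c("head", "mesosoma", "metasoma"), ]
  expect_equal(sums$surface_area_mm2, sum(parts$surface_area_mm2))
  expect_equal(sums$volume_mm3, sum(parts$volume_mm3))
  # no appendages in this fixture: whole body equals the tagmata sum
  expect_equal(tab$surface_area_mm2[tab$scope == "whole_body"],
               sums$surface_area_mm2)
  expect_true(all(tab$watertight))
})
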