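# Mesh export/import round trips and landmark files.

test_that("export writes one file per bone and round-trips", {
  g <- fixture_geometry()
  d <- withr::local_tempdir()
  paths <- export_meshes(g, d, "stl")
  expect_length(paths, 3)
  expect_true(all(file.exists(paths)))
  ## STL stores float32: vertex coordinates reproduced to float precision
  m <- read_mesh(paths[2])
  expect_equal(nrow(m$vertices), nrow(g$patella_mesh$vertices))
  expect_equal(nrow(m$faces), nrow(g$patella_mesh$faces))
  expect_error(export_meshes(g, file.path(d, "missing_dir"), "stl"),
               "does not exist")
})

test_that("OBJ and PLY reproduce coordinates and triangle counts", {
  g <- fixture_geometry()
  d <- withr::local_tempdir()
  obj <- write_mesh(g$patella_mesh, file.path(d, "p.obj"), "obj")
  ply <- write_mesh(g$patella_mesh, file.path(d, "p.ply"), "ply")
  stl <- write_mesh(g$patella_mesh, file.path(d, "p.stl"), "stl")
  mo <- read_mesh(obj); mp <- read_mesh(ply); ms <- read_mesh(stl)
  expect_lt(max(abs(mo$vertices - g$patella_mesh$vertices)), 1e-6)
  expect_lt(max(abs(mp$vertices - g$patella_mesh$vertices)), 1e-6)
  ## STL re-welds the triangle soup: vertex order may change, so compare
  ## the face-expanded coordinates triangle by triangle (float32 storage)
  soup <- function(m) m$vertices[t(m$faces), ]
  expect_lt(max(abs(soup(ms) - soup(g$patella_mesh))), 1e-4)
  expect_identical(mo$faces, g$patella_mesh$faces)
  ## same triangle count across formats
  expect_equal(nrow(mo$faces), nrow(ms$faces))
  expect_equal(nrow(mp$faces), nrow(ms$faces))
})

test_that("landmark files round-trip through YAML and JSON", {
  g <- fixture_geometry()
  d <- withr::local_tempdir()
  y <- file.path(d, "lm.yaml"); j <- file.path(d, "lm.json")
  write_landmarks(g$landmarks, y)
  write_landmarks(g$landmarks, j)
  ly <- read_landmarks(y); lj <- read_landmarks(j)
  expect_equal(names(ly), names(g$landmarks))
  expect_equal(ly$tibial_tuberosity, g$landmarks$tibial_tuberosity,
               tolerance = 1e-6)               # YAML prints ~6 digits
  expect_equal(lj$femoral_head_center, g$landmarks$femoral_head_center,
               tolerance = 1e-12)
  ## user-supplied meshes + landmarks assemble into a working geometry
  paths <- export_meshes(g, d, "obj")
  g2 <- stifle_geometry_from_files(paths[1], paths[2], paths[3], j)
  expect_equal(measure_aldfa(g2), 95, tolerance = 0.01)
  expect_equal(measure_lp_ratio(g2), 1.55, tolerance = 1e-6)
})
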