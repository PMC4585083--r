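test_that("surface files round-trip bit-identical coordinates", {
  m <- fixture_sphere(2)
  for (fmt in c("stl", "ply", "obj")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_surface(m, path)
    m2 <- read_surface(path)
    expect_true(mesh_is_watertight(m2), info = fmt)
    expect_equal(enclosed_volume(m2), enclosed_volume(m), tolerance = 1e-12,
                 info = fmt)
    if (fmt != "stl") # STL re-welds vertices, order may differ
      expect_identical(m2$vertices, m$vertices)
  }
})

test_that("quad OBJ files load as quad meshes", {
  path <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
               "f 1 2 3 4"), path)
  qm <- read_surface(path)
  expect_s3_class(qm, "vf_quadmesh")
  expect_equal(nrow(qm$quads), 1L)
})

test_that("surface sequences round-trip through the manifest", {
  kin <- fixture_kinematics()
  dir <- tempfile()
  man <- write_surface_sequence(kin, dir, name = "fr")
  kin2 <- read_surface_sequence(man)
  expect_equal(kin2$period, kin$period)
  expect_identical(kin2$triangles, kin$triangles)
  for (i in seq_along(kin$frames))
    expect_identical(kin2$frames[[i]], kin$frames[[i]])
})

test_that("conformality violations are rejected with the frame named", {
  kin <- fixture_kinematics()
  dir <- tempfile()
  man <- write_surface_sequence(kin, dir, name = "fr")
  # corrupt frame 2's connectivity by swapping two vertex references
  f2 <- file.path(dir, "fr_002.ply")
  m <- read_surface(f2)
  m$triangles[1, ] <- m$triangles[1, c(2, 1, 3)]
  write_surface(m, f2)
  expect_error(read_surface_sequence(man), "frame 2")
})

test_that("short sequences are rejected", {
  kin <- fixture_kinematics()
  dir <- tempfile()
  man <- write_surface_sequence(kin, dir, name = "fr")
  y <- yaml::read_yaml(man)
  y$frames <- y$frames[1:2]
  yaml::write_yaml(y, man)
  expect_error(read_surface_sequence(man), "3 frames")
})
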