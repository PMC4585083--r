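test_that("enclosed volume matches analytic solids", {
  cube <- fixture_cube()
  expect_true(mesh_is_watertight(cube))
  expect_equal(enclosed_volume(cube), 1.0, tolerance = 1e-12)

  sph <- icosphere(1, 4)
  expect_true(mesh_is_watertight(sph))
  expect_equal(enclosed_volume(sph), 4 * pi / 3, tolerance = 0.005)
  expect_equal(surface_area(sph), 4 * pi, tolerance = 0.005)

  ell <- sph
  ell$vertices <- sweep(sph$vertices, 2, c(2, 1, 1), "*")
  expect_equal(enclosed_volume(ell), 8 * pi / 3, tolerance = 0.005)
})

test_that("uniform scaling multiplies the enclosed volume by s^3", {
  s <- fixture_sphere()
  v0 <- enclosed_volume(s)
  for (sc in c(0.5, 1.3, 2.1)) {
    s2 <- s
    s2$vertices <- s$vertices * sc
    expect_equal(enclosed_volume(s2) / v0, sc^3, tolerance = 1e-12)
  }
})

test_that("watertightness audit detects open and misoriented surfaces", {
  cube <- fixture_cube()
  open_mesh <- vf_mesh(cube$vertices, cube$triangles[-1, ])
  expect_false(mesh_is_watertight(open_mesh))
  flipped <- cube
  flipped$triangles[3, ] <- flipped$triangles[3, c(1, 3, 2)]
  expect_false(mesh_is_watertight(flipped))
  expect_error(enclosed_volume(open_mesh), "watertight")
})

test_that("welding merges coincident vertices and drops slivers", {
  cube <- fixture_cube()
  # duplicate a vertex and reference the duplicate from one triangle
  v <- rbind(cube$vertices, cube$vertices[1, ])
  tr <- cube$triangles
  tr[1, 1] <- nrow(v)
  broken <- vf_mesh(v, tr)
  expect_false(mesh_is_watertight(broken))
  fixed <- weld_mesh(broken)
  expect_true(mesh_is_watertight(fixed))
  expect_equal(enclosed_volume(fixed), 1.0, tolerance = 1e-12)
})

test_that("signed distance and parity classification agree on a sphere", {
  s <- fixture_sphere()
  pts <- rbind(c(0, 0, 0), c(0.5, 0.2, -0.3), c(1.5, 0, 0), c(0, 2, 0))
  q <- ventriflow:::point_mesh_query(pts, s$vertices, s$triangles)
  expect_true(all(q$signed_distance[1:2] < 0))  # inside
  expect_true(all(q$signed_distance[3:4] > 0))  # outside
  r <- sqrt(rowSums(pts^2))
  expect_equal(abs(q$signed_distance), abs(r - 1), tolerance = 0.02)
})
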