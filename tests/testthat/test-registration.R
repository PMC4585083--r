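test_that("quad subdivision conserves area and watertightness", {
  # one planar unit quad, n = 5 -> fifty triangles of total area 1
  quad <- structure(list(vertices = rbind(c(0, 0, 0), c(1, 0, 0),
                                          c(1, 1, 0), c(0, 1, 0)),
                         quads = matrix(1:4, 1)), class = "vf_quadmesh")
  m <- subdivide_quads(quad, n = 5)
  expect_equal(nrow(m$triangles), 50L)
  expect_equal(surface_area(m), 1.0, tolerance = 1e-12)
  m1 <- subdivide_quads(quad, n = 1)
  expect_equal(nrow(m1$triangles), 2L)

  # closed quad surface (cube) stays watertight after subdivision
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  quads <- rbind(c(1, 3, 4, 2), c(5, 6, 8, 7), c(1, 2, 6, 5),
                 c(3, 7, 8, 4), c(1, 5, 7, 3), c(2, 4, 8, 6))
  cubeq <- structure(list(vertices = v, quads = quads), class = "vf_quadmesh")
  mc <- subdivide_quads(cubeq, n = 3)
  expect_equal(nrow(mc$triangles), 6L * 2L * 9L)
  expect_true(mesh_is_watertight(mc))
  expect_equal(abs(enclosed_volume(mc)), 1.0, tolerance = 1e-12)

  tri_only <- fixture_sphere(1)
  expect_error(subdivide_quads(tri_only), "format error")
})

test_that("currents energy is a symmetric nonnegative matching metric", {
  s <- fixture_sphere(2)
  expect_lt(abs(currents_energy(s, s, 0.5)), 1e-12)
  shift <- function(d) {
    s2 <- s; s2$vertices <- sweep(s$vertices, 2, c(d, 0, 0), "+"); s2
  }
  e <- vapply(c(0.1, 0.25, 0.4), function(d)
    currents_energy(s, shift(d), 0.5), numeric(1))
  expect_true(all(diff(e) > 0))          # grows with separation within sigma
  expect_true(all(e > 0))
  s2 <- shift(0.2)
  expect_equal(currents_energy(s, s2, 0.5), currents_energy(s2, s, 0.5),
               tolerance = 1e-12)
})

test_that("analytic currents gradient matches finite differences", {
  s <- fixture_sphere(1)
  t <- s; t$vertices <- sweep(s$vertices, 2, c(1.15, 1.0, 0.9), "*")
  g <- ventriflow:::currents_gradient_cpp(s$vertices, s$triangles,
                                          t$vertices, t$triangles, 0.6)
  eps <- 1e-6
  for (idx in list(c(1, 1), c(5, 2), c(9, 3))) {
    vp <- s$vertices; vp[idx[1], idx[2]] <- vp[idx[1], idx[2]] + eps
    vm <- s$vertices; vm[idx[1], idx[2]] <- vm[idx[1], idx[2]] - eps
    fd <- (ventriflow:::currents_energy_cpp(vp, s$triangles, t$vertices,
                                            t$triangles, 0.6) -
           ventriflow:::currents_energy_cpp(vm, s$triangles, t$vertices,
                                            t$triangles, 0.6)) / (2 * eps)
    expect_equal(g[idx[1], idx[2]], fd, tolerance = 1e-5 * max(abs(fd), 1e-4))
  }
})

test_that("identity target produces an identity map with zero energy", {
  s <- fixture_sphere(2)
  r <- greedy_lddmm(s, s, registration_config(max_iter = 5))
  expect_lt(max(abs(r$mapped$vertices - s$vertices)), 1e-10)
  expect_lt(abs(r$final_energy), 1e-12)
})

test_that("greedy flow recovers a translated sphere within tolerance", {
  s <- fixture_sphere(2)
  cfg <- registration_config(step = 0.5)
  cfg2 <- ventriflow:::reg_auto_widths(s, cfg)
  delta <- 0.1 * cfg2$sigma_v
  tgt <- s; tgt$vertices <- sweep(s$vertices, 2, c(delta, 0, 0), "+")
  r <- greedy_lddmm(s, tgt, cfg)
  expect_lt(r$hausdorff, 0.05)           # 5% of the unit radius
  expect_equal(r$inverted, 0)
})

test_that("sphere-to-ellipsoid registration converges monotonically", {
  s <- fixture_sphere(2)
  tgt <- s; tgt$vertices <- sweep(s$vertices, 2, c(1.2, 1.0, 0.9), "*")
  r <- greedy_lddmm(s, tgt, registration_config(step = 0.5, max_iter = 150,
                                                tol = 1e-6))
  expect_true(all(diff(r$energy_trace) <= 1e-12))
  expect_lt(r$final_energy, 0.1 * r$energy_trace[1])
  expect_equal(r$inverted, 0)
})

test_that("a known small deformation is recovered to within 10 percent", {
  s <- fixture_sphere(2)
  scale <- 1.06                           # radial displacement 0.06
  tgt <- s; tgt$vertices <- s$vertices * scale
  r <- greedy_lddmm(s, tgt, registration_config(step = 0.5, max_iter = 150,
                                                tol = 1e-8))
  err <- sqrt(rowSums((r$mapped$vertices - tgt$vertices)^2))
  expect_lt(mean(err), 0.1 * (scale - 1))
})

test_that("map_sequence yields a conformal kinematics matching target volumes", {
  s <- fixture_sphere(2)
  scales <- c(1, 1.04, 1.08, 1.04)
  targets <- lapply(scales, function(sc) {
    t <- s; t$vertices <- s$vertices * sc; t
  })
  kin <- map_sequence(s, targets, times = c(0, 0.125, 0.25, 0.375),
                      period = 0.5,
                      cfg = registration_config(step = 0.5, max_iter = 100,
                                                tol = 1e-7))
  expect_s3_class(kin, "vf_kinematics")
  for (i in seq_along(scales)) {
    v <- enclosed_volume(vf_mesh(kin$frames[[i]], kin$triangles),
                         check = FALSE)
    expect_equal(v, enclosed_volume(targets[[i]], check = FALSE),
                 tolerance = 0.02 * v)
  }
  ik <- interpolate_kinematics(kin, 0.1)   # conformality contract holds
  expect_equal(dim(ik$vertices), dim(s$vertices))

  # identical targets produce frames identical to the template
  kin2 <- map_sequence(s, list(s, s, s), times = c(0, 0.1, 0.2), period = 0.5,
                       cfg = registration_config(max_iter = 3))
  for (f in kin2$frames) expect_lt(max(abs(f - s$vertices)), 1e-10)
})
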