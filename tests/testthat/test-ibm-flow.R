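test_that("Taylor-Green convergence is at least second order in space", {
  tg <- tg_study()
  o1 <- log2(tg$e32$err / tg$e64$err)
  o2 <- log2(tg$e64$err / tg$e128$err)
  expect_gt(o1, 1.9)
  expect_gt(o2, 1.9)
})

test_that("post-projection divergence is below 1e-8", {
  tg <- tg_study()
  expect_lt(tg$e128$div, 1e-8)
})

test_that("temporal refinement at fixed grid is at least second order", {
  run_dt <- function(nsteps) {
    nn <- 64; nu <- 0.01; tend <- 0.1
    grid <- cartesian_grid(c(nn, nn, 1), c(0, 0, 0), c(2 * pi, 2 * pi, 2 * pi),
                           bc = rep("periodic", 6))
    cc <- grid_centers(grid)
    X <- outer(cc$x, rep(1, nn)); Y <- outer(rep(1, nn), cc$y)
    u0 <- -cos(X) * sin(Y); v0 <- sin(X) * cos(Y)
    st <- flow_state(grid, u = u0, v = v0)
    tags <- fluid_tags(grid)
    props <- fluid_properties(rho = 1, mu = nu)
    dt <- tend / nsteps
    for (s in seq_len(nsteps))
      st <- flow_step(st, dt, props, tags, poisson_tol = 1e-12, max_cycles = 100)
    st
  }
  # Richardson against the 4x-finer solution removes the fixed spatial
  # error; pure second order gives e1/e2 = (1 - 1/16)/(1/4 - 1/16) = 5
  s1 <- run_dt(10); s2 <- run_dt(20); s4 <- run_dt(40)
  e1 <- sqrt(mean((s1$u - s4$u)^2 + (s1$v - s4$v)^2))
  e2 <- sqrt(mean((s2$u - s4$u)^2 + (s2$v - s4$v)^2))
  expect_gt(e1 / e2, 3.6)
})

test_that("kinetic energy decays without forcing", {
  nn <- 48
  grid <- cartesian_grid(c(nn, nn, 1), c(0, 0, 0), c(2 * pi, 2 * pi, 2 * pi),
                         bc = rep("periodic", 6))
  cc <- grid_centers(grid)
  X <- outer(cc$x, rep(1, nn)); Y <- outer(rep(1, nn), cc$y)
  st <- flow_state(grid, u = -cos(X) * sin(Y), v = sin(X) * cos(Y))
  tags <- fluid_tags(grid)
  props <- fluid_properties(rho = 1, mu = 0.02)
  ke <- function(s) sum(s$u^2 + s$v^2)
  kes <- ke(st)
  for (i in 1:20) {
    st <- flow_step(st, 0.02, props, tags, poisson_tol = 1e-10)
    kes <- c(kes, ke(st))
  }
  expect_true(all(diff(kes) < 0))
})

test_that("Crank-Nicolson diffusion matches the scalar amplification factor", {
  nn <- 32; nu <- 0.05; dt <- 0.01
  grid <- cartesian_grid(c(nn, nn, 1), c(0, 0, 0), c(2 * pi, 2 * pi, 2 * pi),
                         bc = rep("periodic", 6))
  cc <- grid_centers(grid)
  k <- 2
  v0 <- sin(k * outer(cc$x, rep(1, nn)))   # v varies in x only: zero advection
  st <- flow_state(grid, v = v0)
  st <- predict_velocity(st, dt, fluid_properties(rho = 1, mu = nu),
                         fluid_tags(grid), helmholtz_tol = 1e-15,
                         helmholtz_maxit = 400)
  lam <- nu * 2 * (1 - cos(k * grid$h)) / grid$h^2   # discrete mode eigenvalue
  gain <- (1 - lam * dt / 2) / (1 + lam * dt / 2)
  expect_equal(max(abs(st$v)) / max(abs(v0)), gain, tolerance = 1e-10)
})

test_that("uniform flow in a periodic box is an exact steady state", {
  grid <- cartesian_grid(c(16, 16, 1), c(0, 0, 0), c(1, 1, 1),
                         bc = rep("periodic", 6))
  st <- flow_state(grid, u = rep(0.7, 256), v = rep(-0.3, 256))
  st <- flow_step(st, 0.01, fluid_properties(1, 0.01), fluid_tags(grid),
                  poisson_tol = 1e-12)
  expect_equal(st$u, rep(0.7, 256), tolerance = 1e-12)
  expect_equal(st$v, rep(-0.3, 256), tolerance = 1e-12)
})

test_that("manufactured Poisson solution converges at second order", {
  errs <- vapply(c(32, 64), function(nn) {
    grid <- cartesian_grid(c(nn, nn, 1), c(0, 0, 0), c(1, 1, 1))
    cc <- grid_centers(grid)
    X <- outer(cc$x, rep(1, nn)); Y <- outer(rep(1, nn), cc$y)
    pe <- cos(pi * X) * cos(pi * Y)
    res <- ventriflow:::mg_poisson(as.numeric(-2 * pi^2 * pe),
                                   fluid_tags(grid)$tags, nn, nn, 1, grid$h,
                                   grid$bc, 1e-10, 100, 2, 0, NULL)
    p <- res$p
    max(abs(p - mean(p) - (pe - mean(pe))))
  }, numeric(1))
  expect_gt(log2(errs[1] / errs[2]), 1.9)
})

test_that("each V-cycle reduces the residual at least fourfold", {
  nn <- 64
  grid <- cartesian_grid(c(nn, nn, 1), c(0, 0, 0), c(1, 1, 1))
  cc <- grid_centers(grid)
  X <- outer(cc$x, rep(1, nn)); Y <- outer(rep(1, nn), cc$y)
  rhs <- -2 * pi^2 * cos(pi * X) * cos(pi * Y)
  res <- ventriflow:::mg_poisson(as.numeric(rhs), fluid_tags(grid)$tags,
                                 nn, nn, 1, grid$h, grid$bc, 0, 10, 2, 0, NULL)
  tr <- c(attr(res$p, "residual0"), attr(res$p, "trace"))
  expect_true(all(tr[-length(tr)] / tr[-1] >= 4))
})

test_that("zero Poisson right-hand side returns a constant pressure", {
  grid <- cartesian_grid(c(16, 16, 1), c(0, 0, 0), c(1, 1, 1))
  res <- ventriflow:::mg_poisson(numeric(256), fluid_tags(grid)$tags,
                                 16, 16, 1, grid$h, grid$bc, 1e-12, 10, 2,
                                 0, NULL)
  expect_lt(max(abs(res$p)), 1e-12)
})

test_that("projection annihilates a pure gradient field", {
  nn <- 64
  grid <- cartesian_grid(c(nn, nn, 1), c(0, 0, 0), c(2 * pi, 2 * pi, 2 * pi),
                         bc = rep("periodic", 6))
  cc <- grid_centers(grid)
  X <- outer(cc$x, rep(1, nn)); Y <- outer(rep(1, nn), cc$y)
  ustar <- cos(X) * cos(Y)              # grad of phi = sin(x)cos(y)
  vstar <- -sin(X) * sin(Y)
  st <- flow_state(grid, u = ustar, v = vstar)
  tags <- fluid_tags(grid)
  ff <- ventriflow:::face_fluxes(st$u, st$v, st$w, nn, nn, 1, grid$h,
                                 grid$bc, tags$tags)
  st$ux <- ff$ux; st$uy <- ff$uy; st$uz <- ff$uz
  div <- ventriflow:::face_divergence(st$ux, st$uy, st$uz, nn, nn, 1,
                                      grid$h, tags$tags)
  p <- solve_pressure_poisson(div, tags, 0.1, 1, tol = 1e-12, max_cycles = 100)
  st <- project(st, p, 0.1, 1, tags)
  expect_lt(max(abs(st$u), abs(st$v)), 0.01 * max(abs(ustar)))
  d2 <- ventriflow:::face_divergence(st$ux, st$uy, st$uz, nn, nn, 1,
                                     grid$h, tags$tags)
  expect_lt(max(abs(d2)), 1e-10)
})

test_that("cell classification matches the analytic sphere fraction", {
  grid <- cartesian_grid(c(40, 40, 40), rep(-2, 3), rep(2, 3))
  s <- fixture_sphere()
  tags <- classify_cells(grid, s)
  frac <- sum(tags$tags == 1L) * grid$h^3
  expect_equal(frac, 4 * pi / 3, tolerance = 2 * grid$h)  # 2h/R relative
  # corner subdomain far from the sphere is entirely fluid when inverted
  tags_out <- classify_cells(grid, s, fluid = "outside")
  arr <- array(tags_out$tags, grid$n)
  expect_true(all(arr[1:5, 1:5, 1:5] == 1L))
  expect_true(all(array(tags$tags, grid$n)[1:5, 1:5, 1:5] == 0L |
                    array(tags$tags, grid$n)[1:5, 1:5, 1:5] == 2L))
})

test_that("classification is shift-equivariant by whole cells", {
  grid <- cartesian_grid(c(40, 40, 40), rep(-2, 3), rep(2, 3))
  s <- fixture_sphere()
  t1 <- array(classify_cells(grid, s)$tags, grid$n)
  s2 <- s; s2$vertices <- sweep(s$vertices, 2, c(grid$h, 0, 0), "+")
  t2 <- array(classify_cells(grid, s2)$tags, grid$n)
  interior <- 5:35
  expect_identical(t2[interior + 1, interior, interior],
                   t1[interior, interior, interior])
})

test_that("ghost closure extends a linear shear profile through the wall", {
  # solid slab below y = y0, fluid above; u = gamma (y - y0)
  grid <- cartesian_grid(c(32, 32, 32), rep(-2, 3), rep(2, 3))
  y0 <- -0.515
  slab <- fixture_cube()
  slab$vertices <- sweep(sweep(slab$vertices, 2, c(3.8, 1, 3.8), "*"), 2,
                         c(-1.9, y0 - 1, -1.9), "+")
  tags <- classify_cells(grid, slab, fluid = "outside")
  cc <- grid_centers(grid)
  gamma <- 2
  Y <- rep(rep(cc$y, each = 32), times = 32)
  st <- flow_state(grid, u = gamma * pmax(Y - y0, 0))
  st <- apply_ghost_bc(st, tags, wall_velocity = NULL)
  g <- tags$ghost
  under <- g$centers[, 2] < y0 & g$centers[, 2] > y0 - grid$h &
    abs(g$centers[, 1]) < 1 & abs(g$centers[, 3]) < 1
  expect_gt(sum(under), 10)
  # ghost values continue the linear profile to negative values so the
  # reconstructed wall velocity is zero
  expect_equal(st$u[g$cells[under]], gamma * (g$centers[under, 2] - y0),
               tolerance = 1e-10)
})

test_that("prescribed wall velocity is reconstructed exactly at the wall", {
  grid <- cartesian_grid(c(32, 32, 32), rep(-2, 3), rep(2, 3))
  s <- fixture_sphere()
  tags <- classify_cells(grid, s, fluid = "outside")
  V <- 1.7
  wall <- matrix(rep(c(V, 0, 0), each = length(tags$ghost$cells)), ncol = 3)
  st <- flow_state(grid)   # quiescent interior
  st <- apply_ghost_bc(st, tags, wall)
  # the linear reconstruction at the wall, weighting ghost and image values
  # by their distances, must return the prescribed wall velocity exactly
  g <- tags$ghost
  ip <- ventriflow:::interp_fluid(g$image, list(st$u), 32, 32, 32,
                                  grid$lower[1], grid$lower[2], grid$lower[3],
                                  grid$h, tags$tags)
  full <- ip$weight > 0.999
  recon <- (g$image_dist[full] * st$u[g$cells[full]] +
            g$distance[full] * ip$values[full, 1]) /
    (g$image_dist[full] + g$distance[full])
  expect_equal(recon, rep(V, sum(full)), tolerance = 1e-10)
})

test_that("a quiescent fluid inside a static wall stays at rest", {
  grid <- cartesian_grid(c(24, 24, 24), rep(-2, 3), rep(2, 3))
  tags <- classify_cells(grid, fixture_sphere(2))
  st <- flow_state(grid)
  props <- fluid_properties()
  for (i in 1:100) st <- flow_step(st, 1e-3, props, tags)
  expect_lt(max(abs(st$u), abs(st$v), abs(st$w)), 1e-12)
})

test_that("wall-driven mass flux balances the wall-motion volume rate", {
  # contracting sphere in a box with one open face: flux through a
  # surrounding measurement box matches 4 pi R^2 V within 2%
  grid <- cartesian_grid(c(48, 48, 48), rep(-2, 3), rep(2, 3),
                         bc = c("wall", "wall", "wall", "wall", "wall", "open"))
  s <- fixture_sphere()
  tags <- classify_cells(grid, s, fluid = "outside")
  V <- 2
  nrm <- s$vertices / sqrt(rowSums(s$vertices^2))
  wall <- ghost_wall_velocity(tags, -V * nrm)
  st <- flow_state(grid)
  props <- fluid_properties()
  for (i in 1:3) st <- flow_step(st, 5e-4, props, tags, wall_velocity = wall,
                                 poisson_tol = 1e-9)
  fl <- box_outflux(st, tags, list(lower = rep(-1.5, 3), upper = rep(1.5, 3)))
  expect_equal(fl, -4 * pi * V, tolerance = 0.02 * 4 * pi * V)
})

test_that("the CFL guard aborts runaway steps", {
  grid <- cartesian_grid(c(16, 16, 1), c(0, 0, 0), c(1, 1, 1),
                         bc = rep("periodic", 6))
  st <- flow_state(grid, u = rep(100, 256))
  expect_error(predict_velocity(st, 0.01, fluid_properties(1, 0.01),
                                fluid_tags(grid), cfl_limit = 0.8),
               "CFL")
})
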