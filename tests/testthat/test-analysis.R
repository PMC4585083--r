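make_field_2d <- function(nn, fu, fv, L = 2) {
  grid <- cartesian_grid(c(nn, nn, 1), c(-L, -L, -L), c(L, L, L),
                         bc = rep("periodic", 6))
  cc <- grid_centers(grid)
  X <- outer(cc$x, rep(1, nn)); Y <- outer(rep(1, nn), cc$y)
  list(grid = grid, state = flow_state(grid, u = fu(X, Y), v = fv(X, Y)),
       tags = fluid_tags(grid))
}

test_that("velocity-gradient invariants match analytic flows", {
  om <- 1.3
  f <- make_field_2d(32, function(x, y) -om * y, function(x, y) om * x)
  inv <- velocity_gradient_invariants(f$state, f$tags)
  interior <- as.vector(matrix(TRUE, 32, 32)[5:28, 5:28])
  sel <- array(FALSE, c(32, 32, 1)); sel[5:28, 5:28, 1] <- TRUE
  expect_equal(inv$lambda_ci[sel], rep(om, sum(sel)), tolerance = 1e-10)
  expect_equal(inv$q[sel], rep(om^2, sum(sel)), tolerance = 1e-10)

  g <- make_field_2d(32, function(x, y) 2 * y, function(x, y) 0 * x)
  invs <- velocity_gradient_invariants(g$state, g$tags)
  expect_equal(max(abs(invs$lambda_ci[sel])), 0, tolerance = 1e-12)

  a <- 0.8
  h <- make_field_2d(32, function(x, y) a * x, function(x, y) -a * y)
  invh <- velocity_gradient_invariants(h$state, h$tags)
  expect_equal(invh$q[sel], rep(-a^2, sum(sel)), tolerance = 1e-10)
  expect_equal(max(abs(invh$lambda_ci[sel])), 0, tolerance = 1e-12)
})

test_that("swirl strength is nonnegative and frame-invariant", {
  om <- 1.1
  f <- make_field_2d(32, function(x, y) -om * y + 0.3 * y^2,
                     function(x, y) om * x)
  inv <- velocity_gradient_invariants(f$state, f$tags)
  expect_true(all(inv$lambda_ci >= 0))
  # rotate field and frame by 90 degrees: v'(x) = R v(R^T x); the swirl
  # field rotates with it, so its value set over a rotation-symmetric
  # interior window is unchanged
  g <- make_field_2d(32, function(x, y) -om * y,
                     function(x, y) om * x + 0.3 * x^2)
  inv2 <- velocity_gradient_invariants(g$state, g$tags)
  a1 <- array(inv$lambda_ci, c(32, 32))
  a2 <- array(inv2$lambda_ci, c(32, 32))
  expect_equal(sort(as.vector(a2[5:28, 5:28])),
               sort(as.vector(a1[5:28, 5:28])), tolerance = 1e-9)
})

test_that("probes interpolate exactly and flag solid samples", {
  f <- make_field_2d(16, function(x, y) 0 * x + 0.4, function(x, y) 0 * x - 0.3)
  pr <- probe_velocity(f$state, f$tags, c(0.1, 0.2, 0))
  expect_equal(pr$magnitude, sqrt(0.4^2 + 0.3^2), tolerance = 1e-12)
  # probe at a cell centre returns the nodal value exactly
  cc <- grid_centers(f$grid)
  f$state$u[5 + 16 * 4] <- 9.9
  pr2 <- probe_velocity(f$state, f$tags, c(cc$x[5], cc$y[5], 0))
  expect_equal(pr2$u, 9.9, tolerance = 1e-12)
  # probe inside solid yields a flagged NA, not a silent zero
  grid <- cartesian_grid(c(24, 24, 24), rep(-2, 3), rep(2, 3))
  tags <- classify_cells(grid, fixture_sphere(2), fluid = "outside")
  st <- flow_state(grid)
  pr3 <- probe_velocity(st, tags, c(0, 0, 0))
  expect_false(pr3$in_fluid)
  expect_true(is.na(pr3$magnitude))
})

test_that("volume-averaged pressure equals the masked Riemann mean", {
  f <- make_field_2d(32, function(x, y) 0 * x, function(x, y) 0 * x)
  n <- prod(f$grid$n)
  f$state$p <- rep(3.7, n)
  mask <- rep(TRUE, n)
  expect_equal(volume_averaged_pressure(f$state, f$tags, mask), 3.7)
  # linear pressure over a symmetric mask: midpoint rule gives the centroid
  cc <- grid_centers(f$grid)
  X <- as.vector(outer(cc$x, rep(1, 32)))
  f$state$p <- 2 * X + 1
  sym <- abs(X) < 1
  expect_equal(volume_averaged_pressure(f$state, f$tags, sym), 1,
               tolerance = 1e-12)
  # independent summation oracle
  oracle <- sum(f$state$p[sym]) / sum(sym)
  expect_equal(volume_averaged_pressure(f$state, f$tags, sym), oracle,
               tolerance = 1e-12)
  expect_equal(volume_averaged_pressure(f$state, f$tags, sym, anchor = 5),
               oracle + 5, tolerance = 1e-12)
  expect_error(volume_averaged_pressure(f$state, f$tags, rep(FALSE, n)),
               "empty")
})

test_that("stroke work equals the loop area in mJ", {
  # rectangle traversed clockwise in (V, p): area (b - a)(d - c)
  Vs <- c(10, 10, 30, 30); Ps <- c(2, 8, 8, 2)
  loop <- pv_loop_and_stroke_work(1:4, Vs, Ps, closure_tol = 1)
  expect_equal(loop$stroke_work_mJ, 6 * 20, tolerance = 1e-12)
  # degenerate loop at constant volume does no work
  expect_equal(pv_loop_and_stroke_work(1:4, rep(5, 4), c(1, 2, 3, 2),
                                       closure_tol = 1)$stroke_work_mJ,
               0, tolerance = 1e-12)
  # ellipse loop: area pi dV dP / 4
  th <- seq(0, 2 * pi, length.out = 400)[-400]
  dV <- 18; dP <- 7
  loopE <- pv_loop_and_stroke_work(th, 20 + dV / 2 * cos(th),
                                   5 + dP / 2 * sin(th))
  expect_equal(loopE$stroke_work_mJ, pi * dV * dP / 4, tolerance = 1e-3)
  # cyclic shift of the samples leaves the area unchanged
  sh <- c(100:399, 1:99)
  loopS <- pv_loop_and_stroke_work(th, (20 + dV / 2 * cos(th))[sh],
                                   (5 + dP / 2 * sin(th))[sh],
                                   closure_tol = 1)
  expect_equal(loopS$stroke_work_mJ, loopE$stroke_work_mJ, tolerance = 1e-10)
  # a non-closing loop warns with the gap
  expect_warning(pv_loop_and_stroke_work(1:3, c(1, 5, 9), c(1, 1, 1),
                                         closure_tol = 0.05), "close")
})
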