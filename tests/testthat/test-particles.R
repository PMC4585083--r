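test_that("seeding is uniform over fluid cells, tagged and reproducible", {
  grid <- cartesian_grid(c(24, 24, 24), rep(-2, 3), rep(2, 3))
  tags <- classify_cells(grid, fixture_sphere(2))
  ens <- seed_particles(12000, tags, seed = 42)
  expect_equal(sum(ens$status == "active"), 12000L)
  ct <- ventriflow:::particle_cell_tag(ens$positions, tags$tags, 24, 24, 24,
                                       grid$lower[1], grid$lower[2],
                                       grid$lower[3], grid$h)
  expect_true(all(ct == 1L))
  ens2 <- seed_particles(12000, tags, seed = 42)
  expect_identical(ens$positions, ens2$positions)
  ens3 <- seed_particles(12000, tags, seed = 43)
  expect_false(identical(ens3$positions, ens$positions))
  expect_error(seed_particles(0, tags), "seeding error")
})

test_that("uniform advection is exact and RK4 holds a circular orbit", {
  nn <- 48
  grid <- cartesian_grid(c(nn, nn, 1), rep(-2, 3), rep(2, 3),
                         bc = rep("periodic", 6))
  tags <- fluid_tags(grid)
  cc <- grid_centers(grid)
  # uniform field
  stU <- flow_state(grid, u = rep(0.3, nn * nn), v = rep(-0.2, nn * nn))
  ens <- particle_ensemble(matrix(c(0.1, 0.2, 0), 1), "ventricular")
  ens <- advect_rk4(ens, stU, stU, tags, dt = 0.5, reproject = FALSE)
  expect_equal(ens$positions[1, ], c(0.1 + 0.15, 0.2 - 0.1, 0),
               tolerance = 1e-14)

  # solid-body rotation, one full revolution at omega dt = 0.01
  om <- 1
  X <- outer(cc$x, rep(1, nn)); Y <- outer(rep(1, nn), cc$y)
  stR <- flow_state(grid, u = -om * Y, v = om * X)
  dt <- 0.01 / om
  nrev <- ceiling(2 * pi / (om * dt))
  p <- particle_ensemble(matrix(c(1, 0, 0), 1), "ventricular")
  for (s in seq_len(nrev))
    p <- advect_rk4(p, stR, stR, tags, dt, reproject = FALSE)
  r_end <- sqrt(sum(p$positions[1, 1:2]^2))
  expect_lt(abs(r_end - 1), 1e-8)
})

test_that("advection is exact for velocity linear in time", {
  nn <- 16
  grid <- cartesian_grid(c(nn, nn, 1), c(0, 0, 0), c(1, 1, 1),
                         bc = rep("periodic", 6))
  tags <- fluid_tags(grid)
  a <- 0.3; b <- 2.0; dt <- 0.2
  st0 <- flow_state(grid, u = rep(a, nn * nn))
  st1 <- flow_state(grid, u = rep(a + b * dt, nn * nn))
  ens <- particle_ensemble(matrix(c(0.2, 0.5, 0), 1), "atrial")
  ens <- advect_rk4(ens, st0, st1, tags, dt, reproject = FALSE)
  expect_equal(ens$positions[1, 1], 0.2 + a * dt + b * dt^2 / 2,
               tolerance = 1e-14)
})

test_that("the injection accumulator integrates density times flux", {
  grid <- cartesian_grid(c(16, 16, 16), rep(0, 3), rep(1, 3))
  ens <- particle_ensemble(matrix(numeric(0), 0, 3), character(0))
  inlet <- list(center = c(0.4, 0.5), radius = 0.1, z = 0.5)
  outlet <- list(center = c(0.7, 0.5), radius = 0.1, z = 0.5)
  acc <- new.env(); acc$acc <- 0
  Q <- 7.3; dens <- 11.1; dt <- 0.01; nstep <- 250
  set.seed(1)
  for (s in seq_len(nstep))
    ens <- inject_and_remove(ens, inlet, outlet, Q, dens, dt, s * dt,
                             accumulator = acc)
  expect_lte(abs(nrow(ens$positions) - dens * Q * dt * nstep), 1)
  expect_true(all(ens$tag == "atrial"))
  # zero flux injects nothing
  n0 <- nrow(ens$positions)
  ens <- inject_and_remove(ens, inlet, outlet, 0, dens, dt, 1, accumulator = acc)
  expect_equal(nrow(ens$positions), n0)
  expect_error(inject_and_remove(ens, inlet, outlet, 1, -1, dt, 1),
               "parameter error")
})

test_that("outlet crossings are marked ejected with their exit time", {
  grid <- cartesian_grid(c(16, 16, 16), rep(0, 3), rep(1, 3))
  inlet <- list(center = c(0.3, 0.5), radius = 0.1, z = 0.6)
  outlet <- list(center = c(0.7, 0.5), radius = 0.1, z = 0.6)
  pos <- rbind(c(0.7, 0.5, 0.65),   # inside outlet tube above the plane
               c(0.3, 0.5, 0.65),   # inlet side: not ejected
               c(0.7, 0.5, 0.55))   # below the plane: not ejected
  ens <- particle_ensemble(pos, "ventricular")
  ens <- inject_and_remove(ens, inlet, outlet, 0, 1, 0.01, t = 0.123)
  expect_equal(ens$status, c("ejected", "active", "active"))
  expect_equal(ens$exit_time[1], 0.123)
})

test_that("transport decomposition handles limits and degenerate classes", {
  # piston flow: every inflow particle ejected, no ventricular particle is
  dec <- decompose_transport(100, 100, 200, 0, inflow_volume = 18,
                             start_volume = 23)
  m <- transport_metrics(dec)
  expect_equal(m$dr, 1)
  expect_equal(m$wr, 0)
  expect_true(is.infinite(m$n1pct_real))
  # all ventricular ejected, but no inflow -> undefined fraction, not 0
  expect_error(decompose_transport(0, 0, 200, 200, 18, 23), "undefined")
  # volume partition identity
  dec2 <- decompose_transport(120, 40, 300, 100, 17.8, 23.4)
  expect_equal(dec2$I + dec2$II + dec2$III + dec2$IV, 17.8 + 23.4)
})

test_that("the washout formulas reproduce the reference transport table", {
  # (DR %, WR %, N1%) rows for the four reference cases
  rows <- list(c(27.8, 43.5, 8), c(22.1, 36.6, 10),
               c(27.3, 16.6, 25), c(17.0, 8.0, 55))
  for (r in rows) {
    m <- transport_metrics(list(I = r[1], II = 100 - r[1],
                                III = r[2], IV = 100 - r[2]))
    expect_equal(100 * m$dr, r[1], tolerance = 1e-12)
    expect_equal(100 * m$wr, r[2], tolerance = 1e-12)
    expect_equal(m$n1pct, r[3])
  }
  # closed-form edge: WR = 99% -> RR = 0.01 -> exactly one cycle
  expect_equal(transport_metrics(list(I = 0, II = 1, III = 99, IV = 1))$n1pct_real,
               1, tolerance = 1e-12)
})

test_that("well-mixed tank sampling recovers E[WR] = SV/EDV and RR^N decay", {
  set.seed(2024)
  edv <- 41.2; esv <- 23.4; sv <- edv - esv
  p_eject <- sv / edv
  n <- 12000
  # one cycle: ejection is a uniform draw over the end-diastolic pool
  vent_ej <- rbinom(1, n, p_eject)
  dec <- decompose_transport(n, rbinom(1, n, p_eject), n, vent_ej,
                             inflow_volume = sv, start_volume = esv)
  m <- transport_metrics(dec)
  se <- sqrt(p_eject * (1 - p_eject) / n)
  expect_lt(abs(m$wr - p_eject), 4 * se)
  # residual-fraction decay over N cycles matches RR^N within sampling error
  rr <- 1 - p_eject
  for (trial in 1:3) {
    alive <- rep(TRUE, n)
    N <- 5
    for (cyc in seq_len(N))
      alive[alive] <- runif(sum(alive)) > p_eject
    expect_lt(abs(mean(alive) - rr^N), 5 * sqrt(rr^N * (1 - rr^N) / n) + 1e-9)
  }
})

test_that("II equals III at periodic steady state of the mixed oracle", {
  # at steady periodicity inflow = stroke volume, so retained inflow (II)
  # and delayed ejection (III) agree in expectation
  set.seed(7)
  edv <- 41.2; esv <- 23.4; sv <- edv - esv
  p_eject <- sv / edv
  n_in <- 12000; n_v <- 12000
  reps <- vapply(1:50, function(i) {
    dec <- decompose_transport(n_in, rbinom(1, n_in, p_eject),
                               n_v, rbinom(1, n_v, p_eject),
                               inflow_volume = sv, start_volume = esv)
    dec$II - dec$III   # E[II] = (esv/edv) sv = E[III] under common p
  }, numeric(1))
  expect_lt(abs(mean(reps)), 0.2)
})
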