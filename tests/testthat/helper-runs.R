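# heavier shared fixtures: Taylor-Green refinement study and the paired
# scaled-down ventricle simulations (built once, reused across test files)

tg_error <- function(nn, tend = 0.2, nu = 0.01, cfl = 0.4) {
  grid <- cartesian_grid(c(nn, nn, 1), c(0, 0, 0), c(2 * pi, 2 * pi, 2 * pi),
                         bc = rep("periodic", 6))
  cc <- grid_centers(grid)
  X <- outer(cc$x, rep(1, nn)); Y <- outer(rep(1, nn), cc$y)
  u0 <- -cos(X) * sin(Y); v0 <- sin(X) * cos(Y)
  props <- fluid_properties(rho = 1, mu = nu)
  tags <- fluid_tags(grid)
  st <- flow_state(grid, u = u0, v = v0)
  nsteps <- ceiling(tend / (cfl * grid$h))
  dt <- tend / nsteps
  for (s in seq_len(nsteps))
    st <- flow_step(st, dt, props, tags, poisson_tol = 1e-11, max_cycles = 80)
  dec <- exp(-2 * nu * tend)
  list(err = sqrt(mean((st$u - u0 * dec)^2 + (st$v - v0 * dec)^2)),
       div = attr(st, "div_max"), state = st, tags = tags, grid = grid)
}

tg_study <- function() memo("tg_study", {
  list(e32 = tg_error(32), e64 = tg_error(64), e128 = tg_error(128))
})

# paired synthetic runs: reference-characteristic volumes for the normal
# (41.2/23.4 mL) and failing (116.4/100.2 mL) hearts, identical solver
# settings; desk-scale grid and two cycles
paired_case <- function(edv, esv, name) {
  run_pipeline(run_config(list(
    case = name,
    geometry = list(synthetic = list(edv = edv, esv = esv)),
    grid = list(n = c(32, 32, 64), margin = 0.4),
    time = list(dt = 5e-4, cycles = 2, period = 0.5),
    particles = list(n = 12000, seed = 11),
    solver = list(output_every = 10, n_frames = 12, poisson_rtol = 1e-4))))
}

paired_runs <- function() memo("paired_runs", {
  list(normal = paired_case(41.2, 23.4, "normal-sr"),
       failing = paired_case(116.4, 100.2, "failing-sr"))
})
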