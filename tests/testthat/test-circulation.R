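const_wf <- function(v = 30) list(v_fun = function(t) rep(v, length(t)),
                                  dvdt_fun = function(t) rep(0, length(t)),
                                  period = 0.5)

test_that("closed-loop blood volume is conserved to round-off", {
  cfg <- circulation_config()
  wf <- fixture_waveform()
  st <- circulation_state(cfg, wf$v_fun(0))
  v0 <- circulation_total_volume(st)
  for (i in 1:10000)
    st <- step_circulation(cfg, st, wf$v_fun, wf$dvdt_fun, 1e-3)
  expect_lt(abs(circulation_total_volume(st) - v0) / v0, 1e-8)
})

test_that("an isolated Windkessel discharges with the analytic RC decay", {
  # huge downstream compliance pins the venous pressure near zero, so the
  # arterial compartment sees a pure RC discharge
  cfg <- circulation_config(R_sys = 0.2, C_art = 5, C_ven = 1e9)
  st <- circulation_state(cfg, 30)
  st$V[["art"]] <- 40  # charge the arterial compartment
  p0 <- st$V[["art"]] / cfg$C_art
  wf <- const_wf(30)
  tend <- 0.4
  for (i in seq_len(round(tend / 1e-3)))
    st <- step_circulation(cfg, st, wf$v_fun, wf$dvdt_fun, 1e-3)
  p_t <- st$V[["art"]] / cfg$C_art
  expect_equal(p_t, p0 * exp(-tend / (cfg$R_sys * cfg$C_art)),
               tolerance = 1e-4 * p0)
})

test_that("valves never carry negative flow", {
  cfg <- circulation_config()
  wf <- fixture_waveform()
  st <- circulation_state(cfg, wf$v_fun(0))
  for (i in 1:2000) {
    st <- step_circulation(cfg, st, wf$v_fun, wf$dvdt_fun, 1e-3)
    fl <- attr(st, "flows")
    expect_gte(fl[["tv"]], 0)
    expect_gte(fl[["pv"]], 0)
    expect_gte(fl[["lv_in"]], 0)
    expect_gte(fl[["lv_out"]], 0)
  }
})

test_that("the loop reaches periodic steady state under a cyclic drive", {
  res <- run_to_periodicity(circulation_config(), fixture_waveform(),
                            dt = 1e-3)
  expect_true(res$converged)
  st1 <- res$state$V
  st2 <- res$state
  wf <- fixture_waveform()
  for (i in 1:500) st2 <- step_circulation(circulation_config(), st2,
                                           wf$v_fun, wf$dvdt_fun, 1e-3)
  expect_equal(st2$V, st1, tolerance = 2e-4)
  # pressures are canine-plausible at steady state
  expect_gt(max(res$trace$p_art), 6)   # systolic aortic above ~6 kPa
  expect_lt(max(res$trace$p_art), 20)
  expect_gt(min(res$trace$p_art), 2)
})

test_that("a constant LV volume relaxes to equilibrium with zero loop area", {
  res <- run_to_periodicity(circulation_config(), const_wf(30), dt = 1e-3,
                            max_cycles = 400)
  expect_true(res$converged)
  expect_lt(res$pv_loop$stroke_work_mJ, 1e-4)
})

test_that("raising systemic resistance raises the steady aortic pressure", {
  wf <- fixture_waveform()
  base <- run_to_periodicity(circulation_config(), wf, dt = 1e-3)
  high <- run_to_periodicity(circulation_config(R_sys = 2 * 0.26), wf,
                             dt = 1e-3, max_cycles = 400)
  expect_gt(mean(high$trace$p_art), mean(base$trace$p_art))
})

test_that("too-large steps that empty a compartment are caught", {
  cfg <- circulation_config(C_art = 0.01)  # tiny compliance, huge flows
  st <- circulation_state(cfg, 30)
  st$V[["art"]] <- 5   # P = 500 kPa discharges far more than 5 mL per step
  wf <- const_wf(30)
  expect_error({
    for (i in 1:200) st <- step_circulation(cfg, st, wf$v_fun, wf$dvdt_fun, 0.05)
  }, "negative compartment")
})
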