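#' Closed-loop lumped circulation configuration
#'
#' Two Windkessel compartments in series per circulation (arterial and
#' venous for both the systemic and pulmonic sides), time-varying-elastance
#' atria and right ventricle, diode valves, and a kinematically driven LV
#' (its volume trajectory is an input: the one-way coupling).  Parameter
#' defaults are canine-plausible placeholders in kPa, mL and s (resistances
#' kPa.s/mL, compliances mL/kPa, elastances kPa/mL); none of the downstream
#' acceptance checks depend on their specific values, only on conservation,
#' periodicity and directional responses.
#'
#' @param R_av,R_sys,R_ven aortic valve, systemic (arterial-to-venous) and
#'   venous-return resistances.
#' @param R_tv,R_pv,R_pul,R_pven tricuspid, pulmonic valve, pulmonary
#'   (arterial-to-venous) and pulmonary venous-return resistances.
#' @param R_mv mitral valve resistance.
#' @param C_art,C_ven,C_part,C_pven compliances of the four Windkessel
#'   compartments.
#' @param la,ra,rv lists with `Emin`, `Emax` (kPa/mL), `V0` (mL) and
#'   activation timing `t_peak`, `duration` (fractions of the period) for
#'   the elastance chambers.
#' @param total_volume total (stressed) blood volume (mL).
#' @param period cycle period (s).
#' @return object of class `vf_circ_config`.
#' @export
circulation_config <- function(R_av = 0.008, R_sys = 0.26, R_ven = 0.003,
                               R_tv = 0.004, R_pv = 0.008, R_pul = 0.06,
                               R_pven = 0.003, R_mv = 0.006,
                               C_art = 5, C_ven = 50, C_part = 4, C_pven = 15,
                               la = list(Emin = 0.01, Emax = 0.03, V0 = 3,
                                         t_peak = 0.92, duration = 0.18),
                               ra = list(Emin = 0.008, Emax = 0.025, V0 = 3,
                                         t_peak = 0.92, duration = 0.18),
                               rv = list(Emin = 0.01, Emax = 0.18, V0 = 8,
                                         t_peak = 0.25, duration = 0.45),
                               total_volume = 350, period = 0.5) {
  structure(as.list(environment()), class = "vf_circ_config")
}

# smooth half-sine activation, peak 1 at t_peak, support width `duration`
elastance_at <- function(ch, t, period) {
  tau <- (t / period) %% 1
  d <- ch$duration
  x <- (tau - (ch$t_peak - d / 2)) %% 1
  act <- ifelse(x < d, sin(pi * x / d)^2, 0)
  ch$Emin + (ch$Emax - ch$Emin) * act
}

#' Initial circulation state
#'
#' Distributes the total blood volume (minus the initial LV volume) over the
#' compartments in proportion to plausible resting pressures.
#'
#' @param cfg a [circulation_config()].
#' @param v_lv0 LV volume at t = 0 (mL).
#' @return object of class `vf_circ_state`: compartment volumes (mL) and time.
#' @export
circulation_state <- function(cfg, v_lv0) {
  rest <- cfg$total_volume - v_lv0
  # resting split: most volume in the venous beds
  w <- c(art = 0.12, ven = 0.55, part = 0.10, pven = 0.13, la = 0.04,
         ra = 0.03, rv = 0.03)
  v <- c(rest * w / sum(w), lv = v_lv0)
  structure(list(V = v, t = 0), class = "vf_circ_state")
}

circ_pressures <- function(cfg, V, t) {
  c(art = V[["art"]] / cfg$C_art,
    ven = V[["ven"]] / cfg$C_ven,
    part = V[["part"]] / cfg$C_part,
    pven = V[["pven"]] / cfg$C_pven,
    la = elastance_at(cfg$la, t, cfg$period) * (V[["la"]] - cfg$la$V0),
    ra = elastance_at(cfg$ra, t, cfg$period) * (V[["ra"]] - cfg$ra$V0),
    rv = elastance_at(cfg$rv, t, cfg$period) * (V[["rv"]] - cfg$rv$V0))
}

# compartment volume derivatives given the prescribed LV in/outflow split
circ_rhs <- function(cfg, V, t, q_lv_in, q_lv_out) {
  P <- circ_pressures(cfg, V, t)
  diode <- function(dp, R) max(dp, 0) / R
  q_sys <- (P[["art"]] - P[["ven"]]) / cfg$R_sys        # arterial -> venous
  q_ret <- (P[["ven"]] - P[["ra"]]) / cfg$R_ven          # venous -> RA
  q_tv <- diode(P[["ra"]] - P[["rv"]], cfg$R_tv)         # RA -> RV
  q_pv <- diode(P[["rv"]] - P[["part"]], cfg$R_pv)       # RV -> pulm art
  q_pul <- (P[["part"]] - P[["pven"]]) / cfg$R_pul       # pulm art -> pulm ven
  q_pret <- (P[["pven"]] - P[["la"]]) / cfg$R_pven       # pulm ven -> LA
  # the LV volume is integrated with the same RK4 stages as the
  # compartments so the closed-loop total is conserved to round-off
  dV <- c(art = q_lv_out - q_sys,
          ven = q_sys - q_ret,
          part = q_pv - q_pul,
          pven = q_pul - q_pret,
          la = q_pret - q_lv_in,
          ra = q_ret - q_tv,
          rv = q_tv - q_pv,
          lv = q_lv_in - q_lv_out)
  list(dV = dV, P = P,
       flows = c(sys = q_sys, ret = q_ret, tv = q_tv, pv = q_pv,
                 pul = q_pul, pret = q_pret, lv_in = q_lv_in,
                 lv_out = q_lv_out))
}

#' Advance the circulation by one time step
#'
#' Classical RK4 on the compartment volume ODEs `dV_i/dt = Q_in - Q_out`
#' with `Q = dP/R` through resistances, diode valves enforcing one-way flow,
#' Windkessel pressures `P = V/C` and elastance pressures `P = E(t)(V - V0)`.
#' The LV is volume-driven: its filling and ejection flows are set by the
#' sign of `dv_lv` (mitral inflow when filling, aortic outflow when
#' ejecting), so total blood volume is conserved exactly up to round-off.
#'
#' @param cfg a [circulation_config()].
#' @param state a [circulation_state()].
#' @param v_lv_fun function of time returning the LV volume (mL).
#' @param dvdt_fun function of time returning dV_LV/dt (mL/s).
#' @param dt time step (s).
#' @return updated state; attribute `pressures` holds the compartment
#'   pressures at the new time, `lv_pressure` the LEM estimate of LV
#'   pressure.
#' @export
step_circulation <- function(cfg, state, v_lv_fun, dvdt_fun, dt) {
  if (dt <= 0) stop("dt must be positive")
  lv_split <- function(t) {
    dv <- dvdt_fun(t)
    c(q_in = max(dv, 0), q_out = max(-dv, 0))
  }
  f <- function(t, V) {
    q <- lv_split(t)
    circ_rhs(cfg, V, t, q[["q_in"]], q[["q_out"]])$dV
  }
  t <- state$t; V <- state$V
  k1 <- f(t, V)
  k2 <- f(t + dt / 2, V + dt / 2 * k1)
  k3 <- f(t + dt / 2, V + dt / 2 * k2)
  k4 <- f(t + dt, V + dt * k3)
  Vn <- V + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(Vn < 0))
    stop("integration error: negative compartment volume (reduce dt)",
         call. = FALSE)
  tn <- t + dt
  state$V <- Vn
  state$t <- tn
  rhs <- circ_rhs(cfg, Vn, tn, lv_split(tn)[["q_in"]], lv_split(tn)[["q_out"]])
  P <- rhs$P
  # LEM LV pressure: consistent with the open valve, or relaxed in between
  dv <- dvdt_fun(tn)
  p_lv <- if (dv < 0) P[["art"]] + (-dv) * cfg$R_av
  else if (dv > 0) P[["la"]] - dv * cfg$R_mv
  else (P[["art"]] + P[["la"]]) / 2
  attr(state, "pressures") <- P
  attr(state, "lv_pressure") <- p_lv
  attr(state, "flows") <- rhs$flows
  state
}

#' Run the circulation to periodic steady state
#'
#' Cycles the closed loop under the prescribed LV volume waveform until the
#' compartment state changes by less than `tol` (relative, max-norm) between
#' successive cycles, then emits one converged cycle: compartment pressure
#' traces (aortic after-load and atrial pre-load for pressure anchoring) and
#' the lumped-model P-V loop.
#'
#' @param cfg a [circulation_config()].
#' @param waveform a [make_volume_waveform()] (or any object with `v_fun`,
#'   `dvdt_fun`, `period`).
#' @param dt integration step (s).
#' @param tol relative cycle-to-cycle convergence tolerance.
#' @param max_cycles maximum number of cycles.
#' @return list: `state` (final), `trace` (converged-cycle data.frame with
#'   times, compartment pressures, LV pressure and volume), `pv_loop` (a
#'   [pv_loop_and_stroke_work()] result), `cycles`, `converged`.
#' @export
run_to_periodicity <- function(cfg, waveform, dt = 1e-3, tol = 1e-4,
                               max_cycles = 200) {
  state <- circulation_state(cfg, waveform$v_fun(0))
  nstep <- round(cfg$period / dt)
  converged <- FALSE
  cyc <- 0
  change <- NA_real_
  for (cyc in seq_len(max_cycles)) {
    Vstart <- state$V
    for (s in seq_len(nstep))
      state <- step_circulation(cfg, state, waveform$v_fun, waveform$dvdt_fun, dt)
    change <- max(abs(state$V - Vstart) / pmax(abs(Vstart), 1))
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("circulation did not reach periodicity in %d cycles (last change %.3g)",
                 max_cycles, change), call. = FALSE)
  # emit one converged cycle
  n <- nstep
  trace <- data.frame(t = numeric(n), p_art = numeric(n), p_ven = numeric(n),
                      p_part = numeric(n), p_pven = numeric(n),
                      p_la = numeric(n), p_ra = numeric(n), p_rv = numeric(n),
                      p_lv = numeric(n), v_lv = numeric(n))
  t0 <- state$t
  for (s in seq_len(n)) {
    state <- step_circulation(cfg, state, waveform$v_fun, waveform$dvdt_fun, dt)
    P <- attr(state, "pressures")
    trace[s, ] <- c(state$t - t0, P[["art"]], P[["ven"]], P[["part"]],
                    P[["pven"]], P[["la"]], P[["ra"]], P[["rv"]],
                    attr(state, "lv_pressure"), state$V[["lv"]])
  }
  loop <- pv_loop_and_stroke_work(trace$t, trace$v_lv, trace$p_lv,
                                  closure_tol = 1)
  list(state = state, trace = trace, pv_loop = loop, cycles = cyc,
       converged = converged)
}

#' Total blood volume of a circulation state (closed-loop audit)
#' @param state a [circulation_state()].
#' @return total volume (mL) including the LV.
#' @export
circulation_total_volume <- function(state) {
  sum(state$V)
}
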