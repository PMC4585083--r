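#' Advance the flow through one or more cardiac cycles
#'
#' The moving-boundary time loop: at every step the endocardial surface is
#' interpolated to the new time level, the grid is re-classified, fresh cells
#' (solid that became fluid) are filled with wall-consistent velocities,
#' ghost closures impose the wall velocity, and one projection step advances
#' the flow.  Optionally a particle ensemble is advected alongside (RK4,
#' trilinear-in-space / linear-in-time velocity), inflow particles are
#' injected in proportion to the instantaneous mitral flux, ejected particles
#' are removed at the aortic plane, and a per-cycle transport decomposition
#' is accumulated.
#'
#' @param kin a [surface_kinematics()] (with `basal_z` set for cavity
#'   bookkeeping).
#' @param grid a [cartesian_grid()] enclosing all frames; the tube
#'   cross-sections should meet an `"open"` face.
#' @param props [fluid_properties()].
#' @param dt time step (s).
#' @param n_cycles number of cardiac cycles to run.
#' @param inlet,outlet lists with `center` (xy), `radius` and `z` (plane
#'   height, defaults to `kin$basal_z`) defining the mitral and aortic
#'   planes; NULL disables particle transport and flux bookkeeping tied to
#'   them.
#' @param particles optional [particle_ensemble()] seeded at t = 0.
#' @param particle_density number density for inflow injection
#'   (particles/mL); NULL = seeded density.
#' @param probe_points optional matrix of probe locations (one row each).
#' @param output_every store series samples every this many steps.
#' @param blend upwind blend fraction for the advection term.
#' @param reclassify_every re-classify the grid against the moved surface
#'   every this many steps (the wall travels a small fraction of a cell per
#'   step, so a short reuse interval changes the tag field negligibly while
#'   saving most of the classification cost); ghost wall velocities are
#'   refreshed every step regardless.
#' @param poisson_rtol,poisson_tol pressure-solve tolerances.
#' @param valve_plugs close the far end of the atrial tube during ejection
#'   and of the aortic tube during filling (a boundary-condition stand-in
#'   for the absent valve leaflets, switching with the sign of dV/dt) so
#'   inflow enters via the mitral side and ejection leaves via the aorta.
#' @param swirl_threshold swirl-strength threshold (1/s) for the isosurface
#'   volume fraction series; NULL skips it.
#' @param cfl_limit CFL abort threshold.
#' @param snapshot_times times (s) at which to keep full field snapshots.
#' @param verbose print progress every cycle.
#' @return object of class `vf_flow_result`: `series` (data.frame),
#'   `probes` (data.frame), `state`, `particles`, `decompositions` (one per
#'   completed cycle), `snapshots`, `diagnostics`.
#' @export
advance_cycle <- function(kin, grid, props, dt, n_cycles = 1,
                          inlet = NULL, outlet = NULL,
                          particles = NULL, particle_density = NULL,
                          probe_points = NULL, output_every = 10,
                          blend = 0.15, reclassify_every = 1,
                          valve_plugs = TRUE,
                          poisson_rtol = 1e-5,
                          poisson_tol = 1e-10, swirl_threshold = NULL,
                          cfl_limit = 0.95, snapshot_times = numeric(0),
                          verbose = FALSE) {
  period <- kin$period
  nstep_cycle <- round(period / dt)
  if (abs(nstep_cycle * dt - period) > 1e-9 * period)
    stop("dt must divide the cycle period")
  basal_z <- kin$basal_z
  cc <- grid_centers(grid)
  nxyz <- grid$n
  cell_z <- rep(cc$z, each = nxyz[1] * nxyz[2])
  cav_mask <- if (!is.null(basal_z)) cell_z < basal_z else rep(TRUE, prod(nxyz))

  mesh_at <- function(t) {
    ik <- interpolate_kinematics(kin, t)
    list(mesh = vf_mesh(ik$vertices, kin$triangles), vel = ik$velocities)
  }

  f0 <- mesh_at(0)
  tags <- classify_cells(grid, f0$mesh)
  if (sum(tags$tags == 1L) == 0) stop("geometry error: no fluid cells")
  state <- flow_state(grid)
  vol0 <- enclosed_volume(f0$mesh, check = FALSE)
  cav0 <- if (!is.null(basal_z)) cavity_volume(f0$mesh, basal_z) else vol0
  fixed_above <- vol0 - cav0

  density <- NULL
  acc <- new.env(parent = emptyenv()); acc$acc <- 0
  if (!is.null(particles)) {
    if (is.null(inlet) || is.null(outlet))
      stop("particle transport needs inlet and outlet definitions")
    if (is.null(inlet$z)) inlet$z <- basal_z
    if (is.null(outlet$z)) outlet$z <- basal_z
    fluid_vol <- sum(tags$tags == 1L) * grid$h^3
    density <- if (is.null(particle_density))
      nrow(particles$positions) / fluid_vol else particle_density
  }

  nsamp_max <- ceiling(n_cycles * nstep_cycle / output_every) + 2
  series <- data.frame(t = rep(NA_real_, nsamp_max), v_lv = NA_real_,
                       p_lv_raw = NA_real_, p_inlet_raw = NA_real_,
                       p_outlet_raw = NA_real_, inlet_flux = NA_real_,
                       outlet_flux = NA_real_, swirl_frac = NA_real_,
                       div_max = NA_real_, kinetic_energy = NA_real_)
  probes <- NULL
  srow <- 0L
  snapshots <- list()
  decomps <- list()
  diag <- list(mg_cycles = integer(0), reprojections = 0L)

  tube_mask <- function(tube) {
    if (is.null(tube)) return(NULL)
    xy <- expand.grid(x = cc$x, y = cc$y)
    r2 <- (xy$x - tube$center[1])^2 + (xy$y - tube$center[2])^2
    inxy <- r2 <= (1.3 * tube$radius)^2
    rep(inxy, times = nxyz[3]) & (cell_z >= basal_z)
  }
  inlet_mask <- if (!is.null(inlet) && !is.null(basal_z)) {
    if (is.null(inlet$z)) inlet$z <- basal_z
    tube_mask(inlet)
  } else NULL
  outlet_mask <- if (!is.null(outlet) && !is.null(basal_z)) {
    if (is.null(outlet$z)) outlet$z <- basal_z
    tube_mask(outlet)
  } else NULL

  plug_mask <- function(tube) {
    # top three cell layers inside the tube cross-section
    if (is.null(tube)) return(integer(0))
    xy <- expand.grid(x = cc$x, y = cc$y)
    r2 <- (xy$x - tube$center[1])^2 + (xy$y - tube$center[2])^2
    # clip to the tube's own half so the plug cannot shade the other tube
    own <- sign(xy$x) == sign(tube$center[1])
    inxy <- which(r2 <= (1.3 * tube$radius)^2 & own)
    unlist(lapply((nxyz[3] - 2):nxyz[3], function(k)
      inxy + (k - 1) * nxyz[1] * nxyz[2]))
  }
  inlet_plug <- if (valve_plugs && !is.null(inlet)) plug_mask(inlet) else integer(0)
  outlet_plug <- if (valve_plugs && !is.null(outlet)) plug_mask(outlet) else integer(0)

  plane_flux <- function(st, tube, direction = 1) {
    # volume flux (mL/s) across the basal plane through a tube cross-section
    k <- max(1L, min(nxyz[3], round((tube$z - grid$lower[3]) / grid$h)))
    uz <- array(st$uz, c(nxyz[1], nxyz[2], nxyz[3] + 1))
    xy <- expand.grid(x = cc$x, y = cc$y)
    r2 <- (xy$x - tube$center[1])^2 + (xy$y - tube$center[2])^2
    sel <- matrix(r2 <= (1.3 * tube$radius)^2, nxyz[1], nxyz[2])
    sum(uz[, , k + 1][sel]) * grid$h^2 * direction
  }

  record <- function(st, tags, t, inflx, outflx) {
    srow <<- srow + 1L
    m <- mesh_at(t)
    vlv <- enclosed_volume(m$mesh, check = FALSE) - fixed_above
    plvr <- tryCatch(volume_averaged_pressure(st, tags, cav_mask),
                     error = function(e) NA_real_)
    sw <- if (!is.null(swirl_threshold))
      swirl_volume_fraction(st, tags, swirl_threshold, mask = cav_mask)
    else NA_real_
    ke <- 0.5 * props$rho * sum((st$u^2 + st$v^2 + st$w^2)[tags$tags == 1L]) *
      grid$h^3
    pin <- if (!is.null(inlet_mask) && any(tags$tags == 1L & inlet_mask))
      mean(st$p[tags$tags == 1L & inlet_mask]) else NA_real_
    pout <- if (!is.null(outlet_mask) && any(tags$tags == 1L & outlet_mask))
      mean(st$p[tags$tags == 1L & outlet_mask]) else NA_real_
    series[srow, ] <<- c(t, vlv, plvr, pin, pout, inflx, outflx, sw,
                         attr(st, "div_max") %||% NA_real_, ke)
    if (!is.null(probe_points)) {
      pr <- do.call(rbind, lapply(seq_len(nrow(probe_points)), function(i) {
        cbind(probe = i, probe_velocity(st, tags, probe_points[i, ]))
      }))
      probes <<- rbind(probes, pr)
    }
  }

  `%||%` <- function(a, b) if (is.null(a)) b else a

  # particle cycle bookkeeping
  cycle_start_lv <- NULL
  cycle_start_vol <- cav0
  reset_cycle_tracking <- function(t) {
    if (is.null(particles)) return()
    act <- particles$status == "active"
    inlv <- act & particles$positions[, 3] < basal_z
    cycle_start_lv <<- which(inlv)
    particles$entered_lv[] <<- FALSE
    cycle_start_vol <<- enclosed_volume(mesh_at(t)$mesh, check = FALSE) -
      fixed_above
  }
  reset_cycle_tracking(0)
  inflow_acc <- 0

  record(state, tags, 0, NA_real_, NA_real_)

  total_steps <- n_cycles * nstep_cycle
  for (step in seq_len(total_steps)) {
    t_new <- step * dt
    fr <- mesh_at(t_new)
    reclass <- step %% reclassify_every == 0 || step == 1
    tags_old <- tags
    if (reclass) tags <- classify_cells(grid, fr$mesh)
    # valve plugs: block the far end of the idle tube for this phase
    if (valve_plugs && (length(inlet_plug) || length(outlet_plug))) {
      filling <- enclosed_volume(fr$mesh, check = FALSE) -
        enclosed_volume(mesh_at(t_new - dt)$mesh, check = FALSE) >= 0
      plug <- if (filling) outlet_plug else inlet_plug
      plug <- plug[tags$tags[plug] == 1L]
      if (length(plug)) {
        tags$tags[plug] <- 0L
        state$u[plug] <- 0; state$v[plug] <- 0; state$w[plug] <- 0
      }
    }
    # fresh cells: solid -> fluid this step
    fresh <- if (reclass) which(tags$tags == 1L & tags_old$tags != 1L)
             else integer(0)
    fresh <- fresh[!(fresh %in% c(inlet_plug, outlet_plug))]
    if (length(fresh)) {
      pts <- cbind(cc$x[arrayInd(fresh, nxyz)[, 1]],
                   cc$y[arrayInd(fresh, nxyz)[, 2]],
                   cc$z[arrayInd(fresh, nxyz)[, 3]])
      q <- point_mesh_query(pts, fr$mesh$vertices, fr$mesh$triangles)
      tri <- kin$triangles[q$triangle, , drop = FALSE]
      b <- q$barycentric
      vw <- b[, 1] * fr$vel[tri[, 1], , drop = FALSE] +
        b[, 2] * fr$vel[tri[, 2], , drop = FALSE] +
        b[, 3] * fr$vel[tri[, 3], , drop = FALSE]
      state$u[fresh] <- vw[, 1]; state$v[fresh] <- vw[, 2]
      state$w[fresh] <- vw[, 3]
    }
    wall <- ghost_wall_velocity(tags, fr$vel)
    state0 <- state
    state <- apply_ghost_bc(state, tags, wall)
    # non-incremental correction: the pressure is recomputed from scratch
    # every step, which keeps the moving geometry honest (cells swept by the
    # wall never contribute a stale lagged pressure to the momentum balance)
    state <- predict_velocity(state, dt, props, tags, blend = blend,
                              cfl_limit = cfl_limit)
    state <- apply_ghost_bc(state, tags, wall)
    ff <- face_fluxes(state$u, state$v, state$w, nxyz[1], nxyz[2], nxyz[3],
                      grid$h, grid$bc, tags$tags)
    state$ux <- ff$ux; state$uy <- ff$uy; state$uz <- ff$uz
    div <- face_divergence(state$ux, state$uy, state$uz, nxyz[1], nxyz[2],
                           nxyz[3], grid$h, tags$tags)
    p_prev <- state$p
    p <- solve_pressure_poisson(div, tags, dt, props$rho, tol = poisson_tol,
                                rtol = poisson_rtol, max_cycles = 50,
                                nsmooth = 3, p_init = p_prev)
    diag$mg_cycles <- c(diag$mg_cycles, attr(p, "cycles"))
    state$p <- numeric(length(state$p))
    state <- project(state, p, dt, props$rho, tags)
    d2 <- face_divergence(state$ux, state$uy, state$uz, nxyz[1], nxyz[2],
                          nxyz[3], grid$h, tags$tags)
    attr(state, "div_max") <- max(abs(d2))
    state$t <- t_new

    inflx <- outflx <- NA_real_
    if (!is.null(inlet)) {
      inflx <- -plane_flux(state, inlet)    # downward (into LV) positive
      outflx <- plane_flux(state, outlet)   # upward (out of LV) positive
    }

    if (!is.null(particles)) {
      particles <- advect_rk4(particles, state0, state, tags, dt)
      pre <- particles$reprojections
      particles <- inject_and_remove(particles, inlet, outlet,
                                     inlet_flux = max(inflx, 0),
                                     density = density, dt = dt, t = t_new,
                                     accumulator = acc)
      if (inflx > 0) inflow_acc <- inflow_acc + inflx * dt
    }

    if (step %% output_every == 0 || step == total_steps)
      record(state, tags, t_new, inflx, outflx)
    for (ts in snapshot_times)
      if (abs(t_new - ts) < dt / 2)
        snapshots[[length(snapshots) + 1]] <-
          list(t = t_new, state = state, tags = tags)

    # cycle boundary: decompose and reset
    if (step %% nstep_cycle == 0 && !is.null(particles)) {
      cyc_t0 <- (step / nstep_cycle - 1) * period
      atr <- particles$tag == "atrial"
      inflow_members <- which(atr & particles$entered_lv)
      ej <- particles$status == "ejected" &
        !is.na(particles$exit_time) & particles$exit_time > cyc_t0
      inflow_ej <- sum(ej[inflow_members])
      vent_ej <- sum(ej[cycle_start_lv])
      dec <- tryCatch(
        decompose_transport(length(inflow_members), inflow_ej,
                            length(cycle_start_lv), vent_ej,
                            inflow_volume = inflow_acc,
                            start_volume = cycle_start_vol),
        error = function(e) e)
      decomps[[length(decomps) + 1]] <- dec
      inflow_acc <- 0
      reset_cycle_tracking(t_new %% period)
    }
    if (verbose && step %% nstep_cycle == 0)
      message(sprintf("cycle %d/%d done (t = %.3f s)",
                      step %/% nstep_cycle, n_cycles, t_new))
  }

  diag$reprojections <- if (!is.null(particles)) particles$reprojections else 0L
  structure(list(series = series[seq_len(srow), ],
                 probes = probes, state = state, tags = tags,
                 particles = particles, decompositions = decomps,
                 snapshots = snapshots, diagnostics = diag,
                 grid = grid, kin = kin, dt = dt, n_cycles = n_cycles),
            class = "vf_flow_result")
}

#' @export
print.vf_flow_result <- function(x, ...) {
  cat(sprintf("<vf_flow_result> %d cycles, dt = %g s, grid %s\n",
              x$n_cycles, x$dt, paste(x$grid$n, collapse = "x")))
  if (length(x$decompositions)) {
    d <- x$decompositions[[length(x$decompositions)]]
    if (inherits(d, "vf_decomposition")) print(d)
  }
  invisible(x)
}
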