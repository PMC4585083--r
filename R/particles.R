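#' Particle ensemble
#'
#' Tagged point-mass blood cells: positions, an immutable origin tag
#' (`"atrial"` for cells seeded or injected on the atrial side, `"ventricular"`
#' for cells inside the LV cavity at seeding, `"aortic"` for cells seeded in
#' the outflow tract), birth time, status (`"active"`, `"ejected"`,
#' `"frozen"`) and exit time.
#'
#' @param positions n x 3 matrix (cm).
#' @param tag character vector of origin tags.
#' @param birth numeric birth times (s).
#' @return object of class `vf_particles`.
#' @export
particle_ensemble <- function(positions, tag, birth = 0) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  structure(list(positions = positions,
                 tag = rep_len(tag, n),
                 birth = rep_len(birth, n),
                 status = rep("active", n),
                 exit_time = rep(NA_real_, n),
                 entered_lv = rep(FALSE, n),
                 reprojections = 0L),
            class = "vf_particles")
}

#' @export
print.vf_particles <- function(x, ...) {
  cat(sprintf("<vf_particles> %d particles (%d active, %d ejected, %d frozen)\n",
              length(x$tag), sum(x$status == "active"),
              sum(x$status == "ejected"), sum(x$status == "frozen")))
  invisible(x)
}

#' Seed particles uniformly over the fluid region
#'
#' Rejection-samples `n` uniform positions over the fluid cells of the tagged
#' domain (the whole lumen: LA inlet, LV and aortic outlet).  Particles below
#' the basal plane are tagged `"ventricular"`; above it they are tagged
#' `"atrial"` on the inlet side and `"aortic"` on the outlet side.
#'
#' @param n number of particles (the reference study uses 12,000).
#' @param tags a [classify_cells()] result for the seeding geometry.
#' @param seed RNG seed (recorded; reproducible).
#' @param basal_z basal plane height (cm); NULL tags everything ventricular.
#' @param inlet_center xy centre of the inlet tube, used to split the
#'   above-basal region into atrial vs aortic.
#' @return a [particle_ensemble()].
#' @export
seed_particles <- function(n, tags, seed = 1L, basal_z = NULL,
                           inlet_center = NULL) {
  if (n < 1) stop("seeding error: n must be >= 1", call. = FALSE)
  fluid <- which(tags$tags == 1L)
  if (length(fluid) == 0) stop("seeding error: empty fluid region", call. = FALSE)
  grid <- tags$grid
  set.seed(seed)
  idx <- fluid[sample.int(length(fluid), n, replace = TRUE)]
  ai <- arrayInd(idx, grid$n)
  jitter <- matrix(runif(3 * n) - 0.5, n, 3)
  if (grid$twod) jitter[, 3] <- 0
  pos <- cbind(grid$lower[1] + (ai[, 1] - 0.5) * grid$h,
               grid$lower[2] + (ai[, 2] - 0.5) * grid$h,
               grid$lower[3] + (ai[, 3] - 0.5) * grid$h) + jitter * grid$h
  tag <- rep("ventricular", n)
  if (!is.null(basal_z)) {
    above <- pos[, 3] >= basal_z
    if (is.null(inlet_center)) {
      tag[above] <- "atrial"
    } else {
      # split the above-basal region by which side of x = 0 each tube sits on
      atr <- above & (sign(pos[, 1]) == sign(inlet_center[1]))
      tag[above] <- ifelse(atr[above], "atrial", "aortic")
    }
  }
  particle_ensemble(pos, tag)
}

#' RK4 particle advection over one time step
#'
#' Classical fourth-order Runge-Kutta with trilinear spatial interpolation
#' and linear time interpolation between the bracketing velocity fields.
#' Particles whose update lands inside the solid region are re-projected to
#' the fluid side of the wall (logged); particles whose stage points lose
#' fluid support entirely are frozen with a diagnostic status.
#'
#' @param ens a [particle_ensemble()].
#' @param state0,state1 [flow_state()]s at t and t+dt.
#' @param tags cell tags at t+dt (with `mesh` for re-projection).
#' @param dt time step (s).
#' @param reproject push wall-crossing particles back inside (default TRUE).
#' @return updated ensemble.
#' @export
advect_rk4 <- function(ens, state0, state1, tags, dt, reproject = TRUE) {
  grid <- tags$grid
  # frozen particles regain fluid support when the geometry moves back
  fro <- which(ens$status == "frozen")
  if (length(fro)) {
    ct <- particle_cell_tag(ens$positions[fro, , drop = FALSE], tags$tags,
                            grid$n[1], grid$n[2], grid$n[3],
                            grid$lower[1], grid$lower[2], grid$lower[3],
                            grid$h)
    ens$status[fro[ct == 1L]] <- "active"
  }
  act <- ens$status == "active"
  if (!any(act)) return(ens)
  res <- advect_rk4_cpp(ens$positions, act,
                        state0$u, state0$v, state0$w,
                        state1$u, state1$v, state1$w,
                        tags$tags, grid$n[1], grid$n[2], grid$n[3],
                        grid$lower[1], grid$lower[2], grid$lower[3],
                        grid$h, dt)
  ens$positions <- res$positions
  frozen <- which(res$status == 3L)
  if (length(frozen)) ens$status[frozen] <- "frozen"
  if (reproject && !is.null(tags$mesh)) {
    ct <- particle_cell_tag(ens$positions, tags$tags,
                            grid$n[1], grid$n[2], grid$n[3],
                            grid$lower[1], grid$lower[2], grid$lower[3],
                            grid$h)
    bad <- which(ens$status == "active" & ct != 1L)
    if (length(bad)) {
      q <- point_mesh_query(ens$positions[bad, , drop = FALSE],
                            tags$mesh$vertices, tags$mesh$triangles)
      # only particles at or beyond the wall are pulled back; particles in
      # non-fluid cells that are still geometrically inside the lumen (e.g.
      # plugged tube ends) stay where they are
      cross <- q$signed_distance > 0
      bad <- bad[cross]
      if (length(bad)) {
        d <- pmax(q$distance[cross], 1e-12)
        dirn <- (ens$positions[bad, , drop = FALSE] -
                 q$closest[cross, , drop = FALSE]) / d
        eps <- 0.05 * grid$h
        ens$positions[bad, ] <- q$closest[cross, , drop = FALSE] - dirn * eps
        ens$reprojections <- ens$reprojections + length(bad)
      }
    }
  }
  ens
}

#' Inject inflow particles and remove ejected ones
#'
#' New atrial-tagged particles appear on the inlet plane at a rate equal to
#' `number density x instantaneous inlet volume flux`, kept exact in the long
#' run by a fractional accumulator.  Particles crossing the outlet (aortic)
#' plane are marked `ejected` with their exit time.  Mitral-plane crossings
#' into the LV are recorded so the transport decomposition can identify the
#' inflow population.
#'
#' @param ens a [particle_ensemble()].
#' @param inlet list: `center` (xy), `radius`, `z` (plane height).
#' @param outlet list: `center` (xy), `radius`, `z`.
#' @param inlet_flux instantaneous inlet volume flux into the LV (mL/s,
#'   >= 0 during diastole; negative values inject nothing).
#' @param density number density (particles/mL).
#' @param dt time step (s); `t` current time (s).
#' @param accumulator environment holding the fractional accumulator state.
#' @return updated ensemble.
#' @export
inject_and_remove <- function(ens, inlet, outlet, inlet_flux, density, dt, t,
                              accumulator = NULL) {
  if (density < 0) stop("parameter error: density must be >= 0", call. = FALSE)
  # removal: active particles above the outlet plane inside the outlet tube
  act <- ens$status == "active"
  if (any(act)) {
    p <- ens$positions
    r2 <- (p[, 1] - outlet$center[1])^2 + (p[, 2] - outlet$center[2])^2
    out <- act & (p[, 3] > outlet$z) & (r2 <= (1.2 * outlet$radius)^2)
    if (any(out)) {
      ens$status[out] <- "ejected"
      ens$exit_time[out] <- t
    }
    # record LV entry (below the basal/inlet plane)
    entered <- act & !ens$entered_lv & (p[, 3] < inlet$z)
    ens$entered_lv[entered] <- TRUE
  }
  # injection
  if (inlet_flux > 0 && density > 0) {
    if (is.null(accumulator)) accumulator <- local({ e <- new.env(); e$acc <- 0; e })
    if (is.null(accumulator$acc)) accumulator$acc <- 0
    accumulator$acc <- accumulator$acc + density * inlet_flux * dt
    n_new <- floor(accumulator$acc)
    accumulator$acc <- accumulator$acc - n_new
    if (n_new > 0) {
      rr <- inlet$radius * sqrt(runif(n_new))
      th <- runif(n_new, 0, 2 * pi)
      eps <- if (is.null(inlet$offset)) 0.05 else inlet$offset
      newpos <- cbind(inlet$center[1] + rr * cos(th),
                      inlet$center[2] + rr * sin(th),
                      inlet$z + eps)
      ens$positions <- rbind(ens$positions, newpos)
      ens$tag <- c(ens$tag, rep("atrial", n_new))
      ens$birth <- c(ens$birth, rep(t, n_new))
      ens$status <- c(ens$status, rep("active", n_new))
      ens$exit_time <- c(ens$exit_time, rep(NA_real_, n_new))
      ens$entered_lv <- c(ens$entered_lv, rep(FALSE, n_new))
    }
  }
  ens
}

#' Four-component ventricular transport decomposition
#'
#' Splits the blood handled during one cycle into: direct inflow (I, atrial
#' inflow ejected within the same cycle), retained inflow (II), delayed
#' ejection (III, cycle-start ventricular blood ejected this cycle) and
#' residual volume (IV).  Particle fractions are converted to volumes using
#' each class's reference volume: the diastolic inflow volume for the inflow
#' classes and the cycle-start LV volume for the ventricular classes.
#'
#' @param inflow_total number of inflow particles (entered the LV this cycle).
#' @param inflow_ejected number of those ejected before cycle end.
#' @param vent_total number of cycle-start ventricular particles.
#' @param vent_ejected number of those ejected this cycle.
#' @param inflow_volume diastolic inflow volume (mL; equals the stroke volume
#'   at periodic steady state).
#' @param start_volume cycle-start (end-systolic) LV volume (mL).
#' @return object of class `vf_decomposition` with volumes I-IV, the counts,
#'   and the reference volumes.
#' @export
decompose_transport <- function(inflow_total, inflow_ejected,
                                vent_total, vent_ejected,
                                inflow_volume, start_volume) {
  if (inflow_total <= 0)
    stop("undefined fraction: no inflow particles this cycle", call. = FALSE)
  if (vent_total <= 0)
    stop("undefined fraction: no cycle-start ventricular particles", call. = FALSE)
  dr <- inflow_ejected / inflow_total
  wr <- vent_ejected / vent_total
  I <- dr * inflow_volume
  II <- inflow_volume - I
  III <- wr * start_volume
  IV <- start_volume - III
  structure(list(I = I, II = II, III = III, IV = IV,
                 counts = c(inflow_total = inflow_total,
                            inflow_ejected = inflow_ejected,
                            vent_total = vent_total,
                            vent_ejected = vent_ejected),
                 inflow_volume = inflow_volume, start_volume = start_volume),
            class = "vf_decomposition")
}

#' @export
print.vf_decomposition <- function(x, ...) {
  m <- transport_metrics(x)
  cat(sprintf("<vf_decomposition> I=%.2f II=%.2f III=%.2f IV=%.2f mL | DR %.1f%% WR %.1f%% N1%% %d\n",
              x$I, x$II, x$III, x$IV, 100 * m$dr, 100 * m$wr, m$n1pct))
  invisible(x)
}

#' Transport metrics: DR, WR, RR, EF and the washout cycle count
#'
#' `DR = I/(I+II)`, `WR = III/(III+IV)`, `RR = 1 - WR`,
#' `EF = (I+III)/(I+II+III+IV)` and `N1pct = -2/log10(RR)`, the number of
#' cycles needed to flush the cycle-start ventricular blood down to 1%
#' (since the residual fraction after N cycles is RR^N).
#'
#' @param dec a [decompose_transport()] result, or a list with fields
#'   `I`, `II`, `III`, `IV`.
#' @return one-row data.frame: `dr`, `wr`, `rr`, `ef` (fractions),
#'   `n1pct_real` and `n1pct` (rounded to the nearest integer cycle count).
#' @export
transport_metrics <- function(dec) {
  I <- dec$I; II <- dec$II; III <- dec$III; IV <- dec$IV
  if (any(c(I, II, III, IV) < -1e-12)) stop("volumes must be nonnegative")
  dr <- I / (I + II)
  wr <- III / (III + IV)
  rr <- 1 - wr
  ef <- (I + III) / (I + II + III + IV)
  n1 <- if (wr >= 1) 0 else if (wr <= 0) Inf else -2 / log10(rr)
  data.frame(dr = dr, wr = wr, rr = rr, ef = ef,
             n1pct_real = n1,
             n1pct = if (is.finite(n1)) round(n1) else n1)
}
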