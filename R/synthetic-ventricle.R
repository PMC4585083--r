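#' Synthetic ventricle template specification
#'
#' Describes the lumen geometry used when no image-derived surfaces are
#' supplied: a prolate-spheroid LV cavity (long axis along z, apex at
#' negative z) with two vertical tubes standing in for the left atrium
#' (inflow) and the aorta (outflow).  Tube ends are capped a little above
#' `tube_length` so the generated surface is closed; in a flow run the caps
#' sit at or beyond the top of the computational box, whose tube
#' cross-sections act as the open ends.
#'
#' @param lv_semi_axes numeric length-3, ellipsoid semi-axes (a, b, c) in cm;
#'   c is the long (z) semi-axis.
#' @param inlet,outlet lists with `center` (x, y on the basal plane), `radius`
#'   (cm) and `length` (cm, tube extent above the basal plane).
#' @param basal_fraction height of the basal plane as a fraction of c
#'   (the tubes attach above this plane; the cavity is measured below it).
#' @param mesh_resolution target lattice spacing for surface extraction (cm).
#' @return object of class `vf_template_spec`.
#' @export
ventricle_template <- function(lv_semi_axes = c(1.7, 1.7, 3.1),
                               inlet = list(center = c(-0.9, 0), radius = 0.85,
                                            length = 2.0),
                               outlet = list(center = c(0.9, 0), radius = 0.8,
                                             length = 2.0),
                               basal_fraction = 0.45,
                               mesh_resolution = 0.12) {
  if (any(lv_semi_axes <= 0)) stop("semi-axes must be positive", call. = FALSE)
  for (tube in list(inlet, outlet)) {
    if (tube$radius <= 0)
      stop("geometry error: tube radius must be positive", call. = FALSE)
    if (tube$length <= 0)
      stop("geometry error: tube length must be positive", call. = FALSE)
  }
  gap <- sqrt(sum((inlet$center - outlet$center)^2))
  if (gap <= inlet$radius + outlet$radius)
    stop("geometry error: inlet and outlet openings overlap", call. = FALSE)
  if (mesh_resolution >= min(inlet$radius, outlet$radius))
    stop("resolution error: mesh_resolution must resolve the tube radii",
         call. = FALSE)
  structure(list(lv_semi_axes = lv_semi_axes, inlet = inlet, outlet = outlet,
                 basal_fraction = basal_fraction,
                 mesh_resolution = mesh_resolution),
            class = "vf_template_spec")
}

template_implicit <- function(spec) {
  ax <- spec$lv_semi_axes
  zb <- spec$basal_fraction * ax[3]
  ztop_in <- zb + spec$inlet$length
  ztop_out <- zb + spec$outlet$length
  fil <- 0.3                 # fillet radius (cm) rounding surface creases
  smax <- function(a, b) {   # smooth intersection (filleted concave crease)
    hh <- pmax(fil - abs(a - b), 0)
    pmax(a, b) + hh * hh / (4 * fil)
  }
  smin <- function(a, b) {   # smooth union
    hh <- pmax(fil - abs(a - b), 0)
    pmin(a, b) - hh * hh / (4 * fil)
  }
  force(spec)
  function(x, y, z) {
    # LV cavity: ellipsoid cut (with a fillet) at the basal plane z = zb
    ell <- sqrt((x / ax[1])^2 + (y / ax[2])^2 + (z / ax[3])^2) - 1
    lv <- smax(ell * min(ax), z - zb)
    cyl <- function(tube, ztop) {
      r <- sqrt((x - tube$center[1])^2 + (y - tube$center[2])^2) - tube$radius
      # capped cylinder rising from inside the cavity so the union is a
      # single connected lumen with two basal openings
      pmax(r, z - ztop, -z)
    }
    smin(lv, smin(cyl(spec$inlet, ztop_in), cyl(spec$outlet, ztop_out)))
  }
}

#' Build the template lumen surface
#'
#' Extracts a watertight triangulated surface of the implicit union
#' (ellipsoid + two capped tubes) by marching tetrahedra on a uniform lattice
#' at the spec's `mesh_resolution`, then (optionally) rescales the cavity so
#' its volume below the basal plane matches `target_cavity_volume`.
#'
#' @param spec a [ventricle_template()].
#' @param target_cavity_volume cavity volume (mL) below the basal plane to
#'   calibrate to via [deform_to_volume()]; NULL for no calibration.
#' @return a [vf_mesh()] with attributes `basal_z` (basal plane height) and
#'   `spec`.
#' @export
build_template <- function(spec, target_cavity_volume = NULL) {
  stopifnot(inherits(spec, "vf_template_spec"))
  ax <- spec$lv_semi_axes
  h <- spec$mesh_resolution
  zb <- spec$basal_fraction * ax[3]
  ztop <- zb + max(spec$inlet$length, spec$outlet$length)
  pad <- 3 * h
  xs <- seq(-ax[1] - pad, ax[1] + pad, by = h)
  ys <- seq(-ax[2] - pad, ax[2] + pad, by = h)
  zs <- seq(-ax[3] - pad, ztop + pad, by = h)
  phi <- template_implicit(spec)
  g <- expand.grid(x = xs, y = ys, z = zs)
  f <- phi(g$x, g$y, g$z)
  iso <- mt_isosurface(f, xs, ys, zs, 0)
  mesh <- weld_mesh(vf_mesh(iso$vertices, iso$triangles))
  if (!mesh_is_watertight(mesh))
    stop("topology error: extracted surface is not watertight", call. = FALSE)
  if (enclosed_volume(mesh, check = FALSE) < 0)
    mesh$triangles <- mesh$triangles[, c(1, 3, 2)]
  attr(mesh, "basal_z") <- zb
  attr(mesh, "spec") <- spec
  if (!is.null(target_cavity_volume))
    mesh <- deform_to_volume(mesh, target_cavity_volume)
  mesh
}

#' Cavity volume below the basal plane
#'
#' Divergence-theorem volume of the lumen region below `z = basal_z`, exact
#' for the polyhedral surface: each triangle is clipped to the half-space and
#' the flux of (0, 0, z - basal_z) is integrated over the clipped polygon.
#'
#' @param mesh a watertight [vf_mesh()].
#' @param basal_z basal plane height; defaults to the mesh's `basal_z`
#'   attribute.
#' @return cavity volume in mL.
#' @export
cavity_volume <- function(mesh, basal_z = attr(mesh, "basal_z")) {
  if (is.null(basal_z)) stop("basal_z not supplied and not stored on mesh")
  V <- mesh$vertices; T3 <- mesh$triangles
  z <- V[, 3] - basal_z
  total <- 0
  for (t in seq_len(nrow(T3))) {
    id <- T3[t, ]
    zz <- z[id]
    if (all(zz >= 0)) next
    P <- V[id, , drop = FALSE]
    if (any(zz > 0)) {
      # clip triangle to z <= basal_z
      poly <- matrix(0, 0, 3)
      for (i in 1:3) {
        j <- i %% 3 + 1
        if (zz[i] <= 0) poly <- rbind(poly, P[i, ])
        if ((zz[i] < 0) != (zz[j] < 0)) {
          s <- zz[i] / (zz[i] - zz[j])
          poly <- rbind(poly, P[i, ] + s * (P[j, ] - P[i, ]))
        }
      }
    } else poly <- P
    if (nrow(poly) < 3) next
    # area vector and centroid of the planar polygon (fan about vertex 1)
    av <- c(0, 0, 0); cz <- 0; asum <- 0
    for (i in 2:(nrow(poly) - 1)) {
      e1 <- poly[i, ] - poly[1, ]; e2 <- poly[i + 1, ] - poly[1, ]
      cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
              e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1]) / 2
      av <- av + cr
      a <- sqrt(sum(cr^2))
      cz <- cz + a * (poly[1, 3] + poly[i, 3] + poly[i + 1, 3]) / 3
      asum <- asum + a
    }
    if (asum == 0) next
    zc <- cz / asum - basal_z
    total <- total + zc * av[3]
  }
  total
}

smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

#' Deform the cavity to a target volume
#'
#' Applies a smooth, apex-weighted radial scaling about the basal centre:
#' vertices at or above the basal plane (the tube regions) are held fixed,
#' vertices below it scale with a C1 blend that reaches full scale one blend
#' length below the plane.  The scale factor is found by 1-D root finding so
#' the enclosed volume matches the target to relative tolerance `tol`.
#'
#' @param mesh template [vf_mesh()] with a `basal_z` attribute.
#' @param target_cavity target cavity volume (mL, below the basal plane).
#' @param blend blend length (cm) over which the scaling fades out below the
#'   basal plane; default 25% of the apex depth.
#' @param tol relative volume tolerance for the root find.
#' @param bounds search interval for the scale factor.
#' @return deformed [vf_mesh()] (connectivity unchanged).
#' @export
deform_to_volume <- function(mesh, target_cavity, blend = NULL, tol = 1e-9,
                             bounds = c(0.2, 3.5)) {
  if (target_cavity <= 0) stop("target volume must be positive", call. = FALSE)
  zb <- attr(mesh, "basal_z")
  if (is.null(zb)) stop("mesh has no basal_z attribute")
  apex <- min(mesh$vertices[, 3])
  if (is.null(blend)) blend <- 0.25 * (zb - apex)
  w <- smoothstep((zb - mesh$vertices[, 3]) / blend)
  pivot <- c(0, 0, zb)
  fixed_above <- enclosed_volume(mesh, check = FALSE) -
    cavity_volume(mesh, zb)
  target_total <- target_cavity + fixed_above
  apply_scale <- function(s) {
    seff <- 1 + (s - 1) * w
    v <- sweep(mesh$vertices, 2, pivot)
    v <- v * seff
    sweep(v, 2, pivot, "+")
  }
  volume_at <- function(s) {
    m2 <- mesh; m2$vertices <- apply_scale(s)
    enclosed_volume(m2, check = FALSE) - target_total
  }
  f_lo <- volume_at(bounds[1]); f_hi <- volume_at(bounds[2])
  if (f_lo * f_hi > 0)
    stop("convergence error: target volume unreachable within scale bounds",
         call. = FALSE)
  root <- stats::uniroot(volume_at, bounds, tol = .Machine$double.eps^0.5,
                         f.lower = f_lo, f.upper = f_hi)
  # polish with a secant step on relative volume
  s <- root$root
  out <- mesh
  out$vertices <- apply_scale(s)
  rel <- (enclosed_volume(out, check = FALSE) - target_total) / target_total
  if (abs(rel) > tol) {
    root <- stats::uniroot(volume_at, c(s * 0.999, s * 1.001),
                           tol = .Machine$double.eps, extendInt = "yes")
    out$vertices <- apply_scale(root$root)
  }
  out
}

#' Cavity volume waveform over one cardiac cycle
#'
#' Builds a C1 periodic volume history V(t) with the cycle starting at
#' diastole onset (V(0) = ESV): biphasic filling (E wave then A wave, raised-
#' cosine rate bumps) over the diastolic fraction of the period, followed by a
#' single smooth emptying bump during systole.
#'
#' @param edv,esv end-diastolic / end-systolic volume (mL); `edv > esv > 0`.
#' @param period cycle duration (s); the canine models here beat at 0.5 s.
#' @param diastole_fraction fraction of the period spent filling (default
#'   0.6; the split is not fixed by the physiology emulated and is exposed
#'   here).
#' @param e_duration_fraction fraction of diastole occupied by the E wave.
#' @param ea_peak_ratio ratio of E-wave to A-wave peak filling rate.
#' @param n_samples number of stored sample times over the cycle.
#' @return object of class `vf_waveform`: sample `times`/`volumes`, closures
#'   `v_fun(t)` and `dvdt_fun(t)` valid for any real t, plus the defining
#'   parameters.
#' @export
make_volume_waveform <- function(edv, esv, period = 0.5,
                                 diastole_fraction = 0.6,
                                 e_duration_fraction = 0.55,
                                 ea_peak_ratio = 2,
                                 n_samples = 128) {
  if (!(edv > esv && esv > 0)) stop("parameter error: need EDV > ESV > 0",
                                    call. = FALSE)
  if (period <= 0) stop("parameter error: period must be positive", call. = FALSE)
  if (diastole_fraction <= 0 || diastole_fraction >= 1)
    stop("parameter error: diastole_fraction in (0,1)", call. = FALSE)
  sv <- edv - esv
  td <- diastole_fraction * period
  ts <- period - td
  de <- e_duration_fraction * td      # E-wave duration
  da <- td - de                        # A-wave duration
  # raised-cosine bump on [0, d] with unit volume has peak rate 2/d;
  # choose E/A volumes so peak-rate ratio equals ea_peak_ratio
  volA <- sv / (1 + ea_peak_ratio * de / da)
  volE <- sv - volA
  bump_int <- function(u) ifelse(u <= 0, 0, ifelse(u >= 1, 1,
                                                   u - sin(2 * pi * u) / (2 * pi)))
  bump_rate <- function(u) ifelse(u <= 0 | u >= 1, 0, (1 - cos(2 * pi * u)))
  v_fun <- function(t) {
    t <- t %% period
    esv + volE * bump_int(t / de) +
      volA * bump_int((t - de) / da) -
      sv * bump_int((t - td) / ts)
  }
  dvdt_fun <- function(t) {
    t <- t %% period
    volE / de * bump_rate(t / de) +
      volA / da * bump_rate((t - de) / da) -
      sv / ts * bump_rate((t - td) / ts)
  }
  times <- seq(0, period, length.out = n_samples + 1)[seq_len(n_samples)]
  structure(list(times = times, volumes = v_fun(times),
                 v_fun = v_fun, dvdt_fun = dvdt_fun,
                 edv = edv, esv = esv, period = period,
                 diastole_fraction = diastole_fraction,
                 e_duration_fraction = e_duration_fraction,
                 ea_peak_ratio = ea_peak_ratio),
            class = "vf_waveform")
}

#' @export
print.vf_waveform <- function(x, ...) {
  cat(sprintf("<vf_waveform> EDV %.1f mL, ESV %.1f mL, SV %.1f mL, EF %.1f%%, T = %g s\n",
              x$edv, x$esv, x$edv - x$esv, 100 * (x$edv - x$esv) / x$edv,
              x$period))
  invisible(x)
}

#' Summary metrics of a volume waveform
#' @param x a `vf_waveform`.
#' @param ... unused.
#' @return one-row data.frame with EDV, ESV, SV (mL) and EF (%).
#' @export
waveform_metrics <- function(x, ...) {
  data.frame(edv_ml = x$edv, esv_ml = x$esv, sv_ml = x$edv - x$esv,
             ef_pct = 100 * (x$edv - x$esv) / x$edv)
}

#' Conformal surface kinematics
#'
#' A time sequence of vertex coordinate frames sharing one triangle
#' connectivity ("conformal"), with key-frame times inside one period.
#'
#' @param frames list of vertex matrices (same dimensions).
#' @param triangles shared triangle connectivity.
#' @param times key-frame times (s), strictly increasing in `[0, period)`.
#' @param period cycle period (s).
#' @param basal_z optional basal plane height carried through to analyses.
#' @return object of class `vf_kinematics`.
#' @export
surface_kinematics <- function(frames, triangles, times, period,
                               basal_z = NULL) {
  if (length(frames) < 3L)
    stop("insufficient data: need at least 3 key frames", call. = FALSE)
  if (length(times) != length(frames)) stop("times/frames length mismatch")
  if (any(diff(times) <= 0) || times[1] < 0 || times[length(times)] >= period)
    stop("frame times must be strictly increasing within [0, period)")
  dims <- dim(frames[[1]])
  for (f in frames) if (!identical(dim(f), dims))
    stop("conformality error: frame vertex arrays differ in shape")
  storage.mode(triangles) <- "integer"
  obj <- list(frames = lapply(frames, function(f) {
    f <- as.matrix(f); storage.mode(f) <- "double"; f
  }), triangles = triangles, times = as.numeric(times),
  period = as.numeric(period), basal_z = basal_z)
  obj$spline_cache <- new.env(parent = emptyenv())
  structure(obj, class = "vf_kinematics")
}

#' @export
print.vf_kinematics <- function(x, ...) {
  cat(sprintf("<vf_kinematics> %d frames, %d vertices, period %g s\n",
              length(x$frames), nrow(x$frames[[1]]), x$period))
  invisible(x)
}

# periodic cubic-spline second derivatives for all vertex coordinates at once
kinematics_spline <- function(kin) {
  cache <- kin$spline_cache
  if (!is.null(cache$M)) return(cache)
  n <- length(kin$times)
  tt <- kin$times
  h <- diff(c(tt, tt[1] + kin$period))
  Y <- do.call(cbind, lapply(kin$frames, as.numeric)) # (3nv) x n
  Y <- t(Y)                                           # n x (3nv)
  A <- matrix(0, n, n)
  D <- matrix(0, n, ncol(Y))
  for (i in seq_len(n)) {
    im <- if (i == 1) n else i - 1
    ip <- if (i == n) 1 else i + 1
    A[i, im] <- A[i, im] + h[im] / 6
    A[i, i] <- A[i, i] + (h[im] + h[i]) / 3
    A[i, ip] <- A[i, ip] + h[i] / 6
    D[i, ] <- (Y[ip, ] - Y[i, ]) / h[i] - (Y[i, ] - Y[im, ]) / h[im]
  }
  M <- solve(A, D)
  cache$M <- M; cache$Y <- Y; cache$h <- h
  cache
}

#' Interpolate surface position and wall velocity in time
#'
#' Periodic cubic-spline interpolation of every vertex coordinate over the
#' key frames; the wall velocity is the analytic derivative of the spline.
#' At key-frame times the positions equal the stored frames exactly.
#'
#' @param kin a [surface_kinematics()].
#' @param t time (s), any real value (wrapped modulo the period).
#' @return list with `vertices` (positions, cm) and `velocities` (cm/s).
#' @export
interpolate_kinematics <- function(kin, t) {
  stopifnot(inherits(kin, "vf_kinematics"))
  sp <- kinematics_spline(kin)
  n <- length(kin$times)
  tt <- kin$times
  tw <- t %% kin$period
  # interval index: last knot <= tw (knot n wraps to period + t1)
  i <- findInterval(tw, tt)
  if (i == 0L) { i <- n; tw <- tw + kin$period }
  ip <- if (i == n) 1 else i + 1
  h <- sp$h[i]
  t0 <- if (i == n && tw >= tt[n]) tt[n] else tt[i]
  s <- tw - t0
  a <- (h - s) / h; b <- s / h
  y0 <- sp$Y[i, ]; y1 <- sp$Y[ip, ]
  m0 <- sp$M[i, ]; m1 <- sp$M[ip, ]
  pos <- a * y0 + b * y1 +
    ((a^3 - a) * m0 + (b^3 - b) * m1) * h^2 / 6
  vel <- (y1 - y0) / h +
    ((3 * b^2 - 1) * m1 - (3 * a^2 - 1) * m0) * h / 6
  nv <- nrow(kin$frames[[1]])
  list(vertices = matrix(pos, nv, 3), velocities = matrix(vel, nv, 3))
}

#' Generate moving-ventricle kinematics from a template and a waveform
#'
#' Deforms the template to the waveform's cavity volume at `n_frames` evenly
#' spaced key times, producing a conformal surface sequence (the synthetic
#' stand-in for an image-based electromechanical deformation source).
#'
#' @param template template mesh from [build_template()].
#' @param waveform a [make_volume_waveform()] result.
#' @param n_frames number of key frames over the cycle.
#' @return a [surface_kinematics()] object.
#' @export
ventricle_kinematics <- function(template, waveform, n_frames = 16) {
  stopifnot(inherits(waveform, "vf_waveform"))
  times <- seq(0, waveform$period, length.out = n_frames + 1)[seq_len(n_frames)]
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    m <- deform_to_volume(template, waveform$v_fun(times[i]))
    frames[[i]] <- m$vertices
  }
  surface_kinematics(frames, template$triangles, times, waveform$period,
                     basal_z = attr(template, "basal_z"))
}
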