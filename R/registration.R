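#' Registration configuration
#'
#' Controls for the greedy kernel diffeomorphic surface matcher: the
#' deformation-kernel width sets the smoothness scale of the vertex velocity
#' field (default 20% of the template's longest bounding-box axis), the
#' matching-kernel width sets the spatial sensitivity of the currents metric
#' (default 5 mean edge lengths); both in cm.
#'
#' @param sigma_v deformation-kernel width (cm); NULL = auto from template.
#' @param sigma_w matching-kernel width (cm); NULL = auto from template.
#' @param step initial step size of the greedy flow.
#' @param max_iter maximum number of flow steps.
#' @param tol stop when the relative energy decrease falls below this.
#' @param max_halvings step halvings allowed after an energy increase.
#' @return object of class `vf_reg_config`.
#' @export
registration_config <- function(sigma_v = NULL, sigma_w = NULL, step = 0.1,
                                max_iter = 80, tol = 1e-4, max_halvings = 12) {
  if (!is.null(sigma_v) && sigma_v <= 0) stop("sigma_v must be positive")
  if (!is.null(sigma_w) && sigma_w <= 0) stop("sigma_w must be positive")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(sigma_v = sigma_v, sigma_w = sigma_w, step = step,
                 max_iter = max_iter, tol = tol, max_halvings = max_halvings),
            class = "vf_reg_config")
}

reg_auto_widths <- function(mesh, cfg) {
  if (is.null(cfg$sigma_v)) {
    ext <- apply(mesh$vertices, 2, function(x) diff(range(x)))
    cfg$sigma_v <- 0.2 * max(ext)
  }
  if (is.null(cfg$sigma_w)) {
    T3 <- mesh$triangles; V <- mesh$vertices
    e <- sqrt(rowSums((V[T3[, 1], ] - V[T3[, 2], ])^2))
    cfg$sigma_w <- 5 * mean(e)
  }
  cfg
}

#' Currents matching energy between two oriented surfaces
#'
#' Squared currents distance on area-weighted triangle normals at centroids
#' with a Gaussian kernel: zero iff the two surfaces carry the same current,
#' symmetric, and nonnegative up to round-off.  Degenerate (zero-area)
#' triangles contribute nothing.
#'
#' @param s,t [vf_mesh()] surfaces.
#' @param sigma_w Gaussian kernel width (cm).
#' @return nonnegative scalar.
#' @export
currents_energy <- function(s, t, sigma_w) {
  a <- mesh_face_geometry(s)$areas
  if (any(a == 0)) warning("degenerate zero-area triangles in first surface")
  currents_energy_cpp(s$vertices, s$triangles, t$vertices, t$triangles,
                      sigma_w)
}

#' Greedy kernel diffeomorphic registration
#'
#' Flows the template vertices down the kernel-smoothed gradient of the
#' currents energy towards the target: at each step the momenta are
#' `m = -step * (K_V * grad E)` and the vertices move by `m`.  Steps that
#' increase the energy are retried with a halved step; the energy trace is
#' therefore non-increasing on every accepted step.  Because each update is a
#' smooth kernel velocity field, small steps preserve orientation (no
#' triangle inversions): the diffeomorphism proxy is audited on the result.
#'
#' @param template,target [vf_mesh()] surfaces in a shared coordinate frame
#'   (pre-aligned).
#' @param cfg a [registration_config()].
#' @return object of class `vf_registration`: `mapped` mesh, `energy_trace`,
#'   `final_energy`, `hausdorff` (to target), `inverted` (triangle flips),
#'   `momenta` (last step), `converged`.
#' @export
greedy_lddmm <- function(template, target, cfg = registration_config()) {
  cfg <- reg_auto_widths(template, cfg)
  q <- template$vertices
  T3 <- template$triangles
  e <- currents_energy_cpp(q, T3, target$vertices, target$triangles,
                           cfg$sigma_w)
  trace <- e
  step <- cfg$step
  momenta <- NULL
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    g <- currents_gradient_cpp(q, T3, target$vertices, target$triangles,
                               cfg$sigma_w)
    vel <- kernel_smooth_cpp(q, g, cfg$sigma_v)
    # normalise so `step` has the meaning of a displacement fraction
    vmax <- max(abs(vel))
    if (vmax < 1e-14) { converged <- TRUE; break }
    ok <- FALSE
    s <- step
    for (h in seq_len(cfg$max_halvings)) {
      m <- -s * vel
      qn <- q + m
      en <- currents_energy_cpp(qn, T3, target$vertices, target$triangles,
                                cfg$sigma_w)
      if (en <= e) { ok <- TRUE; break }
      s <- s / 2
    }
    if (!ok) {
      # a step that cannot decrease the energy any further is natural
      # termination when the match is already good; only a stall at high
      # energy is a convergence failure
      converged <- e < 0.1 * trace[1]
      if (!converged)
        warning(sprintf("convergence failure at iteration %d: energy would not decrease", it))
      break
    }
    momenta <- m
    rel_dec <- (e - en) / max(abs(e), 1e-300)
    q <- qn; e <- en
    trace <- c(trace, e)
    step <- min(s * 1.5, cfg$step)  # gentle step recovery
    if (rel_dec < cfg$tol) { converged <- TRUE; break }
  }
  mapped <- template
  mapped$vertices <- q
  # diffeomorphism proxy: orientation flips against the original normals
  n0 <- mesh_face_geometry(template)$normals
  n1 <- mesh_face_geometry(mapped)$normals
  inverted <- sum(rowSums(n0 * n1) < 0)
  # symmetric Hausdorff estimate on vertex samples
  d1 <- point_mesh_query(q, target$vertices, target$triangles)$distance
  d2 <- point_mesh_query(target$vertices, q, T3)$distance
  structure(list(mapped = mapped, energy_trace = trace, final_energy = e,
                 hausdorff = max(max(d1), max(d2)), inverted = inverted,
                 momenta = momenta, converged = converged, config = cfg),
            class = "vf_registration")
}

#' @export
print.vf_registration <- function(x, ...) {
  cat(sprintf("<vf_registration> %d iterations, energy %.3g -> %.3g, Hausdorff %.3g, %d inverted\n",
              length(x$energy_trace) - 1, x$energy_trace[1], x$final_energy,
              x$hausdorff, x$inverted))
  invisible(x)
}

#' Register a template to every frame of a target sequence
#'
#' Runs [greedy_lddmm()] once per target frame, warm-starting each
#' registration from the previous frame's mapped vertices (the frames of a
#' cardiac cycle are temporally coherent).  The output shares the template
#' connectivity across all frames, i.e. it satisfies the conformal-sequence
#' contract consumed by [interpolate_kinematics()].
#'
#' @param template a [vf_mesh()].
#' @param targets list of [vf_mesh()] frames.
#' @param times frame times (s), strictly increasing within the period.
#' @param period cycle period (s).
#' @param cfg a [registration_config()].
#' @return a [surface_kinematics()]; attribute `registrations` keeps the
#'   per-frame results.
#' @export
map_sequence <- function(template, targets, times, period,
                         cfg = registration_config()) {
  if (length(targets) < 3L) stop("need at least 3 target frames")
  cur <- template
  frames <- vector("list", length(targets))
  regs <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    r <- greedy_lddmm(cur, targets[[i]], cfg)
    if (!r$converged && length(r$energy_trace) <= 1)
      stop(sprintf("sequence error: frame %d failed to converge", i),
           call. = FALSE)
    frames[[i]] <- r$mapped$vertices
    regs[[i]] <- r
    cur <- r$mapped
  }
  kin <- surface_kinematics(frames, template$triangles, times, period,
                            basal_z = attr(template, "basal_z"))
  attr(kin, "registrations") <- regs
  kin
}

#' Subdivide quad faces into triangles
#'
#' Splits every quadrilateral face into an `n x n` structured grid of
#' sub-quads (bilinear interpolation of the corners) and cuts each sub-quad
#' along its shorter diagonal (ties broken deterministically towards the
#' first-corner diagonal), giving `2 n^2` triangles per quad; `n = 5` yields
#' the fifty-triangle split used for hexahedral-face surfaces.  Vertices on
#' shared edges coincide exactly, so watertightness is preserved.
#'
#' @param quadmesh a `vf_quadmesh` (from [read_surface()] on a quad OBJ) or
#'   a list with `vertices` and `quads`.
#' @param n subdivision level per edge.
#' @return a [vf_mesh()].
#' @export
subdivide_quads <- function(quadmesh, n = 5) {
  if (is.null(quadmesh$quads))
    stop("format error: input has no quad faces", call. = FALSE)
  V <- quadmesh$vertices
  Q <- quadmesh$quads
  key_env <- new.env(hash = TRUE)
  verts <- list()
  nverts <- 0L
  get_vertex <- function(p) {
    key <- paste(sprintf("%.12g", p), collapse = ",")
    id <- key_env[[key]]
    if (!is.null(id)) return(id)
    nverts <<- nverts + 1L
    verts[[nverts]] <<- p
    assign(key, nverts, envir = key_env)
    nverts
  }
  tris <- vector("list", nrow(Q))
  for (f in seq_len(nrow(Q))) {
    corners <- V[Q[f, ], , drop = FALSE]
    # bilinear lattice of (n+1)^2 points
    ids <- matrix(0L, n + 1, n + 1)
    for (a in 0:n) for (b in 0:n) {
      u <- a / n; w <- b / n
      p <- (1 - u) * (1 - w) * corners[1, ] + u * (1 - w) * corners[2, ] +
        u * w * corners[3, ] + (1 - u) * w * corners[4, ]
      ids[a + 1, b + 1] <- get_vertex(p)
    }
    ft <- matrix(0L, 2 * n * n, 3)
    r <- 0L
    for (a in 1:n) for (b in 1:n) {
      i00 <- ids[a, b]; i10 <- ids[a + 1, b]
      i11 <- ids[a + 1, b + 1]; i01 <- ids[a, b + 1]
      p00 <- verts[[i00]]; p10 <- verts[[i10]]
      p11 <- verts[[i11]]; p01 <- verts[[i01]]
      d1 <- sum((p00 - p11)^2); d2 <- sum((p10 - p01)^2)
      if (d1 <= d2) {
        ft[r + 1L, ] <- c(i00, i10, i11)
        ft[r + 2L, ] <- c(i00, i11, i01)
      } else {
        ft[r + 1L, ] <- c(i00, i10, i01)
        ft[r + 2L, ] <- c(i10, i11, i01)
      }
      r <- r + 2L
    }
    tris[[f]] <- ft
  }
  vf_mesh(do.call(rbind, verts), do.call(rbind, tris))
}
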