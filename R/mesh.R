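#' Triangulated surface mesh
#'
#' Lightweight container for a triangulated surface: an `n x 3` matrix of
#' vertex coordinates (cm) and an `m x 3` integer matrix of 1-based vertex
#' indices.  All surface machinery in the package (enclosed volume, grid
#' classification, registration) operates on this class.
#'
#' @param vertices numeric matrix, one row per vertex (cm).
#' @param triangles integer matrix, one row per triangle, 1-based indices.
#' @return An object of class `vf_mesh`.
#' @export
vf_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(triangles) != 3L) stop("triangles must have 3 columns")
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles),
            class = "vf_mesh")
}

#' @export
print.vf_mesh <- function(x, ...) {
  cat(sprintf("<vf_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Enclosed volume and surface area of a closed mesh
#'
#' Signed volume by the divergence theorem; positive when triangle normals
#' point outward.  The surface must be watertight for the volume to be
#' meaningful; use [mesh_is_watertight()] to audit.
#'
#' @param mesh a [vf_mesh()].
#' @param check audit watertightness first (default TRUE).
#' @return Volume in the cube of the coordinate unit (cm^3 == mL).
#' @export
enclosed_volume <- function(mesh, check = TRUE) {
  if (check && !mesh_is_watertight(mesh))
    stop("surface is not watertight; enclosed volume undefined", call. = FALSE)
  unname(mesh_volume_area(mesh$vertices, mesh$triangles)[["volume"]])
}

#' @rdname enclosed_volume
#' @export
surface_area <- function(mesh) {
  unname(mesh_volume_area(mesh$vertices, mesh$triangles)[["area"]])
}

#' Watertightness audit
#'
#' A closed orientable triangulated surface has every undirected edge shared
#' by exactly two triangles, traversed once in each direction.
#'
#' @param mesh a [vf_mesh()].
#' @return TRUE if every edge is shared by exactly two consistently oriented
#'   triangles.
#' @export
mesh_is_watertight <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0L) return(FALSE)
  he <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  a <- pmin(he[, 1], he[, 2]); b <- pmax(he[, 1], he[, 2])
  key <- paste(a, b)
  cnt <- table(key)
  if (any(cnt != 2L)) return(FALSE)
  # orientation: each undirected edge must appear once in each direction
  dirkey <- paste(he[, 1], he[, 2])
  !any(duplicated(dirkey))
}

#' Per-triangle unit normals, areas and centroids
#' @param mesh a [vf_mesh()].
#' @return list with `normals`, `areas`, `centroids`.
#' @export
mesh_face_geometry <- function(mesh) {
  V <- mesh$vertices; T3 <- mesh$triangles
  a <- V[T3[, 1], , drop = FALSE]
  b <- V[T3[, 2], , drop = FALSE]
  c <- V[T3[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  areas <- len / 2
  unit <- n / ifelse(len > 0, len, 1)
  list(normals = unit, areas = areas, centroids = (a + b + c) / 3)
}

#' Weld coincident vertices and drop degenerate triangles
#'
#' Merges vertices with identical coordinates (as produced when an extracted
#' isosurface crosses exactly through shared lattice features), remaps the
#' triangle indices, and removes triangles left with fewer than three
#' distinct vertices.  Restores watertightness after sliver collapse.
#'
#' @param mesh a [vf_mesh()].
#' @return cleaned [vf_mesh()].
#' @export
weld_mesh <- function(mesh) {
  V <- mesh$vertices
  key <- paste(V[, 1], V[, 2], V[, 3])
  map <- match(key, key)           # first occurrence of each position
  keep <- !duplicated(key)
  newid <- cumsum(keep)
  remap <- newid[map]
  T3 <- matrix(remap[mesh$triangles], ncol = 3)
  good <- T3[, 1] != T3[, 2] & T3[, 2] != T3[, 3] & T3[, 1] != T3[, 3]
  T3 <- T3[good, , drop = FALSE]
  V2 <- V[keep, , drop = FALSE]
  used <- sort(unique(as.vector(T3)))
  lookup <- integer(nrow(V2)); lookup[used] <- seq_along(used)
  vf_mesh(V2[used, , drop = FALSE], matrix(lookup[T3], ncol = 3))
}

#' Icosphere test surface
#'
#' Subdivided icosahedron projected to a sphere; a standard analytic fixture
#' for volume, classification and registration checks.
#'
#' @param radius sphere radius (cm).
#' @param subdivisions number of 4-to-1 subdivision passes.
#' @param center sphere centre.
#' @return a [vf_mesh()] with outward normals.
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_id <- new.env(hash = TRUE)
    mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edge_id[[key]]
      if (!is.null(id)) return(id)
      v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
      id <- nrow(v)
      assign(key, id, envir = edge_id)
      id
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- mid(a, b); bc <- mid(b, c); ca <- mid(c, a)
      nf[4 * t - 3, ] <- c(a, ab, ca)
      nf[4 * t - 2, ] <- c(b, bc, ab)
      nf[4 * t - 1, ] <- c(c, ca, bc)
      nf[4 * t,     ] <- c(ab, bc, ca)
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, "+")
  m <- vf_mesh(v, f)
  if (enclosed_volume(m, check = FALSE) < 0) m$triangles <- m$triangles[, c(1, 3, 2)]
  m
}
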