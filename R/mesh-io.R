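#' Read a triangulated (or quad-faced) surface file
#'
#' Supports ASCII STL, OBJ (triangle and quad faces) and ASCII PLY.  OBJ quad
#' faces are kept as a `quads` attribute so [subdivide_quads()] can consume
#' them; all other paths return pure triangle meshes.
#'
#' @param path file path; format inferred from the extension.
#' @param format override `"stl"`, `"obj"` or `"ply"`.
#' @return a [vf_mesh()]; quad-faced OBJ input yields a list with `vertices`
#'   and `quads` of class `vf_quadmesh`.
#' @export
read_surface <- function(path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
         stl = read_stl_ascii(path),
         obj = read_obj(path),
         ply = read_ply_ascii(path),
         stop("unsupported surface format: ", format))
}

#' Write a surface file
#' @param mesh a [vf_mesh()].
#' @param path output path; format from extension unless given.
#' @param format `"stl"`, `"obj"` or `"ply"`.
#' @export
write_surface <- function(mesh, path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
         stl = write_stl_ascii(mesh, path),
         obj = write_obj(mesh, path),
         ply = write_ply_ascii(mesh, path),
         stop("unsupported surface format: ", format))
  invisible(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("not a valid ASCII STL file: ", path)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  nv <- nrow(nums)
  # weld duplicated vertices (STL stores them per facet)
  key <- apply(nums, 1, function(r) paste(sprintf("%.9g", r), collapse = " "))
  ids <- match(key, unique(key))
  verts <- nums[!duplicated(key), , drop = FALSE]
  tris <- matrix(ids, ncol = 3, byrow = TRUE)
  vf_mesh(verts, tris)
}

write_stl_ascii <- function(mesh, path) {
  geo <- mesh_face_geometry(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid ventriflow", con)
  V <- mesh$vertices; T3 <- mesh$triangles
  for (t in seq_len(nrow(T3))) {
    n <- geo$normals[t, ]
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]), con)
    writeLines("    outer loop", con)
    for (c in 1:3) {
      v <- V[T3[t, c], ]
      writeLines(sprintf("      vertex %.17g %.17g %.17g", v[1], v[2], v[3]), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid ventriflow", con)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- strsplit(trimws(grep("^v\\s", lines, value = TRUE)), "\\s+")
  verts <- do.call(rbind, lapply(vl, function(p) as.numeric(p[2:4])))
  fl <- strsplit(trimws(grep("^f\\s", lines, value = TRUE)), "\\s+")
  idx <- lapply(fl, function(p) as.integer(sub("/.*$", "", p[-1])))
  sizes <- lengths(idx)
  if (all(sizes == 3L)) {
    vf_mesh(verts, do.call(rbind, idx))
  } else if (all(sizes == 4L)) {
    structure(list(vertices = verts, quads = do.call(rbind, idx)),
              class = "vf_quadmesh")
  } else if (all(sizes %in% c(3L, 4L))) {
    # mixed: fan-triangulate quads
    tris <- lapply(idx, function(p)
      if (length(p) == 3L) matrix(p, 1) else rbind(p[c(1, 2, 3)], p[c(1, 3, 4)]))
    vf_mesh(verts, do.call(rbind, tris))
  } else stop("OBJ faces must be triangles or quads")
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- mesh$vertices
  writeLines(sprintf("v %.17g %.17g %.17g", V[, 1], V[, 2], V[, 3]), con)
  if (inherits(mesh, "vf_quadmesh")) {
    Q <- mesh$quads
    writeLines(sprintf("f %d %d %d %d", Q[, 1], Q[, 2], Q[, 3], Q[, 4]), con)
  } else {
    T3 <- mesh$triangles
    writeLines(sprintf("f %d %d %d", T3[, 1], T3[, 2], T3[, 3]), con)
  }
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) stop("not a PLY file: ", path)
  hend <- match("end_header", trimws(lines))
  if (is.na(hend)) stop("PLY header not terminated")
  header <- lines[seq_len(hend)]
  if (!any(grepl("format ascii", header))) stop("only ASCII PLY supported")
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", header, value = TRUE)[1]))
  body <- lines[(hend + 1):length(lines)]
  vl <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vl, function(p) as.numeric(p[1:3])))
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  tris <- do.call(rbind, lapply(fl, function(p) {
    k <- as.integer(p[1])
    if (k != 3L) stop("only triangle faces supported in PLY")
    as.integer(p[2:4]) + 1L
  }))
  vf_mesh(verts, tris)
}

write_ply_ascii <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- mesh$vertices; T3 <- mesh$triangles
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(T3)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("3 %d %d %d", T3[, 1] - 1L, T3[, 2] - 1L, T3[, 3] - 1L), con)
}

#' Write a conformal surface sequence with its manifest
#'
#' One surface file per key frame plus a YAML manifest recording frame files,
#' frame times, cycle period and length unit.
#'
#' @param kin a [surface_kinematics()] object.
#' @param dir output directory (created if needed).
#' @param name case name used as the file stem.
#' @param format surface format, default `"ply"`.
#' @return the manifest path.
#' @export
write_surface_sequence <- function(kin, dir, name = "frame", format = "ply") {
  stopifnot(inherits(kin, "vf_kinematics"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(kin$times))
  for (i in seq_along(kin$times)) {
    files[i] <- sprintf("%s_%03d.%s", name, i, format)
    m <- vf_mesh(kin$frames[[i]], kin$triangles)
    write_surface(m, file.path(dir, files[i]), format = format)
  }
  manifest <- list(period = kin$period, unit = "cm",
                   frames = lapply(seq_along(files), function(i)
                     list(file = files[i], time = kin$times[i])))
  mpath <- file.path(dir, paste0(name, "_manifest.yaml"))
  yaml::write_yaml(manifest, mpath)
  mpath
}

#' Read a surface sequence manifest into kinematics
#'
#' Loads every frame listed in the manifest, validates that the triangle
#' connectivity is bit-identical across frames (the conformality contract the
#' downstream velocity interpolation relies on), and returns kinematics.
#'
#' @param manifest path to a manifest written by [write_surface_sequence()].
#' @return a [surface_kinematics()] object.
#' @export
read_surface_sequence <- function(manifest) {
  man <- yaml::read_yaml(manifest)
  if (length(man$frames) < 3L)
    stop("surface sequence needs at least 3 frames", call. = FALSE)
  dir <- dirname(manifest)
  meshes <- lapply(man$frames, function(fr) read_surface(file.path(dir, fr$file)))
  times <- vapply(man$frames, function(fr) as.numeric(fr$time), numeric(1))
  tris <- meshes[[1]]$triangles
  for (i in seq_along(meshes)[-1]) {
    if (!identical(dim(meshes[[i]]$triangles), dim(tris)) ||
        any(meshes[[i]]$triangles != tris))
      stop(sprintf("conformality error: frame %d connectivity differs from frame 1", i),
           call. = FALSE)
  }
  surface_kinematics(lapply(meshes, `[[`, "vertices"), tris, times,
                     period = as.numeric(man$period))
}
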