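#' Write a flow state as a legacy VTK structured-points file
#'
#' ASCII legacy VTK with the velocity vector field, pressure and cell tags
#' as cell data, for inspection in ParaView or similar; the plain-text
#' alternative to the package's CSV series outputs.
#'
#' @param state a [flow_state()] holding `u`, `v`, `w`, `p`.
#' @param tags cell tags.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_vtk_state <- function(state, tags, path) {
  grid <- state$grid
  n <- grid$n
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "ventriflow flow state", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n[1], n[2], n[3]),
               sprintf("ORIGIN %.9g %.9g %.9g",
                       grid$lower[1] + grid$h / 2, grid$lower[2] + grid$h / 2,
                       grid$lower[3] + grid$h / 2),
               sprintf("SPACING %.9g %.9g %.9g", grid$h, grid$h, grid$h),
               sprintf("POINT_DATA %d", prod(n)),
               "VECTORS velocity double"), con)
  writeLines(sprintf("%.9g %.9g %.9g", state$u, state$v, state$w), con)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", state$p), con)
  writeLines(c("SCALARS tag int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", tags$tags), con)
  invisible(path)
}
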