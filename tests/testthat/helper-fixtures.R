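# shared fixtures, built once per test run and memoised
.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# coarse but watertight ventricle template (fast to build)
fixture_template <- function() memo("template", {
  spec <- ventricle_template(mesh_resolution = 0.25)
  build_template(spec)
})

fixture_template_calibrated <- function() memo("template_cal", {
  deform_to_volume(fixture_template(), 41.2)
})

fixture_waveform <- function() memo("waveform", make_volume_waveform(41.2, 23.4))

fixture_kinematics <- function() memo("kinematics", {
  ventricle_kinematics(fixture_template_calibrated(), fixture_waveform(),
                       n_frames = 8)
})

# unit cube as 12 triangles (outward normals)
fixture_cube <- function() memo("cube", {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  tr <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
              c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
              c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  m <- vf_mesh(v, tr)
  if (enclosed_volume(m, check = FALSE) < 0) m$triangles <- m$triangles[, c(1, 3, 2)]
  m
})

fixture_sphere <- function(sub = 3) memo(paste0("sphere", sub), icosphere(1, sub))
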