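test_that("degenerate template specs are rejected", {
  expect_error(ventricle_template(inlet = list(center = c(-0.9, 0), radius = 0,
                                               length = 2)),
               "geometry error")
  expect_error(ventricle_template(inlet = list(center = c(0, 0), radius = 1,
                                               length = 2),
                                  outlet = list(center = c(0.5, 0), radius = 1,
                                                length = 2)),
               "overlap")
  expect_error(ventricle_template(mesh_resolution = 2), "resolution error")
})

test_that("template is watertight and calibrates to the target cavity volume", {
  tpl <- fixture_template()
  expect_true(mesh_is_watertight(tpl))
  expect_gt(enclosed_volume(tpl, check = FALSE), 0)
  cal <- fixture_template_calibrated()
  expect_equal(cavity_volume(cal), 41.2, tolerance = 0.01)
})

test_that("paper-density template lands in the 24k-48k triangle band", {
  spec <- ventricle_template()   # default resolution is the paper-scale one
  tpl <- build_template(spec)
  expect_gte(nrow(tpl$triangles), 24000)
  expect_lte(nrow(tpl$triangles), 48000)
})

test_that("volume waveform reproduces the four reference EDV/ESV rows", {
  # EDV, ESV, SV, EF% for normal/failing hearts under both activations
  rows <- list(c(41.2, 23.4, 17.8, 43.2), c(44.1, 27.8, 16.3, 37.0),
               c(116.4, 100.2, 16.2, 13.9), c(128.1, 114.5, 13.6, 10.6))
  for (r in rows) {
    wf <- make_volume_waveform(r[1], r[2])
    m <- waveform_metrics(wf)
    expect_equal(m$sv_ml, r[3], tolerance = 1e-12)
    expect_equal(round(m$ef_pct, 1), r[4])
    tt <- seq(0, 0.5, length.out = 2001)
    v <- wf$v_fun(tt)
    expect_equal(max(v), r[1], tolerance = 1e-9)
    expect_equal(min(v), r[2], tolerance = 1e-9)
    expect_equal(wf$v_fun(0), r[2])               # cycle starts at diastole onset
    expect_equal(wf$v_fun(tt + 0.5), v, tolerance = 1e-9)  # periodic
  }
  expect_error(make_volume_waveform(20, 25), "EDV > ESV")
})

test_that("E-wave peak filling rate exceeds A-wave peak when configured", {
  wf <- make_volume_waveform(41.2, 23.4, ea_peak_ratio = 2)
  tt <- seq(0, 0.3, length.out = 3000)
  rate <- wf$dvdt_fun(tt)
  td <- 0.3; de <- 0.55 * td
  peak_e <- max(rate[tt < de]); peak_a <- max(rate[tt >= de])
  expect_gt(peak_e, peak_a)
  expect_equal(peak_e / peak_a, 2, tolerance = 0.05)
})

test_that("deform_to_volume hits targets and scales like similarity", {
  tpl <- fixture_template()
  v0 <- enclosed_volume(tpl, check = FALSE)
  cav0 <- cavity_volume(tpl)
  same <- deform_to_volume(tpl, cav0)
  expect_lt(max(abs(same$vertices - tpl$vertices)), 1e-6)
  for (tgt in c(25, 41.2)) {
    m <- deform_to_volume(tpl, tgt)
    fixed <- v0 - cav0
    expect_equal(enclosed_volume(m, check = FALSE), tgt + fixed,
                 tolerance = 1e-6 * (tgt + fixed))
    expect_identical(m$triangles, tpl$triangles)
    # tube region (above basal plane) held fixed
    zb <- attr(tpl, "basal_z")
    above <- tpl$vertices[, 3] >= zb
    expect_lt(max(abs(m$vertices[above, ] - tpl$vertices[above, ])), 1e-12)
  }
  expect_error(deform_to_volume(tpl, 1e5), "unreachable")
})

test_that("kinematics interpolation is exact at key frames and periodic", {
  kin <- fixture_kinematics()
  for (i in c(1, 4, 7)) {
    ik <- interpolate_kinematics(kin, kin$times[i])
    expect_equal(ik$vertices, kin$frames[[i]], tolerance = 1e-12)
  }
  a <- interpolate_kinematics(kin, 0.1234)
  b <- interpolate_kinematics(kin, 0.1234 + kin$period)
  expect_lt(max(abs(a$velocities - b$velocities)), 1e-8)
  expect_lt(max(abs(a$vertices - b$vertices)), 1e-10)
})

test_that("connectivity is identical across generated frames", {
  kin <- fixture_kinematics()
  expect_true(all(vapply(kin$frames, function(f)
    identical(dim(f), dim(kin$frames[[1]])), logical(1))))
  # frames reproduce the waveform volumes
  wf <- fixture_waveform()
  tpl <- fixture_template_calibrated()
  fixed <- enclosed_volume(tpl, check = FALSE) - cavity_volume(tpl)
  for (i in c(2, 5)) {
    v <- enclosed_volume(vf_mesh(kin$frames[[i]], kin$triangles),
                         check = FALSE) - fixed
    expect_equal(v, wf$v_fun(kin$times[i]), tolerance = 1e-5 * v)
  }
})

test_that("wall motion is kinematically consistent with the volume rate", {
  kin <- fixture_kinematics()
  # dV/dt by finite differences of interpolated frames vs surface integral
  # of wall velocity . outward normal
  for (t0 in c(0.07, 0.21, 0.38)) {
    eps <- 1e-4
    vm <- enclosed_volume(vf_mesh(interpolate_kinematics(kin, t0 - eps)$vertices,
                                  kin$triangles), check = FALSE)
    vp <- enclosed_volume(vf_mesh(interpolate_kinematics(kin, t0 + eps)$vertices,
                                  kin$triangles), check = FALSE)
    dvdt_fd <- (vp - vm) / (2 * eps)
    ik <- interpolate_kinematics(kin, t0)
    m <- vf_mesh(ik$vertices, kin$triangles)
    geo <- mesh_face_geometry(m)
    tri <- kin$triangles
    vface <- (ik$velocities[tri[, 1], ] + ik$velocities[tri[, 2], ] +
                ik$velocities[tri[, 3], ]) / 3
    dvdt_surf <- sum(rowSums(vface * geo$normals) * geo$areas)
    expect_equal(dvdt_surf, dvdt_fd,
                 tolerance = 0.01 * max(abs(dvdt_fd), 1))
  }
})
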