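test_that("2D channel generator reproduces the shell-core configuration", {
  scn <- make_channel_2d(h_s = 0.8, h_c = 0.6, n = c(96, 32))
  g <- scn$grid
  # clot area ~ half-disc of radius h_s, measured on the midlevel set
  # (robust to interface smearing)
  area <- sum(grid_weights(g)[scn$state0$phi < 0.5])
  expect_equal(area, pi * 0.8^2 / 2, tolerance = 0.03)
  # pure blood on inlet and outlet boundaries
  expect_true(all(scn$state0$phi[1, ] > 0.999))
  expect_true(all(scn$state0$phi[g$n[1], ] > 0.999))
  # nested masks: core strictly inside shell
  kap <- scn$kappa$field
  expect_true(all(kap >= scn$material$kappa_c))
  expect_error(make_channel_2d(h_s = 0.5, h_c = 0.6), "h_c < h_s")
  # generators are pure: identical inputs give identical states
  scn2 <- make_channel_2d(h_s = 0.8, h_c = 0.6, n = c(96, 32))
  expect_identical(scn$state0$phi, scn2$state0$phi)
})

test_that("circular vessel generator: geometry, penalization, lumen area", {
  scn <- make_circular_vessel(h_s = 0.5, h_c = 0.3, n = c(40, 96, 96))
  lum <- lumen_fraction(scn)
  # lumen cross-section area = pi/4 within 2% (antialiased mask quadrature)
  a_cs <- sum(lum[10, , ]) * scn$grid$h[2] * scn$grid$h[3]
  expect_equal(a_cs, pi / 4, tolerance = 0.02)
  expect_error(make_circular_vessel(h_s = 0.7), "radius")
  # penalization drives the deep-wall velocity to zero within a few steps
  # (the fringe row still feels the pressure-projection correction)
  scn2 <- make_circular_vessel(n = c(48, 12, 12), rigid = "frozen")
  cfg <- solver_config(dt = 0.01, t_end = 0.1, record_every = 1e6)
  ctx <- solver_context(scn2, cfg)
  st <- scn2$state0
  for (k in 1:10) st <- step(st, ctx)
  m2 <- grid_mesh(scn2$grid)
  deep <- sqrt(m2[[2]]^2 + m2[[3]]^2) > 0.5 + 2 * max(scn2$grid$h[-1])
  expect_lt(max(abs(st$u[[1]][deep])), 0.01 * 0.75)
})

test_that("permeation channel generator hits the requested volume fraction", {
  for (vf in c(0.33, 0.45, 0.57, 0.66)) {
    scn <- make_permeation_channel(vf, n = c(48, 16, 8))
    vfx <- apply(1 - scn$state0$phi, 1, mean)
    expect_equal(max(vfx), vf, tolerance = 0.01)
  }
  scn0 <- make_permeation_channel(1e-9, n = c(48, 16, 8))
  expect_true(all(scn0$state0$phi > 1 - 1e-6))
  expect_error(make_permeation_channel(1.2), "VF")
})

test_that("shear cell generator: printed levels, plate law, slab variant", {
  for (vf in c(0.3419, 0.5129, 0.6335)) {
    scn <- make_shear_cell(vf, lambda_e = 20, n = c(16, 24))
    expect_equal(1 - scn$state0$phi[1, 12], vf, tolerance = 1e-12)
  }
  scn <- make_shear_cell(0.3419, lambda_e = 20, n = c(16, 24))
  v0 <- scn$vel_bc$yhi$value(0, list(numeric(3), numeric(3)))
  expect_equal(v0[[1]], rep(0, 3))      # plate at rest at t = 0
  vq <- scn$vel_bc$yhi$value(1 / 2.4, list(numeric(1), numeric(1)))
  expect_equal(vq[[1]], 0.2 * sin(1.2 * pi / 2.4), tolerance = 1e-12)
  # mid-channel slab variant: fluid outside the extent
  scn2 <- make_shear_cell(0.4, lambda_e = 20, n = c(48, 16),
                          slab_extent = c(2, 4))
  phi_line <- scn2$state0$phi[, 8]
  x <- scn2$grid$coords[[1]]
  expect_true(all(phi_line[x < 1] > 0.99))
  # tanh edge ramps at this resolution leave the plateau a few percent shy
  expect_equal(min(phi_line), 0.6, tolerance = 0.05)
})

test_that("aneurysm generator: bulge limit, site placement, waveform", {
  scn <- make_aneurysm(n = c(40, 20, 20), A = 1)
  expect_equal(scn$lumen_radius(5), 1, tolerance = 1e-12)
  expect_equal(scn$lumen_radius(-100), 0.5, tolerance = 1e-6)
  # A = 0 degenerates to the straight vessel
  scn0 <- make_aneurysm(n = c(40, 20, 20), A = 0)
  expect_equal(scn0$lumen_radius(c(0, 5, 10)), rep(0.5, 3))
  # deposition patches lie on the lumen surface
  for (s in scn$sites) {
    r_pts <- sqrt(s$points[, "y"]^2 + s$points[, "z"]^2)
    expect_equal(r_pts, scn$lumen_radius(s$points[, "x"]), tolerance = 1e-9)
  }
  # waveform: periodicity, positive mean equal to a0, zero-harmonic limit
  tt <- seq(0, 1, length.out = 257)[-257]
  w <- pulsatile_waveform(tt)
  expect_equal(pulsatile_waveform(0.3 + 5), pulsatile_waveform(0.3),
               tolerance = 1e-12)
  expect_equal(mean(w), 1, tolerance = 1e-12)
  expect_true(all(w > 0))
  expect_gt(max(w), 2.5)                 # systolic peak ~3x the mean
  const <- pulsatile_waveform(tt, list(a0 = 2, ac = numeric(0),
                                       as = numeric(0), t_peak = 0))
  expect_true(all(const == 2))
})

test_that("scenario configs round-trip through YAML and rebuild", {
  scn <- make_channel_2d(n = c(48, 16))
  path <- tempfile(fileext = ".yaml")
  write_scenario_config(scn$config, path)
  cfg <- read_scenario_config(path)
  expect_equal(cfg$scenario, "channel_2d")
  scn2 <- build_scenario(cfg)
  # YAML stores numerics at finite precision, so the rebuilt state matches
  # to that precision rather than bit-for-bit
  expect_equal(scn$state0$phi, scn2$state0$phi, tolerance = 1e-7)
  # unknown keys are rejected
  bad <- scn$config; bad$kapa_s <- 1
  path2 <- tempfile(fileext = ".yaml")
  write_scenario_config(bad, path2)
  expect_error(read_scenario_config(path2), "unknown config keys")
})

test_that("every generator yields a state that integrates stably", {
  scns <- list(make_channel_2d(n = c(48, 16)),
               make_permeation_channel(0.45, n = c(32, 12, 6)),
               make_shear_cell(0.3419, lambda_e = 20, n = c(16, 16)))
  for (scn in scns) {
    cfg <- solver_config(dt = 0.004, t_end = 0.05, record_every = 1e6)
    ctx <- solver_context(scn, cfg)
    st <- scn$state0
    for (k in 1:10) st <- step(st, ctx)
    expect_true(all(is.finite(unlist(st$u))))
    expect_true(all(is.finite(st$phi)))
  }
})
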