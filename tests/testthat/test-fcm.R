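test_that("platelet seeding: count, determinism, containment, radial profile", {
  dom <- list(x_range = c(1, 9), radius = 0.5)
  ens <- seed_platelets(dom, 500, seed = 7, r_p = 0.01)
  expect_equal(nrow(ens), 500)
  expect_true(all(ens$x > 1 & ens$x < 9))
  rr <- sqrt(ens$y^2 + ens$z^2)
  expect_true(all(rr < 0.5))
  expect_true(all(ens$state == "passive"))
  expect_identical(ens, seed_platelets(dom, 500, seed = 7, r_p = 0.01))
  # empirical radial CDF matches the configured profile (KS statistic)
  big <- seed_platelets(dom, 10000, seed = 3, r_p = 0.01)
  s <- sqrt(big$y^2 + big$z^2) / (0.5 - 0.01)
  sg <- seq(0, 1, length.out = 400)
  dens <- margination_profile(sg) * sg
  cdf_th <- cumsum(dens) / sum(dens)
  ks <- max(abs(stats::ecdf(s)(sg) - cdf_th))
  expect_lt(ks, 0.05)
})

test_that("state machine: delay-timed activation, irreversibility, radius growth", {
  co <- fcm_config(r_p = 0.01, r_eff_factor = 60, tau_act = 0.2)
  expect_equal(co$r_eff, 0.6)
  site <- deposition_site(0, width = 0.2, angle = -pi / 2, sector = pi / 4,
                          R_of_x = function(x) rep(0.1, length(x)),
                          capture_radius = 0.05)
  # isolated platelet far from everything stays passive forever
  far <- data.frame(id = 1, x = 5, y = 0, z = 0, radius = 0.01,
                    state = "passive", trigger_time = NA_real_, adhered = FALSE)
  for (t in seq(0, 3, by = 0.5))
    far <- update_states(far, list(site), t, co)
  expect_equal(far$state, "passive")
  # contact at t0 = 1.0 with tau_act = 0.2: activated at 1.2, not before
  near <- data.frame(id = 1, x = 0, y = 0, z = -0.1, radius = 0.01,
                     state = "passive", trigger_time = NA_real_, adhered = FALSE)
  near <- update_states(near, list(site), 1.0, co)
  expect_equal(near$state, "triggered")
  expect_equal(near$trigger_time, 1.0)
  near <- update_states(near, list(site), 1.19, co)
  expect_equal(near$state, "triggered")
  near <- update_states(near, list(site), 1.2, co)
  expect_equal(near$state, "activated")
  expect_equal(near$radius, 0.6)     # 60 x the passive radius
  # once activated, never reverts
  near <- update_states(near, list(site), 5, co)
  expect_equal(near$state, "activated")
  expect_error(fcm_config(tau_act = 0.5), "0.1, 0.3")
})

test_that("pairwise forces: minimum at r0, cutoff, Newton's third law, gradient", {
  co <- fcm_config(r_p = 0.01, r_eff_factor = 10, eta = 0.02, gamma_ref = 2,
                   repulse_A = 0)   # isolate the Morse part
  mk <- function(x2) data.frame(id = 1:2, x = c(0, x2), y = 0, z = 0,
                                radius = co$r_eff, state = "activated",
                                trigger_time = 0, adhered = FALSE)
  # zero Morse force at the potential minimum r = r0 = sum of radii
  F0 <- pairwise_forces(mk(2 * co$r_eff), co)
  expect_lt(max(abs(F0)), 1e-12)
  # zero beyond the cutoff 5/beta
  Fc <- pairwise_forces(mk(2 * co$r_eff + 5.1 / co$morse_beta), co)
  expect_true(all(Fc == 0))
  # Newton's third law and a central-difference check of the potential
  co2 <- fcm_config(r_p = 0.01, r_eff_factor = 10, eta = 0.02, gamma_ref = 2)
  r <- 2 * co2$r_eff + 0.1 * co2$repulse_len
  FF <- pairwise_forces(mk(r), co2)
  expect_equal(FF[1, ], -FF[2, ], tolerance = 1e-14)
  U <- function(rr) {
    eb <- exp(-co2$morse_beta * (rr - 2 * co2$r_eff))
    co2$morse_De * (eb^2 - 2 * eb) +
      co2$repulse_A * co2$repulse_len * exp(-rr / co2$repulse_len)
  }
  fd <- -(U(r + 1e-7) - U(r - 1e-7)) / 2e-7
  expect_equal(FF[2, 1], fd, tolerance = 1e-6 * abs(fd))
  expect_warning(pairwise_forces(mk(0), co2), "coincident")
})

test_that("platelet advection: rest, uniform flow, Poiseuille envelope average", {
  co <- fcm_config(r_p = 0.02, r_eff_factor = 10, eta = 0.1)
  g <- grid_create(c(64, 64, 8), length = c(4, 1, 0.5),
                   periodic = c(TRUE, FALSE, TRUE))
  ens <- data.frame(id = 1, x = 2, y = 0.45, z = 0.25, radius = 0.05,
                    state = "passive", trigger_time = NA_real_, adhered = FALSE)
  zero_flow <- list(u = replicate(3, field_const(g, 0), simplify = FALSE),
                    grid = g)
  e0 <- advect_platelets(ens, zero_flow, 0.1, co)
  expect_equal(e0$x, 2)
  uni <- list(u = list(field_const(g, 0.7), field_const(g, 0),
                       field_const(g, 0)), grid = g)
  e1 <- advect_platelets(ens, uni, 0.1, co)
  expect_equal(e1$x, 2 + 0.07, tolerance = 1e-12)
  # adhered platelets are frozen
  ens_a <- ens; ens_a$adhered <- TRUE
  expect_equal(advect_platelets(ens_a, uni, 0.1, co)$x, 2)
  # Poiseuille: envelope-averaged speed matches direct quadrature
  m <- grid_mesh(g)
  pois <- list(u = list(4 * m[[2]] * (1 - m[[2]]), field_const(g, 0),
                        field_const(g, 0)), grid = g)
  vel <- envelope_velocity(ens, pois$u, g, sigma = 0.05 / sqrt(pi))
  wts <- thromboflow:::.envelope_weights(c(2, 0.45, 0.25), 0.05 / sqrt(pi), g)
  direct <- sum(wts$w * pois$u[[1]][wts$idx]) / wts$tot
  expect_equal(vel[1, 1], direct, tolerance = 1e-10)
  # the envelope average differs from the point value by the curvature term
  expect_lt(abs(vel[1, 1] - 4 * 0.45 * 0.55) / (4 * 0.45 * 0.55), 0.01)
  # platelets leaving the axial domain are removed
  edge <- ens; edge$x <- 3.99; edge$adhered <- FALSE
  gone <- advect_platelets(edge, uni, 1, co)
  expect_equal(nrow(gone), 0)
  expect_equal(attr(gone, "removed"), 1)
})

test_that("stationarity rule: the 1/100-diameter threshold", {
  expect_true(stationarity(0, 0.1))
  expect_false(stationarity(2 * 0.1, 0.1))          # one diameter: moving
  expect_true(stationarity(2 * 0.1 / 200, 0.1))     # half the threshold
  expect_false(stationarity(2 * 0.1 / 100, 0.1))    # exactly at: strict
})

test_that("volume-fraction deposit: normalization, superposition, peak, gating", {
  co <- fcm_config(r_p = 0.006, r_eff_factor = 10, eta = 0.02)
  g <- grid_create(c(96, 96, 96), length = c(1, 1, 1))
  yc <- g$coords[[2]][48]      # node-centred placement (the peak check
                               # compares against the on-node maximum)
  mk1 <- function(x) data.frame(id = 1, x = x, y = yc, z = yc,
                                radius = co$r_eff, state = "activated",
                                trigger_time = 0, adhered = TRUE)
  psi <- fcm_volume_fraction(mk1(g$coords[[1]][39]), g, co)
  Vp <- 4 / 3 * pi * co$r_eff^3
  expect_equal(field_integral(psi, g), Vp, tolerance = 5e-3)
  sig <- co$r_eff * co$envelope_factor
  expect_equal(max(psi), Vp * (2 * pi * sig^2)^(-3 / 2), tolerance = 0.02)
  # two particles superpose linearly
  ens2 <- rbind(mk1(0.4), mk1(0.6)); ens2$id <- 1:2
  psi2 <- fcm_volume_fraction(ens2, g, co)
  expect_equal(psi2, fcm_volume_fraction(mk1(0.4), g, co) +
                 fcm_volume_fraction(mk1(0.6), g, co), tolerance = 1e-12)
  # under-resolved envelopes are rejected with the required resolution
  gc <- grid_create(c(12, 12, 12), length = c(1, 1, 1))
  expect_error(fcm_volume_fraction(mk1(0.4), gc, co), "under-resolved")
})

test_that("thrombus VF scaling and the smoothing handoff", {
  co <- fcm_config(r_p = 0.004, r_eff_factor = 10)
  g <- grid_create(c(48, 48, 48), length = c(1, 1, 1))
  psi <- field_const(g, 0)
  psi[20:28, 20:28, 20:28] <- 1
  expect_true(all(thrombus_VF(psi * 0, 1, 0, co) == 0))
  vf <- thrombus_VF(psi, 1, 0, co)
  # c_plat = 0, c_Fbg = 1 mg/mL: VF = 0.0054945 psi pointwise
  expect_equal(max(vf), fibrin_volume_fraction(1), tolerance = 1e-6)
  # monotone in psi_fcm
  expect_true(all(diff(thrombus_VF(c(0.1, 0.5, 0.9), 2, 0, co)) > 0))
  # handoff: VF = 0 gives pure blood
  expect_true(all(handoff_to_phasefield(psi * 0, g, 0.05) == 1))
  # block mean preserved by the conservative smoother, bounds respected
  vfb <- field_const(g, 0); vfb[15:35, 15:35, 15:35] <- 0.66
  phi0 <- handoff_to_phasefield(vfb, g, 2 * max(g$h))
  expect_equal(field_integral(1 - phi0, g), field_integral(vfb, g),
               tolerance = 1e-6)
  expect_equal(mean((1 - phi0)[20:30, 20:30, 20:30]), 0.66, tolerance = 0.01)
  expect_true(min(phi0) >= 0 && max(phi0) <= 1 + 1e-12)
})

test_that("two-way reaction force deposits minus the particle force", {
  co <- fcm_config(r_p = 0.007, r_eff_factor = 10)
  g <- grid_create(c(80, 80, 80), length = c(1, 1, 1))
  ens <- data.frame(id = 1, x = 0.5, y = 0.5, z = 0.5, radius = co$r_eff,
                    state = "activated", trigger_time = 0, adhered = FALSE)
  FF <- matrix(c(0.3, -0.1, 0), 1, 3)
  fr <- fcm_reaction_force(ens, FF, g, co)
  # the field integrates to the opposite of the applied particle force
  expect_equal(field_integral(fr[[1]], g), -0.3, tolerance = 5e-3)
  expect_equal(field_integral(fr[[2]], g), 0.1, tolerance = 5e-3)
  expect_equal(field_integral(fr[[3]], g), 0, tolerance = 1e-12)
})

test_that("total deposited volume is conserved over an ensemble", {
  co <- fcm_config(r_p = 0.007, r_eff_factor = 10)
  g <- grid_create(c(80, 80, 80), length = c(1, 1, 1))
  set.seed(5)
  n <- 12
  ens <- data.frame(id = seq_len(n), x = runif(n, 0.3, 0.7),
                    y = runif(n, 0.3, 0.7), z = runif(n, 0.3, 0.7),
                    radius = co$r_eff, state = "activated",
                    trigger_time = 0, adhered = TRUE)
  psi <- fcm_volume_fraction(ens, g, co)
  expect_equal(field_integral(psi, g), n * 4 / 3 * pi * co$r_eff^3,
               tolerance = 5e-3)
})
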