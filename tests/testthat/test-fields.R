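test_that("double-well derivative: roots, hand value, antisymmetry", {
  expect_equal(double_well_derivative(c(0, 0.5, 1), 1), c(0, 0, 0))
  expect_equal(double_well_derivative(0.25, 1), 0.09375)
  ph <- seq(-0.2, 1.2, length.out = 29)
  expect_equal(double_well_derivative(ph, 0.7),
               -double_well_derivative(1 - ph, 0.7))
  # 1/h^2 scaling
  expect_equal(double_well_derivative(0.3, 0.5),
               4 * double_well_derivative(0.3, 1))
})

test_that("chemical potential assembles the three terms as printed", {
  g <- grid_create(c(12, 12), length = c(1, 1))
  mat <- material_params(sigma = 1e-3, h = 1, gamma = 1, lambda_e0 = 1)
  mat$lambda <- 1   # unit mixing energy density for the hand value
  Fid <- identity_deformation(g)
  # uniform equilibrium phases: mu1 identically zero
  for (p0 in c(0, 1)) {
    mu <- chemical_potential(field_const(g, p0), Fid, mat, g)
    expect_true(all(abs(mu) < 1e-14))
  }
  # uniform phi = 0.25: only the double-well term survives
  mu <- chemical_potential(field_const(g, 0.25), Fid, mat, g)
  expect_equal(mu[3, 3], 0.09375, tolerance = 1e-12)
  # stretched F adds (lambda_e/2) tr(F^T F - I) = 3/2 for diag(2,1) in 2D
  Fst <- Fid; Fst$F11[] <- 2
  mu2 <- chemical_potential(field_const(g, 0.25), Fst, mat, g, lambda_e = 1)
  expect_equal(mu2[3, 3], 0.09375 + 0.5 * 3, tolerance = 1e-12)
})

test_that("elastic stress: zero cases and simple-shear closed form", {
  g <- grid_create(c(6, 6), length = c(1, 1))
  Fid <- identity_deformation(g)
  phi <- field_const(g, 0.2)
  S <- elastic_stress(Fid, phi, 1)
  expect_true(all(vapply(S, function(a) max(abs(a)), numeric(1)) < 1e-15))
  S2 <- elastic_stress(Fid, field_const(g, 1), 1)   # pure blood
  expect_true(all(vapply(S2, function(a) max(abs(a)), numeric(1)) < 1e-15))
  gam <- 0.3
  Fsh <- Fid; Fsh$F12[] <- gam
  S3 <- elastic_stress(Fsh, field_const(g, 0), 1)
  expect_equal(S3$S11[2, 2], gam^2, tolerance = 1e-14)
  expect_equal(S3$S12[2, 2], gam, tolerance = 1e-14)
  expect_equal(S3$S21[2, 2], gam, tolerance = 1e-14)
  expect_equal(S3$S22[2, 2], 0, tolerance = 1e-14)
})

test_that("surface tension force: zero for uniform phi, normal to a 1D interface,
           linear in lambda, integrates to ~0 over a closed interface", {
  g <- grid_create(c(40, 40), length = c(1, 1))
  expect_lt(max(abs(unlist(surface_tension_force(field_const(g, 0.4), 1, g)))),
            1e-12)
  m <- grid_mesh(g)
  phi1d <- interface_profile(m[[1]] - 0.5, 0.05)
  f <- surface_tension_force(phi1d, 1, g)
  expect_lt(max(abs(f[[2]])), 1e-10)          # tangential component vanishes
  f2 <- surface_tension_force(phi1d, 2, g)
  expect_equal(f2[[1]], 2 * f[[1]], tolerance = 1e-12)
  # closed circular interface: net force ~ 0 (momentum consistency)
  d <- sqrt((m[[1]] - 0.5)^2 + (m[[2]] - 0.5)^2) - 0.25
  phic <- interface_profile(d, 0.03)
  fc <- surface_tension_force(phic, 1e-3, g)
  for (comp in fc) {
    l1 <- field_integral(abs(comp), g)
    expect_lt(abs(field_integral(comp, g)), 1e-8 * l1)
  }
})

test_that("Darcy drag is antiparallel to u, vanishes in blood, direct value", {
  g <- grid_create(c(6, 6), length = c(1, 1))
  u <- list(field_const(g, 1), field_const(g, 0))
  expect_true(all(abs(unlist(darcy_drag(u, field_const(g, 1), 2, 1e-4))) == 0))
  dr <- darcy_drag(u, field_const(g, 0), 2, 1e-4)
  expect_equal(dr[[1]][1, 1], -2 / 1e-4)
  expect_true(all(dr[[2]] == 0))
  # large sentinel permeability: free-flow limit
  expect_lt(max(abs(darcy_drag(u, field_const(g, 0), 2, 1e10)[[1]])), 1e-9)
  expect_error(darcy_drag(u, field_const(g, 0), 2, 0), "kappa")
})

test_that("total energy: zero cases, interface energy closed form, stretch", {
  # the 1D equilibrium profile phi = (1 + tanh(d/2h))/2 of the [0,1] well
  # carries mixing energy lambda/(6h) per unit interface area
  h <- 0.02
  g <- grid_create(c(400, 4), length = c(1, 0.1))
  mat <- material_params(sigma = 1e-3, h = h, lambda_e0 = 0)
  m <- grid_mesh(g)
  st0 <- simulation_state(g, phi = field_const(g, 1))
  expect_equal(as.numeric(total_energy(st0, mat)), 0)
  st <- simulation_state(g, phi = interface_profile(m[[1]] - 0.5, h))
  emix <- attr(total_energy(st, mat), "mixing")
  area <- 0.1
  expect_equal(emix / area, mat$lambda / (6 * h), tolerance = 0.02)
  # uniform stretch: elastic part (lambda_e/2)(2 eps + eps^2) V
  eps <- 0.1
  Fst <- identity_deformation(g); Fst$F11[] <- 1 + eps
  st2 <- simulation_state(g, phi = field_const(g, 0), F = Fst)
  mat2 <- material_params(lambda_e0 = 0.7, h = h)
  eel <- attr(total_energy(st2, mat2), "elastic")
  expect_equal(eel, 0.7 / 2 * (2 * eps + eps^2) * 0.1, tolerance = 1e-10)
})

test_that("bulk volume fraction conventions", {
  g <- grid_create(c(16, 16), length = c(1, 1))
  expect_equal(bulk_volume_fraction(field_const(g, 1), g), 0)
  expect_equal(bulk_volume_fraction(field_const(g, 1), g, "as_printed"), 0)
  expect_equal(bulk_volume_fraction(field_const(g, 0), g), 1)
  expect_equal(bulk_volume_fraction(field_const(g, 0), g, "as_printed"), 0.5)
  m <- grid_mesh(g)
  half <- ifelse(m[[1]] < 0.5, 0, 1)
  expect_equal(bulk_volume_fraction(half, g), 0.5, tolerance = 0.05)
})

test_that("curl potential: identity, linear fields, column divergence, shear", {
  g <- grid_create(c(32, 32), length = c(1, 1))
  Fid <- curl_potential_to_F(identity_potential(g), g)
  expect_equal(Fid$F11, field_const(g, 1), tolerance = 1e-12)
  expect_equal(Fid$F22, field_const(g, 1), tolerance = 1e-12)
  expect_lt(max(abs(Fid$F12)), 1e-12)
  # linear potential psi = (a1 x + b1 y, a2 x + b2 y):
  # columns of F are the curls of the components
  m <- grid_mesh(g)
  a1 <- 0.3; b1 <- 1.4; a2 <- -0.8; b2 <- 0.6
  psi <- list(a1 * m[[1]] + b1 * m[[2]], a2 * m[[1]] + b2 * m[[2]])
  Fl <- curl_potential_to_F(psi, g)
  expect_equal(Fl$F11[5, 5], b1, tolerance = 1e-10)
  expect_equal(Fl$F21[5, 5], -a1, tolerance = 1e-10)
  expect_equal(Fl$F12[5, 5], b2, tolerance = 1e-10)
  expect_equal(Fl$F22[5, 5], -a2, tolerance = 1e-10)
  # sheared labels reproduce the simple-shear deformation gradient
  gam <- 0.25
  psi_sh <- list(m[[2]], -(m[[1]] - gam * m[[2]]))
  Fsh <- curl_potential_to_F(psi_sh, g)
  expect_equal(Fsh$F12[8, 8], gam, tolerance = 1e-10)
  expect_equal(Fsh$F11[8, 8], 1, tolerance = 1e-10)
  # discrete column divergence vanishes for smooth random potentials
  gp <- grid_create(c(64, 64), length = c(2 * pi, 2 * pi), periodic = c(TRUE, TRUE))
  mp <- grid_mesh(gp)
  psir <- list(mp[[2]] + 0.1 * sin(mp[[1]]) * cos(2 * mp[[2]]),
               -mp[[1]] + 0.07 * cos(2 * mp[[1]]) * sin(mp[[2]]))
  Fr <- curl_potential_to_F(psir, gp, scheme = "spectral")
  div1 <- deriv1(Fr$F11, gp, 1, "spectral") + deriv1(Fr$F21, gp, 2, "spectral")
  div2 <- deriv1(Fr$F12, gp, 1, "spectral") + deriv1(Fr$F22, gp, 2, "spectral")
  expect_lt(max(abs(div1)), 1e-10)
  expect_lt(max(abs(div2)), 1e-10)
})

test_that("grid quadrature and derivative building blocks are second order", {
  g1 <- grid_create(c(33, 5), length = c(1, 1))
  g2 <- grid_create(c(65, 5), length = c(1, 1))
  f <- function(g) { m <- grid_mesh(g); sin(2 * pi * m[[1]] / 1) }
  fx <- function(g) { m <- grid_mesh(g); 2 * pi * cos(2 * pi * m[[1]]) }
  e1 <- max(abs(deriv1(f(g1), g1, 1) - fx(g1)))
  e2 <- max(abs(deriv1(f(g2), g2, 1) - fx(g2)))
  expect_gt(log2(e1 / e2), 1.7)
  expect_equal(field_integral(field_const(g1, 2.5), g1), 2.5)
})
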