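test_that("deformation transport: fixed point at rest, simple shear closed form", {
  g <- grid_create(c(16, 16), length = c(1, 1))
  F0 <- identity_deformation(g)
  u0 <- list(field_const(g, 0), field_const(g, 0))
  F1 <- advance_deformation(F0, u0, g, 0.01)
  for (nm in names(F0)) expect_equal(F1[[nm]], F0[[nm]], tolerance = 1e-14)
  # spatially uniform simple shear: F12(t) = gdot * t within O(dt^2) per step
  gdot <- 0.8
  m <- grid_mesh(g)
  ush <- list(gdot * m[[2]], field_const(g, 0))
  F <- F0
  dt <- 0.005
  for (k in 1:100) F <- advance_deformation(F, ush, g, dt)
  expect_equal(mean(F$F12[4:13, 4:13]), gdot * 0.5, tolerance = 1e-3)
  expect_equal(mean(F$F11[4:13, 4:13]), 1, tolerance = 1e-6)
  expect_error(advance_deformation(F0, list(field_const(g, 200), u0[[2]]),
                                   g, 0.01), "CFL")
})

test_that("deformation transport preserves column divergence on a vortex", {
  g <- grid_create(c(64, 64), length = c(2 * pi, 2 * pi),
                   periodic = c(TRUE, TRUE))
  m <- grid_mesh(g)
  u <- list(0.1 * sin(m[[1]]) * cos(m[[2]]), -0.1 * cos(m[[1]]) * sin(m[[2]]))
  F <- identity_deformation(g)
  for (k in 1:100) F <- advance_deformation(F, u, g, 0.005, spectral = TRUE)
  dcol <- function(i)
    max(abs(deriv1(F[[paste0("F1", i)]], g, 1, "spectral") +
              deriv1(F[[paste0("F2", i)]], g, 2, "spectral")))
  expect_lt(dcol(1), 1e-6)
  expect_lt(dcol(2), 1e-6)
})

test_that("psi advection: rest fixed point, translation, commutation with F transport", {
  g <- grid_create(c(128, 8), length = c(2, 1), periodic = c(TRUE, TRUE))
  m <- grid_mesh(g)
  pid <- identity_potential(g)
  blob <- exp(-(m[[1]] - 1)^2 / (2 * 0.04))
  psi0 <- list(pid[[1]] + blob, pid[[2]])
  u0 <- list(field_const(g, 0), field_const(g, 0))
  p1 <- advance_psi(psi0, u0, g, 0.01)
  expect_equal(p1[[1]], psi0[[1]], tolerance = 1e-14)
  # uniform translation by one domain transit
  uc <- list(field_const(g, 0.5), field_const(g, 0))
  psi <- psi0
  dt <- 0.005
  for (k in seq_len(round(2 / 0.5 / dt)))
    psi <- advance_psi(psi, uc, g, dt, spectral = TRUE)
  err <- sqrt(sum((psi[[1]] - psi0[[1]])^2) / sum(blob^2))
  expect_lt(err, 0.01)
  # advancing psi then taking the curl matches direct F transport
  gs <- grid_create(c(48, 48), length = c(2 * pi, 2 * pi),
                    periodic = c(TRUE, TRUE))
  ms <- grid_mesh(gs)
  us <- list(0.2 * sin(ms[[1]]) * cos(ms[[2]]),
             -0.2 * cos(ms[[1]]) * sin(ms[[2]]))
  psis <- identity_potential(gs)
  Fs <- identity_deformation(gs)
  for (k in 1:40) {
    psis <- advance_psi(psis, us, gs, 0.01, spectral = TRUE)
    Fs <- advance_deformation(Fs, us, gs, 0.01, spectral = TRUE)
  }
  Fpsi <- curl_potential_to_F(psis, gs, scheme = "spectral")
  for (nm in names(Fs))
    expect_lt(max(abs(Fpsi[[nm]] - Fs[[nm]])), 5e-3)
})

test_that("phase update: equilibrium fixed point, mass conservation, energy decay", {
  scn <- box_bubble_scenario(n = 40)
  cfg <- solver_config(dt = 2e-3, t_end = 1)
  ctx <- solver_context(scn, cfg)
  st <- scn$state0
  mass0 <- field_integral(st$phi, st$grid)
  for (k in 1:200) st <- step(st, ctx)
  diag <- do.call(rbind, lapply(ctx$diag, as.data.frame))
  # mass conservation in the closed box
  expect_lt(abs(field_integral(st$phi, st$grid) - mass0) / mass0, 1e-8)
  # the perturbed interface relaxes: mixing energy non-increasing
  expect_lt(tail(diag$energy_mixing, 1), diag$energy_mixing[1])
  expect_lt(max(diff(diag$energy_total)), 1e-8 * diag$energy_total[1])
  # uniform state is a fixed point of the full cycle
  g <- scn$grid
  stu <- simulation_state(g, phi = field_const(g, 1))
  scn2 <- scn; scn2$state0 <- stu
  ctx2 <- solver_context(scn2, cfg)
  st2 <- step(stu, ctx2)
  expect_equal(st2$phi, stu$phi, tolerance = 1e-12)
  expect_lt(max(abs(unlist(st2$u))), 1e-12)
})

test_that("flow solver reproduces Poiseuille exactly and the Brinkman profile", {
  # body-force-driven plane channel: the parabola is an exact discrete
  # steady state (quadratic through second-order stencils)
  g <- grid_create(c(8, 33), length = c(2, 1), periodic = c(TRUE, FALSE))
  mat <- material_params(rho1 = 1, rho2 = 1, eta1 = 0.1, eta2 = 0.1,
                         lambda_e0 = 0, h = 0.05)
  m <- grid_mesh(g)
  uex <- 1 / (2 * 0.1) * m[[2]] * (1 - m[[2]])
  st <- simulation_state(g, u = list(uex, field_const(g, 0)))
  noslip <- list(type = "dirichlet",
                 value = function(t, X) list(numeric(length(X[[1]])),
                                             numeric(length(X[[1]]))))
  scn <- make_scenario(g, mat, st, list(ylo = noslip, yhi = noslip),
                       body_force = function(t, gg)
                         list(field_const(gg, 1), field_const(gg, 0)),
                       name = "poiseuille")
  ctx <- solver_context(scn, solver_config(dt = 5e-3, t_end = 1))
  u0 <- st$u[[1]]
  for (k in 1:20) st <- step(st, ctx)
  expect_lt(max(abs(st$u[[1]] - u0)) / 20, 1e-8)
  # Brinkman slab at 129 nodes: within 1% of the closed form
  scn_b <- brinkman_scenario(129)
  stb <- run_to_steady(scn_b)
  uexb <- brinkman_exact(scn_b$grid)
  expect_lt(sqrt(sum((stb$u[[1]] - uexb)^2) / sum(uexb^2)), 0.01)
})

test_that("post-projection divergence stays below tolerance in a driven box", {
  scn <- box_bubble_scenario(n = 40, lambda_e0 = 0.2)
  cfg <- solver_config(dt = 2e-3, t_end = 0.2, div_tol = 1e-3)
  ctx <- solver_context(scn, cfg)
  st <- scn$state0
  for (k in 1:100) st <- step(st, ctx)
  diag <- do.call(rbind, lapply(ctx$diag, as.data.frame))
  expect_true(all(diag$div_norm < cfg$div_tol))
})

test_that("CFL violation is caught at runtime", {
  scn <- box_bubble_scenario(n = 24)
  cfg <- solver_config(dt = 0.5, t_end = 1)
  ctx <- solver_context(scn, cfg)
  st <- scn$state0
  st$u[[1]][] <- 10
  expect_error(step(st, ctx), "CFL")
})
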