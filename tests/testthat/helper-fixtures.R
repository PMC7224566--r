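# shared fixtures built in code

# synthetic torque-displacement ellipse with phase angle delta0
ellipse_record <- function(delta0, ncyc = 2, m = 5000, period = 2,
                           amp_d = 1, amp_t = 1) {
  t <- seq(0, ncyc * period, length.out = ncyc * m + 1)[-1]
  th <- 2 * pi * t / period
  rec <- data.frame(time = t, displacement = amp_d * sin(th),
                    traction = amp_t * sin(th + delta0))
  attr(rec, "period") <- period
  rec
}

# closed 2D box scenario with a perturbed thrombus bubble, no forcing
box_bubble_scenario <- function(n = 48, h = 0.04, lambda_e0 = 0,
                                perturb = 0.02) {
  g <- grid_create(c(n, n), length = c(1, 1))
  mat <- material_params(rho1 = 1, rho2 = 1, eta1 = 0.1, eta2 = 0.1,
                         lambda_e0 = lambda_e0, sigma = 1e-3, h = h)
  m <- grid_mesh(g)
  d <- sqrt((m[[1]] - 0.5)^2 + (m[[2]] - 0.5)^2) - 0.22
  phi <- interface_profile(d, h) +
    perturb * sin(7 * pi * m[[1]]) * sin(5 * pi * m[[2]])
  st <- simulation_state(g, phi = phi)
  noslip <- list(type = "dirichlet",
                 value = function(t, X) list(numeric(length(X[[1]])),
                                             numeric(length(X[[1]]))))
  make_scenario(g, mat, st,
                list(xlo = noslip, xhi = noslip, ylo = noslip, yhi = noslip),
                name = "box_bubble")
}

# uniform-drag Brinkman channel: body-force driven, periodic in x
brinkman_scenario <- function(ny, kappa = 0.02, phi0 = 0.5, G = 1) {
  g <- grid_create(c(8, ny), length = c(2, 1), periodic = c(TRUE, FALSE))
  mat <- material_params(rho1 = 1, rho2 = 1, eta1 = 1, eta2 = 1,
                         lambda_e0 = 0, h = 0.05)
  phif <- field_const(g, phi0)
  st <- simulation_state(g, phi = phif)
  noslip <- list(type = "dirichlet",
                 value = function(t, X) list(numeric(length(X[[1]])),
                                             numeric(length(X[[1]]))))
  scn <- make_scenario(g, mat, st, list(ylo = noslip, yhi = noslip),
                       body_force = function(t, gg)
                         list(field_const(gg, G), field_const(gg, 0)),
                       rigid = "frozen",
                       drag_static = mat$eta1 * (1 - phif) / (mat$rho1 * kappa),
                       name = "brinkman")
  scn
}

brinkman_exact <- function(g, kappa = 0.02, phi0 = 0.5, G = 1) {
  m <- grid_mesh(g)
  al <- sqrt((1 - phi0) / kappa)
  (G / ((1 - phi0) / kappa)) * (1 - cosh(al * (m[[2]] - 0.5)) / cosh(al / 2))
}

run_to_steady <- function(scn, dt = 0.05, tol = 1e-11, max_steps = 2000) {
  ctx <- solver_context(scn, solver_config(dt = dt, t_end = dt * max_steps,
                                           record_every = 1e6))
  st <- scn$state0
  for (k in seq_len(max_steps)) {
    up <- st$u[[1]]
    st <- step(st, ctx)
    if (max(abs(st$u[[1]] - up)) < tol) break
  }
  st
}
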