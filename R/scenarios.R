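# Scenario generators: every geometry / initial condition / boundary forcing
# used by the virtual experiments, plus plain-text config serialization.

#' Assemble a scenario
#'
#' Low-level constructor bundling everything [run()] needs.  The geometry
#' builders ([make_channel_2d()], [make_circular_vessel()],
#' [make_permeation_channel()], [make_shear_cell()], [make_aneurysm()]) are
#' the user-facing entry points.
#'
#' @param grid `tf_grid`.
#' @param material `tf_material`.
#' @param state0 initial `tf_state`.
#' @param vel_bc named per-face (`xlo`, ..., `zhi`) list of velocity
#'   boundary conditions `list(type, value(t, X))`.
#' @param pressure_outlet face name with `p = 0`, or NULL (closed domain).
#' @param body_force `function(t, grid)` returning force-per-volume
#'   component arrays, or NULL.
#' @param kappa permeability spec: `list(mode, field, kappa_free)` with mode
#'   `"shell_core"` (static `field`), `"davies"` (recomputed from phi), or
#'   `"none"`.
#' @param drag_static static drag-coefficient array (wall penalization,
#'   frozen clot), or NULL.
#' @param rigid `"none"`, `"literal"` (elastic force off, fields evolve) or
#'   `"frozen"` (phase/deformation updates disabled, drag folded static).
#' @param lambda_e_mode `"constant"` or `"via_relaxation"`.
#' @param F_inflow_mask logical array of nodes where `F = I` is re-imposed.
#' @param probes list of node-index vectors for velocity probes.
#' @param name scenario name.
#' @param config plain-value parameter list kept for serialization.
#' @export
make_scenario <- function(grid, material, state0, vel_bc,
                          pressure_outlet = NULL, body_force = NULL,
                          kappa = list(mode = "none"), drag_static = NULL,
                          rigid = "none", lambda_e_mode = "constant",
                          F_inflow_mask = NULL, probes = NULL,
                          name = "scenario", config = list()) {
  stopifnot(rigid %in% c("none", "literal", "frozen"))
  structure(list(grid = grid, material = material, state0 = state0,
                 vel_bc = vel_bc, pressure_outlet = pressure_outlet,
                 body_force = body_force, kappa = kappa,
                 drag_static = drag_static, rigid = rigid,
                 lambda_e_mode = lambda_e_mode,
                 F_inflow_mask = F_inflow_mask, probes = probes,
                 name = name, config = config),
            class = "tf_scenario")
}

#' @export
print.tf_scenario <- function(x, ...) {
  cat(sprintf("<tf_scenario> %s  %s nodes  rigid = %s\n", x$name,
              paste(x$grid$n, collapse = "x"), x$rigid))
  invisible(x)
}

.noslip <- function(nd) list(type = "dirichlet",
                             value = function(t, X)
                               replicate(nd, numeric(length(X[[1]])), simplify = FALSE))

.smooth_ramp <- function(t, t_ramp) if (t_ramp <= 0) 1 else tanh(t / t_ramp)^2

# smooth axial box indicator over [x1, x2] with tanh edges of width h
.axial_box <- function(x, x1, x2, h) {
  0.25 * (1 + tanh((x - x1) / (2 * h))) * (1 + tanh((x2 - x) / (2 * h)))
}

#' Shell-core thrombus in a 2D rectangular channel
#'
#' Domain `[0,6] x [0,2]` with nested semicircular core (radius `h_c`) and
#' shell (radius `h_s`) on the bottom-wall midpoint, a parabolic inlet with
#' maximum `u_max`, a zero-Neumann outlet, and no-slip walls.  The state
#' uses the 2D curl-potential formulation.
#'
#' @param h_s,h_c shell and core radii (`h_c < h_s < 2`).
#' @param n node counts (default `c(96, 32)`).
#' @param material `tf_material` (defaults to the channel parameter set:
#'   density ratio 2, viscosity ratio 1, `lambda_e = 0.5`).
#' @param u_max maximum inlet velocity.
#' @param inflow_ramp start-up ramp time (smooth impulsive start).
#' @param inflow_scale optional multiplier function of time (pulsatile).
#' @param h_int interface thickness (default twice the coarsest spacing).
#' @param use_F use the deformation-tensor formulation instead of psi.
#' @export
make_channel_2d <- function(h_s = 0.8, h_c = 0.6, n = c(96, 32),
                            material = NULL, u_max = 0.75,
                            inflow_ramp = 0.1, inflow_scale = NULL,
                            h_int = NULL, use_F = FALSE) {
  if (!(h_c < h_s && h_s < 2)) stop("need h_c < h_s < 2: clot must fit the channel")
  nd <- length(n)
  if (nd == 3L)        # z-periodic extrusion of the same setup (F formulation)
    return(.make_channel_3d(h_s, h_c, n, material, u_max, inflow_ramp,
                            inflow_scale, h_int))
  g <- grid_create(n, length = c(6, 2))
  if (is.null(h_int)) h_int <- 2 * max(g$h[1:2])
  if (is.null(material))
    material <- material_params(rho1 = 1, rho2 = 2, eta1 = 0.05, eta2 = 0.05,
                                lambda_e0 = 0.5, sigma = 1e-3, h = h_int,
                                kappa_s = 1e4, kappa_c = 1e-4)
  m <- grid_mesh(g)
  dist <- sqrt((m[[1]] - 3)^2 + m[[2]]^2)
  phi <- interface_profile(dist - h_s, h_int)
  core <- dist < h_c
  shell <- dist >= h_c & dist < h_s
  kap <- permeability_field(phi, material, "shell_core",
                            core_mask = core, shell_mask = shell)
  st <- simulation_state(g, phi = phi,
                         F = if (use_F) identity_deformation(g) else NULL,
                         psi = if (use_F) NULL else identity_potential(g))
  inlet <- function(t, X) {
    sc <- .smooth_ramp(t, inflow_ramp)
    if (!is.null(inflow_scale)) sc <- sc * inflow_scale(t)
    y <- X[[2]]
    list(sc * u_max * (1 - (y - 1)^2), numeric(length(y)))
  }
  vel_bc <- list(xlo = list(type = "dirichlet", value = inlet),
                 xhi = list(type = "neumann"),
                 ylo = .noslip(2L), yhi = .noslip(2L))
  probes <- lapply(list(c(2, 1), c(3, 1.2), c(4, 1)), function(pt)
    c(which.min(abs(g$coords[[1]] - pt[1])), which.min(abs(g$coords[[2]] - pt[2]))))
  make_scenario(g, material, st, vel_bc, pressure_outlet = "xhi",
                kappa = list(mode = "shell_core", field = kap),
                F_inflow_mask = .face_mask(g, 1L, "lo"),
                probes = probes, name = "channel_2d",
                config = list(scenario = "channel_2d", h_s = h_s, h_c = h_c,
                              n = n, u_max = u_max, h_int = h_int))
}

# 3D z-periodic extrusion of the 2D channel (thickness 1): same clot and
# boundary forcing, deformation-gradient formulation
.make_channel_3d <- function(h_s, h_c, n, material, u_max, inflow_ramp,
                             inflow_scale, h_int) {
  g <- grid_create(n, length = c(6, 2, 1), periodic = c(FALSE, FALSE, TRUE))
  if (is.null(h_int)) h_int <- 2 * max(g$h[1:2])
  if (is.null(material))
    material <- material_params(rho1 = 1, rho2 = 2, eta1 = 0.05, eta2 = 0.05,
                                lambda_e0 = 0.5, sigma = 1e-3, h = h_int,
                                kappa_s = 1e4, kappa_c = 1e-4)
  m <- grid_mesh(g)
  dist <- sqrt((m[[1]] - 3)^2 + m[[2]]^2)
  phi <- interface_profile(dist - h_s, h_int)
  core <- dist < h_c
  shell <- dist >= h_c & dist < h_s
  kap <- permeability_field(phi, material, "shell_core",
                            core_mask = core, shell_mask = shell)
  st <- simulation_state(g, phi = phi, F = identity_deformation(g))
  inlet <- function(t, X) {
    sc <- .smooth_ramp(t, inflow_ramp)
    if (!is.null(inflow_scale)) sc <- sc * inflow_scale(t)
    y <- X[[2]]
    list(sc * u_max * (1 - (y - 1)^2), numeric(length(y)), numeric(length(y)))
  }
  vel_bc <- list(xlo = list(type = "dirichlet", value = inlet),
                 xhi = list(type = "neumann"),
                 ylo = .noslip(3L), yhi = .noslip(3L))
  probes <- lapply(list(c(2, 1), c(3, 1.2), c(4, 1)), function(pt)
    c(which.min(abs(g$coords[[1]] - pt[1])),
      which.min(abs(g$coords[[2]] - pt[2])), 1L))
  make_scenario(g, material, st, vel_bc, pressure_outlet = "xhi",
                kappa = list(mode = "shell_core", field = kap),
                F_inflow_mask = .face_mask(g, 1L, "lo"),
                probes = probes, name = "channel_3d",
                config = list(scenario = "channel_2d", h_s = h_s, h_c = h_c,
                              n = n, u_max = u_max, h_int = h_int))
}

#' Shell-core thrombus in a circular vessel (volume-penalized)
#'
#' Straight vessel of unit diameter and length 10 realized on a box grid by
#' volume penalization (nodes outside the lumen get a phi-independent drag
#' with `kappa_wall = 1e-8`).  A semi-spherical shell/core clot sits on the
#' bottom wall; the inlet is Hagen-Poiseuille with maximum `inlet_max`.
#'
#' @param h_s,h_c shell and core radii (`h_s <= 0.5`).
#' @param n node counts (default `c(80, 16, 16)`).
#' @param material defaults to the vessel parameter set (density ratio 10,
#'   viscosity ratio 2, `sigma = 1e-3`).
#' @param inlet_max maximum inlet axial velocity.
#' @param rigid `"literal"`, `"frozen"`, or `"none"`.
#' @param kappa_wall penalization permeability.
#' @inheritParams make_channel_2d
#' @export
make_circular_vessel <- function(h_s = 0.5, h_c = 0.3, n = c(80, 16, 16),
                                 material = NULL, inlet_max = 0.75,
                                 rigid = "literal", inflow_ramp = 0.1,
                                 inflow_scale = NULL, h_int = NULL,
                                 kappa_wall = 1e-8) {
  if (h_s > 0.5) stop("h_s must not exceed the vessel radius 0.5")
  R <- 0.5
  g <- grid_create(n, length = c(10, 1.2, 1.2), origin = c(0, -0.6, -0.6))
  if (is.null(h_int)) h_int <- 2 * max(g$h)
  if (is.null(material))
    material <- material_params(rho1 = 1, rho2 = 10, eta1 = 0.025, eta2 = 0.05,
                                lambda_e0 = 0.5, sigma = 1e-3, h = h_int,
                                kappa_s = 1e-2, kappa_c = 1e-4)
  m <- grid_mesh(g)
  r <- sqrt(m[[2]]^2 + m[[3]]^2)
  hh <- max(g$h[-1])              # antialias over one cross-section cell
  wall_frac <- pmin(pmax((r - R) / hh + 0.5, 0), 1)
  drag_wall <- wall_frac * (material$eta1 / material$rho1) / kappa_wall
  dist <- sqrt((m[[1]] - 3)^2 + m[[2]]^2 + (m[[3]] + R)^2)
  lumen <- 1 - wall_frac
  phi <- 1 - (1 - interface_profile(dist - h_s, h_int)) * lumen
  core <- dist < h_c & wall_frac < 0.5
  shell <- dist >= h_c & dist < h_s & wall_frac < 0.5
  kap <- permeability_field(phi, material, "shell_core",
                            core_mask = core, shell_mask = shell)
  drag_static <- drag_wall
  if (identical(rigid, "frozen")) {
    mixe <- mixture_property(phi, material$eta1, material$eta2)
    mixr <- mixture_property(phi, material$rho1, material$rho2)
    drag_static <- drag_static + mixe * (1 - phi) / (mixr * kap)
  }
  st <- simulation_state(g, phi = phi, F = identity_deformation(g))
  inlet <- function(t, X) {
    sc <- .smooth_ramp(t, inflow_ramp)
    if (!is.null(inflow_scale)) sc <- sc * inflow_scale(t)
    rr2 <- X[[2]]^2 + X[[3]]^2
    ax <- sc * inlet_max * pmax(1 - rr2 / R^2, 0)
    list(ax, numeric(length(ax)), numeric(length(ax)))
  }
  vel_bc <- list(xlo = list(type = "dirichlet", value = inlet),
                 xhi = list(type = "neumann"),
                 ylo = .noslip(3L), yhi = .noslip(3L),
                 zlo = .noslip(3L), zhi = .noslip(3L))
  make_scenario(g, material, st, vel_bc, pressure_outlet = "xhi",
                kappa = list(mode = "shell_core", field = kap),
                drag_static = drag_static, rigid = rigid,
                F_inflow_mask = .face_mask(g, 1L, "lo"),
                name = "circular_vessel",
                config = list(scenario = "circular_vessel", h_s = h_s,
                              h_c = h_c, n = n, inlet_max = inlet_max,
                              rigid = rigid, h_int = h_int))
}

#' Lumen mask of a penalized vessel scenario (antialiased)
#' @param scenario a vessel/aneurysm `tf_scenario`.
#' @return array in `[0, 1]`, 1 inside the lumen.
#' @export
lumen_fraction <- function(scenario) {
  kw <- scenario$config$kappa_wall %||% 1e-8
  dw <- scenario$drag_static
  if (is.null(dw)) stop("scenario has no penalized wall")
  mat <- scenario$material
  pmin(pmax(1 - dw / ((mat$eta1 / mat$rho1) / kw), 0), 1)
}

#' Permeation chamber: channel-filling clot block
#'
#' Domain `[0,6] x [0,2] x [0,1]` (z periodic), parabolic inlet of maximum
#' `v_max = 1`, zero-Neumann outlet, no-slip y-walls.  A clot block with
#' uniform `phi = 1 - VF` spans the full cross-section over `x` in
#' `[2, 4]`; its permeability follows Davies' law at `psi_f = VF`.
#' Default material: density ratio 1, viscosity ratio 2, `eta1` chosen so
#' the Reynolds number `rho1 v_max H / eta1 = 0.02` (Stokes regime).
#'
#' @param VF initial clot volume fraction in (0, 1).
#' @param n node counts (default `c(96, 32, 16)`).
#' @param rigid `"frozen"` (default: the permeability test isolates drag)
#'   or `"none"` (deformable variant).
#' @inheritParams make_channel_2d
#' @export
make_permeation_channel <- function(VF, n = c(96, 32, 16), material = NULL,
                                    rigid = "frozen", h_int = NULL,
                                    inflow_ramp = 0) {
  if (VF < 0 || VF >= 1) stop("VF must lie in [0, 1)")
  nd <- length(n)
  g <- grid_create(n, length = c(6, 2, 1)[seq_len(nd)],
                   periodic = c(FALSE, FALSE, TRUE)[seq_len(nd)])
  if (is.null(h_int)) h_int <- 2 * max(g$h)
  if (is.null(material))
    material <- material_params(rho1 = 1, rho2 = 1, eta1 = 100, eta2 = 200,
                                lambda_e0 = 0, sigma = 1e-3, h = h_int)
  m <- grid_mesh(g)
  # frozen clots take near-sharp edges (one cell): the phase never evolves,
  # and sharp edges keep the measured clot length close to nominal
  h_edge <- if (identical(rigid, "frozen")) max(g$h) / 2 else h_int
  phi <- 1 - VF * .axial_box(m[[1]], 2, 4, h_edge)
  kap <- permeability_field(phi, material, "davies")
  drag_static <- NULL
  if (identical(rigid, "frozen")) {
    mixe <- mixture_property(phi, material$eta1, material$eta2)
    mixr <- mixture_property(phi, material$rho1, material$rho2)
    drag_static <- mixe * (1 - phi) / (mixr * kap)
  }
  st <- simulation_state(g, phi = phi,
                         F = if (nd == 3L) identity_deformation(g) else NULL)
  inlet <- function(t, X) {
    sc <- .smooth_ramp(t, inflow_ramp)
    y <- X[[2]]
    c(list(sc * (1 - (y - 1)^2)),
      replicate(nd - 1L, numeric(length(y)), simplify = FALSE))
  }
  vel_bc <- c(list(xlo = list(type = "dirichlet", value = inlet),
                   xhi = list(type = "neumann"),
                   ylo = .noslip(nd), yhi = .noslip(nd)))
  make_scenario(g, material, st, vel_bc, pressure_outlet = "xhi",
                kappa = list(mode = "davies"), drag_static = drag_static,
                rigid = rigid,
                F_inflow_mask = .face_mask(g, 1L, "lo"),
                name = "permeation_channel",
                config = list(scenario = "permeation_channel", VF = VF,
                              n = n, rigid = rigid, h_int = h_int))
}

#' Oscillatory shear cell (plate-gap rheometer analogue)
#'
#' 2D cell `[0,6] x [0,1]`, periodic in x: the top plate moves at
#' `v = plate_amp * sin(plate_omega * t)`, the bottom plate is no-slip.
#' By default the thrombus sample fills the measuring gap uniformly at
#' volume fraction `VF` (as a rheometry sample fills the plate gap; the
#' cell then responds affinely with `G' = lambda_e VF`).  A mid-channel
#' slab over `slab_extent` in x, flanked by pure fluid, is available as a
#' variant.
#'
#' @param VF slab volume fraction in (0, 1) (reference levels 0.3419, 0.5129,
#'   0.6335).
#' @param lambda_e nondimensional elastic shear modulus of the slab.
#' @param n node counts (default `c(96, 32)`).
#' @param plate_amp,plate_omega plate velocity law.
#' @param eta_ratio,rho_ratio thrombus/blood property ratios (reference
#'   oscillatory-shear values: 2 and 2).
#' @param kappa_mode interstitial drag of the slab: `"none"` (default; the
#'   calibration experiment probes the viscoelastic response, and the
#'   published relaxation-time magnitudes are consistent only with a
#'   drag-free cell) or `"davies"`.
#' @param slab_extent NULL (default: sample fills the cell) or an x-interval
#'   like `c(2, 4)` for a mid-channel slab flanked by pure fluid.
#' @inheritParams make_channel_2d
#' @export
make_shear_cell <- function(VF, lambda_e, n = c(96, 32),
                            plate_amp = 0.2, plate_omega = 1.2 * pi,
                            eta_ratio = 2, rho_ratio = 2,
                            material = NULL, h_int = NULL,
                            kappa_mode = "none", slab_extent = NULL) {
  if (VF <= 0 || VF >= 1) stop("VF must lie in (0, 1)")
  g <- grid_create(n, length = c(6, 1), periodic = c(TRUE, FALSE))
  if (is.null(h_int)) h_int <- 2 * max(g$h)
  if (is.null(material))
    material <- material_params(rho1 = 1, rho2 = rho_ratio,
                                eta1 = 1, eta2 = eta_ratio,
                                lambda_e0 = lambda_e, sigma = 1e-3, h = h_int)
  m <- grid_mesh(g)
  phi <- if (is.null(slab_extent)) field_const(g, 1 - VF) else
    1 - VF * .axial_box(m[[1]], slab_extent[1], slab_extent[2], h_int)
  st <- simulation_state(g, phi = phi)
  plate <- function(t, X)
    list(rep(plate_amp * sin(plate_omega * t), length(X[[1]])),
         numeric(length(X[[1]])))
  vel_bc <- list(ylo = .noslip(2L),
                 yhi = list(type = "dirichlet", value = plate))
  make_scenario(g, material, st, vel_bc, pressure_outlet = NULL,
                kappa = list(mode = kappa_mode),
                name = "shear_cell",
                config = list(scenario = "shear_cell", VF = VF,
                              lambda_e = lambda_e, n = n,
                              plate_amp = plate_amp,
                              plate_omega = plate_omega, h_int = h_int))
}

#' Fusiform aneurysm with platelet deposition sites
#'
#' Axisymmetric lumen `R(x) = R0 (1 + A exp(-(x - x0)^2 / w^2))` realized by
#' volume penalization, with three deposition-site patches (proximal neck,
#' distal neck, bottom) and a pulsatile inlet.
#'
#' @param n node counts (default `c(80, 24, 24)`).
#' @param R0 inlet radius; `A` bulge amplitude (relative); `w` bulge width;
#'   `x0` bulge center.
#' @param waveform inlet scale function of time (default
#'   [pulsatile_waveform()] with default coefficients).
#' @param capture_radius deposition-site capture radius.
#' @inheritParams make_circular_vessel
#' @return a `tf_scenario`; the deposition sites are attached as
#'   `$sites` (a list of patch descriptors with surface sample points).
#' @export
make_aneurysm <- function(n = c(80, 24, 24), R0 = 0.5, A = 1.0, w = 1.5,
                          x0 = 5, material = NULL, inlet_max = 1,
                          waveform = NULL, rigid = "none",
                          inflow_ramp = 0.1, h_int = NULL,
                          kappa_wall = 1e-8, capture_radius = 0.15) {
  if (A * R0 >= 10 / 4) stop("bulge amplitude too large for the vessel length")
  side <- 2.4 * R0 * (1 + A)
  g <- grid_create(n, length = c(10, side, side), origin = c(0, -side / 2, -side / 2))
  if (is.null(h_int)) h_int <- 2 * max(g$h)
  if (is.null(material))
    material <- material_params(rho1 = 1, rho2 = 2, eta1 = 0.02, eta2 = 0.04,
                                lambda_e0 = 0.5, sigma = 1e-3, h = h_int)
  m <- grid_mesh(g)
  Rx <- R0 * (1 + A * exp(-(m[[1]] - x0)^2 / w^2))
  r <- sqrt(m[[2]]^2 + m[[3]]^2)
  hh <- max(g$h[-1])              # antialias over one cross-section cell
  wall_frac <- pmin(pmax((r - Rx) / hh + 0.5, 0), 1)
  drag_wall <- wall_frac * (material$eta1 / material$rho1) / kappa_wall
  st <- simulation_state(g, F = identity_deformation(g))
  if (is.null(waveform)) waveform <- function(t) pulsatile_waveform(t)
  inlet <- function(t, X) {
    sc <- .smooth_ramp(t, inflow_ramp) * waveform(t)
    rr2 <- X[[2]]^2 + X[[3]]^2
    ax <- sc * inlet_max * pmax(1 - rr2 / R0^2, 0)
    list(ax, numeric(length(ax)), numeric(length(ax)))
  }
  vel_bc <- list(xlo = list(type = "dirichlet", value = inlet),
                 xhi = list(type = "neumann"),
                 ylo = .noslip(3L), yhi = .noslip(3L),
                 zlo = .noslip(3L), zhi = .noslip(3L))
  sites <- list(
    deposition_site(x0 - w, width = 0.6, angle = -pi / 2, sector = pi,
                    R_of_x = function(x) R0 * (1 + A * exp(-(x - x0)^2 / w^2)),
                    capture_radius = capture_radius, label = "proximal_neck"),
    deposition_site(x0 + w, width = 0.6, angle = -pi / 2, sector = pi,
                    R_of_x = function(x) R0 * (1 + A * exp(-(x - x0)^2 / w^2)),
                    capture_radius = capture_radius, label = "distal_neck"),
    deposition_site(x0, width = 0.8, angle = -pi / 2, sector = pi / 2,
                    R_of_x = function(x) R0 * (1 + A * exp(-(x - x0)^2 / w^2)),
                    capture_radius = capture_radius, label = "bottom"))
  scn <- make_scenario(g, material, st, vel_bc, pressure_outlet = "xhi",
                       kappa = list(mode = "davies"), drag_static = drag_wall,
                       rigid = rigid,
                       F_inflow_mask = .face_mask(g, 1L, "lo"),
                       name = "aneurysm",
                       config = list(scenario = "aneurysm", n = n, R0 = R0,
                                     A = A, w = w, x0 = x0,
                                     inlet_max = inlet_max, h_int = h_int,
                                     kappa_wall = kappa_wall))
  scn$sites <- sites
  scn$lumen_radius <- function(x) R0 * (1 + A * exp(-(x - x0)^2 / w^2))
  scn
}

#' Platelet deposition site on a vessel surface
#'
#' A wall patch described by an axial interval and an angular sector on the
#' (axisymmetric) lumen surface, discretized into surface sample points.
#' @param x_center,width axial extent of the patch.
#' @param angle,sector angular center and half-width (radians; angle
#'   measured from +y toward +z, -pi/2 is the vessel bottom).
#' @param R_of_x lumen radius function.
#' @param capture_radius capture distance for platelet contact.
#' @param label site name.
#' @param n_samples surface sample points along each direction.
#' @export
deposition_site <- function(x_center, width, angle, sector, R_of_x,
                            capture_radius = 0.15, label = "site",
                            n_samples = 7L) {
  xs <- seq(x_center - width / 2, x_center + width / 2, length.out = n_samples)
  ths <- seq(angle - sector / 2, angle + sector / 2, length.out = n_samples)
  # polar convention: y = R cos(theta), z = R sin(theta); theta = -pi/2 is
  # the vessel bottom (z < 0 side is arbitrary but fixed)
  pts <- do.call(rbind, lapply(xs, function(x) {
    R <- R_of_x(x)
    cbind(x = rep(x, length(ths)), y = R * cos(ths), z = R * sin(ths))
  }))
  structure(list(points = pts, capture_radius = capture_radius,
                 label = label, x_center = x_center, angle = angle),
            class = "tf_site")
}

#' Generic pulsatile inlet waveform (truncated Fourier series)
#'
#' `f(t) = a0 + sum_k [ac_k cos(2 pi k (t - t_peak)/T) +
#'                     as_k sin(2 pi k (t - t_peak)/T)]`.
#' The default coefficients are the first four Fourier modes of a von-Mises
#' pulse with concentration 2, giving a positive waveform with mean `a0 = 1`
#' and a systolic peak about 3.2x the mean.
#' @param t time (vectorized).
#' @param coefficients list with `a0`, `ac`, `as`, `t_peak`.
#' @param period cycle period.
#' @export
pulsatile_waveform <- function(t, coefficients = pulsatile_coefficients(),
                               period = 1) {
  if (period <= 0) stop("period must be > 0")
  co <- coefficients
  th <- 2 * pi * (t - (co$t_peak %||% 0)) / period
  out <- rep(co$a0, length(t))
  for (k in seq_along(co$ac)) out <- out + co$ac[k] * cos(k * th)
  for (k in seq_along(co$as)) out <- out + co$as[k] * sin(k * th)
  out
}

#' Default pulsatile waveform coefficients
#' @export
pulsatile_coefficients <- function() {
  # 2 I_k(2) / I_0(2), k = 1..4: Fourier modes of exp(2(cos - 1)) pulse
  list(a0 = 1, ac = c(1.39552, 0.60439, 0.18661, 0.04448),
       as = numeric(0), t_peak = 0.15)
}

# ---- plain-text scenario configs ----------------------------------------

.known_config_keys <- c("scenario", "h_s", "h_c", "n", "u_max", "inlet_max",
                        "VF", "lambda_e", "plate_amp", "plate_omega",
                        "rigid", "h_int", "R0", "A", "w", "x0",
                        "kappa_wall", "seed")

#' Write / read a scenario config as plain-text YAML
#'
#' Round-trips the plain-value parameter list of a scenario; unknown keys
#' are rejected on read (typo protection).
#' @param config list (a scenario's `$config`).
#' @param path file path.
#' @export
write_scenario_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), .known_config_keys)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (is.null(cfg$scenario)) stop("config lacks a 'scenario' key")
  cfg
}

#' Rebuild a scenario from a plain-value config
#' @param cfg config list from [read_scenario_config()].
#' @export
build_scenario <- function(cfg) {
  args <- cfg[setdiff(names(cfg), c("scenario", "seed"))]
  switch(cfg$scenario,
         channel_2d = do.call(make_channel_2d, args),
         circular_vessel = do.call(make_circular_vessel, args),
         permeation_channel = do.call(make_permeation_channel, args),
         shear_cell = do.call(make_shear_cell, args),
         aneurysm = do.call(make_aneurysm, args),
         stop("unknown scenario: ", cfg$scenario))
}
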