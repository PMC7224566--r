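# Time integration of the coupled phase-field / flow / Eulerian-elasticity
# system.  One operator-split cycle per step:
#   (1) explicit SSP-RK2 transport of F (or the 2D curl potential psi) with
#       entropy-viscosity stabilization,
#   (2) semi-implicit conservative Cahn-Hilliard update of phi (fourth-order
#       operator factorized once, stabilized double-well splitting),
#   (3) velocity-correction projection step for (u, p) with constant
#       kinematic viscosity treated implicitly, the variable-viscosity
#       remainder explicitly, and the (stiff) Darcy drag pointwise
#       implicitly.
# All constant-coefficient operators are assembled and factorized once per
# run, so each step costs a handful of sparse triangular solves.

#' Solver configuration
#'
#' @param dt time step (> 0).
#' @param t_end final time.
#' @param out_times times at which snapshots are kept (default: final only).
#' @param n_proj number of pressure-projection passes per step (>= 1).
#' @param stabilize logical: entropy-viscosity stabilization of the
#'   hyperbolic F/psi transport.
#' @param c_E entropy-viscosity residual constant.
#' @param c_max entropy-viscosity first-order cap (`nu_max = c_max h |u|`).
#' @param S_stab stabilization constant of the double-well splitting
#'   (default `lambda * gamma / h^2`).
#' @param div_tol post-projection divergence tolerance (diagnostic; in
#'   (0, 1e-2]).
#' @param cfl_max advective CFL bound enforced at runtime (< 1).
#' @param spectral use Fourier differentiation on periodic axes for the
#'   F/psi transport.
#' @param record_every record diagnostics every k-th step.
#' @param phi_warn,phi_abort phase overshoot bounds: beyond
#'   `[-phi_warn, 1+phi_warn]` a diagnostic warning is raised, beyond
#'   `[-phi_abort, 1+phi_abort]` the run aborts (phi is never clipped,
#'   which would destroy mass conservation).
#' @export
solver_config <- function(dt, t_end, out_times = NULL, n_proj = 2L,
                          stabilize = TRUE, c_E = 1, c_max = 0.5,
                          S_stab = NULL, div_tol = 1e-3, cfl_max = 0.9,
                          spectral = TRUE, record_every = 1L,
                          phi_warn = 0.05, phi_abort = 0.2) {
  stopifnot(dt > 0, t_end > 0, n_proj >= 1)
  if (div_tol <= 0 || div_tol > 1e-2) stop("div_tol must lie in (0, 1e-2]")
  structure(list(dt = dt, t_end = t_end, out_times = out_times,
                 n_proj = as.integer(n_proj), stabilize = stabilize,
                 c_E = c_E, c_max = c_max, S_stab = S_stab,
                 div_tol = div_tol, cfl_max = cfl_max, spectral = spectral,
                 record_every = as.integer(record_every),
                 phi_warn = phi_warn, phi_abort = phi_abort),
            class = "tf_solver_config")
}

# derivative honouring the configured scheme on periodic axes
.d1 <- function(a, g, axis, spectral) {
  deriv1(a, g, axis, scheme = if (spectral && g$periodic[axis]) "spectral" else "central")
}

.advect_term <- function(q, u, g, spectral = FALSE) {
  out <- 0
  for (ax in seq_len(g$ndim)) out <- out + u[[ax]] * .d1(q, g, ax, spectral)
  out
}

.vel_magnitude <- function(u) sqrt(Reduce(`+`, lapply(u, function(c) c^2)))

#' Build the solver context for a scenario
#'
#' Assembles and factorizes every constant-coefficient operator (phase
#' biharmonic, velocity Helmholtz including static penalization/frozen-clot
#' drag, pressure Poisson) and precomputes boundary machinery.  The context
#' is an environment reused across steps.
#' @param scenario `tf_scenario` (see [make_scenario()]).
#' @param config `tf_solver_config`.
#' @export
solver_context <- function(scenario, config) {
  g <- scenario$grid
  mat <- scenario$material
  ctx <- new.env(parent = emptyenv())
  ctx$g <- g; ctx$mat <- mat; ctx$cfg <- config; ctx$scn <- scenario
  ctx$W <- grid_weights(g)

  # phase operator (skipped entirely for frozen-clot runs)
  S <- if (is.null(config$S_stab)) mat$lambda * mat$gamma / mat$h^2 else config$S_stab
  ctx$S_stab <- S
  if (!identical(scenario$rigid, "frozen"))
    ctx$ch <- ch_factor(g, config$dt, mat$tau, mat$lambda, S)

  # velocity Dirichlet machinery
  faces <- scenario$vel_bc
  dmask <- array(FALSE, dim = g$n)
  for (f in names(faces)) if (identical(faces[[f]]$type, "dirichlet")) {
    axis <- match(substr(f, 1, 1), c("x", "y", "z"))
    if (!g$periodic[axis]) dmask <- dmask | .face_mask(g, axis, substr(f, 2, 3))
  }
  ctx$dmask <- dmask
  ctx$bvals <- function(t) {
    out <- replicate(g$ndim, array(0, dim = g$n), simplify = FALSE)
    for (f in names(faces)) {
      bc <- faces[[f]]
      if (!identical(bc$type, "dirichlet")) next
      axis <- match(substr(f, 1, 1), c("x", "y", "z"))
      if (g$periodic[axis]) next
      msk <- .face_mask(g, axis, substr(f, 2, 3))
      vals <- bc$value(t, .face_coords(g, axis, substr(f, 2, 3)))
      for (c in seq_len(g$ndim)) out[[c]][msk] <- vals[[c]]
    }
    out
  }

  # reference scales for the constant-coefficient splittings
  ctx$nu0 <- max(mat$eta1 / mat$rho1, mat$eta2 / mat$rho2)
  ctx$rho0 <- min(mat$rho1, mat$rho2)

  # semi-implicit elastic stiffness shift (defect correction): adds
  # dt * max(lambda_e (1 - phi)) / rho0 to the implicit viscosity and the
  # same Laplacian explicitly, removing the elastic-wave step restriction
  # with an O(dt^2) consistency error
  lam_eff <- .lambda_e_field(scenario$state0$phi, ctx) * (1 - scenario$state0$phi)
  ctx$nu_imp <- ctx$nu0 + config$dt * max(lam_eff, 0) / ctx$rho0

  # static drag (wall penalization, frozen clot)
  drag <- scenario$drag_static
  if (is.null(drag)) drag <- array(0, dim = g$n)
  ctx$drag_static <- drag
  ctx$helm <- helmholtz_factor(g, 1 / config$dt + drag, ctx$nu_imp, dmask)

  # pressure Poisson: Dirichlet at the outlet face if present, pinned else
  pmask <- NULL
  if (!is.null(scenario$pressure_outlet)) {
    f <- scenario$pressure_outlet
    axis <- match(substr(f, 1, 1), c("x", "y", "z"))
    pmask <- .face_mask(g, axis, substr(f, 2, 3))
  }
  ctx$pois <- poisson_factor(g, pmask)

  ctx$ev_prev <- NULL
  ctx$diag <- list()
  ctx$nstep <- 0L
  ctx
}

# mixture fields at the current phi ---------------------------------------

.mixture_fields <- function(phi, mat) {
  list(rho = mixture_property(phi, mat$rho1, mat$rho2),
       eta = mixture_property(phi, mat$eta1, mat$eta2))
}

.kappa_field <- function(phi, ctx) {
  ks <- ctx$scn$kappa
  if (is.null(ks) || identical(ks$mode, "none")) return(NULL)
  if (!is.null(ks$field)) return(ks$field)
  if (identical(ks$mode, "davies"))
    return(permeability_field(phi, ctx$mat, "davies",
                              kappa_free = ks$kappa_free %||% 1e10))
  stop("unknown permeability mode: ", ks$mode)
}

.lambda_e_field <- function(phi, ctx) {
  md <- ctx$scn$lambda_e_mode %||% "constant"
  if (identical(ctx$scn$rigid, "literal")) return(array(0, dim = dim(phi)))
  elastic_modulus_field(phi, ctx$mat, md)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# entropy-viscosity field shared by the transported components ------------

# entropy-viscosity cap: first-order bound scaled by the FINE grid spacing
# (on anisotropic grids the explicit diffusion stability is set by the
# smallest spacing), additionally clamped by the explicit-step stability
# limit 0.2 * hmin^2 / dt.  The cap is tapered to zero on the two planes
# nearest each non-periodic boundary: the transported deviations carry
# genuine boundary gradients there, and the zero-flux closure of the
# stabilizing diffusion would otherwise distort them (those rows are
# boundary-condition-dominated and need no stabilization).
.ev_cap <- function(ctx, u) {
  g <- ctx$g; cfg <- ctx$cfg
  hmin <- min(g$h)
  cap <- pmin(cfg$c_max * hmin * .vel_magnitude(u), 0.2 * hmin^2 / cfg$dt)
  if (is.null(ctx$ev_edge_mask)) {
    msk <- array(1, dim = g$n)
    for (ax in seq_len(g$ndim)) {
      if (g$periodic[ax]) next
      tf <- .axis_to_front(msk, ax)
      m <- tf$m; n <- nrow(m)
      m[c(1L, 2L, n - 1L, n), ] <- 0
      msk <- .axis_from_front(m, tf$d, ax)
    }
    ctx$ev_edge_mask <- msk
  }
  cap * ctx$ev_edge_mask
}

.entropy_viscosity <- function(ctx, qlist, srclist, u) {
  g <- ctx$g; cfg <- ctx$cfg
  nu_max <- .ev_cap(ctx, u)
  if (!cfg$stabilize) return(array(0, dim = g$n))
  prev <- ctx$ev_prev
  if (is.null(prev)) return(array(0, dim = g$n))
  rmax <- array(0, dim = g$n)
  for (k in seq_along(qlist)) {
    R <- (qlist[[k]] - prev$q[[k]]) / prev$dt + .advect_term(qlist[[k]], u, g, cfg$spectral)
    if (!is.null(srclist)) R <- R - srclist[[k]]
    denom <- max(abs(qlist[[k]] - mean(qlist[[k]])), 1e-12)
    rmax <- pmax(rmax, abs(R) / denom)
  }
  pmin(nu_max, cfg$c_E * min(g$h)^2 * rmax)
}

.entropy_viscosity_phi <- function(ctx, phi, u) {
  g <- ctx$g; cfg <- ctx$cfg
  nu_max <- .ev_cap(ctx, u)
  if (!cfg$stabilize) return(NULL)
  prev <- ctx$ev_prev_phi
  if (is.null(prev)) return(nu_max * 0)
  R <- (phi - prev$q) / prev$dt + .advect_term(phi, u, g, FALSE)
  denom <- max(abs(phi - mean(phi)), 1e-12)
  pmin(nu_max, cfg$c_E * min(g$h)^2 * abs(R) / denom)
}

# compact flux-form variable-coefficient diffusion div(nu grad q):
# face-averaged nu, tight second-difference stencil (damps grid-scale
# sawtooth, which a wide first-derivative-of-first-derivative stencil
# cannot), zero-flux at non-periodic boundaries
.ev_diffuse <- function(q, nu_e, g, spectral = FALSE) {
  out <- 0
  for (ax in seq_len(g$ndim)) {
    h2 <- g$h[ax]^2
    tq <- .axis_to_front(q, ax); tn <- .axis_to_front(nu_e, ax)
    m <- tq$m; nu <- tn$m
    n <- nrow(m)
    if (g$periodic[ax]) {
      up <- c(2:n, 1L); dn <- c(n, 1:(n - 1L))
    } else {
      up <- c(2:n, n); dn <- c(1L, 1:(n - 1L))   # edge replication: zero flux
    }
    nup <- (nu + nu[up, , drop = FALSE]) / 2
    ndn <- (nu + nu[dn, , drop = FALSE]) / 2
    d <- (nup * (m[up, , drop = FALSE] - m) -
            ndn * (m - m[dn, , drop = FALSE])) / h2
    out <- out + .axis_from_front(d, tq$d, ax)
  }
  out
}

#' Advance the deformation gradient one step
#'
#' Explicit SSP-RK2 step of `dF/dt + u.grad F = (grad u) F` (convention
#' `(grad u)_ij = du_i/dx_j`), advancing the deviation `F - I` with
#' entropy-viscosity artificial diffusion.  Preserves the row-divergence-free
#' property to stencil commutation error.
#' @param F named component list.
#' @param u velocity component list.
#' @param g `tf_grid`.
#' @param dt time step.
#' @param nu_e entropy-viscosity field (NULL for none).
#' @param inflow_mask logical array where `F = I` is re-imposed, or NULL.
#' @param spectral use spectral derivatives on periodic axes.
#' @export
advance_deformation <- function(F, u, g, dt, nu_e = NULL, inflow_mask = NULL,
                                spectral = TRUE) {
  umax <- max(abs(unlist(lapply(u, range))))
  if (dt * umax / min(g$h) >= 1) stop("CFL violation in advance_deformation")
  nd <- g$ndim
  gradu <- lapply(seq_len(nd), function(i)
    lapply(seq_len(nd), function(j) .d1(u[[i]], g, j, spectral)))
  rhs <- function(G) {
    Fful <- G
    for (i in seq_len(nd)) {
      nm <- paste0("F", i, i)
      Fful[[nm]] <- Fful[[nm]] + 1
    }
    out <- list()
    for (i in seq_len(nd)) for (j in seq_len(nd)) {
      nm <- paste0("F", i, j)
      stretch <- 0
      for (k in seq_len(nd)) stretch <- stretch + gradu[[i]][[k]] * Fful[[paste0("F", k, j)]]
      term <- -.advect_term(G[[nm]], u, g, spectral) + stretch
      if (!is.null(nu_e)) term <- term + .ev_diffuse(G[[nm]], nu_e, g, spectral)
      out[[nm]] <- term
    }
    out
  }
  G <- F
  for (i in seq_len(nd)) G[[paste0("F", i, i)]] <- G[[paste0("F", i, i)]] - 1
  L1 <- rhs(G)
  G1 <- mapply(function(q, l) q + dt * l, G, L1, SIMPLIFY = FALSE)
  L2 <- rhs(G1)
  Gn <- mapply(function(q, q1, l) 0.5 * q + 0.5 * (q1 + dt * l), G, G1, L2,
               SIMPLIFY = FALSE)
  if (!is.null(inflow_mask))
    Gn <- lapply(Gn, function(q) { q[inflow_mask] <- 0; q })
  for (i in seq_len(nd)) Gn[[paste0("F", i, i)]] <- Gn[[paste0("F", i, i)]] + 1
  Gn
}

#' Advance the 2D curl potential one step
#'
#' Explicit SSP-RK2 step of `d psi/dt + u.grad psi = 0`, integrated for the
#' deviation from the identity potential `(y, -x)` (whose advection
#' contributes the exact source `-(v, -u)`), with entropy-viscosity
#' stabilization.
#' @param psi list of 2 component arrays.
#' @inheritParams advance_deformation
#' @export
advance_psi <- function(psi, u, g, dt, nu_e = NULL, inflow_mask = NULL,
                        spectral = TRUE) {
  if (g$ndim != 2L) stop("advance_psi is 2D only")
  umax <- max(abs(unlist(lapply(u, range))))
  if (dt * umax / min(g$h) >= 1) stop("CFL violation in advance_psi")
  pid <- identity_potential(g)
  src <- list(-u[[2]], u[[1]])     # -(u.grad) psi_id = (-v, u)
  dev <- list(psi[[1]] - pid[[1]], psi[[2]] - pid[[2]])
  rhs <- function(q, k) {
    term <- -.advect_term(q, u, g, spectral) + src[[k]]
    if (!is.null(nu_e)) term <- term + .ev_diffuse(q, nu_e, g, spectral)
    term
  }
  out <- vector("list", 2L)
  for (k in 1:2) {
    q <- dev[[k]]
    q1 <- q + dt * rhs(q, k)
    qn <- 0.5 * q + 0.5 * (q1 + dt * rhs(q1, k))
    if (!is.null(inflow_mask)) qn[inflow_mask] <- 0
    out[[k]] <- qn + pid[[k]]
  }
  out
}

#' Advance the phase field one semi-implicit step
#'
#' Conservative Cahn-Hilliard update
#' `(phi^{n+1}-phi^n)/dt + u.grad phi^n = tau Lap(mu1)` with the linear
#' fourth-order part implicit (factorized operator in `ctx`) and the
#' double-well and elastic parts explicit with stabilization shift `S`.
#' With zero-flux boundaries and `u = 0`, `int phi` is conserved to solver
#' precision.
#' @param state `tf_state`.
#' @param ctx solver context.
#' @param F_new deformation tensor used in the elastic part of mu1
#'   (defaults to the state's).
#' @return updated phi array.
#' @export
advance_phase <- function(state, ctx, F_new = NULL) {
  g <- ctx$g; mat <- ctx$mat; cfg <- ctx$cfg
  dt <- cfg$dt
  u <- state$u
  if (is.null(F_new)) F_new <- state_deformation(state)

  # advective half: SSP-RK2 with entropy-viscosity stabilization (forward
  # Euler + centred differences alone is weakly unstable over long runs)
  nu_e <- .entropy_viscosity_phi(ctx, state$phi, u)
  rhs_adv <- function(q) {
    term <- -.advect_term(q, u, g, FALSE)
    if (!is.null(nu_e)) term <- term + .ev_diffuse(q, nu_e, g, FALSE)
    term
  }
  q1 <- state$phi + dt * rhs_adv(state$phi)
  phi <- 0.5 * state$phi + 0.5 * (q1 + dt * rhs_adv(q1))
  ctx$ev_prev_phi <- list(q = phi, dt = dt)

  # Cahn-Hilliard half: implicit linear fourth-order part, stabilized
  # explicit double-well and elastic parts
  lam_e <- .lambda_e_field(phi, ctx)
  e_phi <- (lam_e / 2) * trace_FtF_minus_I(F_new)
  expl <- mat$lambda * mat$gamma * double_well_derivative(phi, mat$h) +
    e_phi - ctx$S_stab * phi
  rhs_w <- as.vector(ctx$W) * as.vector(phi / dt) -
    mat$tau * as.vector(ctx$ch$K %*% as.vector(expl))
  phi_new <- ctx$ch$solve(rhs_w)
  lo <- min(phi_new); hi <- max(phi_new)
  if (lo < -cfg$phi_abort || hi > 1 + cfg$phi_abort)
    stop(sprintf("phase field overshoot out of bounds: range [%.3f, %.3f]", lo, hi))
  if (lo < -cfg$phi_warn || hi > 1 + cfg$phi_warn)
    warning(sprintf("phase field overshoot: range [%.3f, %.3f]", lo, hi))
  phi_new
}

#' Advance velocity and pressure one projection step
#'
#' Velocity correction scheme: semi-implicit Helmholtz solve per component
#' (constant kinematic viscosity `nu0` implicit, variable-viscosity
#' remainder and all source terms explicit, static drag in the matrix),
#' pointwise-implicit dynamic Darcy drag, then `n_proj` incremental
#' pressure-projection passes.
#' @param state `tf_state` (holds `u`, `p` at time n).
#' @param ctx solver context.
#' @param phi_new,F_new fields at time n+1 used for the source terms.
#' @return list `u`, `p`, `div_norm`.
#' @export
advance_flow <- function(state, ctx, phi_new = NULL, F_new = NULL) {
  g <- ctx$g; mat <- ctx$mat; cfg <- ctx$cfg
  dt <- cfg$dt
  phi <- phi_new %||% state$phi
  F <- F_new %||% state_deformation(state)
  mix <- .mixture_fields(phi, mat)
  rho <- mix$rho; eta <- mix$eta
  lam_e <- .lambda_e_field(phi, ctx)
  u <- state$u; p <- state$p
  nd <- g$ndim

  # explicit momentum sources (per unit mass)
  fel <- tensor_divergence(elastic_stress(F, phi, lam_e), g)
  fst <- surface_tension_force(phi, mat$lambda, g)
  geta <- gradient(eta, g)
  gp <- gradient(p, g)
  bodyf <- if (is.null(ctx$scn$body_force)) NULL else ctx$scn$body_force(state$time, g)
  rhs <- vector("list", nd)
  for (c in seq_len(nd)) {
    lap_uc <- laplacian(u[[c]], g, bc = "neumann")
    visc <- eta * lap_uc
    for (ax in seq_len(nd)) visc <- visc + geta[[ax]] * .d1(u[[c]], g, ax, FALSE)
    r <- -.advect_term(u[[c]], u, g, FALSE) - gp[[c]] / rho +
      (visc / rho - ctx$nu_imp * lap_uc) + (fel[[c]] + fst[[c]]) / rho
    if (!is.null(bodyf)) r <- r + bodyf[[c]] / rho
    rhs[[c]] <- u[[c]] / dt + r
  }

  bv <- ctx$bvals(state$time + dt)
  ustar <- lapply(seq_len(nd), function(c) ctx$helm$solve(rhs[[c]], bv[[c]]))

  # dynamic Darcy drag, pointwise implicit
  kap <- .kappa_field(phi, ctx)
  if (!is.null(kap) && !identical(ctx$scn$rigid, "frozen")) {
    D <- eta * (1 - phi) / (rho * kap)
    fac <- 1 / (1 + dt * D)
    ustar <- lapply(ustar, function(c) c * fac)
    for (c in seq_len(nd)) ustar[[c]][ctx$dmask] <- bv[[c]][ctx$dmask]
  }

  # incremental pressure projection
  for (pass in seq_len(cfg$n_proj)) {
    d <- divergence(ustar, g)
    psi_p <- ctx$pois$solve(-(ctx$rho0 / dt) * d)
    gpsi <- gradient(psi_p, g)
    ustar <- lapply(seq_len(nd), function(c) ustar[[c]] - (dt / ctx$rho0) * gpsi[[c]])
    p <- p + psi_p
    for (c in seq_len(nd)) ustar[[c]][ctx$dmask] <- bv[[c]][ctx$dmask]
  }
  dnorm <- .interior_div_norm(ustar, g)
  list(u = ustar, p = p, div_norm = dnorm)
}

# max-norm of the divergence over strict-interior nodes
.interior_div_norm <- function(u, g) {
  d <- divergence(u, g)
  idx <- lapply(seq_len(g$ndim), function(a)
    if (g$periodic[a]) seq_len(g$n[a]) else 2:(g$n[a] - 1L))
  max(abs(do.call(`[`, c(list(d), idx))))
}

#' One full operator-split cycle
#'
#' (1) F/psi transport, (2) phase update, (3) flow update; advances time by
#' `dt` and appends a diagnostics record (energies, volume fraction, phase
#' mass, divergence norm, probe velocities).
#' @param state `tf_state`.
#' @param ctx solver context from [solver_context()].
#' @export
step <- function(state, ctx) {
  g <- ctx$g; cfg <- ctx$cfg; mat <- ctx$mat
  dt <- cfg$dt
  umax <- max(abs(unlist(lapply(state$u, range))), 0)
  if (dt * umax / min(g$h) >= cfg$cfl_max)
    stop(sprintf("CFL violation: dt*|u|/h = %.3f", dt * umax / min(g$h)))

  frozen <- identical(ctx$scn$rigid, "frozen")
  inflow_mask <- ctx$scn$F_inflow_mask

  # (1) deformation transport
  if (!frozen) {
    if (!is.null(state$psi)) {
      qs <- state$psi
      srcs <- list(-state$u[[2]], state$u[[1]])
      pid <- identity_potential(g)
      qdev <- list(qs[[1]] - pid[[1]], qs[[2]] - pid[[2]])
      nu_e <- .entropy_viscosity(ctx, qdev, srcs, state$u)
      psi_new <- advance_psi(qs, state$u, g, dt, nu_e = nu_e,
                             inflow_mask = inflow_mask, spectral = cfg$spectral)
      ctx$ev_prev <- list(q = list(psi_new[[1]] - pid[[1]], psi_new[[2]] - pid[[2]]), dt = dt)
      state$psi <- psi_new
      F_new <- curl_potential_to_F(psi_new, g,
                                   scheme = if (cfg$spectral && any(g$periodic)) "central" else "central")
    } else {
      G <- state$F
      for (i in seq_len(g$ndim)) G[[paste0("F", i, i)]] <- G[[paste0("F", i, i)]] - 1
      nu_e <- .entropy_viscosity(ctx, G, NULL, state$u)
      F_new <- advance_deformation(state$F, state$u, g, dt, nu_e = nu_e,
                                   inflow_mask = inflow_mask, spectral = cfg$spectral)
      Gn <- F_new
      for (i in seq_len(g$ndim)) Gn[[paste0("F", i, i)]] <- Gn[[paste0("F", i, i)]] - 1
      ctx$ev_prev <- list(q = Gn, dt = dt)
      state$F <- F_new
    }
  } else {
    F_new <- state_deformation(state)
  }

  # (2) phase update
  if (!frozen) state$phi <- advance_phase(state, ctx, F_new = F_new)

  # (3) flow update
  fl <- advance_flow(state, ctx, phi_new = state$phi, F_new = F_new)
  state$u <- fl$u
  state$p <- fl$p
  state$time <- state$time + dt

  ctx$nstep <- ctx$nstep + 1L
  if (ctx$nstep %% cfg$record_every == 0L) {
    en <- total_energy(state, mat, lambda_e = .lambda_e_field(state$phi, ctx))
    rho <- .mixture_fields(state$phi, mat)$rho
    ekin <- field_integral(rho / 2 * .vel_magnitude(state$u)^2, g)
    row <- list(time = state$time,
                energy_mixing = attr(en, "mixing"),
                energy_elastic = attr(en, "elastic"),
                energy_kinetic = ekin,
                energy_total = as.numeric(en) + ekin,
                vf = bulk_volume_fraction(state$phi, g),
                phase_mass = field_integral(state$phi, g),
                div_norm = fl$div_norm,
                umax = max(abs(unlist(lapply(state$u, range)))),
                phi_min = min(state$phi), phi_max = max(state$phi))
    pr <- ctx$scn$probes
    if (!is.null(pr)) for (k in seq_along(pr)) {
      idx <- matrix(pr[[k]], nrow = 1)
      row[[paste0("probe", k, "_u")]] <- state$u[[1]][idx]
    }
    ctx$diag[[length(ctx$diag) + 1L]] <- row
  }
  state
}

#' Run a scenario to completion
#'
#' Deterministic given scenario + config.  Returns the trajectory:
#' snapshots at the requested output times, a diagnostics data frame, and
#' the final state.  On a sub-step failure the run aborts with the last
#' valid state attached to the error condition.
#' @param scenario `tf_scenario`.
#' @param config `tf_solver_config`.
#' @param quiet suppress progress output.
#' @export
run <- function(scenario, config, quiet = TRUE) {
  ctx <- solver_context(scenario, config)
  state <- scenario$state0
  nsteps <- max(1L, round(config$t_end / config$dt))
  out_times <- config$out_times
  snaps <- list()
  for (k in seq_len(nsteps)) {
    state <- tryCatch(step(state, ctx), error = function(e) {
      e$last_state <- state
      stop(e)
    })
    if (!is.null(out_times) &&
        any(abs(state$time - out_times) < config$dt / 2))
      snaps[[length(snaps) + 1L]] <- state
    if (!quiet && k %% 50L == 0L)
      message(sprintf("  step %d/%d  t = %.3f", k, nsteps, state$time))
  }
  diag <- do.call(rbind, lapply(ctx$diag, function(r) as.data.frame(r)))
  structure(list(final = state, snapshots = snaps, diagnostics = diag,
                 scenario = scenario, config = config),
            class = "tf_trajectory")
}

#' @export
print.tf_trajectory <- function(x, ...) {
  cat(sprintf("<tf_trajectory> %s  t = %.4g  %d snapshots, %d diagnostic rows\n",
              x$scenario$name %||% "scenario", x$final$time,
              length(x$snapshots), NROW(x$diagnostics)))
  invisible(x)
}
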