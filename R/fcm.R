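# Coarse-grained platelet transport and aggregation (force-coupling-method
# style): passive -> triggered -> activated state machine, Morse attraction
# and exponential repulsion between activated pseudo-platelets, Gaussian
# envelope averaging for particle-fluid coupling, and conversion of the
# Lagrangian aggregate into the volume-fraction field handed to the
# phase-field solver.

#' FCM configuration
#'
#' @param r_p passive platelet radius (1.5 um physically; nondimensional in
#'   scaled-down runs).
#' @param r_eff_factor activated (pseudo-platelet) radius multiplier
#'   (default 60: platelets plus associated fibrin).
#' @param tau_act activation delay in seconds, in `[0.1, 0.3]`.
#' @param morse_De,morse_beta,morse_r0_gap Morse well depth, inverse width,
#'   and equilibrium gap added to the radii sum.  `morse_De = NULL` scales
#'   the well depth to balance Stokes drag at the reference wall shear
#'   rate (placeholder calibration: the shear-rate-resolved force table of
#'   the original model is not public; recalibrate for quantitative use).
#' @param repulse_A,repulse_len exponential repulsion amplitude and decay
#'   length (amplitude `NULL`: matched to the Morse well depth).
#' @param shear_bins boundaries of the shear-rate bins (1/s); the Morse
#'   depth is halved in the upper bin (weaker aggregation at high shear).
#' @param envelope_factor Gaussian envelope width as a fraction of the
#'   radius (`sigma = radius / sqrt(pi)` by default).
#' @param capture_margin extra contact distance for state triggering.
#' @param mobility particle mobility multiplying interaction forces
#'   (`NULL`: Stokes drag `1/(6 pi eta r)`).
#' @param eta fluid viscosity for the default mobility.
#' @param coupling `"one_way"` (particles feel the flow) or `"two_way"`.
#' @param seed RNG seed for the insertion machinery.
#' @export
fcm_config <- function(r_p = 0.01, r_eff_factor = 60, tau_act = 0.2,
                       morse_De = NULL, morse_beta = NULL, morse_r0_gap = 0,
                       repulse_A = NULL, repulse_len = NULL,
                       shear_bins = c(0, 100, Inf), gamma_ref = 100,
                       envelope_factor = 1 / sqrt(pi),
                       capture_margin = 0.05, mobility = NULL, eta = 0.02,
                       coupling = c("one_way", "two_way"), seed = 1L) {
  coupling <- match.arg(coupling)
  if (tau_act < 0.1 || tau_act > 0.3)
    stop("tau_act must lie in [0.1, 0.3] s")
  if (r_p <= 0) stop("r_p must be > 0")
  r_eff <- r_p * r_eff_factor
  if (is.null(morse_beta)) morse_beta <- 2 / r_eff
  if (is.null(repulse_len)) repulse_len <- r_eff / 4
  if (is.null(morse_De)) {
    # well depth scaled so the peak attraction balances Stokes drag at the
    # reference wall shear rate gamma_ref (in simulation units; placeholder
    # calibration, see docs)
    f_drag <- 6 * pi * eta * r_eff * (gamma_ref * r_eff)
    morse_De <- 2 * 2 * f_drag / morse_beta
  }
  if (is.null(repulse_A)) repulse_A <- morse_De * morse_beta
  list(r_p = r_p, r_eff_factor = r_eff_factor, r_eff = r_eff,
       tau_act = tau_act, morse_De = morse_De, morse_beta = morse_beta,
       morse_r0_gap = morse_r0_gap, repulse_A = repulse_A,
       repulse_len = repulse_len, shear_bins = shear_bins,
       gamma_ref = gamma_ref,
       envelope_factor = envelope_factor, capture_margin = capture_margin,
       mobility = mobility, eta = eta, coupling = coupling,
       cutoff = 5 / morse_beta, seed = as.integer(seed))
}

#' Seed platelets inside a vessel lumen
#'
#' Draws `n` passive platelets with uniform axial placement and a
#' near-wall-weighted radial profile (a margination surrogate).
#' Reproducible given `seed`.
#'
#' @param domain list describing the lumen: `x_range`, and either a
#'   constant `radius` or a function `R_of_x(x)`.
#' @param n number of platelets.
#' @param profile radial density on `[0, 1]` (fraction of local radius);
#'   default is the near-wall-peaked piecewise-linear margination profile.
#' @param seed RNG seed.
#' @param r_p platelet radius.
#' @return `PlateletEnsemble` data frame: `id`, `x`, `y`, `z`, `radius`,
#'   `state`, `trigger_time`, `adhered`.
#' @export
seed_platelets <- function(domain, n, profile = NULL, seed = 1L, r_p = 0.01) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(profile)) profile <- margination_profile
  set.seed(seed)
  R_of_x <- if (!is.null(domain$R_of_x)) domain$R_of_x else
    function(x) rep(domain$radius, length(x))
  xr <- domain$x_range
  # rejection sampling of the radial fraction s in [0, 1] with density
  # profile(s) * s (cylindrical measure)
  fmax <- max(profile(seq(0, 1, length.out = 512)) * seq(0, 1, length.out = 512)) * 1.05
  xs <- ys <- zs <- numeric(0)
  while (length(xs) < n) {
    m <- 2L * (n - length(xs)) + 16L
    x <- stats::runif(m, xr[1], xr[2])
    s <- stats::runif(m)
    th <- stats::runif(m, 0, 2 * pi)
    acc <- stats::runif(m, 0, fmax) < profile(s) * s
    R <- pmax(R_of_x(x) - r_p, r_p)
    xs <- c(xs, x[acc]); ys <- c(ys, (s * R * cos(th))[acc])
    zs <- c(zs, (s * R * sin(th))[acc])
  }
  data.frame(id = seq_len(n), x = xs[1:n], y = ys[1:n], z = zs[1:n],
             radius = r_p, state = rep("passive", n),
             trigger_time = NA_real_, adhered = FALSE,
             stringsAsFactors = FALSE)
}

#' Near-wall-peaked margination profile
#'
#' Piecewise-linear relative density of platelets versus the radial
#' fraction `s = r / R(x)`: flat core, rising steeply past `s = 0.7` to a
#' five-fold near-wall excess.
#' @param s radial fraction in `[0, 1]`.
#' @export
margination_profile <- function(s) ifelse(s < 0.7, 1, 1 + 4 * (s - 0.7) / 0.3)

#' Update platelet states (passive -> triggered -> activated)
#'
#' Passive platelets touching a deposition site or an activated platelet
#' (centre distance below the radii sum plus the capture margin) become
#' triggered; triggered platelets activate (irreversibly) once
#' `t >= trigger_time + tau_act`, growing to the effective radius.
#' Activated platelets in contact with a site or an already-adhered
#' platelet adhere (are frozen in place), which is how aggregates anchor.
#' @param ensemble `PlateletEnsemble` data frame.
#' @param sites list of `tf_site` deposition sites.
#' @param t current time.
#' @param config from [fcm_config()].
#' @export
update_states <- function(ensemble, sites, t, config) {
  # triggered -> activated after the delay
  trig <- ensemble$state == "triggered" &
    t >= ensemble$trigger_time + config$tau_act
  if (any(trig)) {
    ensemble$state[trig] <- "activated"
    ensemble$radius[trig] <- config$r_eff
  }
  site_pts <- do.call(rbind, lapply(sites, function(s) s$points))
  pas <- which(ensemble$state == "passive")
  if (length(pas)) {
    pos <- as.matrix(ensemble[pas, c("x", "y", "z")])
    touched <- rep(FALSE, length(pas))
    for (s in sites) {
      d2 <- .min_dist2(pos, s$points)
      touched <- touched | d2 < (s$capture_radius + ensemble$radius[pas] +
                                   config$capture_margin)^2
    }
    act <- which(ensemble$state == "activated")
    if (length(act)) {
      apos <- as.matrix(ensemble[act, c("x", "y", "z")])
      d2 <- .min_dist2(pos, apos)
      touched <- touched | d2 < (config$r_eff + ensemble$radius[pas] +
                                   config$capture_margin)^2
    }
    if (any(touched)) {
      idx <- pas[touched]
      ensemble$state[idx] <- "triggered"
      ensemble$trigger_time[idx] <- t
    }
  }
  # adhesion: activated, not yet adhered, in contact with a site or an
  # adhered platelet
  free_act <- which(ensemble$state == "activated" & !ensemble$adhered)
  if (length(free_act)) {
    pos <- as.matrix(ensemble[free_act, c("x", "y", "z")])
    stick <- rep(FALSE, length(free_act))
    if (!is.null(site_pts) && length(sites)) {
      cr <- max(vapply(sites, function(s) s$capture_radius, numeric(1)))
      stick <- .min_dist2(pos, site_pts) <
        (cr + ensemble$radius[free_act] + config$capture_margin)^2
    }
    adh <- which(ensemble$adhered)
    if (length(adh)) {
      apos <- as.matrix(ensemble[adh, c("x", "y", "z")])
      stick <- stick | .min_dist2(pos, apos) <
        (ensemble$radius[free_act] + config$r_eff + config$capture_margin)^2
    }
    ensemble$adhered[free_act[stick]] <- TRUE
  }
  ensemble
}

# squared distance from each row of `a` to its nearest row of `b`
.min_dist2 <- function(a, b) {
  if (!nrow(b)) return(rep(Inf, nrow(a)))
  out <- rep(Inf, nrow(a))
  for (j in seq_len(nrow(b))) {
    d2 <- (a[, 1] - b[j, 1])^2 + (a[, 2] - b[j, 2])^2 + (a[, 3] - b[j, 3])^2
    out <- pmin(out, d2)
  }
  out
}

#' Pairwise interaction forces between activated platelets
#'
#' Morse attraction `U = De (exp(-2 beta (r - r0)) - 2 exp(-beta (r - r0)))`
#' plus exponential repulsion `A exp(-r / l)` along the centre line,
#' between activated pairs only; pairs beyond the cutoff `5 / beta`
#' contribute nothing.  The Morse depth is read from the shear-rate bin of
#' `local_shear_rate` (halved in the high-shear bin).
#' Deposition-site sample points enter as fixed (stationary) activated
#' partners when `site_points` is given, so aggregates anchor at the sites.
#' @inheritParams update_states
#' @param local_shear_rate scalar or per-platelet shear rate (1/s).
#' @param site_points optional matrix of fixed anchor points (x, y, z).
#' @return n x 3 matrix of force vectors (Newton's third law holds by
#'   construction; forces on fixed anchors are discarded).
#' @export
pairwise_forces <- function(ensemble, config, local_shear_rate = 0,
                            site_points = NULL) {
  n <- nrow(ensemble)
  FF <- matrix(0, n, 3)
  act <- which(ensemble$state == "activated")
  nfree <- length(act)
  if (nfree == 0L) return(FF)
  pos <- as.matrix(ensemble[act, c("x", "y", "z")])
  rad <- ensemble$radius[act]
  if (!is.null(site_points) && nrow(site_points)) {
    pos <- rbind(pos, site_points)
    rad <- c(rad, rep(config$r_p, nrow(site_points)))
    act <- c(act, rep(NA_integer_, nrow(site_points)))
  }
  if (nrow(pos) < 2) return(FF)
  bin <- findInterval(local_shear_rate, config$shear_bins,
                      rightmost.closed = TRUE)
  De <- config$morse_De * if (bin[1] >= 2) 0.5 else 1
  cut2 <- config$cutoff^2
  cells <- .cell_list(pos, config$cutoff)
  prs <- .cell_pairs(cells)
  if (!nrow(prs)) return(FF)
  dx <- pos[prs[, 2], , drop = FALSE] - pos[prs[, 1], , drop = FALSE]
  r2 <- rowSums(dx^2)
  keep <- r2 < cut2
  prs <- prs[keep, , drop = FALSE]; dx <- dx[keep, , drop = FALSE]
  r <- sqrt(r2[keep])
  coincident <- r < 1e-12
  if (any(coincident)) {
    warning("coincident platelet centres: repulsion capped")
    r[coincident] <- 1e-12
  }
  r0 <- rad[prs[, 1]] + rad[prs[, 2]] + config$morse_r0_gap
  eb <- exp(-config$morse_beta * (r - r0))
  # dU/dr of the Morse potential; force on i is -(dU/dr) * rhat_{j->i}
  dUdr <- 2 * config$morse_beta * De * (eb - eb^2)
  rep_mag <- config$repulse_A * exp(-pmin(r / config$repulse_len, 500))
  fmag <- -dUdr + rep_mag           # positive = repulsive (along j->i on i)
  fmag <- pmin(fmag, config$repulse_A)   # cap at contact
  rhat <- dx / r
  for (k in seq_len(nrow(prs))) {
    i <- act[prs[k, 1]]; j <- act[prs[k, 2]]
    f <- fmag[k] * rhat[k, ]
    if (!is.na(j)) FF[j, ] <- FF[j, ] + f
    if (!is.na(i)) FF[i, ] <- FF[i, ] - f
  }
  FF
}

# uniform cell list: deterministic iteration order
.cell_list <- function(pos, cell) {
  key <- floor(sweep(pos, 2, apply(pos, 2, min)) / cell)
  id <- key[, 1] + 1e4 * key[, 2] + 1e8 * key[, 3]
  split(seq_len(nrow(pos)), id)
}

.cell_pairs <- function(cells) {
  # candidate pairs: within-cell and between all cells (cells built at the
  # cutoff length; neighbour enumeration over the modest cell count)
  ids <- names(cells)
  out <- list()
  num <- as.numeric(ids)
  kx <- num %% 1e4; ky <- ((num - kx) / 1e4) %% 1e4
  kz <- round(num / 1e8)
  for (a in seq_along(cells)) {
    ia <- cells[[a]]
    if (length(ia) > 1) {
      cmb <- utils::combn(ia, 2)
      out[[length(out) + 1L]] <- cbind(cmb[1, ], cmb[2, ])
    }
    for (b in seq_along(cells)) {
      if (b <= a) next
      if (abs(kx[a] - kx[b]) <= 1 && abs(ky[a] - ky[b]) <= 1 &&
          abs(kz[a] - kz[b]) <= 1) {
        ib <- cells[[b]]
        out[[length(out) + 1L]] <- cbind(rep(ia, each = length(ib)),
                                         rep(ib, times = length(ia)))
      }
    }
  }
  if (!length(out)) return(matrix(integer(0), 0, 2))
  do.call(rbind, out)
}

#' Advect platelets through a flow field
#'
#' Particle velocity is the Gaussian-envelope-weighted average of the local
#' fluid velocity plus mobility times the interaction force; explicit Euler
#' step.  Adhered platelets are frozen; platelets leaving the axial domain
#' are removed (and counted in the `removed` attribute).
#' @param ensemble `PlateletEnsemble`.
#' @param flow list: `u` (velocity component arrays), `grid` (`tf_grid`),
#'   optionally `scale(t)` multiplying the field (pulsatile modulation).
#' @param dt time step.
#' @param config from [fcm_config()].
#' @param t current time.
#' @param forces optional precomputed force matrix.
#' @export
advect_platelets <- function(ensemble, flow, dt, config, t = 0,
                             forces = NULL) {
  if (!nrow(ensemble)) return(ensemble)
  g <- flow$grid
  sc <- if (is.null(flow$scale)) 1 else flow$scale(t)
  mob <- ensemble$radius
  mobility <- if (is.null(config$mobility))
    1 / (6 * pi * config$eta * mob) else rep(config$mobility, nrow(ensemble))
  if (is.null(forces)) forces <- pairwise_forces(ensemble, config)
  vel <- envelope_velocity(ensemble, flow$u, g,
                           sigma = ensemble$radius * config$envelope_factor)
  # cap the interaction-driven velocity so no particle moves more than half
  # a radius per step under the (placeholder-calibrated) forces
  vint <- forces * mobility
  vcap <- 0.5 * ensemble$radius / dt
  vmag <- sqrt(rowSums(vint^2))
  over <- vmag > vcap
  if (any(over)) vint[over, ] <- vint[over, ] * (vcap[over] / vmag[over])
  vel <- vel * sc + vint
  mobile <- !ensemble$adhered
  ensemble$x[mobile] <- ensemble$x[mobile] + dt * vel[mobile, 1]
  ensemble$y[mobile] <- ensemble$y[mobile] + dt * vel[mobile, 2]
  ensemble$z[mobile] <- ensemble$z[mobile] + dt * vel[mobile, 3]
  xr <- range(g$coords[[1]])
  gone <- ensemble$x < xr[1] | ensemble$x > xr[2]
  removed <- sum(gone)
  ensemble <- ensemble[!gone, , drop = FALSE]
  attr(ensemble, "removed") <- removed
  ensemble
}

#' Gaussian-envelope-averaged fluid velocity at particle positions
#' @param ensemble `PlateletEnsemble`.
#' @param u velocity component arrays.
#' @param g `tf_grid`.
#' @param sigma per-particle envelope widths.
#' @return n x 3 matrix.
#' @export
envelope_velocity <- function(ensemble, u, g, sigma) {
  n <- nrow(ensemble)
  out <- matrix(0, n, 3)
  wt <- grid_weights(g)
  for (k in seq_len(n)) {
    w <- .envelope_weights(c(ensemble$x[k], ensemble$y[k], ensemble$z[k]),
                           sigma[k], g)
    for (d in seq_len(g$ndim))
      out[k, d] <- sum(w$w * u[[d]][w$idx]) / w$tot
  }
  out
}

# local Gaussian weights on the grid nodes within 3.5 sigma (returns linear
# indices and weights)
.envelope_weights <- function(p, sigma, g) {
  rngs <- lapply(seq_len(g$ndim), function(a) {
    co <- g$coords[[a]]
    i <- which(abs(co - p[a]) <= 3.5 * sigma)
    if (!length(i)) i <- which.min(abs(co - p[a]))
    i
  })
  idx <- as.matrix(expand.grid(rngs))
  d2 <- 0
  for (a in seq_len(g$ndim))
    d2 <- d2 + (g$coords[[a]][idx[, a]] - p[a])^2
  w <- exp(-d2 / (2 * sigma^2))
  lin <- idx[, 1]
  mulk <- g$n[1]
  for (a in seq_len(g$ndim)[-1]) {
    lin <- lin + (idx[, a] - 1L) * mulk
    mulk <- mulk * g$n[a]
  }
  list(idx = lin, w = w, tot = sum(w))
}

#' Reaction force field for two-way particle-flow coupling
#'
#' Spreads the negative of each particle's interaction force through its
#' Gaussian envelope onto the grid, as a force-per-volume field that can be
#' added to a scenario's `body_force` (the upgrade path from the default
#' one-way coupling; the default stays one-way because the bidirectional
#' problem at physiological counts is beyond desk scale).
#' @param ensemble `PlateletEnsemble`.
#' @param forces n x 3 matrix from [pairwise_forces()].
#' @param g flow `tf_grid`.
#' @param config from [fcm_config()].
#' @return list of `ndim` force-per-volume component arrays.
#' @export
fcm_reaction_force <- function(ensemble, forces, g, config) {
  nd <- g$ndim
  out <- replicate(nd, field_const(g, 0), simplify = FALSE)
  for (k in seq_len(nrow(ensemble))) {
    if (all(forces[k, ] == 0)) next
    sig <- ensemble$radius[k] * config$envelope_factor
    w <- .envelope_weights(c(ensemble$x[k], ensemble$y[k], ensemble$z[k]),
                           sig, g)
    norm <- (2 * pi * sig^2)^(-nd / 2)
    for (d in seq_len(nd))
      out[[d]][w$idx] <- out[[d]][w$idx] - forces[k, d] * norm * w$w
  }
  out
}

#' Stationarity of a platelet over one cardiac cycle
#'
#' True when the net displacement over the last full cycle is below 1/100
#' of the platelet diameter.
#' @param displacement net displacement over the last full cycle.
#' @param radius platelet radius.
#' @export
stationarity <- function(displacement, radius) {
  displacement < 2 * radius / 100
}

#' Local volume fraction of pseudo-platelets on a grid
#'
#' `Psi_fcm(x) = sum_n V_p^n Delta(x - Y^n)` with a normalized Gaussian
#' envelope `Delta` (integral one).  Requires the envelope to be resolved
#' (>= 3 cells per standard deviation).
#' @param ensemble `PlateletEnsemble` (typically the adhered/activated
#'   subset).
#' @param g deposit grid (`tf_grid`, usually finer than the flow grid).
#' @param config from [fcm_config()].
#' @param states which states contribute (default activated only).
#' @export
fcm_volume_fraction <- function(ensemble, g, config,
                                states = "activated") {
  out <- field_const(g, 0)
  sel <- which(ensemble$state %in% states)
  if (!length(sel)) return(out)
  sig_min <- min(ensemble$radius[sel]) * config$envelope_factor
  if (sig_min < 3 * max(g$h))
    stop(sprintf(paste0("envelope under-resolved: sigma = %.4g needs grid ",
                        "spacing <= %.4g (3 cells per sigma)"),
                 sig_min, sig_min / 3))
  nd <- g$ndim
  for (k in sel) {
    r <- ensemble$radius[k]
    sig <- r * config$envelope_factor
    Vp <- if (nd == 3L) 4 / 3 * pi * r^3 else pi * r^2
    w <- .envelope_weights(c(ensemble$x[k], ensemble$y[k], ensemble$z[k]),
                           sig, g)
    norm <- (2 * pi * sig^2)^(-nd / 2)
    out[w$idx] <- out[w$idx] + Vp * norm * w$w
  }
  out
}

#' Thrombus volume fraction from composition and the platelet field
#'
#' `VF = (Psi_f(c_Fbg) + Psi_p(c_plat)) * Psi_fcm`, with the platelet
#' contribution `Psi_p = c_plat * V_platelet` evaluated from the single
#' (passive) platelet volume; clipped to `[0, 1)` with the clipped fraction
#' attached as an attribute.
#' @param psi_fcm field from [fcm_volume_fraction()].
#' @param c_Fbg fibrinogen concentration (mg/mL).
#' @param c_plat platelet number density (1/volume, same units as psi_fcm's
#'   grid).
#' @param config from [fcm_config()].
#' @param rho_Fbg fibrinogen molecular density (mg/mL).
#' @export
thrombus_VF <- function(psi_fcm, c_Fbg, c_plat, config, rho_Fbg = 1400) {
  if (c_Fbg < 0 || c_plat < 0) stop("concentrations must be >= 0")
  psi_f <- if (c_Fbg > 0) fibrin_volume_fraction(c_Fbg, rho_Fbg) else 0
  psi_p <- c_plat * 4 / 3 * pi * config$r_p^3
  vf <- (psi_f + psi_p) * psi_fcm
  clipped <- mean(vf >= 1)
  vf <- pmin(pmax(vf, 0), 1 - 1e-9)
  attr(vf, "clipped_fraction") <- clipped
  vf
}

#' Convert a volume-fraction field to a phase-field initial condition
#'
#' `phi0 = 1 - VF`, followed by a diffusion-smoothing pass at length scale
#' `h`: explicit conservative (flux-form) heat steps totalling a diffusion
#' time `h^2 / 2`, with zero-flux boundaries.  The flux form preserves
#' `int (1 - phi0)` to rounding and the explicit steps respect the maximum
#' principle, so `phi0` stays in `[0, 1]`.
#' @param VF volume-fraction field in `[0, 1)`.
#' @param g `tf_grid` of the field.
#' @param h smoothing length scale (interface thickness).
#' @export
handoff_to_phasefield <- function(VF, g, h) {
  phi <- 1 - VF
  alpha <- 1 / (4 * g$ndim)               # stable, monotone explicit step
  dt_cell <- alpha * min(g$h)^2
  n_pass <- max(1L, ceiling((h^2 / 2) / dt_cell))
  for (k in seq_len(n_pass))
    phi <- phi + dt_cell * laplacian(phi, g, bc = "neumann")
  phi
}
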