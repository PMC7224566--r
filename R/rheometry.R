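# Virtual oscillatory-shear rheometry: drive the plate-gap cell, record
# torque-displacement loops, extract the phase angle and storage/loss
# moduli, and select the elastic shear modulus against the published
# experimental power-law fits.

#' Rheometry run configuration
#'
#' @param vf thrombus slab volume fraction (0 gives a pure-fluid cell).
#' @param lambda_e nondimensional elastic shear modulus of the slab.
#' @param n grid node counts.
#' @param plate_amp,plate_omega plate velocity law `v = A sin(omega t)`
#'   (nondimensional default `0.2 sin(1.2 pi t)`).
#' @param plate_law `"dimensional"` (default) sets the plate angular
#'   frequency from the physical 0.5 Hz through the scale registry
#'   (`omega = 2 pi 0.5 L/U`, quasi-static cell, matching the published
#'   relaxation-time magnitudes); `"nondim"` uses `plate_omega` as given
#'   (the literal `1.2 pi`, which places the slab near its first
#'   shear-wave resonance at the candidate moduli).
#' @param cycles_discard initial transient cycles dropped.
#' @param cycles_record cycles recorded and averaged.
#' @param dt time step (default: period/384).
#' @param patch_threshold top-plate contact patch is where
#'   `phi < patch_threshold` (default `1 - vf/2`, midway between slab and
#'   blood).
#' @param eta_ratio,rho_ratio material ratios (reference values 2 and 2).
#' @param n_proj projection passes per step.
#' @export
rheometry_config <- function(vf, lambda_e, n = c(96, 32),
                             plate_amp = 0.2, plate_omega = 1.2 * pi,
                             plate_law = c("dimensional", "nondim"),
                             cycles_discard = 1L, cycles_record = 2L,
                             dt = NULL, patch_threshold = NULL,
                             eta_ratio = 2, rho_ratio = 2, n_proj = 1L,
                             registry = unit_registry()) {
  plate_law <- match.arg(plate_law)
  if (plate_law == "dimensional") {
    # quasi-static cell: omega from the physical 0.5 Hz; the plate velocity
    # amplitude is set from the experiment's strain amplitude gamma0 = 0.01
    # (the reference plate velocity would give strain ~0.7, outside the linear
    # regime the loop analysis presumes; moduli are amplitude-independent
    # in the linear regime)
    plate_omega <- 2 * pi * 0.5 * registry$time
    plate_amp <- 0.01 * plate_omega
  }
  stopifnot(plate_omega > 0, cycles_record >= 2, cycles_discard >= 1)
  if (is.null(patch_threshold)) patch_threshold <- 1 - vf / 2
  list(vf = vf, lambda_e = lambda_e, n = n, plate_amp = plate_amp,
       plate_omega = plate_omega, plate_law = plate_law,
       cycles_discard = as.integer(cycles_discard),
       cycles_record = as.integer(cycles_record), dt = dt,
       patch_threshold = patch_threshold, eta_ratio = eta_ratio,
       rho_ratio = rho_ratio, n_proj = as.integer(n_proj))
}

#' Run the oscillatory shear cell and record the torque-displacement loop
#'
#' The top plate moves at the configured sinusoidal velocity; plate
#' displacement is the analytic integral of that law (avoiding a spurious
#' quadrature phase error) and the torque surrogate is the area-averaged
#' tangential traction (viscous plus elastic contributions) on the
#' thrombus-plate contact patch.
#'
#' @param config from [rheometry_config()].
#' @param material optional `tf_material` override.
#' @return a `LoopRecord` data frame (time, displacement, traction) over
#'   the recorded cycles, with attributes `period`, `omega`, `drift`.
#' @export
run_oscillatory_shear <- function(config, material = NULL) {
  co <- config
  period <- 2 * pi / co$plate_omega
  scn <- if (co$vf > 0) {
    make_shear_cell(co$vf, co$lambda_e, n = co$n, plate_amp = co$plate_amp,
                    plate_omega = co$plate_omega, eta_ratio = co$eta_ratio,
                    rho_ratio = co$rho_ratio, material = material)
  } else {
    s <- make_shear_cell(1e-9, co$lambda_e, n = co$n, plate_amp = co$plate_amp,
                         plate_omega = co$plate_omega, eta_ratio = co$eta_ratio,
                         rho_ratio = co$rho_ratio, material = material)
    s$state0$phi[] <- 1
    s
  }
  g <- scn$grid
  mat <- scn$material
  dt <- co$dt
  if (is.null(dt)) dt <- period / 384
  ncyc <- co$cycles_discard + co$cycles_record
  cfg <- solver_config(dt = dt, t_end = ncyc * period, n_proj = co$n_proj,
                       record_every = 1000L)
  ctx <- solver_context(scn, cfg)
  st <- scn$state0
  nsteps <- round(ncyc * period / dt)
  ny <- g$n[2]; dy <- g$h[2]
  phi_top0 <- scn$state0$phi[, ny]
  patch <- phi_top0 < co$patch_threshold
  if (!any(patch)) patch <- rep(TRUE, length(phi_top0))
  times <- disp <- trac_v <- trac_e <- numeric(nsteps)
  A <- co$plate_amp; om <- co$plate_omega
  for (k in seq_len(nsteps)) {
    st <- step(st, ctx)
    t <- st$time
    Ff <- state_deformation(st)
    lam_e <- .lambda_e_field(st$phi, ctx)
    eta <- mixture_property(st$phi, mat$eta1, mat$eta2)
    dudy_top <- (3 * st$u[[1]][, ny] - 4 * st$u[[1]][, ny - 1] +
                   st$u[[1]][, ny - 2]) / (2 * dy)
    s12 <- lam_e * (1 - st$phi) *
      (Ff$F11 * Ff$F21 + Ff$F12 * Ff$F22)
    times[k] <- t
    disp[k] <- -(A / om) * (cos(om * t) - 1)
    trac_v[k] <- mean((eta[, ny] * dudy_top)[patch])
    trac_e[k] <- mean(s12[patch, ny])
  }
  # the deformation update integrates the strain rate with a left-endpoint
  # rule, so the elastic traction at step k carries the timestamp
  # t_k - dt/2; averaging consecutive samples re-centers it at t_k with
  # O(dt^2) error, removing a first-order phase bias from the loop
  trac <- trac_v
  trac[seq_len(nsteps - 1L)] <- trac_v[seq_len(nsteps - 1L)] +
    (trac_e[seq_len(nsteps - 1L)] + trac_e[2:nsteps]) / 2
  trac[nsteps] <- trac_v[nsteps] + trac_e[nsteps]
  keep <- times > co$cycles_discard * period + dt / 2 &
    seq_len(nsteps) < nsteps
  rec <- data.frame(time = times[keep], displacement = disp[keep],
                    traction = trac[keep])
  # cycle-to-cycle drift of the recorded loops
  drift <- NA_real_
  if (co$cycles_record >= 2) {
    ph <- (rec$time - min(rec$time)) %/% period
    c1 <- rec$traction[ph == 0]; c2 <- rec$traction[ph == 1]
    nmin <- min(length(c1), length(c2))
    drift <- max(abs(c2[seq_len(nmin)] - c1[seq_len(nmin)])) /
      max(abs(rec$traction))
    if (is.finite(drift) && drift > 0.05)
      warning(sprintf("transient not decayed: cycle-to-cycle loop drift %.1f%%",
                      100 * drift))
  }
  attr(rec, "period") <- period
  attr(rec, "omega") <- om
  attr(rec, "drift") <- drift
  class(rec) <- c("tf_loop_record", "data.frame")
  rec
}

# fold a record into one cycle-averaged loop on a uniform phase grid
.cycle_average <- function(record, m = 512L) {
  period <- attr(record, "period")
  if (is.null(period)) stop("record lacks a period attribute")
  tspan <- diff(range(record$time)) + diff(record$time[1:2])
  ncyc <- tspan / period
  if (abs(ncyc - round(ncyc)) > 0.02)
    stop(sprintf("record covers %.3f cycles: need an integer number", ncyc))
  ncyc <- round(ncyc)
  ph <- ((record$time - record$time[1]) %% period) / period
  grid_ph <- (seq_len(m) - 0.5) / m
  idx <- (record$time - record$time[1]) %/% (period * (1 - 1e-12))
  dmat <- tmat <- matrix(NA_real_, m, ncyc)
  for (k in seq_len(ncyc)) {
    sel <- idx == (k - 1)
    o <- order(ph[sel])
    dmat[, k] <- stats::approx(ph[sel][o], record$displacement[sel][o],
                               xout = grid_ph, rule = 2)$y
    tmat[, k] <- stats::approx(ph[sel][o], record$traction[sel][o],
                               xout = grid_ph, rule = 2)$y
  }
  list(phase = grid_ph, displacement = rowMeans(dmat), traction = rowMeans(tmat))
}

#' Area of the cycle-averaged torque-displacement loop
#'
#' Shoelace (signed polygon) area of the closed averaged loop; the absolute
#' value is returned.  Errors if the record does not cover an integer
#' number of cycles.
#' @param record a `LoopRecord` from [run_oscillatory_shear()] (or any data
#'   frame with `time`, `displacement`, `traction` and a `period`
#'   attribute).
#' @export
loop_area <- function(record) {
  avg <- .cycle_average(record)
  x <- avg$displacement; y <- avg$traction
  n <- length(x)
  nxt <- c(2:n, 1L)
  abs(sum(x * y[nxt] - x[nxt] * y) / 2)
}

#' Phase angle and storage/loss moduli from loop geometry
#'
#' `delta = asin(4 A_r / (pi dTs dd))`, `G' = (dTs/dd) cos(delta)`,
#' `G'' = (dTs/dd) sin(delta)`, with `dTs`, `dd` the PEAK-TO-PEAK torque
#' and displacement amplitudes (for an ellipse `pi a b sin(delta) =
#' (pi/4) dTs dd sin(delta)`, so the factor 4 presumes peak-to-peak).
#' @param A_r loop area.
#' @param dTs,dd peak-to-peak torque and displacement.
#' @return list `delta`, `Gp`, `Gpp`.
#' @export
loop_moduli <- function(A_r, dTs, dd) {
  arg <- 4 * A_r / (pi * dTs * dd)
  if (arg > 1 + 1e-9)
    stop(sprintf(paste0("sin^-1 argument %.4f > 1: dTs/dd are probably not ",
                        "peak-to-peak amplitudes"), arg))
  delta <- asin(min(arg, 1))
  k <- dTs / dd
  list(delta = delta, Gp = k * cos(delta), Gpp = k * sin(delta))
}

#' Full loop analysis of a record
#'
#' Cycle-averages the loop, measures area and peak-to-peak amplitudes,
#' derives the phase angle and moduli, and extracts the Kelvin-Voigt
#' relaxation time.
#' @inheritParams loop_area
#' @param f oscillation frequency (same unit system as the record).
#' @param eta1 fluid viscosity (same unit system).
#' @return `ModuliResult` list: `A_r`, `dTs`, `dd`, `delta`, `Gp`, `Gpp`,
#'   `lambda_s`.
#' @export
loop_analysis <- function(record, f, eta1) {
  avg <- .cycle_average(record)
  A_r <- loop_area(record)
  dTs <- diff(range(avg$traction))
  dd <- diff(range(avg$displacement))
  lm <- loop_moduli(A_r, dTs, dd)
  lam_s <- extract_relaxation_time(lm$Gp, lm$Gpp, f, eta1)
  c(list(A_r = A_r, dTs = dTs, dd = dd), lm, list(lambda_s = lam_s))
}

#' Kelvin-Voigt loss modulus `G'' = 2 pi f (eta1 + lambda_s G')`
#' @param f frequency.
#' @param eta1 fluid viscosity.
#' @param lambda_s relaxation time.
#' @param Gp storage modulus.
#' @export
kelvin_voigt_loss <- function(f, eta1, lambda_s, Gp) {
  if (any(f <= 0)) stop("f must be > 0")
  2 * pi * f * (eta1 + lambda_s * Gp)
}

#' Relaxation time from the moduli: `lambda_s = (G''/(2 pi f) - eta1) / G'`
#'
#' Algebraic inverse of [kelvin_voigt_loss()].  May be negative when
#' `G'' < 2 pi f eta1` (returned as-is, with a warning).
#' @inheritParams kelvin_voigt_loss
#' @param Gpp loss modulus.
#' @export
extract_relaxation_time <- function(Gp, Gpp, f, eta1) {
  if (any(Gp == 0)) stop("Gp must be nonzero")
  out <- (Gpp / (2 * pi * f) - eta1) / Gp
  if (any(out < 0)) warning("negative relaxation time: G'' < 2 pi f eta1")
  out
}

#' Experimental storage/loss modulus fits of fibrin gels
#'
#' Printed power laws `G' = 10 c^2.6` Pa and `G'' = 0.7 c^1.7` Pa for the
#' fibrinogen concentration `c` in mg/mL.
#' @param c_Fbg fibrinogen concentration (mg/mL), > 0.
#' @return list `Gp`, `Gpp` in Pa.
#' @export
experimental_fits <- function(c_Fbg) {
  if (any(c_Fbg <= 0)) stop("c_Fbg must be > 0")
  list(Gp = 10^(2.6 * log10(c_Fbg) + log10(10)),
       Gpp = 10^(1.7 * log10(c_Fbg) + log10(0.7)))
}

#' Experimental relaxation-time curve from the published fits
#' @param c_Fbg fibrinogen concentration (mg/mL).
#' @param f frequency in Hz (0.5 for the reference experiment).
#' @param eta1 fluid dynamic viscosity in Pa s.
#' @export
experimental_relaxation_time <- function(c_Fbg, f = 0.5, eta1 = 1e-3) {
  fits <- experimental_fits(c_Fbg)
  (fits$Gpp / (2 * pi * f) - eta1) / fits$Gp
}

#' Select the elastic shear modulus against the experimental curve
#'
#' For each candidate modulus, fits `log10(lambda_s)` linearly in
#' `log10(c_Fbg)` through its simulated points, extrapolates over
#' `c_range`, and selects the candidate minimizing the mean squared
#' log-distance to the experimental relaxation-time curve.
#'
#' @param sim_points data frame with columns `lambda_e_Pa`, `c_Fbg`,
#'   `lambda_s` (seconds; >= 2 rows per candidate).
#' @param c_range concentration range for the comparison (mg/mL).
#' @param f frequency (Hz).
#' @param eta1 fluid viscosity (Pa s).
#' @param n_eval evaluation points (log-spaced).
#' @return list with `selected` (Pa), `table` (per-candidate fit and
#'   discrepancy), and the evaluation grid.
#' @export
calibrate_lambda_e <- function(sim_points, c_range = c(1, 6), f = 0.5,
                               eta1 = 1e-3, n_eval = 64L) {
  cands <- sort(unique(sim_points$lambda_e_Pa))
  cgrid <- 10^seq(log10(c_range[1]), log10(c_range[2]), length.out = n_eval)
  lexp <- log10(experimental_relaxation_time(cgrid, f, eta1))
  rows <- lapply(cands, function(le) {
    pts <- sim_points[sim_points$lambda_e_Pa == le, ]
    if (nrow(pts) < 2)
      stop(sprintf("need >= 2 simulated points per candidate (lambda_e = %g)", le))
    if (any(pts$lambda_s <= 0))
      return(data.frame(lambda_e_Pa = le, slope = NA, intercept = NA, msd = Inf))
    fit <- stats::lm(log10(lambda_s) ~ log10(c_Fbg), data = pts)
    pred <- stats::predict(fit, newdata = data.frame(c_Fbg = cgrid))
    data.frame(lambda_e_Pa = le, slope = stats::coef(fit)[2],
               intercept = stats::coef(fit)[1],
               msd = mean((pred - lexp)^2))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(selected = tab$lambda_e_Pa[which.min(tab$msd)], table = tab,
       c_grid = cgrid, log10_lambda_s_exp = lexp)
}

#' Full oscillatory-shear calibration pipeline
#'
#' Runs the shear cell for every candidate modulus at each volume-fraction
#' level, extracts the relaxation time from the loop analysis, converts to
#' seconds through the scale registry, maps the volume fractions to
#' fibrinogen concentrations by inverting the fibrin volume-fraction
#' relation, and selects the modulus with [calibrate_lambda_e()].
#'
#' @param lambda_e_Pa candidate moduli in Pa (reference set 0.22, 0.44, 0.67, 0.89 by default).
#' @param vf_levels slab volume fractions used for the fit.
#' @param n grid node counts for the reduced-resolution cell.
#' @param registry scale registry from [unit_registry()].
#' @param verbose print per-run progress.
#' @param ... passed to [rheometry_config()].
#' @return list: `selected` (Pa), `points` (per-run results), `calibration`
#'   (output of [calibrate_lambda_e()]).
#' @export
rheometry_calibration <- function(lambda_e_Pa = c(0.22, 0.44, 0.67, 0.89),
                                  vf_levels = c(0.3419, 0.5219),
                                  n = c(96, 32), registry = unit_registry(),
                                  verbose = FALSE, ...) {
  rows <- list()
  for (le in lambda_e_Pa) for (vf in vf_levels) {
    le_nd <- le / registry$stress
    co <- rheometry_config(vf = vf, lambda_e = le_nd, n = n, ...)
    rec <- run_oscillatory_shear(co)
    f_nd <- attr(rec, "omega") / (2 * pi)
    res <- loop_analysis(rec, f = f_nd, eta1 = 1)
    lam_s_sec <- res$lambda_s * registry$time
    if (verbose)
      message(sprintf("  lambda_e = %.2f Pa  VF = %.4f  G' = %.3g  G'' = %.3g  lambda_s = %.4g s",
                      le, vf, res$Gp, res$Gpp, lam_s_sec))
    rows[[length(rows) + 1L]] <-
      data.frame(lambda_e_Pa = le, vf = vf,
                 c_Fbg = fibrin_concentration(vf),
                 Gp_nd = res$Gp, Gpp_nd = res$Gpp, delta = res$delta,
                 lambda_s = lam_s_sec)
  }
  pts <- do.call(rbind, rows)
  cal <- calibrate_lambda_e(pts)
  list(selected = cal$selected, points = pts, calibration = cal)
}
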