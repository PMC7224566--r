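# Virtual permeation chamber: drive flow through a channel-filling clot,
# measure the pressure drop, and back out the effective permeability via
# Darcy's law for comparison with Davies' equation.

#' Effective permeability from Darcy's law
#'
#' `kappa = v_mean * eta * L_clot / dP`: the conventional form `v = -kappa dP /
#' eta` is treated as a gradient law, with `dP` the pressure drop across
#' the clot and `L_clot` its length (dimensional consistency with the
#' Brinkman closed form).
#' @param v_mean mean superficial velocity through the clot.
#' @param eta viscosity of the percolating fluid.
#' @param dP pressure drop across the clot (> 0 for forward flow).
#' @param L_clot clot length (> 0).
#' @export
darcy_effective_permeability <- function(v_mean, eta, dP, L_clot) {
  if (any(dP <= 0)) stop("dP must be > 0 for forward flow")
  if (any(L_clot <= 0)) stop("L_clot must be > 0")
  v_mean * eta * L_clot / dP
}

#' Run the permeation chamber to steady state
#'
#' Builds the channel-filling clot scenario at the requested volume
#' fraction (Davies permeability at `psi_f = VF`), advances the flow to a
#' steady state, samples plane-averaged pressure half a channel height
#' upstream and downstream of the clot extent, and returns the effective
#' permeability via [darcy_effective_permeability()].
#'
#' @param VF clot volume fraction in (0, 1).
#' @param n grid node counts (`c(96, 32, 16)` for the reference setup).
#' @param material optional `tf_material` override (see
#'   [make_permeation_channel()] for the defaults).
#' @param dt pseudo-time step.
#' @param max_steps steadiness cap.
#' @param steady_tol maximum per-step velocity change declaring steadiness.
#' @param rigid `"frozen"` (default) or `"none"` (deformable variant).
#' @return a `PermeationResult` list: `VF`, `v_mean`, `dP`, `L_clot`,
#'   `kappa_eff`, `kappa_davies`, `steps`, `residual`, and flux-balance
#'   diagnostics.
#' @export
run_permeation <- function(VF, n = c(96, 32, 16), material = NULL,
                           dt = 0.005, max_steps = 600L, steady_tol = 1e-6,
                           rigid = "frozen") {
  if (VF <= 0 || VF >= 1) stop("VF must lie in (0, 1)")
  scn <- make_permeation_channel(VF, n = n, material = material, rigid = rigid)
  g <- scn$grid
  mat <- scn$material
  cfg <- solver_config(dt = dt, t_end = max_steps * dt, record_every = 1e6)
  ctx <- solver_context(scn, cfg)
  st <- scn$state0
  res <- Inf; k <- 0L
  while (k < max_steps) {
    k <- k + 1L
    u_prev <- st$u[[1]]
    st <- step(st, ctx)
    res <- max(abs(st$u[[1]] - u_prev))
    if (res < steady_tol) break
  }
  if (res >= steady_tol)
    warning(sprintf("steadiness not reached in %d steps (residual %.2e)",
                    k, res))
  measure_permeation(st, scn, steps = k, residual = res)
}

#' Measure the Darcy permeability of a (steady) permeation state
#'
#' The measurement stage of [run_permeation()], usable on any steady state
#' of a permeation scenario (e.g. the deformable variant).
#' @param st steady `tf_state`.
#' @param scn the permeation `tf_scenario`.
#' @param steps,residual bookkeeping passed through to the result.
#' @export
measure_permeation <- function(st, scn, steps = NA, residual = NA) {
  g <- st$grid
  mat <- scn$material
  x <- g$coords[[1]]
  # clot extent: axial range where the cross-section-averaged (1 - phi)
  # exceeds 0.05
  vf_x <- apply(1 - st$phi, 1, mean)
  inclot <- which(vf_x > 0.05)
  if (!length(inclot)) stop("no clot found in the channel")
  x1 <- x[min(inclot)]; x2 <- x[max(inclot)]
  L_clot <- x2 - x1
  # sampling planes half a channel height (the narrow cross dimension)
  # before/after the clot extent
  Hmin <- min(g$length[-1])
  ip1 <- which.min(abs(x - (x1 - Hmin / 2)))
  ip2 <- which.min(abs(x - (x2 + Hmin / 2)))
  pbar <- apply(st$p, 1, mean)
  dP <- pbar[ip1] - pbar[ip2]
  # superficial velocity: flux / cross-section area at the two planes
  A_cs <- prod(g$length[-1])
  wt <- grid_weights(g)
  flux_at <- function(i) sum((st$u[[1]] * wt)[i, , ] / g$h[1])
  v_mean <- flux_at(ip1) / A_cs
  flux_balance <- abs(flux_at(ip2) - flux_at(ip1)) / abs(flux_at(ip1))
  kap <- darcy_effective_permeability(v_mean, mat$eta1, dP, L_clot)
  vf_bulk <- max(vf_x)
  structure(list(VF = scn$config$VF, vf_measured = vf_bulk,
                 v_mean = v_mean, dP = dP, L_clot = L_clot,
                 kappa_eff = kap,
                 kappa_davies = davies_permeability(scn$config$VF, mat$a_f),
                 flux_balance = flux_balance,
                 steps = steps, residual = residual),
            class = "tf_permeation_result")
}

#' @export
print.tf_permeation_result <- function(x, ...) {
  cat(sprintf(paste0("<permeation> VF = %.2f  kappa_eff = %.4g  ",
                     "Davies = %.4g  (ratio %.2f)\n"),
              x$VF, x$kappa_eff, x$kappa_davies, x$kappa_eff / x$kappa_davies))
  invisible(x)
}

#' Permeability curve over a set of volume fractions
#'
#' Runs the permeation chamber at each level and tabulates the effective
#' permeability against Davies' equation (a log-scale comparison curve).
#' @param VF_levels numeric vector of volume fractions (>= 2).
#' @param csv optional path: write the table as CSV.
#' @param ... passed to [run_permeation()].
#' @return data frame with columns `VF`, `kappa_eff`, `kappa_davies`,
#'   `rel_error`.
#' @export
permeability_curve <- function(VF_levels, csv = NULL, ...) {
  if (length(VF_levels) < 2) stop("need at least 2 VF levels")
  rows <- lapply(VF_levels, function(vf) {
    r <- run_permeation(vf, ...)
    data.frame(VF = vf, kappa_eff = r$kappa_eff,
               kappa_davies = r$kappa_davies,
               rel_error = abs(r$kappa_eff - r$kappa_davies) / r$kappa_davies)
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
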