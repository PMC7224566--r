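# Aggregation driver: platelet transport in a (quasi-steady) vessel flow
# modulated by the cardiac waveform, state updates at deposition sites,
# stationarity bookkeeping per cycle, and the handoff to the phase field.

#' Quasi-steady carrier flow for platelet transport
#'
#' Advances the scenario's flow (pure blood) to a near-steady state at the
#' mean inflow and returns it as a frozen carrier field; the aggregation
#' stage modulates it by the inlet waveform (a quasi-steady approximation
#' of the pulsatile flow, adequate for transport at low Womersley number).
#' @param scenario vessel/aneurysm `tf_scenario`.
#' @param t_end spin-up time.
#' @param dt time step.
#' @return list `u`, `grid` usable as the `flow` argument of
#'   [advect_platelets()].
#' @export
steady_flow <- function(scenario, t_end = 2, dt = 0.01) {
  scn <- scenario
  scn$rigid <- "frozen"                  # no phase/deformation updates
  cfg <- solver_config(dt = dt, t_end = t_end, record_every = 1e6)
  ctx <- solver_context(scn, cfg)
  st <- scn$state0
  nst <- round(t_end / dt)
  for (k in seq_len(nst)) st <- step(st, ctx)
  list(u = st$u, grid = st$grid)
}

#' Run the platelet aggregation stage
#'
#' Seeds passive platelets in the lumen, then advances them through the
#' carrier flow for the requested number of cardiac cycles: state updates
#' at the deposition sites, pairwise interactions among activated
#' pseudo-platelets, removal of outgoing platelets, optional proximal
#' insertion, and per-cycle stationarity marking (adhered = activated and
#' moving less than 1/100 diameter per cycle).
#'
#' @param scenario an aneurysm scenario (with `$sites`).
#' @param flow carrier flow from [steady_flow()] (computed if NULL).
#' @param config from [fcm_config()].
#' @param n_platelets initial platelet count.
#' @param cycles number of cardiac cycles.
#' @param steps_per_cycle transport steps per cycle.
#' @param period cardiac period.
#' @param waveform inlet modulation function of time (default
#'   [pulsatile_waveform()]).
#' @param insert_per_cycle new platelets inserted proximally each cycle.
#' @param seed RNG seed.
#' @return list: `ensemble`, `history` (per-cycle counts), `flow`.
#' @export
run_fcm_aggregation <- function(scenario, flow = NULL, config = fcm_config(),
                                n_platelets = 400L, cycles = 3L,
                                steps_per_cycle = 60L, period = 1,
                                waveform = pulsatile_waveform,
                                insert_per_cycle = 0L, seed = 1L) {
  if (is.null(scenario$sites)) stop("scenario has no deposition sites")
  if (is.null(flow)) flow <- steady_flow(scenario)
  flow$scale <- waveform
  g <- flow$grid
  domain <- list(x_range = range(g$coords[[1]]) + c(0.3, -0.3),
                 R_of_x = scenario$lumen_radius)
  ens <- seed_platelets(domain, n_platelets, seed = seed, r_p = config$r_p)
  dt <- period / steps_per_cycle
  t <- 0
  hist <- list()
  for (cyc in seq_len(cycles)) {
    start_pos <- ens[, c("id", "x", "y", "z")]
    site_pts <- do.call(rbind, lapply(scenario$sites, function(s) s$points))
    for (s in seq_len(steps_per_cycle)) {
      ens <- update_states(ens, scenario$sites, t, config)
      ff <- pairwise_forces(ens, config, site_points = site_pts)
      ens <- advect_platelets(ens, flow, dt, config, t = t, forces = ff)
      # keep particles inside the lumen (radial clamp onto the wall)
      R <- scenario$lumen_radius(ens$x) - ens$radius / 2
      rr <- sqrt(ens$y^2 + ens$z^2)
      out <- rr > R
      if (any(out)) {
        f <- (R[out] / rr[out])
        ens$y[out] <- ens$y[out] * f
        ens$z[out] <- ens$z[out] * f
      }
      t <- t + dt
    }
    # per-cycle stationarity: adhered platelets are frozen thereafter
    m <- merge(ens[, c("id", "x", "y", "z", "radius", "state")],
               start_pos, by = "id", suffixes = c("", "0"))
    disp <- sqrt((m$x - m$x0)^2 + (m$y - m$y0)^2 + (m$z - m$z0)^2)
    newly <- m$id[m$state == "activated" & stationarity(disp, m$radius)]
    ens$adhered[ens$id %in% newly] <- TRUE
    if (insert_per_cycle > 0) {
      dom_in <- list(x_range = c(domain$x_range[1], domain$x_range[1] + 1),
                     R_of_x = scenario$lumen_radius)
      add <- seed_platelets(dom_in, insert_per_cycle,
                            seed = seed + 1000L + cyc, r_p = config$r_p)
      add$id <- max(ens$id, 0L) + seq_len(nrow(add))
      ens <- rbind(ens, add)
    }
    hist[[cyc]] <- data.frame(cycle = cyc, n = nrow(ens),
                              passive = sum(ens$state == "passive"),
                              triggered = sum(ens$state == "triggered"),
                              activated = sum(ens$state == "activated"),
                              adhered = sum(ens$adhered))
  }
  list(ensemble = ens, history = do.call(rbind, hist), flow = flow)
}

#' Convert an aggregate into the phase-field initial condition
#'
#' [fcm_volume_fraction()] of the adhered/activated platelets on a deposit
#' grid, composition scaling via [thrombus_VF()], and the smoothing handoff
#' [handoff_to_phasefield()].
#' @param ensemble `PlateletEnsemble`.
#' @param g deposit `tf_grid`.
#' @param config from [fcm_config()].
#' @param c_Fbg,c_plat composition (mg/mL, 1/volume).
#' @param h smoothing length.
#' @return list `psi_fcm`, `VF`, `phi0`.
#' @export
aggregate_to_phasefield <- function(ensemble, g, config, c_Fbg = 3,
                                    c_plat = 0, h = NULL) {
  if (is.null(h)) h <- 2 * max(g$h)
  psi <- fcm_volume_fraction(ensemble, g, config)
  vf <- thrombus_VF(psi, c_Fbg, c_plat, config)
  phi0 <- handoff_to_phasefield(vf, g, h)
  list(psi_fcm = psi, VF = vf, phi0 = phi0)
}
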