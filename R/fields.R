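# Simulation state container and the pointwise/differential operators of the
# free-energy functional and momentum source terms.

#' Create a simulation state
#'
#' Bundles the coupled fields on one grid: the phase field `phi` (1 = blood,
#' 0 = thrombus), velocity `u`, pressure `p`, and the Eulerian deformation
#' map: in 3D (or by choice in 2D) the deformation gradient tensor `F`; in
#' 2D by default the 2-component curl potential `psi` with `F = curl(psi)`
#' derived on demand.
#'
#' @param grid `tf_grid`.
#' @param phi phase field array (defaults to pure blood).
#' @param u list of `ndim` velocity component arrays (defaults to rest).
#' @param p pressure array.
#' @param F named list of deformation-gradient component arrays
#'   (`F11, F12, ..`), or NULL.
#' @param psi list of 2 curl-potential component arrays (2D only), or NULL.
#'   When neither `F` nor `psi` is given, 2D states get the identity
#'   potential `psi = (y, -x)` and 3D states get `F = I`.
#' @param time simulation time.
#' @export
simulation_state <- function(grid, phi = NULL, u = NULL, p = NULL,
                             F = NULL, psi = NULL, time = 0) {
  nd <- grid$ndim
  if (is.null(phi)) phi <- field_const(grid, 1)
  if (is.null(u)) u <- replicate(nd, field_const(grid, 0), simplify = FALSE)
  if (is.null(p)) p <- field_const(grid, 0)
  if (is.null(F) && is.null(psi)) {
    if (nd == 2L) psi <- identity_potential(grid) else F <- identity_deformation(grid)
  }
  if (!is.null(F) && !is.null(psi))
    stop("give exactly one of F (tensor) or psi (2D potential)")
  if (!is.null(psi) && nd != 2L) stop("psi formulation is 2D only")
  st <- structure(list(grid = grid, phi = phi, u = u, p = p,
                       F = F, psi = psi, time = time),
                  class = "tf_state")
  st
}

#' @export
print.tf_state <- function(x, ...) {
  cat(sprintf("<tf_state> t = %.4g  %s nodes  formulation: %s\n",
              x$time, paste(x$grid$n, collapse = "x"),
              if (is.null(x$psi)) "F" else "psi"))
  invisible(x)
}

#' Identity curl potential `psi = (y, -x)` (gives `F = I` in 2D)
#' @param grid 2D `tf_grid`.
#' @export
identity_potential <- function(grid) {
  m <- grid_mesh(grid)
  list(m[[2]], -m[[1]])
}

#' Identity deformation gradient field
#' @param grid `tf_grid`.
#' @export
identity_deformation <- function(grid) {
  nd <- grid$ndim
  out <- list()
  for (i in seq_len(nd)) for (j in seq_len(nd))
    out[[paste0("F", i, j)]] <- field_const(grid, as.numeric(i == j))
  out
}

#' Deformation gradient of a state (derived from psi in 2D if needed)
#' @param state `tf_state`.
#' @param scheme derivative scheme for the curl.
#' @export
state_deformation <- function(state, scheme = "central") {
  if (!is.null(state$F)) return(state$F)
  curl_potential_to_F(state$psi, state$grid, scheme = scheme)
}

#' Deformation gradient from a 2D curl potential
#'
#' `F = curl(psi)`: row i of F is `(d psi_i / dy, -d psi_i / dx)`, which
#' makes every row discretely divergence-free up to stencil commutation
#' error (exactly, with spectral stencils on periodic axes).
#' @param psi list of 2 component arrays.
#' @param grid 2D `tf_grid`.
#' @param scheme `"central"` or `"spectral"`.
#' @export
curl_potential_to_F <- function(psi, grid, scheme = "central") {
  if (grid$ndim != 2L) stop("curl potential formulation is 2D only")
  # differentiate the deviation from the identity potential (y, -x), whose
  # curl is I analytically; the raw potential is not periodic even on
  # periodic grids, the deviation is
  # column j of F is the curl of psi_j: the advected potential carries the
  # Lagrangian labels (Y, -X), and inverting the label gradient at unit
  # Jacobian gives F = [[dpsi1/dy, dpsi2/dy], [-dpsi1/dx, -dpsi2/dx]]
  # (verified against the closed-form simple-shear solution of the F
  # transport equation)
  pid <- identity_potential(grid)
  d1 <- psi[[1]] - pid[[1]]
  d2 <- psi[[2]] - pid[[2]]
  list(F11 = 1 + deriv1(d1, grid, 2L, scheme = scheme),
       F12 = deriv1(d2, grid, 2L, scheme = scheme),
       F21 = -deriv1(d1, grid, 1L, scheme = scheme),
       F22 = 1 - deriv1(d2, grid, 1L, scheme = scheme))
}

# tensor helpers ----------------------------------------------------------

.Fcomp <- function(F, i, j) F[[paste0("F", i, j)]]
.tensor_dim <- function(F) as.integer(sqrt(length(F)))

#' Trace of `F^T F - I` (twice the elastic energy density per unit modulus)
#'
#' For a 2D state the tensor is embedded with `F33 = 1`, so the value equals
#' `sum(F_ij^2) - ndim` in both cases.
#' @param F named list of tensor components.
#' @keywords internal
trace_FtF_minus_I <- function(F) {
  nd <- .tensor_dim(F)
  out <- 0
  for (comp in F) out <- out + comp^2
  out - nd
}

#' Derivative of the double-well potential
#'
#' `g1(phi) = phi (phi - 1) (2 phi - 1) / h^2`, the exact cubic derivative
#' of `phi^2 (phi - 1)^2 / (2 h^2)`.
#' @param phi phase field array (or numeric).
#' @param h interface thickness (> 0).
#' @export
double_well_derivative <- function(phi, h) {
  if (any(h <= 0)) stop("h must be > 0")
  phi * (phi - 1) * (2 * phi - 1) / h^2
}

#' Chemical potential of the blood-thrombus free energy
#'
#' `mu1 = -lambda Lap(phi) + lambda gamma g1(phi) +
#'   (lambda_e / 2) tr(F^T F - I)`,
#' with zero-flux phase boundary stencils.
#' @param phi phase field array.
#' @param F deformation tensor component list (or NULL for undeformed).
#' @param params `tf_material`.
#' @param grid `tf_grid`.
#' @param lambda_e scalar or array elastic modulus (default `params$lambda_e0`).
#' @export
chemical_potential <- function(phi, F, params, grid, lambda_e = NULL) {
  if (!identical(dim(phi), as.integer(grid$n)) && !identical(dim(phi), grid$n))
    stop("phi does not live on the supplied grid")
  if (is.null(lambda_e)) lambda_e <- params$lambda_e0
  out <- -params$lambda * laplacian(phi, grid, bc = "neumann") +
    params$lambda * params$gamma * double_well_derivative(phi, params$h)
  if (!is.null(F)) out <- out + (lambda_e / 2) * trace_FtF_minus_I(F)
  out
}

#' Elastic (neo-Hookean) stress tensor field
#'
#' `sigma_e = lambda_e (1 - phi) (F F^T - I)`: symmetric, zero wherever
#' `F = I` or `phi = 1`.
#' @param F deformation tensor component list.
#' @param phi phase field array.
#' @param lambda_e scalar or array elastic modulus.
#' @return named list of tensor components (`S11`, `S12`, ...).
#' @export
elastic_stress <- function(F, phi, lambda_e) {
  nd <- .tensor_dim(F)
  pref <- lambda_e * (1 - phi)
  out <- list()
  for (i in seq_len(nd)) for (j in seq_len(nd)) {
    s <- 0
    for (k in seq_len(nd)) s <- s + .Fcomp(F, i, k) * .Fcomp(F, j, k)
    if (i == j) s <- s - 1
    out[[paste0("S", i, j)]] <- pref * s
  }
  out
}

#' Divergence of a symmetric tensor field
#' @param S named component list (`S11`, `S12`, ...).
#' @param grid `tf_grid`.
#' @return list of `ndim` force component arrays.
#' @keywords internal
tensor_divergence <- function(S, grid) {
  nd <- grid$ndim
  lapply(seq_len(nd), function(i) {
    out <- 0
    for (j in seq_len(nd)) out <- out + deriv1(S[[paste0("S", i, j)]], grid, j)
    out
  })
}

#' Capillary (surface tension) force `-lambda div(grad phi (x) grad phi)`
#' @param phi phase field array.
#' @param lambda mixing energy density.
#' @param grid `tf_grid`.
#' @return list of `ndim` force component arrays; zero for uniform phi.
#' @export
surface_tension_force <- function(phi, lambda, grid) {
  gphi <- gradient(phi, grid)
  nd <- grid$ndim
  S <- list()
  for (i in seq_len(nd)) for (j in seq_len(nd))
    S[[paste0("S", i, j)]] <- gphi[[i]] * gphi[[j]]
  f <- tensor_divergence(S, grid)
  lapply(f, function(comp) -lambda * comp)
}

#' Darcy-Brinkman interstitial drag `-eta(phi) (1 - phi) u / kappa(phi)`
#' @param u list of velocity component arrays.
#' @param phi phase field array.
#' @param eta viscosity field (array or scalar).
#' @param kappa permeability field (array or scalar), strictly positive.
#' @return list of drag force component arrays (antiparallel to `u`).
#' @export
darcy_drag <- function(u, phi, eta, kappa) {
  if (any(kappa <= 0)) stop("kappa must be > 0 everywhere")
  coef <- -eta * (1 - phi) / kappa
  lapply(u, function(comp) coef * comp)
}

#' Total free energy of the blood-thrombus system
#'
#' Mixing part `int lambda/2 |grad phi|^2 + lambda/(2 h^2) phi^2 (phi-1)^2`
#' plus elastic part `int (lambda_e / 2) tr(F^T F - I)`, by trapezoid
#' quadrature.  Returns the total with the two parts as attributes
#' `"mixing"` and `"elastic"`.
#' @param state `tf_state`.
#' @param params `tf_material`.
#' @param lambda_e scalar or array modulus (default `params$lambda_e0`).
#' @export
total_energy <- function(state, params, lambda_e = NULL) {
  g <- state$grid
  if (is.null(lambda_e)) lambda_e <- params$lambda_e0
  gphi <- gradient(state$phi, g)
  grad2 <- 0
  for (comp in gphi) grad2 <- grad2 + comp^2
  mix <- field_integral(params$lambda / 2 * grad2 +
                          params$lambda / (2 * params$h^2) *
                          state$phi^2 * (state$phi - 1)^2, g)
  F <- state_deformation(state)
  ela <- field_integral(lambda_e / 2 * trace_FtF_minus_I(F), g)
  structure(mix + ela, mixing = mix, elastic = ela)
}

#' Bulk thrombus volume fraction of a state
#'
#' Default convention `one_minus_phi`: `VF = int (1 - phi) dv / V`.
#' The `as_printed` convention `VF = int (1 - phi)/2 dv / V` (which
#' presumes a phase variable on \[-1, 1\]) is retained for comparison.
#' @param phi phase field array.
#' @param grid `tf_grid`.
#' @param convention `"one_minus_phi"` or `"as_printed"`.
#' @export
bulk_volume_fraction <- function(phi, grid, convention = c("one_minus_phi", "as_printed")) {
  convention <- match.arg(convention)
  num <- if (convention == "as_printed") (1 - phi) / 2 else (1 - phi)
  field_integral(num, grid) / field_integral(array(1, dim = dim(phi)), grid)
}

#' Equilibrium interface profile of the double well
#'
#' `phi(d) = (1 + tanh(d / (2 h))) / 2` where `d` is the signed distance to
#' the interface (positive on the blood side).  This is the exact 1D
#' minimizer of the mixing energy `lambda/2 |grad phi|^2 +
#' lambda/(2 h^2) phi^2 (1 - phi)^2`.
#' @param d signed distance array (positive in blood).
#' @param h interface thickness.
#' @export
interface_profile <- function(d, h) (1 + tanh(d / (2 * h))) / 2
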