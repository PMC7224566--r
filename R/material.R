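#' Material parameter set for blood-thrombus simulations
#'
#' Collects every constitutive constant of the two-phase model.  Quantities
#' are nondimensional by default; [unit_registry()] converts to and from SI
#' at the package boundary.
#'
#' @param rho1,rho2 mass density of blood and thrombus.
#' @param eta1,eta2 dynamic viscosity of blood and thrombus.
#' @param lambda_e0 elastic shear modulus scale of the thrombus.
#' @param sigma surface-tension parameter (>= 0).
#' @param h interface-thickness length scale.
#' @param gamma interfacial mobility constant multiplying the double-well
#'   term of the chemical potential.
#' @param tau phase relaxation parameter (mobility of the phase equation).
#' @param kappa_s,kappa_c shell and core permeability (shell-core mode).
#' @param a_f fibrin fiber radius (length; cancels in kappa/a_f^2 plots).
#' @param rho_Fbg fibrinogen molecular density in mg/mL (1.4 g/mL default).
#' @param fibrin_log_base base of the logarithm in the fibrin
#'   volume-fraction relation (10 or exp(1)).
#' @return object of class `tf_material`.
#' @export
material_params <- function(rho1 = 1, rho2 = 2, eta1 = 1, eta2 = 2,
                            lambda_e0 = 0.5, sigma = 1e-3, h = 0.05,
                            gamma = 1, tau = 1e-5,
                            kappa_s = 1e-2, kappa_c = 1e-4,
                            a_f = 1, rho_Fbg = 1400,
                            fibrin_log_base = 10) {
  vals <- c(rho1 = rho1, rho2 = rho2, eta1 = eta1, eta2 = eta2,
            h = h, gamma = gamma, tau = tau,
            kappa_s = kappa_s, kappa_c = kappa_c, a_f = a_f, rho_Fbg = rho_Fbg)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad)) stop("material parameters must be strictly positive: ",
                        paste(bad, collapse = ", "))
  if (sigma < 0) stop("sigma must be >= 0")
  if (lambda_e0 < 0) stop("lambda_e0 must be >= 0")
  structure(list(rho1 = rho1, rho2 = rho2, eta1 = eta1, eta2 = eta2,
                 lambda_e0 = lambda_e0, sigma = sigma, h = h, gamma = gamma,
                 tau = tau, kappa_s = kappa_s, kappa_c = kappa_c,
                 a_f = a_f, rho_Fbg = rho_Fbg,
                 fibrin_log_base = fibrin_log_base,
                 lambda = mixing_energy_density(sigma, h)),
            class = "tf_material")
}

#' @export
print.tf_material <- function(x, ...) {
  cat("<tf_material>\n")
  nm <- setdiff(names(x), "fibrin_log_base")
  cat(paste(sprintf("  %-10s %g", nm, unlist(x[nm])), collapse = "\n"), "\n")
  invisible(x)
}

#' Nondimensionalization scale registry
#'
#' Characteristic scales used to convert between nondimensional solver units
#' and SI.  Defaults are the oscillatory-rheometry scales: velocity
#' 3.33e-3 m/s, length 3e-4 m (the plate gap), density 1000 kg/m^3; derived
#' scales are time `L/U`, stress `rho U^2`, and dynamic viscosity `rho U L`.
#' @param velocity characteristic velocity (m/s).
#' @param length characteristic length (m).
#' @param density characteristic density (kg/m^3).
#' @export
unit_registry <- function(velocity = 3.33e-3, length = 3e-4, density = 1000) {
  list(velocity = velocity, length = length, density = density,
       time = length / velocity,
       stress = density * velocity^2,
       viscosity = density * velocity * length)
}

#' Permeability of a fibrous medium (Davies' law)
#'
#' Empirical permeability of a random fiber bed:
#' `kappa / a_f^2 = 1 / (16 psi_f^1.5 (1 + 56 psi_f^3))`,
#' strictly decreasing in the fiber solid fraction `psi_f`.
#'
#' @param psi_f fibrin solid volume fraction, in (0, 1].
#' @param a_f fiber radius.
#' @return permeability (units of `a_f^2`).
#' @examples
#' davies_permeability(0.25)        # = 1/3.75
#' @export
davies_permeability <- function(psi_f, a_f = 1) {
  if (any(a_f <= 0)) stop("a_f must be > 0")
  if (any(psi_f <= 0)) stop("psi_f must be > 0: the dilute limit diverges")
  if (any(psi_f > 1)) stop("psi_f must be <= 1")
  a_f^2 / (16 * psi_f^1.5 * (1 + 56 * psi_f^3))
}

#' Fibrin solid volume fraction from fibrinogen concentration
#'
#' Empirical relation `psi_f = c / (rho_Fbg * (0.015 log(c) + 0.13))` with
#' `c` in mg/mL.  The base of the logarithm is configurable (base 10 by
#' default, matching the companion power-law fits of the same data).
#'
#' @param c_Fbg fibrinogen concentration (mg/mL), > 0.
#' @param rho_Fbg fibrinogen molecular density (mg/mL).
#' @param log_base base of the logarithm (10 or exp(1)).
#' @return fibrin volume fraction (dimensionless).
#' @export
fibrin_volume_fraction <- function(c_Fbg, rho_Fbg = 1400, log_base = 10) {
  if (any(c_Fbg <= 0)) stop("c_Fbg must be > 0")
  br <- 0.015 * log(c_Fbg, base = log_base) + 0.13
  if (any(br <= 0))
    stop("c_Fbg below the validity range of the fibrin fraction relation ",
         sprintf("(need 0.015*log(c) + 0.13 > 0, i.e. c > %.3g mg/mL)",
                 log_base^(-0.13 / 0.015)))
  c_Fbg / (rho_Fbg * br)
}

#' Invert the fibrin volume-fraction relation
#'
#' Monotone bisection of [fibrin_volume_fraction()] in `log(c)` over
#' `c` in `[1e-3, 1000]` mg/mL (no closed-form inverse exists).
#' @param psi_f target fibrin volume fraction.
#' @inheritParams fibrin_volume_fraction
#' @return fibrinogen concentration (mg/mL).
#' @export
fibrin_concentration <- function(psi_f, rho_Fbg = 1400, log_base = 10) {
  vapply(psi_f, function(target) {
    lo <- 1e-3; hi <- 1000
    flo <- fibrin_volume_fraction(lo, rho_Fbg, log_base) - target
    fhi <- fibrin_volume_fraction(hi, rho_Fbg, log_base) - target
    if (flo > 0 || fhi < 0)
      stop(sprintf("psi_f = %g outside invertible range [%.3g, %.3g]",
                   target,
                   fibrin_volume_fraction(lo, rho_Fbg, log_base),
                   fibrin_volume_fraction(hi, rho_Fbg, log_base)))
    for (i in 1:200) {
      mid <- sqrt(lo * hi)
      if (fibrin_volume_fraction(mid, rho_Fbg, log_base) < target) lo <- mid else hi <- mid
      if (hi / lo < 1 + 1e-14) break
    }
    sqrt(lo * hi)
  }, numeric(1))
}

#' Mixing energy density from surface tension and interface thickness
#'
#' `lambda = 3 sigma h / (2 sqrt(2))`.
#' @param sigma surface tension parameter (>= 0).
#' @param h interface thickness (> 0).
#' @export
mixing_energy_density <- function(sigma, h) {
  if (any(h <= 0)) stop("h must be > 0")
  if (any(sigma < 0)) stop("sigma must be >= 0")
  3 * sigma * h / (2 * sqrt(2))
}

#' Linear mixture blend of a bulk property
#'
#' `value(phi) = v_thrombus + phi * (v_blood - v_thrombus)`, so that
#' `phi = 1` gives the blood value and `phi = 0` the thrombus value.
#' Out-of-range phase values are clamped for property evaluation only.
#' @param phi phase field value(s) (1 = blood, 0 = thrombus).
#' @param v_blood,v_thrombus endpoint property values.
#' @export
mixture_property <- function(phi, v_blood, v_thrombus) {
  p <- pmin(pmax(phi, 0), 1)
  v_thrombus + p * (v_blood - v_thrombus)
}

#' Calibrated thrombus relaxation time
#'
#' Power-law fit of the stress relaxation time against fibrinogen
#' concentration: `lambda_s = 10^(-0.7172 log10(c) - 1.1140)` seconds.
#' @param c_Fbg fibrinogen concentration (mg/mL), > 0.
#' @return relaxation time in seconds, strictly decreasing in `c_Fbg`.
#' @export
calibrated_relaxation_time <- function(c_Fbg) {
  if (any(c_Fbg <= 0)) stop("c_Fbg must be > 0")
  10^(-0.7172 * log10(c_Fbg) - 1.1140)
}

#' Elastic shear modulus field
#'
#' In `constant` mode the thrombus gets the uniform modulus
#' `params$lambda_e0` (zero in pure blood).  In `via_relaxation` mode the
#' local volume fraction `1 - phi` is mapped to a fibrinogen concentration
#' by inverting the fibrin volume-fraction relation, the calibrated
#' relaxation time is evaluated there, and the Kelvin-Voigt identity
#' `lambda_e = eta2 / lambda_s` gives the local modulus.
#'
#' @param phi_field phase field array.
#' @param params `tf_material`.
#' @param mode `"constant"` or `"via_relaxation"`.
#' @return array of nonnegative moduli; exactly zero where `phi = 1`.
#' @export
elastic_modulus_field <- function(phi_field, params, mode = c("constant", "via_relaxation")) {
  mode <- match.arg(mode)
  inside <- phi_field < 1 - 1e-12
  if (mode == "constant") {
    out <- array(0, dim = dim(phi_field))
    out[inside] <- params$lambda_e0
    return(out)
  }
  out <- array(0, dim = dim(phi_field))
  vf <- pmin(pmax(1 - phi_field[inside], 0), 1)
  pos <- vf > 1e-10
  if (any(pos)) {
    cvals <- fibrin_concentration(vf[pos], params$rho_Fbg, params$fibrin_log_base)
    lam_s <- calibrated_relaxation_time(cvals)
    vals <- numeric(sum(inside)); vals[pos] <- params$eta2 / lam_s
    out[inside] <- vals
  }
  out
}

#' Permeability field
#'
#' `shell_core` mode assigns `kappa_c` inside the core mask, `kappa_s` in
#' the shell mask, and a large free-flow sentinel elsewhere.  `davies` mode
#' evaluates Davies' law at the local volume fraction `psi_f = 1 - phi`
#' (capped at the same sentinel in nearly pure blood).
#'
#' @param phi_field phase field array.
#' @param params `tf_material`.
#' @param mode `"shell_core"` or `"davies"`.
#' @param core_mask,shell_mask logical arrays (shell-core mode only).
#' @param kappa_free free-flow sentinel permeability.
#' @return positive permeability array.
#' @export
permeability_field <- function(phi_field, params, mode = c("shell_core", "davies"),
                               core_mask = NULL, shell_mask = NULL,
                               kappa_free = 1e10) {
  mode <- match.arg(mode)
  if (mode == "shell_core") {
    if (is.null(core_mask) || is.null(shell_mask))
      stop("shell_core mode needs core_mask and shell_mask")
    out <- array(kappa_free, dim = dim(phi_field))
    out[shell_mask] <- params$kappa_s
    out[core_mask] <- params$kappa_c
    return(out)
  }
  psi <- pmax(1 - phi_field, 0)
  out <- array(kappa_free, dim = dim(phi_field))
  pos <- psi > 1e-8
  out[pos] <- pmin(davies_permeability(pmin(psi[pos], 1), params$a_f), kappa_free)
  out
}
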