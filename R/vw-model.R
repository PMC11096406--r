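#' Uniaxial kinematics of an incompressible isotropic material
#'
#' Converts nominal (engineering) strain under uniaxial extension into the
#' principal stretch and the two deviatoric strain invariants that isotropic
#' hyperelastic energies are written in.
#'
#' For a stretch `lambda = 1 + strain` with incompressible uniaxial
#' kinematics, `I1_bar = lambda^2 + 2/lambda` and
#' `I2_bar = 2*lambda + 1/lambda^2`. Both equal 3 in the undeformed state.
#'
#' @param strain Numeric vector of nominal strains; each must exceed -1
#'   (a strain of -1 would collapse the specimen to zero length).
#' @return A list with numeric vectors `stretch`, `I1_bar`, `I2_bar`.
#' @examples
#' vw_kinematics(c(0, 1))
#' @export
vw_kinematics <- function(strain) {
  if (!is.numeric(strain) || anyNA(strain)) {
    stop("`strain` must be a numeric vector without missing values")
  }
  if (any(strain <= -1)) {
    stop("nominal strain must be > -1 (stretch must be positive)")
  }
  stretch <- 1 + strain
  list(
    stretch = stretch,
    I1_bar  = stretch^2 + 2 / stretch,
    I2_bar  = 2 * stretch + 1 / stretch^2
  )
}

check_vw_params <- function(mu, gamma) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0) {
    stop("`mu` must be a single positive number (MPa)")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0) {
    stop("`gamma` must be a single nonnegative number")
  }
  invisible(NULL)
}

#' Veronda-Westmann strain energy density
#'
#' Energy per unit reference volume of the exponential Veronda-Westmann
#' hyperelastic law,
#' `Psi = (mu/gamma) * (exp(gamma*(I1_bar - 3)) - 1) - mu * (I2_bar - 3)`,
#' evaluated under incompressible uniaxial kinematics. At `gamma = 0` the
#' analytic series limit `mu*(I1_bar - 3) - mu*(I2_bar - 3)` is returned
#' rather than the indeterminate ratio.
#'
#' @param strain Numeric vector of nominal strains (> -1).
#' @param mu Stiffness-scale coefficient (MPa, > 0).
#' @param gamma Strain-stiffening exponent (dimensionless, >= 0).
#' @return Numeric vector of energies (MPa); zero at zero strain.
#' @seealso [vw_nominal_stress()] for the work-conjugate nominal stress.
#' @examples
#' vw_strain_energy(1, mu = 1, gamma = 0)   # 0.75
#' @export
vw_strain_energy <- function(strain, mu, gamma) {
  check_vw_params(mu, gamma)
  kin <- vw_kinematics(strain)
  dev2 <- mu * (kin$I2_bar - 3)
  if (gamma == 0) {
    mu * (kin$I1_bar - 3) - dev2
  } else {
    # expm1 keeps the small-gamma*(I1-3) regime accurate
    (mu / gamma) * expm1(gamma * (kin$I1_bar - 3)) - dev2
  }
}

#' Veronda-Westmann nominal stress under uniaxial extension
#'
#' Nominal (first Piola-Kirchhoff) stress along the loading direction,
#' `sigma_N = 2*mu*(1 - lambda^-3) * (lambda*exp(gamma*(I1_bar - 3)) - 1)`,
#' the derivative of [vw_strain_energy()] with respect to the stretch under
#' incompressible uniaxial kinematics. Because the energy carries the full
#' `-mu*(I2_bar - 3)` term, the initial tangent modulus is zero and the
#' stress grows quadratically at small strain, `sigma_N ~ 6*mu*strain^2` —
#' a pronounced toe region.
#'
#' @inheritParams vw_strain_energy
#' @return Numeric vector of nominal stresses (MPa); zero at zero strain.
#' @examples
#' vw_nominal_stress(1, mu = 1, gamma = 0)  # 1.75
#' @export
vw_nominal_stress <- function(strain, mu, gamma) {
  check_vw_params(mu, gamma)
  kin <- vw_kinematics(strain)
  2 * mu * (1 - kin$stretch^-3) *
    (kin$stretch * exp(gamma * (kin$I1_bar - 3)) - 1)
}

# Jacobian of the nominal stress with respect to (mu, gamma); used by the
# least-squares fitter. d sigma/d mu = sigma/mu; the gamma derivative only
# touches the exponential factor.
vw_stress_jacobian <- function(strain, mu, gamma) {
  kin <- vw_kinematics(strain)
  e <- exp(gamma * (kin$I1_bar - 3))
  pre <- 2 * (1 - kin$stretch^-3)
  cbind(
    mu    = pre * (kin$stretch * e - 1),
    gamma = 2 * mu * (1 - kin$stretch^-3) * kin$stretch * e *
      (kin$I1_bar - 3)
  )
}

#' Define a hyperelastic law for least-squares fitting
#'
#' A light plugin seam so that laws other than Veronda-Westmann can be fit
#' to uniaxial data with [fit_hyperelastic()]. A law supplies its uniaxial
#' nominal-stress function, its strain-energy function, parameter bounds and
#' an initializer.
#'
#' @param name Law name (string).
#' @param par_names Character vector naming the parameters.
#' @param stress `function(strain, par)` returning nominal stress (MPa).
#' @param energy `function(strain, par)` returning strain energy (MPa).
#' @param lower,upper Numeric parameter bounds (same length as `par_names`).
#' @param init `function(curve)` returning a feasible starting vector.
#' @param jacobian Optional `function(strain, par)` returning the
#'   `length(strain) x length(par)` Jacobian of the stress; numerical
#'   differentiation is used when absent.
#' @return An object of class `hyperelastic_law`.
#' @export
hyperelastic_law <- function(name, par_names, stress, energy, lower, upper,
                             init, jacobian = NULL) {
  stopifnot(is.character(name), length(par_names) >= 1L,
            is.function(stress), is.function(energy), is.function(init),
            length(lower) == length(par_names),
            length(upper) == length(par_names))
  structure(
    list(name = name, par_names = par_names, stress = stress,
         energy = energy, lower = lower, upper = upper, init = init,
         jacobian = jacobian),
    class = "hyperelastic_law"
  )
}

#' The Veronda-Westmann law as a fit plugin
#'
#' Parameters are `mu` in (1e-6, 1e3) MPa and `gamma` in \[0, 50\].
#' Initialization fixes `gamma0 = 0.05` and solves `mu0` in closed form
#' from the stress at the mid-strain point (the model is linear in `mu`),
#' which removes any dependence on arbitrary starting values.
#'
#' @return A `hyperelastic_law` object.
#' @export
vw_law <- function() {
  hyperelastic_law(
    name = "veronda-westmann",
    par_names = c("mu", "gamma"),
    stress = function(strain, par) vw_nominal_stress(strain, par[1], par[2]),
    energy = function(strain, par) vw_strain_energy(strain, par[1], par[2]),
    lower = c(1e-6, 0),
    upper = c(1e3, 50),
    init = function(curve) {
      eps <- curve$strain
      sig <- curve$stress
      gamma0 <- 0.05
      i <- which.min(abs(eps - max(eps) / 2))
      if (eps[i] <= 0) i <- which(eps > 0)[1]
      # sigma is linear in mu, so mu0 follows from one point
      denom <- vw_nominal_stress(eps[i], 1, gamma0)
      mu0 <- if (is.finite(denom) && denom > 0) sig[i] / denom else 1
      c(mu = min(max(mu0, 1e-5), 999), gamma = gamma0)
    },
    jacobian = function(strain, par) {
      vw_stress_jacobian(strain, par[1], par[2])
    }
  )
}

#' Fit a hyperelastic law to a stress-strain curve by least squares
#'
#' Minimizes the unweighted sum of squared nominal-stress residuals over the
#' law's parameter box using bounded Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]) with the law's analytic Jacobian when available.
#' The curve is expected to be truncated at its failure peak (see
#' [extract_properties()]).
#'
#' @param curve A `stress_strain` object (or any list with numeric `strain`
#'   and `stress` of equal length >= 5).
#' @param law A `hyperelastic_law`; default [vw_law()].
#' @param relative If `TRUE`, residuals are divided by
#'   `pmax(stress, small)` giving a relative-error fit. Off by default: the
#'   plain least-squares objective is the reference behaviour.
#' @return An object of class `vw_fit`: a list with `par` (named parameter
#'   vector), `r_squared`, `residual_norm` (MPa), `converged`,
#'   `energy_at_peak` (strain energy at the fitted parameters and the
#'   curve's peak stretch, MPa), `fitted`, `law` and the `nls.lm` `info`
#'   code.
#' @examples
#' eps <- seq(0, 1.5, length.out = 50)
#' curve <- stress_strain(eps, vw_nominal_stress(eps, 0.5, 0.1))
#' fit_hyperelastic(curve)$par
#' @export
fit_hyperelastic <- function(curve, law = vw_law(), relative = FALSE) {
  stopifnot(inherits(law, "hyperelastic_law"))
  eps <- as.numeric(curve$strain)
  sig <- as.numeric(curve$stress)
  if (length(eps) != length(sig)) stop("strain and stress lengths differ")
  if (length(eps) < 5L) stop("at least 5 points are required for fitting")
  w <- if (relative) 1 / pmax(sig, 1e-4) else rep(1, length(sig))

  fn <- function(par) w * (law$stress(eps, par) - sig)
  jac <- if (is.null(law$jacobian)) NULL else function(par) {
    w * law$jacobian(eps, par)
  }
  start <- pmin(pmax(law$init(curve), law$lower + 1e-12), law$upper)
  res <- minpack.lm::nls.lm(
    par = start, fn = fn, jac = jac,
    lower = law$lower, upper = law$upper,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12, gtol = 1e-12)
  )
  par <- stats::setNames(as.numeric(res$par), law$par_names)
  fitted <- law$stress(eps, par)
  ss_res <- sum((fitted - sig)^2)
  ss_tot <- sum((sig - mean(sig))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res == 0)
  peak_strain <- eps[which.max(sig)]
  structure(
    list(
      par = par,
      r_squared = r2,
      residual_norm = sqrt(ss_res),
      converged = res$info %in% 1:4,
      info = res$info,
      energy_at_peak = law$energy(peak_strain, par),
      fitted = fitted,
      law = law$name
    ),
    class = "vw_fit"
  )
}

#' @rdname fit_hyperelastic
#' @export
vw_fit <- function(curve, relative = FALSE) {
  fit_hyperelastic(curve, law = vw_law(), relative = relative)
}

#' @export
print.vw_fit <- function(x, ...) {
  cat(sprintf("%s fit: %s\n", x$law,
              paste(sprintf("%s = %.4g", names(x$par), x$par),
                    collapse = ", ")))
  cat(sprintf("  R^2 = %.4f, ||resid|| = %.3g MPa, converged: %s\n",
              x$r_squared, x$residual_norm, x$converged))
  invisible(x)
}
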