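#' Build a validated osteon parameter set
#'
#' Assembles geometry, transverse-isotropic drained elastic constants,
#' poroelastic and fluid constants, and the harmonic axial-strain load into
#' the single input record consumed by every solver in the package. The
#' defaults are the reference parameterisation for a human osteon used
#' throughout: a 50/150 um annulus, canalicular radius 0.5 um, Biot modulus
#' 38 GPa, intrinsic permeability 1e-18 m^2, bone interstitial fluid treated
#' as water, and a 0.1% axial strain cycled at 1 Hz.
#'
#' All values are SI (Pa, m, s, kg). `l = b - a` and `omega = 2*pi*freq_hz`
#' are derived, never supplied.
#'
#' @param E_r,E_z radial and longitudinal drained Young moduli, Pa.
#' @param mu_r,mu_z radial and longitudinal drained Poisson ratios.
#' @param M Biot storage modulus, Pa.
#' @param alpha,alpha_prime radial and longitudinal Biot effective-stress
#'   coefficients.
#' @param k intrinsic permeability of the osteon wall, m^2.
#' @param mu_f fluid dynamic viscosity, Pa s.
#' @param rho_f fluid density, kg m^-3.
#' @param a,b inner (Haversian canal) and outer (cement line) radii, m.
#' @param R canalicular radius, m.
#' @param eps_z0 axial strain amplitude (dimensionless).
#' @param freq_hz loading frequency, Hz (angular frequency is `2*pi*freq_hz`).
#' @param case outer-wall boundary case: `"I"` (elastic restrained; the
#'   surrounding fluid pushes on the cement line with the local pore
#'   pressure) or `"II"` (displacement confined, rigid cement line).
#' @param beta_form `"corrected"` uses the oscillatory Stokes wavenumber
#'   `sqrt(i*omega*rho_f/mu_f)`; `"printed"` evaluates the literal
#'   `sqrt(i*omega/mu_f)` variant for comparison (see the methods vignette).
#' @param outer_restraint case-I mechanical condition at `r = b`:
#'   `"pressure-balanced"` (total radial stress equals minus the local pore
#'   pressure), `"free"` (zero total radial stress) or `"spring"` (elastic
#'   restraint of stiffness `spring_stiffness` plus the fluid push).
#' @param spring_stiffness restraint stiffness, Pa/m; only used when
#'   `outer_restraint = "spring"`.
#' @return an object of class `osteon_params`: a validated named list with
#'   the derived fields `l`, `omega` and `strain_rate` filled in.
#' @examples
#' p <- osteon_params()
#' p$l      # 1e-4 m canalicular length
#' p$omega  # 2*pi rad/s
#' @export
osteon_params <- function(E_r = 15.9e9, E_z = 20.3e9,
                          mu_r = 0.328, mu_z = 0.25,
                          M = 38e9, alpha = 0.132, alpha_prime = 0.092,
                          k = 1e-18, mu_f = 1e-3, rho_f = 1000,
                          a = 50e-6, b = 150e-6, R = 5e-7,
                          eps_z0 = 1e-3, freq_hz = 1,
                          case = c("I", "II"),
                          beta_form = c("corrected", "printed"),
                          outer_restraint = c("pressure-balanced", "free",
                                              "spring"),
                          spring_stiffness = 0) {
  p <- list(
    E_r = E_r, E_z = E_z, mu_r = mu_r, mu_z = mu_z,
    M = M, alpha = alpha, alpha_prime = alpha_prime,
    k = k, mu_f = mu_f, rho_f = rho_f,
    a = a, b = b, R = R,
    eps_z0 = eps_z0, freq_hz = freq_hz,
    case = match.arg(case),
    beta_form = match.arg(beta_form),
    outer_restraint = match.arg(outer_restraint),
    spring_stiffness = spring_stiffness
  )
  p$l <- b - a
  p$omega <- 2 * pi * freq_hz
  p$strain_rate <- abs(eps_z0) * p$omega
  validate_osteon_params(p)
  structure(p, class = "osteon_params")
}

validate_osteon_params <- function(p) {
  num1 <- function(x, nm) {
    if (!is.numeric(p[[x]]) || length(p[[x]]) != 1 || !is.finite(p[[x]]))
      stop("`", x, "` must be a single finite number", call. = FALSE)
  }
  for (nm in c("E_r", "E_z", "mu_r", "mu_z", "M", "alpha", "alpha_prime",
               "k", "mu_f", "rho_f", "a", "b", "R", "eps_z0", "freq_hz",
               "spring_stiffness"))
    num1(nm)
  stopifnot(
    "E_r must be positive" = p$E_r > 0,
    "E_z must be positive" = p$E_z > 0,
    "mu_r must lie in (-1, 0.5)" = p$mu_r > -1 && p$mu_r < 0.5,
    "M must be positive" = p$M > 0,
    "alpha must lie in [0, 1]" = p$alpha >= 0 && p$alpha <= 1,
    "alpha_prime must lie in [0, 1]" = p$alpha_prime >= 0 && p$alpha_prime <= 1,
    "k must be positive" = p$k > 0,
    "mu_f must be positive" = p$mu_f > 0,
    "rho_f must be positive" = p$rho_f > 0,
    "need 0 < a < b" = p$a > 0 && p$a < p$b,
    "need 0 < R < b - a" = p$R > 0 && p$R < p$b - p$a,
    "freq_hz must be positive" = p$freq_hz > 0,
    "spring_stiffness must be non-negative" = p$spring_stiffness >= 0
  )
  if (p$E_z - p$E_z * p$mu_r - 2 * p$E_r * p$mu_z^2 <= 0)
    stop("non-physical elastic constants: ",
         "E_z - E_z*mu_r - 2*E_r*mu_z^2 must be positive (got ",
         format(p$E_z - p$E_z * p$mu_r - 2 * p$E_r * p$mu_z^2), " Pa)",
         call. = FALSE)
  invisible(p)
}

#' Reference parameter set
#'
#' The package's built-in reference parameterisation (see [osteon_params()]
#' for the values). Pure function: repeated calls return identical sets.
#'
#' @param ... overrides passed to [osteon_params()].
#' @return an `osteon_params` object.
#' @export
default_parameters <- function(...) osteon_params(...)

#' Modify an existing parameter set
#'
#' Rebuilds the set through the validating constructor so derived fields
#' (`l`, `omega`, `strain_rate`) stay consistent.
#'
#' @param params an `osteon_params` object.
#' @param ... fields to replace, as in [osteon_params()].
#' @return an `osteon_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "osteon_params"))
  keep <- params[setdiff(names(formals(osteon_params)), "...")]
  repl <- list(...)
  keep[names(repl)] <- repl
  do.call(osteon_params, keep)
}

#' @export
print.osteon_params <- function(x, ...) {
  cat("<osteon_params>\n")
  cat(sprintf("  geometry : a = %g m, b = %g m (l = %g m), R = %g m\n",
              x$a, x$b, x$l, x$R))
  cat(sprintf("  elastic  : E_r = %g Pa, E_z = %g Pa, mu_r = %g, mu_z = %g\n",
              x$E_r, x$E_z, x$mu_r, x$mu_z))
  cat(sprintf("  poro     : M = %g Pa, alpha = %g, alpha' = %g, k = %g m^2\n",
              x$M, x$alpha, x$alpha_prime, x$k))
  cat(sprintf("  fluid    : mu_f = %g Pa s, rho_f = %g kg/m^3\n",
              x$mu_f, x$rho_f))
  cat(sprintf("  load     : eps_z0 = %g at %g Hz (strain rate %g 1/s), case %s\n",
              x$eps_z0, x$freq_hz, x$strain_rate, x$case))
  cat(sprintf("  options  : beta = %s, case-I restraint = %s\n",
              x$beta_form, x$outer_restraint))
  invisible(x)
}

# ---- derived stiffness and wavenumbers --------------------------------------

#' Transverse-isotropic drained stiffness components
#'
#' Inverts the axisymmetric compliance of a skeleton that is isotropic in the
#' radial-circumferential plane (compliance entries `1/E_r`, `-mu_r/E_r`,
#' `-mu_z/E_z`, `1/E_z`), giving the stiffness entries needed by the radial
#' equilibrium of the osteon wall. `c11` is the radial stiffness component
#' that multiplies the radial strain; its closed form is
#' \deqn{C_{11} = \frac{E_r (E_z - E_r \mu_z^2)}
#'   {(1+\mu_r)(E_z - E_z \mu_r - 2 E_r \mu_z^2)}.}
#'
#' @param params an `osteon_params` object.
#' @return named numeric vector with components `c11`, `c12`, `c13`, `c33`
#'   (Pa).
#' @export
stiffness_components <- function(params) {
  stopifnot(inherits(params, "osteon_params"))
  Er <- params$E_r; Ez <- params$E_z
  mur <- params$mu_r; muz <- params$mu_z
  den <- Ez - Ez * mur - 2 * Er * muz^2
  c(c11 = Er * (Ez - Er * muz^2) / ((1 + mur) * den),
    c12 = Er * (mur * Ez + Er * muz^2) / ((1 + mur) * den),
    c13 = muz * Er * Ez / den,
    c33 = Ez^2 * (1 - mur) / den)
}

#' Radial stiffness component M11
#'
#' The stiffness-tensor component governing the radial response, i.e. the
#' `c11` entry of [stiffness_components()]. Strictly positive for admissible
#' elastic constants; degenerates to the isotropic constrained modulus
#' `E(1-nu)/((1+nu)(1-2nu))` when `E_r = E_z` and `mu_r = mu_z`.
#'
#' @inheritParams stiffness_components
#' @return modulus, Pa.
#' @export
stiffness_m11 <- function(params) {
  unname(stiffness_components(params)["c11"])
}

#' Consolidation wavenumber of the osteon wall
#'
#' Principal square root of
#' \eqn{i\omega\mu_f (M_{11} + M\alpha^2) / (k M M_{11})}; its inverse is the
#' radial decay length of the oscillatory pore-pressure profile. The
#' principal branch puts the argument at exactly \eqn{\pi/4}.
#'
#' @inheritParams stiffness_components
#' @return complex wavenumber, 1/m.
#' @export
consolidation_wavenumber <- function(params) {
  stopifnot(inherits(params, "osteon_params"))
  m11 <- stiffness_m11(params)
  sqrt(1i * params$omega * params$mu_f * (m11 + params$M * params$alpha^2) /
         (params$k * params$M * m11))
}

#' Oscillatory Stokes wavenumber of the canaliculus
#'
#' Principal square root of \eqn{i\omega\rho_f/\mu_f} (the Womersley
#' wavenumber of oscillatory tube flow); it measures the departure of the
#' canalicular velocity profile from the steady Poiseuille parabola and
#' recovers it exactly as \eqn{\omega \to 0}. The `"printed"` form evaluates
#' \eqn{\sqrt{i\omega/\mu_f}} instead, which omits the fluid density and does
#' not recover the Poiseuille limit; it is kept only for comparison (see the
#' methods vignette).
#'
#' @inheritParams stiffness_components
#' @param form override the `beta_form` stored in `params`.
#' @return complex wavenumber, 1/m.
#' @export
stokes_wavenumber <- function(params, form = NULL) {
  stopifnot(inherits(params, "osteon_params"))
  form <- if (is.null(form)) params$beta_form else
    match.arg(form, c("corrected", "printed"))
  if (form == "corrected")
    sqrt(1i * params$omega * params$rho_f / params$mu_f)
  else
    sqrt(1i * params$omega / params$mu_f)
}
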