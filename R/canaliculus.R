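# Canaliculus-scale oscillatory Stokes flow.
#
# A canaliculus is a straight tube of radius R spanning the osteon wall from
# the Haversian canal (z' = a, drained, p_0(a) = 0) to the cement line
# (z' = b, amplitude p_0(b) from the osteon solution). The axial pressure is
# linear along the tube; the axial velocity is the classical oscillatory
# tube-flow profile with wavenumber beta, and the flow rate and wall shear
# stress follow in closed form:
#   Q     = (2 pi / (i omega rho l)) p_0(b) [ (R/beta) I1(bR)/I0(bR) - R^2/2 ]
#   tau_w = (mu beta / (i omega rho l)) p_0(b) I1(bR)/I0(bR)

# Cancellation-free evaluation of the two oscillatory tube-flow brackets.
# For the physiological ranges |beta R| <= ~0.01, so both brackets are tiny
# differences of order-one Bessel values; the direct forms lose ~8 digits.
# Ascending series in q = (beta x / 2)^2 remove the cancellation exactly.

# 1 - I0(beta r)/I0(beta R)  (vectorised over r)
vel_bracket <- function(beta, r, R) {
  z <- beta * R
  if (Mod(z) > 0.5) {
    i0r <- besselI_c(beta * r, 0, scaled = TRUE) * exp(beta * (r - R))
    i0R <- besselI_c(z, 0, scaled = TRUE)
    return(1 - i0r / i0R)
  }
  qR <- (beta * R / 2)^2
  qr <- (beta * r / 2)^2
  d <- qR - qr
  # I0(zR) - I0(zr) = d * sum_k p_k / (k!)^2, p_k = sum_j qR^j qr^(k-1-j)
  s <- rep(0 + 0i, length(r))
  pk <- rep(1 + 0i, length(r))
  qRk <- 1 + 0i
  fact <- 1
  for (k in seq_len(60)) {
    fact <- fact * k
    add <- pk / fact^2
    s <- s + add
    if (max(Mod(add)) <= 1e-18 * max(Mod(s), 1e-300)) break
    qRk <- qRk * qR
    pk <- qRk + qr * pk
  }
  d * s / besselI_c(beta * R, 0)
}

# (R/beta) I1(beta R)/I0(beta R) - R^2/2
q_bracket <- function(beta, R) {
  z <- beta * R
  if (Mod(z) > 0.5) {
    ratio <- besselI_c(z, 1, scaled = TRUE) / besselI_c(z, 0, scaled = TRUE)
    return((R / beta) * ratio - R^2 / 2)
  }
  q <- (z / 2)^2
  # (R/beta) I1 - (R^2/2) I0 = -(R^2/2) sum_{k>=1} q^k k / ((k+1) (k!)^2)
  s <- 0 + 0i
  term <- 1 + 0i
  for (k in seq_len(60)) {
    term <- term * q / k^2
    add <- term * k / (k + 1)
    s <- s + add
    if (Mod(add) <= 1e-18 * max(Mod(s), 1e-300)) break
  }
  -(R^2 / 2) * s / besselI_c(z, 0)
}

#' Pressure amplitude along a canaliculus
#'
#' Linear interpolation between the endpoint amplitudes at the Haversian
#' wall (`z' = a`) and the cement line (`z' = b`).
#'
#' @param z_prime axial position(s) along the canaliculus, m, in `[a, b]`.
#' @param p0a,p0b complex endpoint pressure amplitudes, Pa.
#' @param params an [osteon_params()] object (supplies `a`, `b`, `l`).
#' @return complex vector, Pa.
#' @export
canalicular_pressure_amplitude <- function(z_prime, p0a, p0b, params) {
  stopifnot(inherits(params, "osteon_params"))
  z_prime <- check_radius_in_wall(z_prime, params)
  p0a + (p0b - p0a) * (z_prime - params$a) / params$l
}

#' Oscillatory axial velocity profile in a canaliculus
#'
#' Complex amplitude of the axial fluid velocity at tube radius `r_prime`:
#' \deqn{u(r') = \frac{p_0(a) - p_0(b)}{i\omega\rho l}
#'   \left[1 - \frac{I_0(\beta r')}{I_0(\beta R)}\right].}
#' No-slip holds identically at `r' = R`; as \eqn{\omega \to 0} the profile
#' tends to the Poiseuille parabola
#' \eqn{(p_0(a)-p_0(b)) (R^2 - r'^2) / (4 \mu_f l)}.
#'
#' @param r_prime radial position(s) inside the tube, m, in `[0, R]`.
#' @param params an [osteon_params()] object.
#' @param p0a,p0b complex endpoint pressure amplitudes, Pa. By default the
#'   osteon solution is used: `p0a = 0` and `p0b = pressure_amplitude(b)`.
#' @return complex vector, m/s.
#' @export
velocity_amplitude <- function(r_prime, params, p0a = NULL, p0b = NULL) {
  stopifnot(inherits(params, "osteon_params"))
  if (any(r_prime < 0 | r_prime > params$R))
    stop("tube radius outside [0, R]", call. = FALSE)
  ep <- endpoint_pressures(params, p0a, p0b)
  beta <- stokes_wavenumber(params)
  (ep$p0a - ep$p0b) / (1i * params$omega * params$rho_f * params$l) *
    vel_bracket(beta, r_prime, params$R)
}

endpoint_pressures <- function(params, p0a, p0b) {
  if (is.null(p0b)) {
    p0b <- pressure_amplitude(params$b, params)
    if (is.null(p0a)) p0a <- 0 + 0i
  }
  if (is.null(p0a)) p0a <- 0 + 0i
  list(p0a = as.complex(p0a), p0b = as.complex(p0b))
}

#' Canalicular fluid flow rate (FFR) amplitude
#'
#' Closed-form complex amplitude of the volumetric flow rate through one
#' canaliculus, the tube integral of the oscillatory velocity profile:
#' \deqn{Q = \frac{2\pi}{i\omega\rho l} p_0(b)
#'   \left[\frac{R}{\beta}\frac{I_1(\beta R)}{I_0(\beta R)}
#'         - \frac{R^2}{2}\right].}
#' In the low-frequency limit `|Q|` tends to the Poiseuille discharge
#' \eqn{\pi R^4 |p_0(b)| / (8 \mu_f l)}.
#'
#' @param params an [osteon_params()] object.
#' @param p0b complex pressure amplitude at the cement line, Pa; computed
#'   from the osteon solution when omitted (`p_0(a) = 0` always).
#' @return complex flow rate, m^3/s.
#' @export
flow_rate <- function(params, p0b = NULL) {
  stopifnot(inherits(params, "osteon_params"))
  ep <- endpoint_pressures(params, NULL, p0b)
  beta <- stokes_wavenumber(params)
  2 * pi / (1i * params$omega * params$rho_f * params$l) * ep$p0b *
    q_bracket(beta, params$R)
}

#' Canalicular wall fluid shear stress (FSS) amplitude
#'
#' Closed-form complex amplitude of the viscous shear stress exerted on the
#' canalicular wall (equivalently on the osteocyte process membrane):
#' \deqn{\tau_w = \frac{\mu_f \beta}{i\omega\rho l} p_0(b)
#'   \frac{I_1(\beta R)}{I_0(\beta R)}.}
#' In the low-frequency limit `|tau_w|` tends to the Poiseuille value
#' \eqn{R |p_0(b)| / (2 l)}.
#'
#' @inheritParams flow_rate
#' @return complex shear stress, Pa.
#' @export
wall_shear <- function(params, p0b = NULL) {
  stopifnot(inherits(params, "osteon_params"))
  ep <- endpoint_pressures(params, NULL, p0b)
  beta <- stokes_wavenumber(params)
  ratio <- besselI_c(beta * params$R, 1, scaled = TRUE) /
    besselI_c(beta * params$R, 0, scaled = TRUE)
  params$mu_f * beta / (1i * params$omega * params$rho_f * params$l) *
    ep$p0b * ratio
}

#' Full canalicular solution for one boundary case
#'
#' Solves the osteon wall for the requested case and evaluates the
#' canalicular flow rate and wall shear stress amplitudes.
#'
#' @param params an [osteon_params()] object.
#' @param case boundary case override (`"I"` or `"II"`).
#' @return object of class `canalicular_solution`: list with complex `Q`
#'   (m^3/s), `tau_w` (Pa), `beta` (1/m), endpoint pressures `p0a`, `p0b`
#'   (Pa), the `case` tag and the input `params`. Use [generics::tidy()] /
#'   [generics::glance()] for tabular views.
#' @examples
#' sol <- canalicular_solution(osteon_params())
#' Mod(sol$Q)      # FFR amplitude, m^3/s
#' Mod(sol$tau_w)  # FSS amplitude, Pa
#' @export
canalicular_solution <- function(params, case = NULL) {
  stopifnot(inherits(params, "osteon_params"))
  if (!is.null(case)) params <- update_params(params, case = case)
  bc <- solve_boundary_constants(params)
  p0b <- pressure_amplitude(params$b, params, bc)
  structure(
    list(Q = flow_rate(params, p0b),
         tau_w = wall_shear(params, p0b),
         beta = stokes_wavenumber(params),
         p0a = 0 + 0i, p0b = p0b,
         case = params$case,
         bc = bc,
         params = params),
    class = "canalicular_solution"
  )
}

#' @export
print.canalicular_solution <- function(x, ...) {
  cat("<canalicular_solution> case", x$case, "\n")
  cat(sprintf("  |Q|     = %.6g m^3/s (phase %.4f rad)\n",
              Mod(x$Q), Arg(x$Q)))
  cat(sprintf("  |tau_w| = %.6g Pa    (phase %.4f rad)\n",
              Mod(x$tau_w), Arg(x$tau_w)))
  cat(sprintf("  p_0(b)  = %.6g Pa at eps_z0 = %g, f = %g Hz\n",
              Mod(x$p0b), x$params$eps_z0, x$params$freq_hz))
  invisible(x)
}

#' Velocity profile across the canaliculus as a table
#'
#' @param params an [osteon_params()] object.
#' @param case boundary case override.
#' @param n number of radial sample points in `[0, R]`.
#' @return tibble with columns `r_prime_m`, `re_u_m_s`, `im_u_m_s`,
#'   `abs_u_m_s`, `case`.
#' @export
velocity_profile <- function(params, case = NULL, n = 101) {
  stopifnot(n >= 2)
  if (!is.null(case)) params <- update_params(params, case = case)
  p0b <- pressure_amplitude(params$b, params)
  r <- seq(0, params$R, length.out = n)
  u <- velocity_amplitude(r, params, 0, p0b)
  tibble::tibble(r_prime_m = r,
                 re_u_m_s = Re(u), im_u_m_s = Im(u), abs_u_m_s = Mod(u),
                 case = params$case)
}

#' Strain-rate-normalised flow and shear sensitivities
#'
#' The model is linear in the load, so `|Q|` and `|tau_w|` are exactly
#' proportional to the strain-rate amplitude `eps_z0 * omega`. This returns
#' the proportionality constants, computed through the strain-normalised
#' cement-line pressure `p_0(b)/eps_z0`; the result is identical for any
#' non-zero `eps_z0`.
#'
#' @inheritParams canalicular_solution
#' @return tibble with one row: `case`, `ffr_per_strain_rate` (m^3),
#'   `fss_per_strain_rate` (Pa s).
#' @export
strain_rate_sensitivity <- function(params, case = NULL) {
  stopifnot(inherits(params, "osteon_params"))
  if (params$eps_z0 == 0)
    stop("strain-rate sensitivity needs eps_z0 > 0", call. = FALSE)
  sol <- canalicular_solution(params, case)
  rate <- abs(params$eps_z0) * params$omega
  tibble::tibble(case = sol$case,
                 ffr_per_strain_rate = Mod(sol$Q) / rate,
                 fss_per_strain_rate = Mod(sol$tau_w) / rate)
}
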