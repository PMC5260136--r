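# Osteon-scale poroelastic solution.
#
# The pore pressure amplitude in the wall is
#   p_0(r) = P * [ F(r) - 1 ],   F(r) = n(r)/n(a),
#   n(r)   = I0(Cr) K1(Cb) + K0(Cr) I1(Cb),
# with C the consolidation wavenumber and
#   P = M*M11*(alpha*c_m + alpha'*eps_z0) / (M11 + M*alpha^2).
# F is built so that p vanishes at the drained Haversian wall (r = a) and
# dp/dr vanishes at the impermeable cement line (r = b). The volumetric
# radial-strain constant c_m couples back to the radial equilibrium of the
# annulus, whose displacement ansatz is
#   u_r(r) = c1*r + c2/r + (alpha/M11) * (1/r) * int_a^r s p_0(s) ds ,
# so (c1, c2) follow from a 2x2 complex linear system fixed by the wall
# conditions; c_m = 2*c1.

# Scaled Bessel combinations across the annulus. All exponential factors are
# cancelled analytically: every term carries exp() of an argument with
# non-positive real part, so nothing overflows however thin the pressure
# boundary layer (large |C|b) becomes.
annulus_shape <- function(C, a, b, r) {
  i0r <- besselI_c(C * r, 0, scaled = TRUE)
  i1r <- besselI_c(C * r, 1, scaled = TRUE)
  k0r <- besselK_c(C * r, 0, scaled = TRUE)
  k1r <- besselK_c(C * r, 1, scaled = TRUE)
  i0a <- besselI_c(C * a, 0, scaled = TRUE)
  i1a <- besselI_c(C * a, 1, scaled = TRUE)
  k0a <- besselK_c(C * a, 0, scaled = TRUE)
  k1a <- besselK_c(C * a, 1, scaled = TRUE)
  i1b <- besselI_c(C * b, 1, scaled = TRUE)
  k1b <- besselK_c(C * b, 1, scaled = TRUE)

  ntil <- function(i0, k0, x) exp(2 * C * (x - b)) * i0 * k1b + k0 * i1b
  mtil <- function(i1, k1, x) exp(2 * C * (x - b)) * i1 * k1b - k1 * i1b
  na <- ntil(i0a, k0a, a)
  mr <- mtil(i1r, k1r, r)
  ma <- mtil(i1a, k1a, a)

  list(
    F = exp(C * (a - r)) * ntil(i0r, k0r, r) / na,
    dF = C * exp(C * (a - r)) * mr / na,
    # G(r) = int_a^r s F(s) ds, via int r I0 = (r/C) I1, int r K0 = -(r/C) K1
    G = ((r / C) * exp(C * (a - r)) * mr - (a / C) * ma) / na
  )
}

# pressure prefactor split as P = P0 + P1 * c1 (linear in the unknown c1)
pressure_prefactor_parts <- function(params, m11) {
  denom <- m11 + params$M * params$alpha^2
  list(P0 = params$M * m11 * params$alpha_prime * params$eps_z0 / denom,
       P1 = 2 * params$M * m11 * params$alpha / denom)
}

#' Solve the osteon wall boundary constants
#'
#' Determines the complex constants `(c1, c2)` of the radial displacement
#' ansatz and the volumetric radial-strain constant `c_m = 2*c1` that enters
#' the pore-pressure amplitude, for the requested outer-wall case. The inner
#' wall (Haversian canal) always carries zero total radial stress and zero
#' pore pressure; the outer wall (cement line) is impermeable, with
#' mechanics set by the case:
#'
#' * case I ("elastic restrained"): the surrounding fluid pushes on the
#'   cement line, by default with the local pore pressure, so the total
#'   radial stress satisfies `sigma_rr(b) = -p_0(b)` (zero effective radial
#'   stress). The alternatives `"free"` and `"spring"` are selectable via
#'   the parameter set's `outer_restraint` field.
#' * case II ("displacement confined"): `u_r(b) = 0` at a rigid cement line.
#'
#' The pressure prefactor is linear in `c1`, so the coupled solve reduces to
#' a single 2x2 complex linear system; no iteration is involved.
#'
#' @param params an [osteon_params()] object.
#' @param case boundary case, `"I"` or `"II"`; defaults to `params$case`.
#' @return an object of class `osteon_bc`: list with complex `c1`
#'   (dimensionless), `c2` (m^2), `c_m` (dimensionless), the `case` tag and
#'   the case-I restraint used. All three constants scale linearly with
#'   `eps_z0`.
#' @examples
#' bc <- solve_boundary_constants(osteon_params())
#' bc$c_m
#' @export
solve_boundary_constants <- function(params, case = NULL) {
  stopifnot(inherits(params, "osteon_params"))
  case <- if (is.null(case)) params$case else match.arg(case, c("I", "II"))
  st <- stiffness_components(params)
  c11 <- st[["c11"]]; c12 <- st[["c12"]]; c13 <- st[["c13"]]
  m11 <- c11
  a <- params$a; b <- params$b
  Cw <- consolidation_wavenumber(params)
  sh <- annulus_shape(Cw, a, b, b)
  fb <- sh$F - 1                      # pressure shape at r = b
  g <- sh$G - (b^2 - a^2) / 2         # int_a^b s (F - 1) ds
  pp <- pressure_prefactor_parts(params, m11)
  P0 <- pp$P0; P1 <- pp$P1
  al <- params$alpha

  # inner wall r = a: sigma_rr(a) = 0 (p and the particular solution vanish)
  A <- matrix(0 + 0i, 2, 2)
  rhs <- complex(2)
  A[1, 1] <- c11 + c12
  A[1, 2] <- (c12 - c11) / a^2
  rhs[1] <- -c13 * params$eps_z0

  # outer wall building blocks, all affine in c1 through p(b) and
  # J = int_a^b s p ds:  p(b) = (P0 + P1 c1) fb,  J = (P0 + P1 c1) g
  u_b <- list(c1 = b + (al / m11) * P1 * g / b,
              c2 = 1 / b,
              c0 = (al / m11) * P0 * g / b)
  sig_b <- list(
    c1 = (c11 + c12) +
      (al / m11) * (c11 * fb + (c12 - c11) * g / b^2) * P1 - al * P1 * fb,
    c2 = (c12 - c11) / b^2,
    c0 = c13 * params$eps_z0 +
      (al / m11) * (c11 * fb + (c12 - c11) * g / b^2) * P0 - al * P0 * fb
  )

  if (case == "II") {
    A[2, 1] <- u_b$c1
    A[2, 2] <- u_b$c2
    rhs[2] <- -u_b$c0
  } else {
    restr <- params$outer_restraint
    kap <- if (restr == "spring") params$spring_stiffness else 0
    pb1 <- if (restr == "free") 0 else P1 * fb
    pb0 <- if (restr == "free") 0 else P0 * fb
    A[2, 1] <- sig_b$c1 + pb1 + kap * u_b$c1
    A[2, 2] <- sig_b$c2 + kap * u_b$c2
    rhs[2] <- -(sig_b$c0 + pb0 + kap * u_b$c0)
  }

  # scale the c2 column by a*b (its natural magnitude relative to c1), then
  # equilibrate rows (their scales differ by ~1e14) and apply Cramer's rule
  colscale <- a * b
  A[, 2] <- A[, 2] * colscale
  for (i in 1:2) {
    s <- max(Mod(A[i, ]))
    if (s == 0) stop("degenerate boundary conditions: zero wall equation",
                     call. = FALSE)
    A[i, ] <- A[i, ] / s
    rhs[i] <- rhs[i] / s
  }
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (!is.finite(Mod(det)) || Mod(det) <= 1e-14)
    stop("degenerate boundary conditions: singular 2x2 wall system",
         call. = FALSE)
  sol <- c((rhs[1] * A[2, 2] - rhs[2] * A[1, 2]) / det,
           (A[1, 1] * rhs[2] - A[2, 1] * rhs[1]) / det * colscale)
  structure(list(c1 = sol[1], c2 = sol[2], c_m = 2 * sol[1],
                 case = case,
                 outer_restraint = if (case == "I") params$outer_restraint
                                   else "rigid"),
            class = "osteon_bc")
}

#' @export
print.osteon_bc <- function(x, ...) {
  cat("<osteon_bc> case", x$case, "(", x$outer_restraint, ")\n")
  cat("  c1  =", format(x$c1), "\n")
  cat("  c2  =", format(x$c2), "m^2\n")
  cat("  c_m =", format(x$c_m), "\n")
  invisible(x)
}

pressure_prefactor <- function(params, bc) {
  m11 <- stiffness_m11(params)
  params$M * m11 *
    (params$alpha * bc$c_m + params$alpha_prime * params$eps_z0) /
    (m11 + params$M * params$alpha^2)
}

check_radius_in_wall <- function(r, params) {
  tol <- 1e-12 * params$b
  if (any(r < params$a - tol | r > params$b + tol))
    stop("radial position outside the osteon wall [a, b]", call. = FALSE)
  pmin(pmax(r, params$a), params$b)
}

#' Pore-pressure amplitude in the osteon wall
#'
#' Complex amplitude `p_0(r)` of the harmonic pore pressure
#' `Re(p_0(r) e^{i omega t})`. Vanishes identically at the drained inner
#' wall; its radial derivative vanishes at the impermeable outer wall.
#'
#' @param r radial position(s), m, inside `[a, b]`.
#' @param params an [osteon_params()] object.
#' @param bc boundary constants from [solve_boundary_constants()]; computed
#'   from `params` when omitted.
#' @return complex vector, Pa.
#' @export
pressure_amplitude <- function(r, params, bc = NULL) {
  stopifnot(inherits(params, "osteon_params"))
  if (is.null(bc)) bc <- solve_boundary_constants(params)
  r <- check_radius_in_wall(r, params)
  sh <- annulus_shape(consolidation_wavenumber(params), params$a, params$b, r)
  pressure_prefactor(params, bc) * (sh$F - 1)
}

#' Radial derivative of the pore-pressure amplitude
#'
#' Analytic `dp_0/dr`; zero at `r = b` by construction (the Bessel
#' combination `I1(Cr)K1(Cb) - K1(Cr)I1(Cb)` vanishes there identically).
#'
#' @inheritParams pressure_amplitude
#' @return complex vector, Pa/m.
#' @export
pressure_gradient <- function(r, params, bc = NULL) {
  stopifnot(inherits(params, "osteon_params"))
  if (is.null(bc)) bc <- solve_boundary_constants(params)
  r <- check_radius_in_wall(r, params)
  sh <- annulus_shape(consolidation_wavenumber(params), params$a, params$b, r)
  pressure_prefactor(params, bc) * sh$dF
}

#' Radial displacement amplitude of the osteon wall
#'
#' Complex amplitude of the radial displacement consistent with
#' [solve_boundary_constants()]: homogeneous Lame part plus the
#' pressure-driven particular solution. For case II it vanishes at `r = b`
#' to solver tolerance.
#'
#' @inheritParams pressure_amplitude
#' @return complex vector, m.
#' @export
radial_displacement_amplitude <- function(r, params, bc = NULL) {
  stopifnot(inherits(params, "osteon_params"))
  if (is.null(bc)) bc <- solve_boundary_constants(params)
  r <- check_radius_in_wall(r, params)
  m11 <- stiffness_m11(params)
  sh <- annulus_shape(consolidation_wavenumber(params), params$a, params$b, r)
  J <- pressure_prefactor(params, bc) * (sh$G - (r^2 - params$a^2) / 2)
  bc$c1 * r + bc$c2 / r + (params$alpha / m11) * J / r
}

#' Pore-pressure field on a radial grid
#'
#' @param params an [osteon_params()] object.
#' @param case boundary case override.
#' @param n number of grid points across the wall.
#' @return a tibble of class `osteon_radial_field` with columns `r_m`,
#'   `re_p_pa`, `im_p_pa`, `abs_p_pa`, `phase_rad` and the `case` tag.
#' @examples
#' pressure_profile(osteon_params(), n = 11)
#' @export
pressure_profile <- function(params, case = NULL, n = 101) {
  stopifnot(inherits(params, "osteon_params"), n >= 2)
  bc <- solve_boundary_constants(params, case)
  r <- seq(params$a, params$b, length.out = n)
  p <- pressure_amplitude(r, params, bc)
  out <- tibble::tibble(
    r_m = r,
    re_p_pa = Re(p), im_p_pa = Im(p),
    abs_p_pa = Mod(p), phase_rad = Arg(p),
    case = bc$case
  )
  class(out) <- c("osteon_radial_field", class(out))
  out
}

#' Pore pressure time series at a fixed radius
#'
#' Real signal `Re(p_0(r) e^{i omega t})` sampled at the requested times.
#'
#' @param r single radial position, m.
#' @param times numeric vector of times, s.
#' @inheritParams pressure_amplitude
#' @return tibble with columns `t_s` and `p_pa`.
#' @export
pressure_time_series <- function(r, times, params, bc = NULL) {
  stopifnot(length(r) == 1, is.numeric(times), all(is.finite(times)))
  p0 <- pressure_amplitude(r, params, bc)
  tibble::tibble(t_s = times,
                 p_pa = Re(p0 * exp(1i * params$omega * times)))
}
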