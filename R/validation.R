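# Independent brute-force oracles for every closed-form result:
#  - adaptive quadrature of the velocity profile vs the closed-form flow rate
#  - one-sided finite-difference wall derivative vs the closed-form shear
#  - a finite-difference discretisation of the coupled radial equilibrium +
#    harmonic pressure diffusion vs the analytic boundary-constant solve
#  - closed-form Poiseuille steady limits.

#' Flow rate by adaptive quadrature of the velocity profile
#'
#' Numerically integrates `2 pi int_0^R r' u(r') dr'` (real and imaginary
#' parts separately) as an independent check on the closed-form
#' [flow_rate()].
#'
#' @param params an [osteon_params()] object.
#' @param p0a,p0b complex endpoint pressure amplitudes, Pa.
#' @param rel_tol,abs_tol quadrature tolerances (per part).
#' @return complex flow rate, m^3/s.
#' @export
quadrature_flow_rate <- function(params, p0a = NULL, p0b = NULL,
                                 rel_tol = 1e-11, abs_tol = 1e-30) {
  stopifnot(inherits(params, "osteon_params"))
  ep <- endpoint_pressures(params, p0a, p0b)
  integrand <- function(r, part) {
    u <- velocity_amplitude(r, params, ep$p0a, ep$p0b)
    2 * pi * r * if (part == "re") Re(u) else Im(u)
  }
  # magnitude scale from a coarse profile sample, independent of the closed
  # form, so the absolute acceptance floor adapts to the problem size
  u_scale <- max(Mod(velocity_amplitude(seq(0, params$R, length.out = 33),
                                        params, ep$p0a, ep$p0b)), 1e-300)
  floor_tol <- max(abs_tol, 1e-9 * pi * params$R^2 * u_scale)
  quad <- function(part) {
    res <- stats::integrate(integrand, 0, params$R, part = part,
                            rel.tol = rel_tol, abs.tol = abs_tol,
                            subdivisions = 400L, stop.on.error = FALSE)
    ok <- res$message == "OK" ||
      res$abs.error <= max(floor_tol, 10 * rel_tol * abs(res$value))
    if (!ok)
      stop("quadrature did not converge (", res$message,
           "); achieved abs.error ", format(res$abs.error), call. = FALSE)
    res$value
  }
  complex(real = quad("re"), imaginary = quad("im"))
}

#' Wall shear by one-sided finite differencing of the velocity profile
#'
#' Third-order 4-point one-sided derivative of the velocity at the tube
#' wall, times the viscosity; an independent check on [wall_shear()].
#'
#' @inheritParams quadrature_flow_rate
#' @param h_step stencil spacing, m; must satisfy `0 < h_step < R/10`. The
#'   default balances the stencil's `h^3` truncation error against the
#'   `1/h` amplification of floating-point cancellation near the wall,
#'   where the velocity itself vanishes.
#' @return complex shear stress, Pa.
#' @export
finite_difference_wall_shear <- function(params, p0a = NULL, p0b = NULL,
                                         h_step = params$R / 20) {
  stopifnot(inherits(params, "osteon_params"))
  if (h_step <= 0 || h_step >= params$R / 10)
    stop("h_step must lie in (0, R/10)", call. = FALSE)
  ep <- endpoint_pressures(params, p0a, p0b)
  R <- params$R
  u <- velocity_amplitude(R - (0:3) * h_step, params, ep$p0a, ep$p0b)
  dudr <- (11 * u[1] - 18 * u[2] + 9 * u[3] - 2 * u[4]) / (6 * h_step)
  params$mu_f * dudr
}

#' Poiseuille steady-flow reference
#'
#' Closed-form steady laminar tube flow driven by pressure drop `p_drop`
#' over length `l`: discharge `pi R^4 p_drop / (8 mu_f l)` and wall shear
#' `R p_drop / (2 l)`. This is the exact `omega -> 0` limit of the
#' oscillatory closed forms.
#'
#' @param p_drop pressure drop along the tube, Pa (may be complex).
#' @param R tube radius, m.
#' @param l tube length, m.
#' @param mu_f fluid dynamic viscosity, Pa s.
#' @return list with components `Q` (m^3/s) and `tau_w` (Pa).
#' @export
poiseuille_reference <- function(p_drop, R, l, mu_f) {
  stopifnot(R > 0, l > 0, mu_f > 0)
  list(Q = pi * R^4 * p_drop / (8 * mu_f * l),
       tau_w = R * p_drop / (2 * l))
}

#' Finite-difference solution of the coupled osteon wall problem
#'
#' Discretises the coupled radial equilibrium and harmonic pressure
#' diffusion on a uniform radial grid with second-order central stencils
#' (second-order one-sided stencils at derivative boundaries), and solves
#' the resulting complex sparse linear system for the displacement and
#' pressure fields. Boundary conditions match [solve_boundary_constants()]:
#' drained, stress-free inner wall; impermeable outer wall with either the
#' case-I restraint of `params$outer_restraint` or `u(b) = 0` for case II.
#' The discrete analogue of the volumetric radial-strain constant is
#' recovered as the interior average of `(u' + u/r) - (alpha/M11) p`, which
#' the continuum solution makes exactly constant.
#'
#' @param params an [osteon_params()] object.
#' @param case boundary case override.
#' @param n_nodes number of radial grid nodes (>= 200). The default scales
#'   with the consolidation wavenumber so the pressure boundary layer stays
#'   resolved at low permeability.
#' @return list with complex `c_m`, the grid `r`, and complex vectors `u`
#'   (m) and `p` (Pa) at the nodes.
#' @export
finite_difference_bvp <- function(params, case = NULL, n_nodes = NULL) {
  stopifnot(inherits(params, "osteon_params"))
  case <- if (is.null(case)) params$case else match.arg(case, c("I", "II"))
  Cw <- consolidation_wavenumber(params)
  if (is.null(n_nodes))
    n_nodes <- max(1500L, ceiling(60 * Mod(Cw) * params$l))
  if (n_nodes < 200) stop("n_nodes must be >= 200", call. = FALSE)
  n <- as.integer(n_nodes)
  a <- params$a; b <- params$b
  h <- (b - a) / (n - 1)
  r <- a + (0:(n - 1)) * h
  st <- stiffness_components(params)
  c11 <- st[["c11"]]; c12 <- st[["c12"]]; c13 <- st[["c13"]]
  m11 <- c11
  al <- params$alpha; alp <- params$alpha_prime
  om <- params$omega; eps0 <- params$eps_z0
  kmu <- params$k / params$mu_f

  # unknown ordering: u_1..u_n, p_1..p_n (complex); vectorised triplet build
  idx <- 2:(n - 1)
  ri <- r[idx]
  rhs <- complex(2 * n)
  rhs[n + idx] <- 1i * om * alp * eps0

  # equilibrium rows: c11 (u'' + u'/r - u/r^2) - alpha p' = 0
  eq <- list(
    list(idx, idx - 1, c11 * (1 / h^2 - 1 / (2 * h * ri))),
    list(idx, idx, c11 * (-2 / h^2 - 1 / ri^2)),
    list(idx, idx + 1, c11 * (1 / h^2 + 1 / (2 * h * ri))),
    list(idx, n + idx - 1, rep(al / (2 * h) + 0i, n - 2)),
    list(idx, n + idx + 1, rep(-al / (2 * h) + 0i, n - 2)),
    # diffusion rows: (k/mu)(p'' + p'/r) - i w (p/M + alpha(u' + u/r)) = rhs
    list(n + idx, n + idx - 1, kmu * (1 / h^2 - 1 / (2 * h * ri)) + 0i),
    list(n + idx, n + idx, rep(kmu * (-2 / h^2) - 1i * om / params$M, n - 2)),
    list(n + idx, n + idx + 1, kmu * (1 / h^2 + 1 / (2 * h * ri)) + 0i),
    list(n + idx, idx - 1, rep(1i * om * al / (2 * h), n - 2)),
    list(n + idx, idx, -1i * om * al / ri),
    list(n + idx, idx + 1, rep(-1i * om * al / (2 * h), n - 2))
  )

  # boundary rows: drained inner wall, stress-free inner wall,
  # impermeable outer wall, case-dependent outer mechanics
  bnd_i <- c(n + 1,
             1, 1, 1, 1,
             2 * n, 2 * n, 2 * n)
  bnd_j <- c(n + 1,
             1, 2, 3, n + 1,
             2 * n, 2 * n - 1, 2 * n - 2)
  bnd_v <- c(1 + 0i,
             c11 * (-3 / (2 * h)) + c12 / a, c11 * 2 / h,
             c11 * (-1 / (2 * h)), -al + 0i,
             3 / (2 * h), -2 / h, 1 / (2 * h) + 0i)
  rhs[1] <- -c13 * eps0
  if (case == "II") {
    bnd_i <- c(bnd_i, n); bnd_j <- c(bnd_j, n); bnd_v <- c(bnd_v, 1 + 0i)
  } else {
    kap <- if (params$outer_restraint == "spring") params$spring_stiffness else 0
    pcoef <- if (params$outer_restraint == "free") 0 else 1
    # sigma_rr(b) + pcoef * p(b) + kap * u(b) = 0
    bnd_i <- c(bnd_i, n, n, n, n)
    bnd_j <- c(bnd_j, n, n - 1, n - 2, 2 * n)
    bnd_v <- c(bnd_v, c11 * 3 / (2 * h) + c12 / b + kap,
               -c11 * 2 / h, c11 / (2 * h), -al + pcoef + 0i)
    rhs[n] <- -c13 * eps0
  }

  ii <- c(unlist(lapply(eq, `[[`, 1)), bnd_i)
  jj <- c(unlist(lapply(eq, `[[`, 2)), bnd_j)
  vv <- c(unlist(lapply(eq, `[[`, 3)), bnd_v)

  # equilibrate: row scales span ~24 orders (elastic vs Darcy rows) and the
  # displacement/pressure columns differ by ~11, which defeats sparse LU
  # pivot checks; scale rows then columns to O(1) and undo on the solution
  rs <- tapply(Mod(vv), ii, max)
  rsv <- as.numeric(rs)[match(ii, as.integer(names(rs)))]
  vv <- vv / rsv
  rhs_s <- rhs
  nz <- as.integer(names(rs))
  rhs_s[nz] <- rhs_s[nz] / as.numeric(rs)
  cs <- tapply(Mod(vv), jj, max)
  csv <- as.numeric(cs)[match(jj, as.integer(names(cs)))]
  vv <- vv / csv

  # real 2x2 block expansion of the complex system
  N <- 2 * n
  bi <- c(ii, ii, ii + N, ii + N)
  bj <- c(jj, jj + N, jj, jj + N)
  bv <- c(Re(vv), -Im(vv), Im(vv), Re(vv))
  Amat <- Matrix::sparseMatrix(i = bi, j = bj, x = bv, dims = c(2 * N, 2 * N))
  sol <- tryCatch(
    as.numeric(Matrix::solve(Amat, c(Re(rhs_s), Im(rhs_s)))),
    error = function(e) stop("singular discrete system: ",
                             conditionMessage(e), call. = FALSE))
  z <- complex(real = sol[1:N], imaginary = sol[(N + 1):(2 * N)])
  colu <- as.numeric(cs)[match(1:N, as.integer(names(cs)))]
  z <- z / colu
  u <- z[1:n]; p <- z[(n + 1):(2 * n)]

  idx <- 2:(n - 1)
  e <- (u[idx + 1] - u[idx - 1]) / (2 * h) + u[idx] / r[idx]
  cm <- mean(e - (al / m11) * p[idx])
  list(c_m = cm, r = r, u = u, p = p, n_nodes = n, case = case)
}

#' Run the full oracle suite
#'
#' Samples parameter sets uniformly inside the validated physiological
#' ranges (strain 4e-4 to 3e-3, frequency 1 to 20 Hz, canalicular radius
#' 0.1 to 1 um, log-uniform permeability 1e-23 to 1e-18 m^2, both boundary
#' cases) and compares every closed-form quantity against its brute-force
#' oracle: flow rate vs quadrature (tolerance 1e-8), wall shear vs finite
#' difference (1e-6), and boundary constant plus pressure field vs the
#' finite-difference solver (1e-4). Tolerances sit at least two orders of
#' magnitude above each oracle's own convergence floor, so a failure
#' indicates a formula error, not discretisation noise.
#'
#' @param n_sets number of sampled parameter sets.
#' @param seed RNG seed, recorded in the report.
#' @param base template parameter set.
#' @return tibble with columns `set`, `case`, `quantity`, `closed_form`,
#'   `oracle`, `rel_err`, `tolerance`, `pass`; the seed is attached as an
#'   attribute.
#' @export
run_oracle_suite <- function(n_sets = 100, seed = 20260923,
                             base = osteon_params()) {
  stopifnot(inherits(base, "osteon_params"), n_sets >= 1)
  rng <- local({
    set.seed(seed)
    tibble::tibble(
      eps_z0 = stats::runif(n_sets, 4e-4, 3e-3),
      freq_hz = stats::runif(n_sets, 1, 20),
      R = stats::runif(n_sets, 1e-7, 1e-6),
      k = 10^stats::runif(n_sets, -23, -18),
      case = sample(c("I", "II"), n_sets, replace = TRUE)
    )
  })
  report <- purrr::pmap_dfr(
    cbind(rng, set = seq_len(n_sets)),
    function(eps_z0, freq_hz, R, k, case, set) {
      p <- update_params(base, eps_z0 = eps_z0, freq_hz = freq_hz, R = R,
                         k = k, case = case)
      bc <- solve_boundary_constants(p)
      p0b <- pressure_amplitude(p$b, p, bc)

      q_cf <- flow_rate(p, p0b)
      q_or <- quadrature_flow_rate(p, 0, p0b)
      t_cf <- wall_shear(p, p0b)
      t_or <- finite_difference_wall_shear(p, 0, p0b)
      fd <- finite_difference_bvp(p)
      # compare at 10 interior grid nodes so no interpolation error enters
      jn <- round(seq(2, fd$n_nodes - 1, length.out = 10))
      ri <- fd$r[jn]
      p_an <- pressure_amplitude(ri, p, bc)
      p_fd <- fd$p[jn]
      rel <- function(x, y) Mod(x - y) / max(Mod(y), 1e-300)
      tibble::tibble(
        set = set, case = case,
        quantity = c("flow_rate", "wall_shear", "c_m", "pressure_field"),
        closed_form = c(Mod(q_cf), Mod(t_cf), Mod(bc$c_m), max(Mod(p_an))),
        oracle = c(Mod(q_or), Mod(t_or), Mod(fd$c_m), max(Mod(p_fd))),
        rel_err = c(rel(q_or, q_cf), rel(t_or, t_cf), rel(fd$c_m, bc$c_m),
                    max(Mod(p_fd - p_an)) / max(Mod(p_an))),
        tolerance = c(1e-8, 1e-6, 1e-4, 1e-4)
      )
    })
  report$pass <- report$rel_err <= report$tolerance
  attr(report, "seed") <- seed
  report
}
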