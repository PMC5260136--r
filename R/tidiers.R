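#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a canalicular solution
#'
#' One row per physical quantity with the complex amplitude split into
#' modulus, phase, real and imaginary parts.
#'
#' @param x a [canalicular_solution()] object.
#' @param ... unused.
#' @return a tibble with columns `quantity`, `unit`, `amplitude`,
#'   `phase_rad`, `real`, `imag`, `case`.
#' @export
tidy.canalicular_solution <- function(x, ...) {
  vals <- c(x$Q, x$tau_w, x$p0b)
  tibble::tibble(
    quantity = c("flow_rate", "wall_shear", "cement_line_pressure"),
    unit = c("m^3/s", "Pa", "Pa"),
    amplitude = Mod(vals),
    phase_rad = Arg(vals),
    real = Re(vals),
    imag = Im(vals),
    case = x$case
  )
}

#' One-row summary of a canalicular solution
#'
#' @inheritParams tidy.canalicular_solution
#' @return a one-row tibble: load descriptors, FFR and FSS amplitudes, and
#'   the strain-rate sensitivities.
#' @export
glance.canalicular_solution <- function(x, ...) {
  p <- x$params
  rate <- abs(p$eps_z0) * p$omega
  tibble::tibble(
    case = x$case,
    eps_z0 = p$eps_z0,
    freq_hz = p$freq_hz,
    strain_rate = rate,
    abs_Q_m3_s = Mod(x$Q),
    abs_tau_pa = Mod(x$tau_w),
    abs_p0b_pa = Mod(x$p0b),
    ffr_per_strain_rate = Mod(x$Q) / rate,
    fss_per_strain_rate = Mod(x$tau_w) / rate
  )
}

#' Tidy the osteon wall boundary constants
#'
#' @param x an `osteon_bc` object from [solve_boundary_constants()].
#' @param ... unused.
#' @return a tibble with one row per constant (`c1`, `c2`, `c_m`).
#' @export
tidy.osteon_bc <- function(x, ...) {
  vals <- c(x$c1, x$c2, x$c_m)
  tibble::tibble(
    constant = c("c1", "c2", "c_m"),
    unit = c("1", "m^2", "1"),
    real = Re(vals),
    imag = Im(vals),
    modulus = Mod(vals),
    case = x$case
  )
}
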