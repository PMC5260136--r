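# Modified Bessel functions of complex argument.
#
# The consolidation and oscillatory-Stokes wavenumbers are principal square
# roots of positive multiples of i, so every argument met in practice lies on
# the ray arg(z) = pi/4. The implementation covers the whole open half plane
# |arg z| < pi/2: ascending series for |z| <= 15, large-argument asymptotic
# expansions beyond. Exponentially scaled values are returned on request so
# that ratios of Bessel terms across the osteon wall can be formed with the
# exponential factors cancelled analytically.

EULER_GAMMA <- 0.57721566490153286060651209008240243

#' Modified Bessel functions for complex argument
#'
#' Evaluate \eqn{I_0}, \eqn{I_1}, \eqn{K_0}, \eqn{K_1} for complex `z` with
#' \eqn{|\arg z| < \pi/2}. With `scaled = TRUE` the returned values are
#' \eqn{I_\nu(z) e^{-z}} and \eqn{K_\nu(z) e^{z}}, which remain of order one
#' for large \eqn{|z|} and are the quantities used internally wherever ratios
#' across the osteon wall are formed.
#'
#' @param z complex vector, `Re(z) > 0` (or `z = 0` for the `I` functions).
#' @param nu order, 0 or 1.
#' @param scaled logical; return exponentially scaled values.
#' @return complex vector of the same length as `z`.
#' @seealso [consolidation_wavenumber()], [stokes_wavenumber()]
#' @export
besselI_c <- function(z, nu = 0, scaled = FALSE) {
  stopifnot(nu %in% c(0, 1))
  z <- as.complex(z)
  vapply(z, function(zi) bessel_one(zi, nu, "I", scaled), complex(1))
}

#' @rdname besselI_c
#' @export
besselK_c <- function(z, nu = 0, scaled = FALSE) {
  stopifnot(nu %in% c(0, 1))
  z <- as.complex(z)
  vapply(z, function(zi) bessel_one(zi, nu, "K", scaled), complex(1))
}

bessel_one <- function(z, nu, kind, scaled) {
  if (is.na(z)) return(NA_complex_)
  if (z == 0) {
    if (kind == "I") return(if (nu == 0) 1 + 0i else 0 + 0i)
    stop("K_nu is singular at z = 0", call. = FALSE)
  }
  if (Re(z) < 0 || abs(Arg(z)) >= pi / 2) {
    stop("bessel evaluation requires |arg z| < pi/2; got arg = ",
         format(Arg(z)), call. = FALSE)
  }
  if (kind == "I") {
    if (Mod(z) <= 15) {
      val <- bessel_i_series(z, nu)
      if (scaled) val <- val * exp(-z)
    } else {
      val <- bessel_i_asym(z, nu)
      if (!scaled) val <- val * exp(z)
    }
    return(val)
  }
  # K: the ascending series loses ~e^{2 Re z} digits to cancellation between
  # its logarithmic and power parts, so it is confined to |z| <= 2; a Steed
  # continued fraction covers the intermediate zone.
  if (Mod(z) <= 2) {
    val <- bessel_k_series(z, nu)
    if (scaled) val <- val * exp(z)
  } else if (Mod(z) <= 15) {
    val <- bessel_k_cf2(z)[[nu + 1]]
    if (!scaled) val <- val * exp(-z)
  } else {
    val <- bessel_k_asym(z, nu)
    if (!scaled) val <- val * exp(-z)
  }
  val
}

# Steed/Lentz continued fraction (CF2) for K_0 and K_1, Re z > 0, |z| >~ 2.
# Returns exponentially scaled values K_nu(z) e^{z}.
bessel_k_cf2 <- function(z) {
  b <- 2 * (1 + z)
  d <- 1 / b
  h <- d
  delh <- d
  q1 <- 0 + 0i
  q2 <- 1 + 0i
  a1 <- 0.25
  q <- a1
  cc <- a1
  a <- -a1
  s <- 1 + q * delh
  for (i in seq_len(5000)) {
    a <- a - 2 * i
    cc <- -a * cc / (i + 1)
    qnew <- (q1 - b * q2) / a
    q1 <- q2
    q2 <- qnew
    q <- q + cc * qnew
    b <- b + 2
    d <- 1 / (b + a * d)
    delh <- (b * d - 1) * delh
    h <- h + delh
    dels <- q * delh
    s <- s + dels
    if (Mod(dels) < 1e-17 * Mod(s)) break
  }
  h <- a1 * h
  k0 <- sqrt(pi / (2 * z)) / s
  list(k0, k0 * (z + 0.5 - h) / z)
}

# ascending series: I_nu(z) = (z/2)^nu sum_k (z^2/4)^k / (k! (k+nu)!)
bessel_i_series <- function(z, nu) {
  q <- z * z / 4
  term <- 1 + 0i
  s <- term
  for (k in seq_len(300)) {
    term <- term * q / (k * (k + nu))
    s <- s + term
    if (Mod(term) <= 1e-18 * Mod(s)) break
  }
  if (nu == 0) s else s * z / 2
}

# ascending series with logarithmic part (DLMF 10.31):
#   K_0(z) = -(log(z/2) + gamma) I_0(z) + sum_{k>=1} H_k (z^2/4)^k / (k!)^2
#   K_1(z) = 1/z + log(z/2) I_1(z)
#            - (z/4) sum_{k>=0} (psi(k+1) + psi(k+2)) (z^2/4)^k / (k! (k+1)!)
bessel_k_series <- function(z, nu) {
  q <- z * z / 4
  lg <- log(z / 2)
  if (nu == 0) {
    s <- 0 + 0i
    term <- 1 + 0i
    hk <- 0
    for (k in seq_len(300)) {
      term <- term * q / (k * k)
      hk <- hk + 1 / k
      s <- s + term * hk
      if (Mod(term) * hk <= 1e-18 * max(Mod(s), 1)) break
    }
    -(lg + EULER_GAMMA) * bessel_i_series(z, 0) + s
  } else {
    s <- 0 + 0i
    term <- 1 + 0i            # (z^2/4)^k / (k! (k+1)!)
    psum <- 1 - 2 * EULER_GAMMA  # psi(1) + psi(2)
    for (k in 0:300) {
      if (k > 0) {
        term <- term * q / (k * (k + 1))
        psum <- psum + 1 / k + 1 / (k + 1)
      }
      add <- term * psum
      s <- s + add
      if (k > 2 && Mod(add) <= 1e-18 * max(Mod(s), 1)) break
    }
    1 / z + lg * bessel_i_series(z, 1) - (z / 4) * s
  }
}

# large-argument expansions (DLMF 10.40), returned exponentially scaled.
# a_k(nu) terms via the recurrence t_k = t_{k-1} (4 nu^2 - (2k-1)^2)/(8 k z).
bessel_asym_sums <- function(z, nu) {
  t <- 1 + 0i
  s_alt <- t   # sum (-1)^k a_k / z^k
  s_pos <- t   # sum a_k / z^k
  prev <- Inf
  for (k in seq_len(40)) {
    t <- t * (4 * nu^2 - (2 * k - 1)^2) / (8 * k * z)
    if (Mod(t) >= prev) break  # asymptotic series: stop at smallest term
    s_alt <- s_alt + t * (-1)^k
    s_pos <- s_pos + t
    if (Mod(t) <= 1e-17) break
    prev <- Mod(t)
  }
  list(alt = s_alt, pos = s_pos)
}

bessel_k_asym <- function(z, nu) {
  s <- bessel_asym_sums(z, nu)
  sqrt(pi / (2 * z)) * s$pos
}

# I_nu(z) e^{-z} = [s_alt + e^{-2z} e^{(nu+1/2) pi i} s_pos] / sqrt(2 pi z),
# valid for -pi/2 < arg z < 3*pi/2; the second, exponentially small term
# matters near the accuracy floor at moderate |z|.
bessel_i_asym <- function(z, nu) {
  s <- bessel_asym_sums(z, nu)
  circ <- exp((nu + 0.5) * pi * 1i)
  (s$alt + exp(-2 * z) * circ * s$pos) / sqrt(2 * pi * z)
}
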