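# Parameter validation, stiffness assembly and the two wavenumbers.

test_that("M11 matches direct evaluation of its closed form at the reference set", {
  p <- ref_params()
  # direct arithmetic, written out independently of the implementation;
  # the exact rational value of the reference combination is
  # 63951953125000000/3224301 Pa = 19834361967.136444 Pa
  direct <- 15.9e9 * (20.3e9 - 15.9e9 * 0.25^2) /
    ((1 + 0.328) * (20.3e9 - 20.3e9 * 0.328 - 2 * 15.9e9 * 0.25^2))
  expect_equal(stiffness_m11(p), direct, tolerance = 1e-14)
  expect_equal(stiffness_m11(p), 19834361967.136444, tolerance = 1e-12)
})

test_that("M11 reduces to the isotropic constrained modulus and scales linearly", {
  for (cse in list(c(E = 12e9, nu = 0.3), c(E = 1, nu = 0),
                   c(E = 5e9, nu = 0.45))) {
    p <- ref_params(E_r = cse[["E"]], E_z = cse[["E"]],
                    mu_r = cse[["nu"]], mu_z = cse[["nu"]])
    iso <- cse[["E"]] * (1 - cse[["nu"]]) /
      ((1 + cse[["nu"]]) * (1 - 2 * cse[["nu"]]))
    expect_equal(stiffness_m11(p), iso, tolerance = 1e-13)
  }
  p1 <- ref_params()
  for (s in c(0.5, 2, 7.3)) {
    ps <- update_params(p1, E_r = s * p1$E_r, E_z = s * p1$E_z)
    expect_equal(stiffness_m11(ps), s * stiffness_m11(p1), tolerance = 1e-12)
  }
})

test_that("non-physical elastic combinations are rejected with a named error", {
  expect_error(osteon_params(mu_z = 0.8),
               "E_z - E_z\\*mu_r - 2\\*E_r\\*mu_z\\^2")
  expect_error(osteon_params(E_r = -1), "E_r")
  expect_error(osteon_params(a = 2e-4), "a < b")
  expect_error(osteon_params(R = 2e-4), "R < b - a")
  expect_error(osteon_params(freq_hz = 0), "freq_hz")
  expect_error(osteon_params(alpha = 1.2), "alpha")
})

test_that("consolidation wavenumber has modulus ~413/m at reference and arg pi/4", {
  p <- ref_params()
  Cw <- consolidation_wavenumber(p)
  expect_equal(Mod(Cw), 413.3601405442517, tolerance = 1e-10)
  expect_equal(Arg(Cw), pi / 4, tolerance = 1e-14)
  # |C|^2 identity
  m11 <- stiffness_m11(p)
  expect_equal(Mod(Cw)^2,
               p$omega * p$mu_f * (m11 + p$M * p$alpha^2) /
                 (p$k * p$M * m11),
               tolerance = 1e-12)
})

test_that("|C| scales as 1/sqrt(k) and sqrt(omega); arg stays pi/4 throughout", {
  p <- ref_params()
  c0 <- Mod(consolidation_wavenumber(p))
  for (k in 10^seq(-23, -18)) {
    pk <- update_params(p, k = k)
    expect_equal(Mod(consolidation_wavenumber(pk)), c0 * sqrt(1e-18 / k),
                 tolerance = 1e-12)
    expect_equal(Arg(consolidation_wavenumber(pk)), pi / 4, tolerance = 1e-14)
  }
  for (f in c(1, 5, 20)) {
    pf <- update_params(p, freq_hz = f)
    expect_equal(Mod(consolidation_wavenumber(pf)), c0 * sqrt(f),
                 tolerance = 1e-12)
  }
  # omega -> 0 continuously
  expect_lt(Mod(consolidation_wavenumber(update_params(p, freq_hz = 1e-12))),
            1e-3)
})

test_that("Stokes wavenumber: corrected default, printed variant, skeleton independence", {
  p <- ref_params()
  b <- stokes_wavenumber(p)
  expect_equal(Mod(b), 2506.6282746310003, tolerance = 1e-10)
  expect_equal(Arg(b), pi / 4, tolerance = 1e-14)
  expect_equal(Mod(stokes_wavenumber(p, form = "printed")),
               sqrt(p$omega / p$mu_f), tolerance = 1e-12)
  # independent of every skeleton constant
  p2 <- update_params(p, E_r = 1e9, E_z = 2e9, mu_r = 0.1, mu_z = 0.1,
                      M = 1e9, alpha = 0.9, alpha_prime = 0.5, k = 1e-20)
  expect_equal(stokes_wavenumber(p2), b)
  expect_lt(Mod(stokes_wavenumber(update_params(p, freq_hz = 1e-12))), 1e-2)
})

test_that("reference set carries the documented geometry and is pure", {
  p <- default_parameters()
  expect_equal(p$a, 5e-5)
  expect_equal(p$b, 1.5e-4)
  expect_equal(p$l, 1e-4)
  expect_equal(p$R, 5e-7)
  expect_equal(p$omega, 2 * pi)
  expect_equal(stiffness_m11(p), 1.983436e10, tolerance = 1e-6)
  expect_identical(default_parameters(), default_parameters())
})

test_that("derived fields track updates and strain-rate definition", {
  p <- update_params(ref_params(), freq_hz = 5, eps_z0 = 2e-3)
  expect_equal(p$omega, 10 * pi)
  expect_equal(p$strain_rate, 2e-3 * 10 * pi)
  expect_equal(p$l, p$b - p$a)
})

test_that("config files with unit strings round-trip through the constructor", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("E_r: 15.9 GPa", "E_z: 20.3 GPa",
               "a: 50 um", "b: 150 um", "R: 0.5 um",
               "k: 1e-18 m^2", "freq_hz: 2", "case: II"), cfg)
  p <- read_osteon_config(cfg)
  expect_s3_class(p, "osteon_params")
  expect_equal(p$E_r, 15.9e9)
  expect_equal(p$a, 5e-5)
  expect_equal(p$R, 5e-7)
  expect_equal(p$case, "II")
  expect_equal(p$freq_hz, 2)
  # CLI-style overrides beat the file
  p2 <- read_osteon_config(cfg, freq_hz = 7)
  expect_equal(p2$freq_hz, 7)
  writeLines("not_a_key: 1", cfg)
  expect_error(read_osteon_config(cfg), "unknown config keys")
  writeLines("E_r: 15.9 furlongs", cfg)
  expect_error(read_osteon_config(cfg), "unknown unit")
})
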