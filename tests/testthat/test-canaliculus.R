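# Canalicular pressure, velocity, flow rate and wall shear.

test_that("axial pressure interpolates linearly between the endpoints", {
  p <- ref_params()
  p0b <- 1200 - 300i
  expect_equal(canalicular_pressure_amplitude(p$a, 0, p0b, p), 0 + 0i)
  expect_equal(canalicular_pressure_amplitude(p$b, 0, p0b, p), p0b)
  expect_equal(canalicular_pressure_amplitude((p$a + p$b) / 2, 0, p0b, p),
               p0b / 2)
  expect_error(canalicular_pressure_amplitude(p$b * 2, 0, p0b, p), "outside")
})

test_that("no-slip holds identically at the tube wall", {
  for (p in sample_params(10, seed = 3)) {
    expect_equal(Mod(velocity_amplitude(p$R, p)), 0)
  }
  expect_error(velocity_amplitude(ref_params()$R * 1.01, ref_params()),
               "\\[0, R\\]")
})

test_that("low-frequency limit recovers the Poiseuille profile and moduli", {
  p <- ref_params(freq_hz = 1e-3)
  p0b <- pressure_amplitude(p$b, p)
  r <- seq(0, p$R, length.out = 21)
  u <- velocity_amplitude(r, p, 0, p0b)
  u_pois <- -p0b * (p$R^2 - r^2) / (4 * p$mu_f * p$l)
  expect_lt(max(Mod(u - u_pois)) / max(Mod(u_pois)), 1e-4)
  expect_equal(Mod(velocity_amplitude(p$R / 2, p, 0, p0b) /
                     velocity_amplitude(0, p, 0, p0b)), 0.75,
               tolerance = 1e-6)
  ref <- poiseuille_reference(Mod(p0b), p$R, p$l, p$mu_f)
  expect_lt(abs(Mod(flow_rate(p, p0b)) - ref$Q) / ref$Q, 1e-4)
  expect_lt(abs(Mod(wall_shear(p, p0b)) - ref$tau_w) / ref$tau_w, 1e-4)
})

test_that("closed-form flow rate matches quadrature of the velocity profile", {
  p <- ref_params()
  p0b <- pressure_amplitude(p$b, p)
  expect_lt(rel_err(quadrature_flow_rate(p, 0, p0b), flow_rate(p, p0b)), 1e-8)
  # zero pressure difference, zero flow
  expect_equal(Mod(quadrature_flow_rate(p, 1 + 2i, 1 + 2i)), 0)
})

test_that("closed-form wall shear matches the finite-difference derivative", {
  p <- ref_params()
  p0b <- pressure_amplitude(p$b, p)
  expect_lt(rel_err(finite_difference_wall_shear(p, 0, p0b),
                    wall_shear(p, p0b)), 1e-6)
})

test_that("wall shear is proportional to the canalicular radius at 1 Hz", {
  p <- ref_params(R = 2.5e-7)
  p2 <- update_params(p, R = 5e-7)
  t1 <- Mod(canalicular_solution(p)$tau_w)
  t2 <- Mod(canalicular_solution(p2)$tau_w)
  expect_lt(abs(t2 / t1 - 2), 2e-3)  # within 0.1%
})

test_that("amplitudes are exactly proportional to strain amplitude and rate", {
  p <- ref_params()
  s1 <- canalicular_solution(p)
  s3 <- canalicular_solution(update_params(p, eps_z0 = 3e-3))
  expect_equal(Mod(s3$Q) / Mod(s1$Q), 3, tolerance = 1e-12)
  expect_equal(Mod(s3$tau_w) / Mod(s1$tau_w), 3, tolerance = 1e-12)
  # sensitivity is strain-invariant and reconstructs |Q| exactly
  g1 <- strain_rate_sensitivity(p)
  g3 <- strain_rate_sensitivity(update_params(p, eps_z0 = 3e-3))
  expect_equal(g1$ffr_per_strain_rate, g3$ffr_per_strain_rate,
               tolerance = 1e-12)
  expect_equal(g1$fss_per_strain_rate, g3$fss_per_strain_rate,
               tolerance = 1e-12)
  expect_equal(g1$ffr_per_strain_rate * p$strain_rate, Mod(s1$Q),
               tolerance = 1e-12)
  expect_error(strain_rate_sensitivity(update_params(p, eps_z0 = 0)),
               "eps_z0")
})

test_that("sensitivity-reconstructed amplitudes are nearly flat in frequency", {
  # fixed strain rate 0.001/s over 1..21 Hz at the reference permeability
  p <- ref_params()
  qs <- vapply(c(1, 6, 11, 16, 21), function(f) {
    pf <- suppressWarnings(
      update_params(p, freq_hz = f, eps_z0 = 1e-3 / (2 * pi * f)))
    Mod(canalicular_solution(pf)$Q)
  }, numeric(1))
  expect_lt(diff(range(qs)) / mean(qs), 0.02)
})

test_that("displacement-confined case II exceeds elastic-restrained case I", {
  p <- ref_params()
  sI <- canalicular_solution(p, "I")
  sII <- canalicular_solution(p, "II")
  expect_gt(Mod(sII$Q), Mod(sI$Q))
  expect_gt(Mod(sII$tau_w), Mod(sI$tau_w))
})

test_that("tidy and glance views expose the amplitudes coherently", {
  sol <- canalicular_solution(ref_params())
  td <- generics::tidy(sol)
  expect_equal(nrow(td), 3)
  expect_equal(td$amplitude[td$quantity == "flow_rate"], Mod(sol$Q))
  gl <- generics::glance(sol)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$abs_tau_pa, Mod(sol$tau_w))
  expect_equal(gl$ffr_per_strain_rate * gl$strain_rate, gl$abs_Q_m3_s)
  bc_tidy <- generics::tidy(solve_boundary_constants(ref_params()))
  expect_equal(bc_tidy$constant, c("c1", "c2", "c_m"))
})

test_that("velocity profile table is monotone from centreline to wall", {
  vp <- velocity_profile(ref_params(), n = 41)
  expect_equal(nrow(vp), 41)
  expect_equal(vp$abs_u_m_s[41], 0)
  expect_true(all(diff(vp$abs_u_m_s) <= 0))
})
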