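# Sweeps, time responses, case ratio, reproduction tables.

test_that("strain sweep is a line through the origin for both cases", {
  sw <- sweep_parameter(ref_params(), "strain", seq(4e-4, 3e-3, length.out = 8))
  for (cs in c("I", "II")) {
    d <- sw[sw$case == cs, ]
    slope <- d$abs_Q_m3_s / d$value
    expect_lt(diff(range(slope)) / mean(slope), 1e-12)
    fit <- stats::lm(abs_Q_m3_s ~ value, data = d)
    # lm itself warns that the fit is essentially perfect - the point here
    expect_gt(suppressWarnings(summary(fit)$r.squared), 1 - 1e-12)
    expect_lt(abs(stats::coef(fit)[1]) / max(d$abs_Q_m3_s), 1e-10)
  }
})

test_that("radius sweep: FFR strictly increasing and convex, FSS proportional", {
  sw <- sweep_parameter(ref_params(), "radius", seq(1e-7, 1e-6, length.out = 10))
  for (cs in c("I", "II")) {
    d <- sw[sw$case == cs, ]
    expect_true(all(diff(d$abs_Q_m3_s) > 0))
    expect_true(all(diff(diff(d$abs_Q_m3_s)) > 0))
    ratio <- d$abs_tau_pa / d$value
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-3)
  }
})

test_that("case II amplitudes exceed case I at every point of every sweep", {
  base <- ref_params()
  sweeps <- list(
    sweep_parameter(base, "strain", c(4e-4, 1e-3, 3e-3)),
    sweep_parameter(base, "freq_hz", c(1, 10, 20)),
    sweep_parameter(base, "radius", c(1e-7, 5e-7, 1e-6)),
    sweep_parameter(base, "permeability", 10^seq(-23, -18))
  )
  for (sw in sweeps) {
    w <- tidyr::pivot_wider(sw[, c("value", "case", "abs_Q_m3_s",
                                   "abs_tau_pa")],
                            names_from = "case",
                            values_from = c("abs_Q_m3_s", "abs_tau_pa"))
    expect_true(all(w$abs_Q_m3_s_II > w$abs_Q_m3_s_I))
    expect_true(all(w$abs_tau_pa_II > w$abs_tau_pa_I))
  }
})

test_that("unknown sweep names and out-of-range grids are handled", {
  expect_error(sweep_parameter(ref_params(), "viscosity", 1),
               "strain, freq_hz, radius, permeability")
  expect_warning(sweep_parameter(ref_params(), "radius", c(5e-8, 5e-7)),
                 "outside the validated")
})

test_that("fixed strain-rate rows scale exactly with the rate and are flat in f", {
  base <- ref_params()
  sw <- suppressWarnings(
    sweep_fixed_strain_rate(base, rates = c(5e-4, 1e-3, 3e-3),
                            freqs = c(1, 6, 11, 16, 21)))
  pick <- function(rate, cs) sw[sw$strain_rate == rate & sw$case == cs, ]
  for (cs in c("I", "II")) {
    r1 <- pick(1e-3, cs)
    expect_equal(pick(3e-3, cs)$abs_Q_m3_s, 3 * r1$abs_Q_m3_s,
                 tolerance = 1e-12)
    expect_equal(pick(5e-4, cs)$abs_Q_m3_s, 0.5 * r1$abs_Q_m3_s,
                 tolerance = 1e-12)
    expect_equal(pick(3e-3, cs)$abs_tau_pa, 3 * r1$abs_tau_pa,
                 tolerance = 1e-12)
    # near-flat frequency response at fixed rate
    expect_lt(diff(range(r1$abs_Q_m3_s)) / mean(r1$abs_Q_m3_s), 0.02)
    expect_lt(diff(range(r1$abs_tau_pa)) / mean(r1$abs_tau_pa), 0.02)
  }
})

test_that("time responses are harmonic with peaks at the amplitude moduli", {
  base <- ref_params()
  tr <- time_response(base, times = seq(0, 1, length.out = 2001))
  for (cs in c("I", "II")) {
    d <- tr[tr$case == cs, ]
    sol <- canalicular_solution(base, cs)
    expect_equal(max(d$Q_m3_s) - min(d$Q_m3_s), 2 * Mod(sol$Q),
                 tolerance = 1e-5)
    expect_equal(max(d$tau_pa) - min(d$tau_pa), 2 * Mod(sol$tau_w),
                 tolerance = 1e-5)
    expect_equal(max(d$strain), base$eps_z0, tolerance = 1e-5)
    # one full period: signals return to their initial values
    expect_equal(d$Q_m3_s[2001], d$Q_m3_s[1], tolerance = 1e-9)
  }
  expect_error(time_response(base, times = c(0, 0.2)), "one loading period")
})

test_that("the case ratio is route-independent and insensitive to R", {
  base <- ref_params()
  r0 <- case_ratio(base)
  # manual recomputation through all three routes
  sI <- canalicular_solution(base, "I")
  sII <- canalicular_solution(base, "II")
  expect_equal(r0, Mod(sII$Q) / Mod(sI$Q), tolerance = 1e-12)
  expect_equal(r0, Mod(sII$tau_w) / Mod(sI$tau_w), tolerance = 1e-12)
  expect_equal(r0, Mod(sII$p0b) / Mod(sI$p0b), tolerance = 1e-12)
  ratios <- vapply(c(1e-7, 3e-7, 1e-6),
                   function(R) case_ratio(update_params(base, R = R)),
                   numeric(1))
  expect_lt(diff(range(ratios)) / mean(ratios), 1e-2)
  expect_error(case_ratio(update_params(base, eps_z0 = 0)), "degenerate")
})

test_that("reproduction run emits all table families and is deterministic", {
  td <- file.path(tempdir(), "osteonflow-repro")
  unlink(td, recursive = TRUE)
  m1 <- suppressWarnings(reproduce_all(td))
  files <- sort(list.files(td))
  expect_setequal(files, c("manifest.json", "sweep_strain.csv",
                           "sweep_frequency.csv",
                           "sweep_fixed_strain_rate.csv",
                           "strain_history.csv", "time_response.csv",
                           "sweep_radius.csv", "sweep_permeability.csv"))
  sig1 <- tools::md5sum(file.path(td, files))
  m2 <- suppressWarnings(reproduce_all(td))
  sig2 <- tools::md5sum(file.path(td, files))
  expect_identical(sig1, sig2)
  manifest <- jsonlite::read_json(file.path(td, "manifest.json"))
  expect_equal(manifest$beta_form, "corrected")
  expect_equal(manifest$case_I_outer_restraint, "pressure-balanced")
  expect_equal(manifest$parameters$M, 38e9)
  unlink(td, recursive = TRUE)
})

test_that("autoplot methods return ggplot objects", {
  base <- ref_params()
  expect_s3_class(
    ggplot2::autoplot(sweep_parameter(base, "radius", c(1e-7, 5e-7, 1e-6))),
    "ggplot")
  expect_s3_class(
    ggplot2::autoplot(time_response(base, seq(0, 1, length.out = 51))),
    "ggplot")
  expect_s3_class(ggplot2::autoplot(pressure_profile(base, n = 11)), "ggplot")
})
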