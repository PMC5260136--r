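# Parameter sweeps, time responses, and the case-II/case-I amplitude ratio.

sweep_param_names <- c(strain = "eps_z0", freq_hz = "freq_hz",
                       radius = "R", permeability = "k")

solution_row <- function(params, case) {
  sol <- canalicular_solution(params, case)
  tibble::tibble(case = sol$case,
                 abs_Q_m3_s = Mod(sol$Q), phase_Q_rad = Arg(sol$Q),
                 abs_tau_pa = Mod(sol$tau_w), phase_tau_rad = Arg(sol$tau_w),
                 abs_p0b_pa = Mod(sol$p0b))
}

both_cases <- function(params) {
  dplyr::bind_rows(solution_row(params, "I"), solution_row(params, "II"))
}

new_sweep <- function(tbl, base, swept) {
  attr(tbl, "base_params") <- base
  attr(tbl, "swept") <- swept
  class(tbl) <- c("osteon_sweep", class(tbl))
  tbl
}

#' Sweep one loading or material parameter
#'
#' Recomputes the canalicular flow rate and wall shear stress amplitudes for
#' both boundary cases at every value of the swept parameter, all other
#' parameters held at `base`. The physiologically motivated validation
#' ranges are strain 4e-4 to 3e-3, frequency 1 to 20 Hz, canalicular radius
#' 0.1 to 1 um and permeability 1e-23 to 1e-18 m^2; values outside them are
#' computed with a warning.
#'
#' @param base an [osteon_params()] object.
#' @param param one of `"strain"`, `"freq_hz"`, `"radius"`, `"permeability"`.
#' @param values numeric grid of swept values (SI units).
#' @return a tibble of class `osteon_sweep`, one row per (value, case),
#'   ordered by swept value, with columns `param`, `value`, `case`,
#'   `abs_Q_m3_s`, `phase_Q_rad`, `abs_tau_pa`, `phase_tau_rad`,
#'   `abs_p0b_pa`. The fixed base parameters are attached as the
#'   `base_params` attribute.
#' @examples
#' sweep_parameter(osteon_params(), "radius", c(1e-7, 5e-7, 1e-6))
#' @export
sweep_parameter <- function(base, param, values) {
  stopifnot(inherits(base, "osteon_params"))
  if (!param %in% names(sweep_param_names))
    stop("unknown sweep parameter '", param, "'; valid names: ",
         paste(names(sweep_param_names), collapse = ", "), call. = FALSE)
  stopifnot(length(values) >= 1, all(is.finite(values)))
  rng <- switch(param,
    strain = c(4e-4, 3e-3), freq_hz = c(1, 20),
    radius = c(1e-7, 1e-6), permeability = c(1e-23, 1e-18))
  if (any(values < rng[1] | values > rng[2]))
    warning("some swept '", param, "' values fall outside the validated ",
            "range [", rng[1], ", ", rng[2], "]", call. = FALSE)
  values <- sort(values)
  field <- sweep_param_names[[param]]
  tbl <- purrr::map_dfr(values, function(v) {
    args <- stats::setNames(list(v), field)
    p <- do.call(update_params, c(list(base), args))
    dplyr::mutate(both_cases(p), param = param, value = v, .before = 1)
  })
  new_sweep(tbl, base, param)
}

#' Sweep frequency at fixed strain-rate amplitude
#'
#' For each (rate, frequency) pair the strain amplitude is set to
#' `rate / omega` and both cases are solved. Because the model response is
#' proportional to the strain rate and the cement-line pressure is nearly
#' proportional to frequency at the reference permeability, the amplitudes
#' are almost flat in frequency at fixed rate.
#'
#' @param base an [osteon_params()] object.
#' @param rates strain-rate amplitudes, 1/s.
#' @param freqs loading frequencies, Hz.
#' @return a tibble of class `osteon_sweep` with columns `strain_rate`,
#'   `freq_hz`, `eps_z0`, `case` and the amplitude columns of
#'   [sweep_parameter()]. Strain amplitudes falling outside the validated
#'   strain range trigger a warning, not an error.
#' @export
sweep_fixed_strain_rate <- function(base, rates = c(5e-4, 1e-3, 3e-3),
                                    freqs = 1:21) {
  stopifnot(inherits(base, "osteon_params"), all(rates > 0), all(freqs > 0))
  grid <- tidyr::expand_grid(strain_rate = sort(rates),
                             freq_hz = sort(freqs))
  eps <- grid$strain_rate / (2 * pi * grid$freq_hz)
  out_of_range <- eps < 4e-4 | eps > 3e-3
  if (any(out_of_range))
    warning(sum(out_of_range), " of ", length(eps), " (rate, frequency) ",
            "pairs imply strain amplitudes outside [4e-4, 3e-3]; computed ",
            "anyway", call. = FALSE)
  tbl <- purrr::pmap_dfr(grid, function(strain_rate, freq_hz) {
    p <- update_params(base, freq_hz = freq_hz,
                       eps_z0 = strain_rate / (2 * pi * freq_hz))
    dplyr::mutate(both_cases(p),
                  strain_rate = strain_rate, freq_hz = freq_hz,
                  eps_z0 = p$eps_z0, .before = 1)
  })
  new_sweep(tbl, base, "freq_hz_at_fixed_strain_rate")
}

#' Time responses of strain, FFR and FSS
#'
#' Real harmonic signals `Re(A e^{i omega t})` for the axial strain and for
#' the canalicular flow rate and wall shear stress of both cases.
#'
#' @param base an [osteon_params()] object.
#' @param times sample times, s; must span at least one loading period.
#' @return a tibble of class `osteon_time_response` with columns `t_s`,
#'   `case`, `strain`, `Q_m3_s`, `tau_pa`.
#' @export
time_response <- function(base, times = seq(0, 2, length.out = 401)) {
  stopifnot(inherits(base, "osteon_params"),
            is.numeric(times), all(is.finite(times)))
  if (diff(range(times)) < 1 / base$freq_hz)
    stop("times must cover at least one loading period (",
         format(1 / base$freq_hz), " s)", call. = FALSE)
  rows <- purrr::map_dfr(c("I", "II"), function(cs) {
    sol <- canalicular_solution(base, cs)
    ph <- exp(1i * base$omega * times)
    tibble::tibble(t_s = times, case = cs,
                   strain = Re(base$eps_z0 * ph),
                   Q_m3_s = Re(sol$Q * ph),
                   tau_pa = Re(sol$tau_w * ph))
  })
  attr(rows, "base_params") <- base
  class(rows) <- c("osteon_time_response", class(rows))
  rows
}

#' Case-II to case-I amplitude ratio
#'
#' Ratio of the displacement-confined (case II) to elastic-restrained
#' (case I) canalicular amplitudes. Flow rate, wall shear stress and
#' cement-line pressure share the ratio exactly (the canalicular transfer
#' factor cancels), and it is independent of the canalicular radius; the
#' three routes are checked against each other to machine precision before
#' returning.
#'
#' @param base an [osteon_params()] object.
#' @return single positive number.
#' @examples
#' case_ratio(osteon_params())
#' @export
case_ratio <- function(base) {
  stopifnot(inherits(base, "osteon_params"))
  s1 <- canalicular_solution(base, "I")
  s2 <- canalicular_solution(base, "II")
  if (Mod(s1$Q) == 0)
    stop("degenerate load: case I amplitude is zero", call. = FALSE)
  r <- c(Mod(s2$Q) / Mod(s1$Q),
         Mod(s2$tau_w) / Mod(s1$tau_w),
         Mod(s2$p0b) / Mod(s1$p0b))
  if (diff(range(r)) > 1e-10 * r[1])
    stop("internal inconsistency: FFR, FSS and pressure ratios disagree",
         call. = FALSE)
  r[[1]]
}

#' Reproduce the package's standard result tables
#'
#' Writes one CSV per standard experiment family (strain sweep, frequency
#' sweep, fixed-strain-rate frequency sweep, strain-load history, time
#' response, radius sweep, permeability sweep) plus a JSON manifest
#' recording every fixed parameter and modelling option in force. The
#' pipeline contains no random numbers; reruns are byte-identical.
#'
#' @param outdir output directory (created if needed).
#' @param base an [osteon_params()] object.
#' @return invisibly, the manifest as a list.
#' @export
reproduce_all <- function(outdir, base = osteon_params()) {
  stopifnot(inherits(base, "osteon_params"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0)
    stop("output directory is not writable: ", outdir, call. = FALSE)

  wide <- function(s) {
    s$param <- NULL
    tidyr::pivot_wider(
      dplyr::select(s, -dplyr::any_of(c("phase_Q_rad", "phase_tau_rad",
                                        "abs_p0b_pa"))),
      names_from = "case",
      values_from = c("abs_Q_m3_s", "abs_tau_pa"))
  }
  emit <- function(tbl, name) {
    utils::write.csv(tbl, file.path(outdir, paste0(name, ".csv")),
                     row.names = FALSE)
    name
  }

  tables <- c(
    emit(wide(sweep_parameter(base, "strain",
                              seq(4e-4, 3e-3, length.out = 14))),
         "sweep_strain"),
    emit(wide(sweep_parameter(base, "freq_hz", 1:20)), "sweep_frequency"),
    emit(wide(sweep_fixed_strain_rate(base)), "sweep_fixed_strain_rate"),
    emit({
      tr <- time_response(base)
      dplyr::distinct(tr[, c("t_s", "strain")])
    }, "strain_history"),
    emit(time_response(base), "time_response"),
    emit(wide(sweep_parameter(base, "radius",
                              seq(1e-7, 1e-6, length.out = 10))),
         "sweep_radius"),
    emit(wide(sweep_parameter(
      update_params(base, R = 1e-7, eps_z0 = 1e-3 / base$omega),
      "permeability", 10^seq(-23, -18, by = 0.5))), "sweep_permeability")
  )

  manifest <- list(
    package = "osteonflow",
    version = as.character(utils::packageVersion("osteonflow")),
    beta_form = base$beta_form,
    case_I_outer_restraint = base$outer_restraint,
    parameters = unclass(base)[c("E_r", "E_z", "mu_r", "mu_z", "M", "alpha",
                                 "alpha_prime", "k", "mu_f", "rho_f", "a",
                                 "b", "R", "eps_z0", "freq_hz")],
    tables = tables
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
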