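# Shared fixtures: the reference parameter set and a sampler of parameter
# sets inside the validated physiological ranges (strain 4e-4..3e-3,
# frequency 1..20 Hz, canalicular radius 0.1..1 um, log-uniform
# permeability 1e-23..1e-18 m^2, both boundary cases).

ref_params <- function(...) osteon_params(...)

sample_params <- function(n, seed = 7321) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    osteon_params(
      eps_z0 = runif(1, 4e-4, 3e-3),
      freq_hz = runif(1, 1, 20),
      R = runif(1, 1e-7, 1e-6),
      k = 10^runif(1, -23, -18),
      case = sample(c("I", "II"), 1)
    )
  })
}

rel_err <- function(x, y) Mod(x - y) / max(Mod(y), 1e-300)
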