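# Reference osteon parameterisation with explicit unit strings.
# Load with: read_osteon_config(system.file("extdata", "reference_config.yaml", package = "osteonflow"))
E_r: 15.9 GPa
E_z: 20.3 GPa
mu_r: 0.328
mu_z: 0.25
M: 38 GPa
alpha: 0.132
alpha_prime: 0.092
k: 1e-18 m^2
mu_f: 1e-3 Pa.s
rho_f: 1000
a: 50 um
b: 150 um
R: 0.5 um
eps_z0: 0.001
freq_hz: 1
case: I
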