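# shared fixtures: influx shapes and reference parameter sets
influx_cd4 <- default_influx("CD4")
influx_cd8 <- default_influx("CD8")
params_cd4 <- reference_params("CD4")
params_cd8 <- reference_params("CD8")

# constant-influx descriptor (handy for closed-form checks)
influx_const <- function(S = 1e4, k = 0.4, psi = 1) {
  influx_descriptor(count_params = c(A = S), ki67_params = c(k = k),
                    psi = psi, count_family = "constant",
                    ki67_family = "constant")
}

table2_truth <- c(delta0 = 1 / 22, r_delta = log(2) / 92, rho0 = 1 / 548)
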