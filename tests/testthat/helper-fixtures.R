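# Shared fixtures: small synthetic experiments and the reference mass grid.

ref_calc <- reference_masses("calculated")
ref_obs <- reference_masses("observed")

make_experiment <- function(seed, cv = 0.10, n_replicates = 4, ppm_sd = 5) {
  list(
    wt = synthetic_config(wt_params(), n_replicates = n_replicates, cv = cv,
                          ppm_sd = ppm_sd, seed = seed),
    mut = synthetic_config(yafk_params(), n_replicates = n_replicates,
                           cv = cv, ppm_sd = ppm_sd, seed = seed + 500000))
}
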