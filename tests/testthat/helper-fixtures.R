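# Shared fixtures: tiny spot tables and simulation presets built in code.

# A minimal valid spot table: n_samples series of n_dil steps each,
# laid out row-major in one block, intensities from a supplied function
# of (sample index, dilution covariate).
toy_spot_table <- function(n_samples = 3L, n_dil = 5L, n_rep = 1L,
                           intensity_fun = function(i, d) 100 + 10 * i + d) {
  grid <- expand.grid(sample = seq_len(n_samples),
                      dil = seq_len(n_dil),
                      rep = seq_len(n_rep))
  d <- center_dilution_covariates(dilution_design(n_dil))
  data.frame(
    array_id = "a1",
    block = 1L,
    row = ((seq_len(nrow(grid)) - 1L) %/% 40L) + 1L,
    col = ((seq_len(nrow(grid)) - 1L) %% 40L) + 1L,
    sample_id = sprintf("S%02d", grid$sample),
    dilution_step = grid$dil,
    replicate_id = grid$rep,
    intensity = intensity_fun(grid$sample, d[grid$dil]),
    stringsAsFactors = FALSE)
}

# Small simulated experiment used across tests; planted effects off by
# default.
quick_sim <- function(seed = 1L, n_samples = 8L, n_dil = 5L, n_rep = 3L,
                      noise_cv = 0.10, ...) {
  simulate_rppa_experiment(simulation_params(
    n_samples = n_samples, n_dilutions = n_dil, n_replicates = n_rep,
    noise_cv = noise_cv, seed = seed, ...))
}

# Median per-sample estimate from a quantification table.
per_sample <- function(quant) {
  ok <- quant$flag != "flat_series" & is.finite(quant$x_hat)
  tapply(quant$x_hat[ok], quant$sample_id[ok], stats::median)
}
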