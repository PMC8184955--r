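# shared fixtures: default panel/library built once per test run
fx_panel <- default_panel()
fx_lib <- build_library(fx_panel, verbose = FALSE)
fx_components <- names(fx_panel$components)

# deterministic positive weight vector over all 16 components
fx_theta <- function(lo = 20, hi = 120) {
  stats::setNames(seq(lo, hi, length.out = length(fx_components)),
                  fx_components)
}

# quiet noiseless rendering helper
fx_clean_spectrum <- function(theta = fx_theta()) {
  render_cell_spectrum(theta, fx_lib,
                       noise_spec(additive_sigma = 0,
                                  baseline_amplitude = 0,
                                  outlier_fraction = 0))
}

# small simulated experiment: simulate, background-correct, QC
fx_sim_qc <- function(preset, seed, noise = noise_spec()) {
  sim <- simulate_experiment(preset$design, fx_panel, noise, seed = seed,
                             control = preset$control, library = fx_lib)
  bg <- remove_background(sim$spectra)
  qc <- filter_outliers(bg$spectra)
  list(sim = sim, qc = qc)
}

# simulate -> feature table in one go
fx_features <- function(preset, seed, mode = "nnls",
                        noise = noise_spec()) {
  sq <- fx_sim_qc(preset, seed, noise)
  ft <- build_feature_table(unmix_set(sq$qc$retained, fx_lib, mode = mode),
                            fx_panel, labels = sq$qc$retained$meta)
  list(features = ft, truth = sq$sim$truth, qc = sq$qc$report)
}
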