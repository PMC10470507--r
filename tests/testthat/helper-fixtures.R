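# Shared fixtures: small compound panels and batch builders used across the
# module tests. Everything is generated in code; no stored data.

# Two-fragment analyte with a convenient retention time.
test_compound <- function(name = "FAMP", rel = c(0.6, 0.4), rt = 2.6,
                          sigma = 0.05) {
  compound_spec(name, 167.1, c(122.1, 150.1)[seq_along(rel)] , rel, rt,
                peak_sigma = sigma)
}

# Single-analyte panel (FAMP only) used where internal-standard handling is
# irrelevant; keeps simulation cheap.
famp_panel <- function() {
  make_default_panel()["FAMP"]
}

# A complete small batch: environmental samples at `concs` pM, an optional
# spiked/unspiked recovery pair, three medium blanks, and a QC pool of the
# environmental samples.
make_test_design <- function(concs = c(5, 20, 100, 500), efficiency = 0.5,
                             spike_pM = NULL, noise_sd = 10,
                             baseline_level = 50, response_rel_sd = 0,
                             seed = 1, sample_volume = 20,
                             resuspension_volume = 100) {
  env <- lapply(seq_along(concs), function(i) {
    sample_design(sprintf("S%d", i), "environmental_dissolved",
                  c(FAMP = concs[i]), sample_volume, efficiency,
                  resuspension_volume)
  })
  extra <- list()
  if (!is.null(spike_pM)) {
    extra <- list(sample_design("S_spiked", "environmental_dissolved",
                                c(FAMP = concs[1]), sample_volume, efficiency,
                                resuspension_volume,
                                spikes = c(FAMP = spike_pM)))
  }
  blanks <- lapply(1:3, function(i) {
    sample_design(sprintf("Blank%d", i), "medium_blank", c(), sample_volume,
                  1, resuspension_volume)
  })
  pool <- make_qc_pool(env, "QC", compounds = "FAMP")
  batch_design(
    samples = c(env, extra, blanks, list(pool)),
    calibration_levels_fmol = list(".default" = c(0, 25, 50, 250)),
    noise_sd = noise_sd, baseline_level = baseline_level,
    response_rel_sd = response_rel_sd, seed = seed
  )
}

make_test_batch <- function(..., seed = 1) {
  simulate_batch(make_test_design(..., seed = seed), famp_panel())
}

# Closed-form area of a Gaussian peak.
gaussian_area <- function(amplitude, sigma) amplitude * sigma * sqrt(2 * pi)
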