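# Shared fixtures, all built in code.

# Reference calibration used generatively throughout.
ref_calib <- function() calibration_model(10.02, 88.028)

# Small 11-vial phantom on a 48x48x1 grid (~29 voxels per vial) for fast
# unit tests; acceptance tests use the full default phantom.
tiny_phantom_spec <- function(noise_sigma = 0, ...) {
  phantom_spec(
    vial_layout = vial_layout_disks(c(48L, 48L, 1L), 11, radius = 3),
    noise_sigma = noise_sigma,
    ...
  )
}

tiny_phantom_params <- function() {
  p <- acquisition_preset("phantom-multiecho")
  scale_acquisition_grid(p, c(48, 48, 1))
}

# Single-region layout: every voxel belongs to vial 1 except a background rim.
one_region_layout <- function(dims, margin = 2) {
  lab <- array(0L, dim = dims)
  lab[(margin + 1):(dims[1] - margin), (margin + 1):(dims[2] - margin), ] <- 1L
  lab
}

# Noiseless mono-exponential image on a tiny grid: every voxel has the same
# decay; convenient for closed-form checks.
uniform_decay_image <- function(rate_s, s0 = 1000, params, dims = c(4, 4, 1)) {
  te_s <- params$echo_times / 1000
  data <- array(0, dim = c(dims, length(te_s)))
  for (e in seq_along(te_s)) data[, , , e] <- s0 * exp(-rate_s * te_s[e])
  multi_echo_image(data, scale_acquisition_grid(params, dims))
}

table1_path <- function() {
  system.file("extdata", "table1_phantom_calibration.tsv", package = "ferrokin")
}
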