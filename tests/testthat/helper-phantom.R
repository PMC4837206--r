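# Shared fixtures: all phantom data is generated in code at test time.

zero_baseline <- matrix(0, 3L, 2L)

# Small, fully deterministic phantom: no noise, no baseline, no spikes.
noiseless_config <- function(width = 4L, height = 4L,
                             baseline_coeffs_range = zero_baseline, ...) {
  phantom_config(width = width, height = height, noise_sd = 0,
                 spike_rate = 0,
                 baseline_coeffs_range = baseline_coeffs_range, ...)
}

# Small phantom at the default noise/baseline/spike settings.
small_config <- function(width = 6L, height = 6L, ...) {
  phantom_config(width = width, height = height, ...)
}

# Hand-built stack of single-row planes with prescribed intensities.
toy_stack <- function(intensity_rows, z = seq_along(intensity_rows) - 1,
                      wavenumber = NULL, dialect = "fixed") {
  n <- length(intensity_rows[[1L]])
  if (is.null(wavenumber)) wavenumber <- seq_len(n)
  planes <- lapply(seq_along(intensity_rows), function(k)
    raman_plane(wavenumber, matrix(intensity_rows[[k]], ncol = 1L),
                width = 1L, height = 1L, z = z[k]))
  raman_stack(planes, dialect = dialect)
}

# Upper-compartment measure of one preprocessed + profiled stack.
compartment_value <- function(gen, compartment, measure) {
  p <- profile_stack(preprocess_stack(gen$stack),
                     assignment = assign_layers(gen$stack))
  p$compartments[p$compartments$compartment == compartment, measure]
}
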