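# shared fixtures for the suite: built in code, no files on disk

# a collimated, point-like source entering along the surface normal
pencil_source <- function(tilt = 90) {
  source_spec(core_diameter = 1e-9, numerical_aperture = 1e-9, tilt = tilt)
}

# a single uniform slab with ambient indices matched to the slab
matched_slab <- function(mua, mus, d, n = 1) {
  tissue_stack(list(layer_optics(mua, mus, g = 0, n = n, thickness = d)),
               n_above = n, n_below = n)
}

# a spectrum that is constant over the full synthetic band
constant_spectrum <- function(value, name = "custom") {
  chromophore_spectrum(c(750, 1150), c(value, value), name = name)
}

# spectrum set where every constituent absorbs a constant `value`
constant_spectra <- function(value) {
  keys <- c("water", "fat", "melanin", "deoxy_hb", "oxy_hb")
  stats::setNames(lapply(keys, function(k) constant_spectrum(value, k)), keys)
}

fixture_spectra <- default_spectra()
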