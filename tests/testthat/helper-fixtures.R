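# Shared fixtures, built lazily once per test run and cached.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# three perpendicular detectors at classic study separations
fx_probe3 <- function() {
  fixture("probe3", function() radial_probe(c(0.1, 0.5, 0.9), tilts = 0))
}

# small monolayer LUT containing the reference tissue triplet as a node
fx_mono_grid <- function() {
  grid_spec(mus_p = c(1.0, 2.0, 3.0), gamma = c(1.2, 1.5, 1.8),
            mua = c(0, 0.2, 0.5, 1.0))
}

fx_mono_lut <- function() {
  fixture("mono_lut", function() {
    build_lut(fx_mono_grid(), fx_probe3(), n_photons = 4e4, seed = 42,
              oil_thickness = 0)
  })
}

# homogeneous medium helper with tissue defaults
fx_props <- function(mus_p = 1, gamma = 1.5, mua = 0, n = 1.43) {
  optical_properties(mus_p, gamma, mua, n)
}

# a cached forward run on the default 16-fiber probe
fx_default_paths <- function() {
  fixture("default_paths", function() {
    med <- layered_medium(fx_props(1.5, 1.6), fx_props(1.0, 1.2),
                          z_top = 0.5, oil_thickness = 0.05)
    run_forward(med, build_probe(), n_photons = 3e4, seed = 7,
                max_path = 60, max_lateral = 10)
  })
}
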