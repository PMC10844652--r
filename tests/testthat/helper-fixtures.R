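# shared small fixtures, built in code

med_default <- function() pa_medium()            # 1540 / 2700 m/s
ir_default  <- function() gaussian_bandpass_ir(1e6, 0.75, 20e6)

flat_profile <- function(z = 10e-3, aperture = 64e-3, spacing = 1e-3) {
  x <- seq(-aperture / 2, aperture / 2, by = spacing)
  pa_profile(x, rep(z, length(x)))
}

# one point source behind a flat layer, 65-element array
point_scene <- function(z_layer = 10e-3, src = c(0, 40e-3), ca = 2700) {
  list(medium = pa_medium(ca = ca), array = pa_array(65, 1e-3),
       ir = ir_default(), profile = flat_profile(z_layer),
       target = data.frame(x = src[1], z = src[2], a = 1))
}

# tiny inversion instance: 3 pixels, 4 sensors, 8 interface points
tiny_instance <- function() {
  med <- pa_medium()
  ir <- ir_default()
  arr <- pa_array(4, 3e-3)
  ifc_x <- seq(-5e-3, 5e-3, length.out = 8)
  z <- 8e-3 + 1e-3 * sin(ifc_x / 3e-3)
  grid <- pa_grid(c(-3e-3, 0, 3e-3), 28e-3)
  model <- pa_forward_model(grid, med, arr, ir, interface_x = ifc_x)
  meas <- simulate_rf(data.frame(x = c(-3e-3, 0, 3e-3), z = 28e-3,
                                 a = c(1, 0.5, 0.8)),
                      pa_profile(ifc_x, z + 3e-4 * cos(ifc_x / 2e-3)),
                      med, arr, ir)
  list(model = model, measured = meas, z = z, medium = med, ir = ir)
}

envelope_peak_time <- function(rf, n) {
  env <- rf_envelope(rf)
  rf$t0 + (which.max(env[, n]) - 1) / rf$fs
}
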