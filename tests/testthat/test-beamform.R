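lambda <- 1540 / 1e6   # acoustic wavelength in water at 1 MHz

test_that("all beamformers return zero images for zero RF", {
  sc <- point_scene()
  rf0 <- pa_rf(matrix(0, 800, 65), 20e6, 0, sc$array$x)
  grid <- pa_grid(seq(-10e-3, 10e-3, 1e-3), seq(30e-3, 50e-3, 1e-3))
  expect_true(all(beamform_wave(rf0, sc$profile, sc$medium, sc$array,
                                grid)$amplitude == 0))
  expect_true(all(beamform_das(rf0, sc$medium, sc$array, grid)$amplitude == 0))
  expect_true(all(beamform_straight_ray(rf0, sc$profile, sc$medium, sc$array,
                                        grid)$amplitude == 0))
})

test_that("wave-based beamforming localizes a source through the layer", {
  sc <- point_scene()
  rf <- simulate_rf(sc$target, sc$profile, sc$medium, sc$array, sc$ir)
  grid <- pa_grid(seq(-10e-3, 10e-3, 0.5e-3), seq(30e-3, 50e-3, 0.5e-3))
  img <- beamform_wave(rf, sc$profile, sc$medium, sc$array, grid)
  pk <- image_argmax(img)
  expect_lt(sqrt(sum((pk - c(0, 40e-3))^2)), lambda)
})

test_that("beamformers are linear in the RF data", {
  sc <- point_scene()
  rf <- simulate_rf(sc$target, sc$profile, sc$medium, sc$array, sc$ir)
  rf2 <- rf; rf2$traces <- 2 * rf$traces
  grid <- pa_grid(seq(-5e-3, 5e-3, 1e-3), seq(35e-3, 45e-3, 1e-3))
  for (bf in list(
    function(r) beamform_wave(r, sc$profile, sc$medium, sc$array, grid),
    function(r) beamform_das(r, sc$medium, sc$array, grid),
    function(r) beamform_straight_ray(r, sc$profile, sc$medium, sc$array,
                                      grid))) {
    expect_equal(bf(rf2)$amplitude, 2 * bf(rf)$amplitude, tolerance = 1e-12)
  }
})

test_that("adjoint-mode beamforming passes the dot-product test", {
  inst <- tiny_instance()
  set.seed(9)
  a <- runif(3)
  Fa <- pawave:::forward_theta(list(z = inst$z, a = a), inst$model,
                               inst$measured)
  y <- matrix(rnorm(length(Fa$traces)), nrow(Fa$traces))
  yrf <- pa_rf(y, Fa$fs, Fa$t0, inst$model$array$x)
  bt <- beamform_wave(yrf, pa_profile(inst$model$interface_x, inst$z),
                      inst$medium, inst$model$array, inst$model$grid,
                      mode = "adjoint", ir = inst$ir)
  lhs <- sum(y * Fa$traces)
  rhs <- sum(as.vector(bt$amplitude) * a)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
})

test_that("DAS localizes in homogeneous water but biases shallow through a fast layer", {
  # no layer: homogeneous medium, DAS is exact
  sch <- point_scene(ca = 1540)
  rfh <- simulate_rf(sch$target, sch$profile, sch$medium, sch$array, sch$ir)
  grid <- pa_grid(seq(-10e-3, 10e-3, 0.5e-3), seq(25e-3, 50e-3, 0.5e-3))
  pk <- image_argmax(beamform_das(rfh, sch$medium, sch$array, grid))
  expect_lt(sqrt(sum((pk - c(0, 40e-3))^2)), lambda)

  # fast layer mapped with cw: target appears strictly too shallow
  sc <- point_scene()
  rf <- simulate_rf(sc$target, sc$profile, sc$medium, sc$array, sc$ir)
  pk2 <- image_argmax(beamform_das(rf, sc$medium, sc$array, grid))
  expect_lt(pk2["z"], 40e-3)
})

test_that("straight-ray delay matches the similar-triangles closed form", {
  # flat 10 mm layer, source (20, 40) mm, sensor at the origin:
  # crossing at (5, 10) mm
  med <- med_default()
  prof <- flat_profile(10e-3)
  arr <- pa_array(65, 1e-3)
  r_sj <- sqrt(15^2 + 30^2) * 1e-3
  r_jn <- sqrt(5^2 + 10^2) * 1e-3
  expected <- r_sj / 1540 + r_jn / 2700

  # read the delay through the beamformer by placing a known spike
  fs <- 20e6
  nt <- 800
  n0 <- which(arr$x == 0)
  grid1 <- pa_grid(c(19.9e-3, 20e-3), c(40e-3))
  tr <- matrix(0, nt, 65)
  i0 <- floor(expected * fs); f <- expected * fs - i0
  tr[i0 + 1, n0] <- (1 - f); tr[i0 + 2, n0] <- f
  rf <- pa_rf(tr, fs, 0, arr$x)
  img <- beamform_straight_ray(rf, prof, med, arr, grid1)
  # the pixel at exactly (20, 40) mm reads the spike back at the
  # similar-triangles delay; a linearly deposited then linearly read spike
  # returns (1-f)^2 + f^2 of its amplitude, weighted by r_sn
  expect_equal(img$amplitude[2, 1],
               sqrt(0.02^2 + 0.04^2) * ((1 - f)^2 + f^2),
               tolerance = 1e-6)
})

test_that("straight-ray equals DAS in the homogeneous limit", {
  sch <- point_scene(ca = 1540)
  rfh <- simulate_rf(sch$target, sch$profile, sch$medium, sch$array, sch$ir)
  grid <- pa_grid(seq(-8e-3, 8e-3, 1e-3), seq(32e-3, 48e-3, 1e-3))
  i_das <- beamform_das(rfh, sch$medium, sch$array, grid)
  i_ray <- beamform_straight_ray(rfh, sch$profile, sch$medium, sch$array,
                                 grid)
  # identical delays and weights up to bisection tolerance
  expect_equal(i_ray$amplitude, i_das$amplitude, tolerance = 1e-4)
  # wave-model argmax coincides with DAS argmax within one pixel
  i_wav <- beamform_wave(rfh, sch$profile, sch$medium, sch$array, grid)
  expect_lte(max(abs(image_argmax(i_wav) - image_argmax(i_das))), 1e-3)
})

test_that("depth fidelity ordering: wave <= straight-ray <= DAS", {
  sc <- point_scene()
  rf <- simulate_rf(sc$target, sc$profile, sc$medium, sc$array, sc$ir)
  grid <- pa_grid(seq(-10e-3, 10e-3, 0.5e-3), seq(25e-3, 50e-3, 0.25e-3))
  z_true <- 40e-3
  e_wave <- abs(image_argmax(beamform_wave(rf, sc$profile, sc$medium,
                                           sc$array, grid))["z"] - z_true)
  e_ray <- abs(image_argmax(beamform_straight_ray(rf, sc$profile, sc$medium,
                                                  sc$array, grid))["z"] - z_true)
  e_das <- abs(image_argmax(beamform_das(rf, sc$medium, sc$array,
                                         grid))["z"] - z_true)
  expect_lte(e_wave, e_ray + 1e-12)
  expect_lte(e_ray, e_das + 1e-12)
  expect_lt(e_wave, lambda)
  expect_gt(e_das, lambda)
})

test_that("out-of-window contributions are counted and flagged", {
  sc <- point_scene()
  rf <- simulate_rf(sc$target, sc$profile, sc$medium, sc$array, sc$ir)
  short <- pa_rf(rf$traces[1:50, ], rf$fs, 0, rf$sensor_x)
  grid <- pa_grid(seq(-5e-3, 5e-3, 1e-3), seq(35e-3, 45e-3, 1e-3))
  img <- beamform_wave(short, sc$profile, sc$medium, sc$array, grid)
  expect_true(img$meta$clipped_warning)
  expect_true(all(img$amplitude == 0))
})
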