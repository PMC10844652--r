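test_that("Gaussian band-pass kernel has the specified spectrum", {
  ir <- gaussian_bandpass_ir(1e6, 0.75, 20e6)
  h <- ir$kernel
  nf <- 4096
  H <- Mod(stats::fft(c(h, numeric(nf - length(h)))))
  f <- (seq_len(nf) - 1) * ir$fs / nf
  pos <- f < ir$fs / 2
  fp <- f[pos]; Hp <- H[pos]
  df <- ir$fs / nf
  # peak at f0 (within one bin)
  expect_lt(abs(fp[which.max(Hp)] - 1e6), df + 1e-9)
  # -6 dB (power) full width = 0.75 MHz within one bin per edge
  w <- range(fp[Hp^2 > max(Hp)^2 * 10^(-0.6)])
  expect_lt(abs(diff(w) - 0.75e6), 2 * df)
  # exactly band-pass: no DC
  expect_lt(abs(mean(h)), 1e-6 * max(abs(h)))
  expect_error(gaussian_bandpass_ir(1e6, 0.75, 3e6), "Nyquist")
})

test_that("kernel spectrum is invariant to the sampling rate", {
  ir1 <- gaussian_bandpass_ir(1e6, 0.75, 20e6)
  ir2 <- gaussian_bandpass_ir(1e6, 0.75, 40e6)
  spec <- function(ir, fgrid) {
    nf <- 2^16
    H <- Mod(stats::fft(c(ir$kernel, numeric(nf - length(ir$kernel)))))
    f <- (seq_len(nf) - 1) * ir$fs / nf
    stats::approx(f[f < ir$fs / 2], H[f < ir$fs / 2], fgrid)$y
  }
  fg <- seq(0.3e6, 2e6, 1e4)
  s1 <- spec(ir1, fg); s2 <- spec(ir2, fg)
  expect_lt(max(abs(s1 - s2)) / max(s1), 0.01)
})

test_that("simulate_rf is linear and superposes", {
  sc <- point_scene()
  rf0 <- simulate_rf(sc$target[0, ], sc$profile, sc$medium, sc$array, sc$ir)
  expect_true(all(rf0$traces == 0))

  rf1 <- simulate_rf(sc$target, sc$profile, sc$medium, sc$array, sc$ir)
  t2 <- sc$target; t2$a <- 2
  rf2 <- simulate_rf(t2, sc$profile, sc$medium, sc$array, sc$ir)
  expect_identical(rf2$traces, 2 * rf1$traces)

  tb <- data.frame(x = 5e-3, z = 35e-3, a = 0.7)
  tg <- list(fs = rf1$fs, t0 = 0, nt = max(nrow(rf1$traces), 1300))
  ra <- simulate_rf(sc$target, sc$profile, sc$medium, sc$array, sc$ir, tg)
  rb <- simulate_rf(tb, sc$profile, sc$medium, sc$array, sc$ir, tg)
  rab <- simulate_rf(rbind(sc$target, tb), sc$profile, sc$medium, sc$array,
                     sc$ir, tg)
  expect_equal(rab$traces, ra$traces + rb$traces, tolerance = 1e-12)
})

test_that("envelope arrival matches the two-segment travel time", {
  # layered collinear case: 23.184 us at the central element
  sc <- point_scene()
  rf <- simulate_rf(sc$target, sc$profile, sc$medium, sc$array, sc$ir)
  n0 <- which.min(abs(sc$array$x))
  expect_lt(abs(envelope_peak_time(rf, n0) - 23.184e-6), 2 / rf$fs)

  # homogeneous limit: arrival r_sn / c at every sensor
  sch <- point_scene(ca = 1540)
  rfh <- simulate_rf(sch$target, sch$profile, sch$medium, sch$array, sch$ir)
  for (n in c(1, 17, 33, 49, 65)) {
    expected <- sqrt(sch$array$x[n]^2 + (40e-3)^2) / 1540
    expect_lt(abs(envelope_peak_time(rfh, n) - expected), 2 / rfh$fs)
  }
})

test_that("arrival times agree across all four obliquity variants", {
  sc <- point_scene()
  times <- sapply(c("kirchhoff", "sommerfeld1", "sommerfeld2", "unity"),
                  function(v) {
    rf <- simulate_rf(sc$target, sc$profile, sc$medium, sc$array, sc$ir,
                      variant = v)
    vapply(c(1, 33, 65), function(n) envelope_peak_time(rf, n), numeric(1))
  })
  for (n in 1:3)
    expect_lt(diff(range(times[n, ])), 2 / sc$ir$fs)
})

test_that("time window validation reports the required span", {
  sc <- point_scene()
  expect_error(simulate_rf(sc$target, sc$profile, sc$medium, sc$array, sc$ir,
                           time_grid = list(nt = 100)),
               "time window too short")
})

test_that("noise injection is calibrated and reproducible", {
  sc <- point_scene()
  rf <- simulate_rf(sc$target, sc$profile, sc$medium, sc$array, sc$ir)
  expect_gt(length(rf$traces), 1e4)

  # snr = Inf sentinel leaves the data untouched
  expect_identical(add_noise(rf, Inf)$traces, rf$traces)

  # fixed seed: bit-identical noise
  n1 <- add_noise(rf, 3, seed = 42)
  n2 <- add_noise(rf, 3, seed = 42)
  expect_identical(n1$traces, n2$traces)

  # measured SNR close to nominal (large-sample Monte Carlo)
  big <- pa_rf(matrix(rep(rf$traces, 2), ncol = ncol(rf$traces)),
               rf$fs, 0, rf$sensor_x)
  expect_lt(abs(measure_snr(big, add_noise(big, 3, seed = 1)) - 3), 0.2)

  z0 <- pa_rf(matrix(0, 100, 2), 1e6, 0, c(0, 1))
  expect_error(add_noise(z0, 3), "SNR undefined")
})

test_that("measure_snr matches its closed forms", {
  set.seed(5)
  s <- pa_rf(matrix(rnorm(4000), 1000, 4), 1e6, 0, 1:4)
  pw <- mean(s$traces^2)
  mk <- function(noise_sd) {
    n <- s; n$traces <- n$traces +
      matrix(rnorm(4000, sd = noise_sd), 1000, 4); n
  }
  # noise power = half signal power: 3.0103 dB (the 3.0 dB study condition)
  half <- s; half$traces <- half$traces * (1 + 0)  # copy
  noise <- matrix(rnorm(4000), 1000, 4)
  noise <- noise * sqrt(pw / 2 / mean(noise^2))
  half$traces <- s$traces + noise
  expect_equal(measure_snr(s, half), 10 * log10(2), tolerance = 1e-9)

  # equal powers: 0 dB
  noise0 <- noise * sqrt(2)
  eq <- s; eq$traces <- s$traces + noise0
  expect_equal(measure_snr(s, eq), 0, tolerance = 1e-9)

  # scaling the signal by 10 adds exactly 20 dB
  s10 <- s; s10$traces <- 10 * s$traces
  eq10 <- s10; eq10$traces <- s10$traces + noise0
  expect_equal(measure_snr(s10, eq10) - measure_snr(s, eq), 20,
               tolerance = 1e-9)

  expect_equal(measure_snr(s, s), Inf)
})
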