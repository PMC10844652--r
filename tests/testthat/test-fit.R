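# loss terms, gradients and optimizer mechanics on small instances

test_that("data consistency matches its closed forms", {
  inst <- tiny_instance()
  npix <- 3
  # a = 0: D equals the measured energy
  D0 <- pa_data_consistency(list(z = inst$z, a = numeric(npix)),
                            inst$measured, inst$model)
  expect_equal(D0, sum(inst$measured$traces^2), tolerance = 1e-12)

  # measured = model + constant offset on every sample: D = N*T*eps^2
  th <- list(z = inst$z, a = c(0.5, 0.2, 0.1))
  mod_rf <- pawave:::forward_theta(th, inst$model, inst$measured)
  eps <- 0.01
  shifted <- mod_rf; shifted$traces <- mod_rf$traces + eps
  expect_equal(pa_data_consistency(th, shifted, inst$model),
               length(mod_rf$traces) * eps^2, tolerance = 1e-9)

  # perfect fit: D = 0
  expect_equal(pa_data_consistency(th, mod_rf, inst$model), 0)
})

test_that("prior penalty matches hand arithmetic in both bases", {
  th <- list(z = rep(10e-3, 5), a = c(1, -2, 3))
  pr <- pa_prior(alpha = 0.1, beta = 0, dim = c(3, 1),
                 z_ref = rep(10e-3, 5))
  expect_equal(pa_prior_penalty(th, pr), 0.6)

  # 1 mm deviation at 5 points, beta = 1e3
  th2 <- list(z = rep(10e-3, 5) + 1e-3, a = numeric(3))
  pr2 <- pa_prior(alpha = 0, beta = 1e3, z_ref = rep(10e-3, 5), dim = c(3, 1))
  expect_equal(pa_prior_penalty(th2, pr2), 5e-3, tolerance = 1e-12)

  # Fourier basis, constant image: single nonzero unitary coefficient
  M <- 16
  thc <- list(z = rep(10e-3, 5), a = rep(2, M))
  prf <- pa_prior(alpha = 0.1, beta = 0, basis = "fourier", dim = c(4, 4),
                  z_ref = rep(10e-3, 5))
  # oracle: direct summation of the unitary transform's moduli
  direct <- 0.1 * sum(Mod(stats::fft(matrix(2, 4, 4)) / 4))
  expect_equal(pa_prior_penalty(thc, prf), direct, tolerance = 1e-12)
  expect_equal(direct, 0.1 * M * 2 / sqrt(M), tolerance = 1e-12)
})

test_that("loss decomposes as L = D + P with both terms non-negative", {
  inst <- tiny_instance()
  th <- list(z = inst$z, a = c(0.3, 0, 0.4))
  pr <- pa_prior(alpha = 0.2, beta = 1e3, z_ref = inst$z + 1e-4,
                 dim = c(3, 1))
  l <- pa_loss(th, inst$measured, pr, inst$model)
  expect_equal(l$L, l$D + l$P)
  expect_gte(l$L, l$D)
  expect_gte(l$L, l$P)
  pr0 <- pa_prior(alpha = 0, beta = 0, z_ref = inst$z, dim = c(3, 1))
  l0 <- pa_loss(th, inst$measured, pr0, inst$model)
  expect_equal(l0$L, l0$D)
})

test_that("analytic gradient matches central finite differences", {
  inst <- tiny_instance()
  th <- list(z = inst$z, a = c(0.2, 0.9, 0.4))
  for (basis in c("direct", "fourier")) {
    pr <- pa_prior(alpha = 0.3 * sum(inst$measured$traces^2) * 1e-3,
                   beta = 1e4, basis = basis, z_ref = inst$z * 0 + 8e-3,
                   dim = c(3, 1))
    g <- pa_loss_gradient(th, inst$measured, pr, inst$model)
    expect_equal(g$value$L,
                 pa_loss(th, inst$measured, pr, inst$model)$L,
                 tolerance = 1e-12)
    f <- function(v) pa_loss(list(z = v[1:8], a = v[9:11]),
                             inst$measured, pr, inst$model)$L
    v0 <- c(th$z, th$a)
    num <- vapply(seq_along(v0), function(i) {
      h <- 1e-7 * max(abs(v0[i]), 1e-4)
      vp <- v0; vm <- v0
      vp[i] <- vp[i] + h; vm[i] <- vm[i] - h
      (f(vp) - f(vm)) / (2 * h)
    }, numeric(1))
    ana <- c(g$z, g$a)
    expect_lt(max(abs(ana - num) / pmax(abs(num), 1e-8 * max(abs(num)))),
              1e-4)
  }
})

test_that("quadratic-term gradients and L1 subgradient follow their closed forms", {
  inst <- tiny_instance()
  # dP/dz = 2*beta*(z - z_ref) in both bases
  zr <- inst$z - 2e-4
  for (basis in c("direct", "fourier")) {
    pr <- pa_prior(alpha = 0, beta = 500, basis = basis, z_ref = zr,
                   dim = c(3, 1))
    zero_meas <- inst$measured; zero_meas$traces[] <- 0
    g <- pa_loss_gradient(list(z = inst$z, a = numeric(3)), zero_meas, pr,
                          inst$model)
    expect_equal(g$z, 2 * 500 * (inst$z - zr), tolerance = 1e-9)
  }
  # dD/da at a = 0 with zero measurement: a perfect minimum
  pr0 <- pa_prior(z_ref = inst$z, dim = c(3, 1))
  zero_meas <- inst$measured; zero_meas$traces[] <- 0
  g0 <- pa_loss_gradient(list(z = inst$z, a = numeric(3)), zero_meas, pr0,
                         inst$model)
  expect_equal(g0$a, numeric(3))
  # L1 subgradient at 0 is 0
  pr1 <- pa_prior(alpha = 5, z_ref = inst$z, dim = c(3, 1))
  g1 <- pa_loss_gradient(list(z = inst$z, a = numeric(3)), zero_meas, pr1,
                         inst$model)
  expect_equal(g1$a, numeric(3))
})

test_that("pure quadratic descent pulls z monotonically toward the anchor", {
  inst <- tiny_instance()
  zero_meas <- inst$measured; zero_meas$traces[] <- 0
  z_start <- inst$z + 5e-4
  fit <- pa_fit(zero_meas, inst$model, z_init = z_start,
                prior = pa_prior(alpha = 0, beta = 1e6, z_ref = inst$z,
                                 dim = c(3, 1)),
                control = pa_control(iterations = 60, z_warmup = 0,
                                     stages = data.frame(sigma = Inf,
                                                         frac = 1)))
  d_start <- sqrt(mean((z_start - inst$z)^2))
  d_end <- sqrt(mean((fit$z - inst$z)^2))
  expect_lt(d_end, d_start / 3)
  # loss history decreases overall
  expect_lt(tail(fit$history$L, 1), fit$history$L[1])
})

test_that("strong anchoring and strong sparsity dominate as their weights grow", {
  inst <- tiny_instance()
  # beta -> large: z stays at the reference within a time-sample of thickness
  # extreme weights can trip the divergence guard on the very first step;
  # the projected parameters are still the quantity under test
  fit_b <- suppressWarnings(
    pa_fit(inst$measured, inst$model, z_init = inst$z,
           prior = pa_prior(alpha = 0, beta = 1e12, z_ref = inst$z,
                            dim = c(3, 1)),
           control = pa_control(iterations = 30, z_warmup = 0,
                                stages = data.frame(sigma = Inf,
                                                    frac = 1))))
  expect_lt(max(abs(fit_b$z - inst$z)),
            inst$model$medium$ca / (2 * inst$measured$fs))

  # alpha -> large: amplitudes shrink to zero
  big_alpha <- 1e6 * sum(inst$measured$traces^2)
  fit_a <- suppressWarnings(
    pa_fit(inst$measured, inst$model, z_init = inst$z,
           a_init = c(1, 1, 1),
           prior = pa_prior(alpha = big_alpha, beta = 0,
                            z_ref = inst$z, dim = c(3, 1)),
           control = pa_control(iterations = 50, z_warmup = 0,
                                stages = data.frame(sigma = Inf,
                                                    frac = 1))))
  expect_lt(max(abs(fit_a$a)), 1e-3)
})

test_that("the fit is deterministic and its methods are coherent", {
  inst <- tiny_instance()
  ctrl <- pa_control(iterations = 8)
  f1 <- pa_fit(inst$measured, inst$model, z_init = inst$z, control = ctrl)
  f2 <- pa_fit(inst$measured, inst$model, z_init = inst$z, control = ctrl)
  expect_identical(f1$z, f2$z)
  expect_identical(f1$a, f2$a)
  expect_identical(f1$history, f2$history)

  co <- coef(f1)
  expect_length(co$z, 8)
  expect_length(co$a, 3)
  expect_equal(dim(residuals(f1)), dim(inst$measured$traces))
  expect_equal(residuals(f1), inst$measured$traces - fitted(f1)$traces)
  expect_s3_class(predict(f1, "image"), "pa_image")
  sim <- simulate(f1, nsim = 2, seed = 3, snr_db = 10)
  expect_length(sim, 2)
  expect_false(identical(sim[[1]]$traces, sim[[2]]$traces))
  expect_output(print(f1), "Joint aberrator/target inversion")
  expect_output(print(summary(f1)), "loss")
})
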