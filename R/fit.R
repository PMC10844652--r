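#' Forward-model configuration for the joint inversion
#'
#' Bundles the fixed ingredients of the discretized Fresnel-Kirchhoff model:
#' the image grid carrying the unknown amplitudes, the medium, array and
#' impulse response, the obliquity variant, and the lateral positions of the
#' interface samples carrying the unknown thicknesses (by default one above
#' each array element).
#'
#' @param grid A [pa_grid]; its pixels are the amplitude unknowns.
#' @param medium A [pa_medium].
#' @param array A [pa_array].
#' @param ir A [pa_ir].
#' @param variant Obliquity variant, see [obliquity()].
#' @param interface_x Lateral interface sample positions (m); default the
#'   array element positions.
#' @return An object of class `pa_model`.
#' @export
pa_forward_model <- function(grid, medium, array, ir,
                             variant = c("kirchhoff", "sommerfeld1",
                                         "sommerfeld2", "unity"),
                             interface_x = NULL) {
  variant <- match.arg(variant)
  if (is.null(interface_x)) interface_x <- array$x
  structure(list(grid = grid, medium = medium, array = array, ir = ir,
                 variant = variant, interface_x = as.numeric(interface_x)),
            class = "pa_model")
}

# parameter vector: list(z = thicknesses (m), a = pixel amplitudes)
pa_theta <- function(z, a, model) {
  stopifnot(length(z) == length(model$interface_x),
            length(a) == length(model$grid$x) * length(model$grid$z),
            all(is.finite(z)), all(is.finite(a)), all(z >= 0))
  list(z = as.numeric(z), a = as.numeric(a))
}

theta_profile <- function(theta, model) pa_profile(model$interface_x, theta$z)

# forward model at theta on the time grid of a measured recording
forward_theta <- function(theta, model, measured) {
  prof <- theta_profile(theta, model)
  ka <- kernel_args(prof, model$medium, model$array, model$variant)
  px <- grid_pixels(model$grid)
  dep <- cpp_deposit(px$x, px$z, theta$a,
                     ka$ix, ka$iz, ka$nx, ka$nz, ka$slope, ka$ax, ka$az,
                     ka$cw, ka$ca, ka$variant, ka$quad,
                     ka$alpha_w, ka$alpha_a,
                     measured$fs, measured$t0, nrow(measured$traces),
                     ka$min_dist)
  pa_rf(convolve_traces(dep$deposits, model$ir), measured$fs, measured$t0,
        model$array$x)
}

#' Data-consistency term of the inversion loss
#'
#' Sum over all sensors and time samples of the squared residual between the
#' modelled and the measured traces.
#'
#' @param theta Parameter list with elements `z` (interface thicknesses, m)
#'   and `a` (pixel amplitudes on the model grid).
#' @param measured A [pa_rf].
#' @param model A [pa_model].
#' @return Scalar penalty.
#' @export
pa_data_consistency <- function(theta, measured, model) {
  theta <- pa_theta(theta$z, theta$a, model)
  sum((forward_theta(theta, model, measured)$traces - measured$traces)^2)
}

#' Prior penalty configuration
#'
#' `alpha` weights an L1 sparsity term on the target amplitudes, applied
#' either directly (`basis = "direct"`) or to the modulus of the unitary 2-D
#' discrete Fourier transform of the amplitude image (`basis = "fourier"`,
#' for targets such as vessels that are sparse in the Fourier domain).
#' `beta` weights an L2 anchor of the thickness profile to a reference
#' (typically the initial, echo-measured guess).
#'
#' @param alpha Sparsity weight (>= 0), or `NA` to let [pa_fit()] pick its
#'   data-scaled default.
#' @param beta Aberrator-deviation weight (>= 0), or `NA` as for `alpha`.
#' @param basis `"direct"` or `"fourier"`.
#' @param z_ref Reference thickness profile (m); filled in by [pa_fit()] from
#'   the initial guess when `NULL`.
#' @param dim Image dimensions `c(nx, nz)` for the Fourier basis; filled in
#'   by [pa_fit()] from the model grid when `NULL`.
#' @return An object of class `pa_prior`.
#' @export
pa_prior <- function(alpha = 0, beta = 0, basis = c("direct", "fourier"),
                     z_ref = NULL, dim = NULL) {
  basis <- match.arg(basis)
  stopifnot(is.na(alpha) || alpha >= 0, is.na(beta) || beta >= 0)
  structure(list(alpha = alpha, beta = beta, basis = basis,
                 z_ref = z_ref, dim = dim),
            class = "pa_prior")
}

# unitary 2-D DFT and its adjoint (a real)
unitary_fft2 <- function(A) stats::fft(A) / sqrt(length(A))
unitary_fft2_adj <- function(U) Re(stats::fft(U, inverse = TRUE)) / sqrt(length(U))

#' Prior penalty value
#'
#' @inheritParams pa_data_consistency
#' @param prior A [pa_prior] with `z_ref` (and `dim` for the Fourier basis)
#'   set.
#' @return Scalar penalty `alpha * sum|a~| + beta * sum (z - z_ref)^2`.
#' @export
pa_prior_penalty <- function(theta, prior) {
  pz <- if (prior$beta > 0) {
    stopifnot(length(prior$z_ref) == length(theta$z))
    prior$beta * sum((theta$z - prior$z_ref)^2)
  } else 0
  pa <- if (prior$alpha > 0) {
    if (prior$basis == "direct") prior$alpha * sum(abs(theta$a))
    else {
      A <- matrix(theta$a, prior$dim[1], prior$dim[2])
      prior$alpha * sum(Mod(unitary_fft2(A)))
    }
  } else 0
  pz + pa
}

#' Inversion loss with breakdown
#'
#' @inheritParams pa_data_consistency
#' @param prior A [pa_prior].
#' @return List with elements `L` (= `D + P`), `D` and `P`.
#' @export
pa_loss <- function(theta, measured, prior, model) {
  D <- pa_data_consistency(theta, measured, model)
  P <- pa_prior_penalty(theta, prior)
  list(L = D + P, D = D, P = P)
}

# subgradient of the sparsity term with respect to a (0 at 0)
prior_grad_a <- function(theta, prior) {
  if (prior$alpha == 0) return(numeric(length(theta$a)))
  if (prior$basis == "direct") return(prior$alpha * sign(theta$a))
  A <- matrix(theta$a, prior$dim[1], prior$dim[2])
  U <- unitary_fft2(A)
  m <- Mod(U)
  U <- ifelse(m > 0, U / m, 0 + 0i)
  prior$alpha * as.vector(unitary_fft2_adj(U))
}

#' Gradient of the inversion loss
#'
#' Exact gradient of the discretized loss with respect to every thickness
#' `z_j` and amplitude `a_s`, obtained by the adjoint-state rule through the
#' forward model (delta deposition, linear time interpolation, impulse-
#' response convolution), including the dependence of the surface normals on
#' neighbouring thickness samples through the finite-difference slope.
#' Matches central finite differences to better than 1e-4 relative error.
#'
#' @inheritParams pa_loss
#' @return List with elements `z` and `a` (gradients), plus the loss
#'   breakdown `value` at `theta`.
#' @export
pa_loss_gradient <- function(theta, measured, prior, model) {
  theta <- pa_theta(theta$z, theta$a, model)
  prof <- theta_profile(theta, model)
  ka <- kernel_args(prof, model$medium, model$array, model$variant)
  px <- grid_pixels(model$grid)
  nt <- nrow(measured$traces)
  dep <- cpp_deposit(px$x, px$z, theta$a,
                     ka$ix, ka$iz, ka$nx, ka$nz, ka$slope, ka$ax, ka$az,
                     ka$cw, ka$ca, ka$variant, ka$quad,
                     ka$alpha_w, ka$alpha_a,
                     measured$fs, measured$t0, nt, ka$min_dist)
  res <- convolve_traces(dep$deposits, model$ir) - measured$traces
  if (!all(is.finite(res))) stop("non-finite loss at theta")
  D <- sum(res^2)
  q <- convolve_traces(res, model$ir, adjoint = TRUE)
  g <- cpp_grad(q, px$x, px$z, theta$a,
                ka$ix, ka$iz, ka$nx, ka$nz, ka$slope, ka$ax, ka$az,
                ka$cw, ka$ca, ka$variant, ka$quad,
                ka$alpha_w, ka$alpha_a,
                measured$fs, measured$t0, ka$min_dist)
  gz <- g$grad_z + drop(crossprod(slope_jacobian(model$interface_x),
                                  g$grad_slope))
  ga <- g$grad_a
  if (prior$beta > 0) gz <- gz + 2 * prior$beta * (theta$z - prior$z_ref)
  ga <- ga + prior_grad_a(theta, prior)
  P <- pa_prior_penalty(theta, prior)
  list(z = gz, a = ga, value = list(L = D + P, D = D, P = P))
}

#' Optimizer settings for [pa_fit()]
#'
#' ADAM with separate step sizes for the two parameter blocks, whose
#' physical scales differ by many orders of magnitude.  Because ADAM
#' normalizes each coordinate by its gradient magnitude, the step sizes are
#' expressed directly in parameter units: `lr_z` in metres of thickness per
#' iteration (default one fiftieth of the acoustic wavelength in water) and
#' `lr_a` in amplitude units (default 1/100 of the initial back-projected
#' image maximum, resolved inside [pa_fit()]).
#'
#' @param iterations Maximum iterations (default 100), split over the
#'   continuation stages.
#' @param lr_z Thickness step (m/iteration) at full bandwidth; `NULL` for
#'   `lambda/50`.  Low-pass stages scale it by `f0 / f_effective`.
#' @param lr_a Amplitude step; `NULL` for 1/100 of the least-squares
#'   back-projection maximum.
#' @param beta1,beta2 ADAM moment decay rates.
#' @param eps ADAM denominator offset (relative to the RMS gradient).
#' @param tol Early-stop threshold on the relative loss change.
#' @param patience Consecutive iterations below `tol` required to stop (or,
#'   in a low-pass stage, to advance to the next stage).
#' @param nonneg_a Project amplitudes onto `a >= 0` (initial pressure is
#'   physically non-negative); set `FALSE` to disable.
#' @param stages Frequency-continuation schedule guarding against cycle
#'   skipping when the initial thickness error approaches the wrap period
#'   `1/(f0 (1/cw - 1/ca))`: a data frame with columns `sigma` (SD in Hz of
#'   an extra zero-phase Gaussian low-pass applied to both the data and the
#'   model kernel; `Inf` = full bandwidth) and `frac` (fraction of the
#'   iteration budget).  Default: a single full-bandwidth stage (plain
#'   joint ADAM); e.g. `data.frame(sigma = c(0.25e6, 0.4e6, Inf),
#'   frac = c(0.4, 0.3, 0.3))` marches from 0.25 MHz up.
#' @param z_warmup Iterations at the start of the first stage during which
#'   the thickness block is frozen, letting the amplitude image form before
#'   the (amplitude-weighted) thickness gradient becomes informative.
#' @param seed Stored for provenance; the optimizer itself is deterministic.
#' @param verbose Print per-iteration loss.
#' @return An object of class `pa_control`.
#' @export
pa_control <- function(iterations = 100, lr_z = NULL, lr_a = NULL,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       tol = 1e-6, patience = 10, nonneg_a = TRUE,
                       stages = data.frame(sigma = Inf, frac = 1),
                       z_warmup = 10, seed = NULL, verbose = FALSE) {
  stopifnot(iterations >= 1, is.null(lr_z) || lr_z > 0,
            is.null(lr_a) || lr_a > 0,
            is.data.frame(stages), all(c("sigma", "frac") %in% names(stages)),
            abs(sum(stages$frac) - 1) < 1e-9)
  structure(list(iterations = as.integer(iterations), lr_z = lr_z,
                 lr_a = lr_a, beta1 = beta1, beta2 = beta2, eps = eps,
                 tol = tol, patience = patience, nonneg_a = nonneg_a,
                 stages = stages, z_warmup = as.integer(z_warmup),
                 seed = seed, verbose = verbose),
            class = "pa_control")
}

# extra zero-phase Gaussian low-pass (spectral SD sigma) on an impulse
# response / on trace columns; sigma = Inf is the identity
lowpass_ir <- function(ir, sigma) {
  if (!is.finite(sigma)) return(ir)
  ir$kernel <- as.vector(lowpass_traces(matrix(ir$kernel), ir$fs, sigma))
  ir
}

lowpass_traces <- function(mat, fs, sigma) {
  if (!is.finite(sigma)) return(mat)
  nt <- nrow(mat)
  L <- 2^ceiling(log2(2 * nt))
  f <- c(0:(L / 2), -(L / 2 - 1):-1) * fs / L
  H <- exp(-f^2 / (2 * sigma^2))
  pad <- rbind(mat, matrix(0, L - nt, ncol(mat)))
  Re(stats::mvfft(stats::mvfft(pad) * H, inverse = TRUE))[seq_len(nt), ,
                                                          drop = FALSE] / L
}

# effective centre frequency of the f0-centred Gaussian amplitude spectrum
# (SD sf) after an extra low-pass of SD sigma
effective_f0 <- function(f0, sf, sigma) {
  if (!is.finite(sigma)) return(f0)
  f0 * sigma^2 / (sf^2 + sigma^2)
}

resolve_z_init <- function(z_init, model) {
  if (inherits(z_init, "pa_profile_estimate")) z_init <- as_profile(z_init)
  if (inherits(z_init, "pa_profile")) {
    if (length(z_init$x) == length(model$interface_x) &&
        isTRUE(all.equal(z_init$x, model$interface_x)))
      return(z_init$z)
    return(pmax(stats::spline(z_init$x, z_init$z, xout = model$interface_x,
                              method = "natural")$y, 0))
  }
  stopifnot(is.numeric(z_init), length(z_init) == length(model$interface_x))
  as.numeric(z_init)
}

#' Joint inversion of aberrator profile and target image
#'
#' Fits the unknown thickness profile of the aberrating layer and the
#' initial pressure distribution of the target simultaneously, by ADAM
#' gradient descent on the regularized model-fit loss
#' `L(theta) = D(theta) + P(theta)`: `D` is the squared misfit between the
#' Fresnel-Kirchhoff forward model of the current parameters and the
#' measured RF traces, and `P` combines an L1 sparsity prior on the
#' amplitudes (direct or Fourier basis) with an L2 anchor of the thickness
#' profile to its initial estimate.  Thicknesses are projected onto
#' `z >= 0` (and amplitudes onto `a >= 0` unless disabled) after every step.
#'
#' @param measured A [pa_rf]: the recorded traces.
#' @param model A [pa_forward_model()] configuration.
#' @param z_init Initial thickness guess: a [pa_profile], a profile estimate
#'   from [estimate_profile_echo()], or a numeric vector on
#'   `model$interface_x`.
#' @param a_init Initial amplitudes (default all zero).
#' @param prior A [pa_prior]; `z_ref` defaults to `z_init` and `dim` to the
#'   model grid.  Default: a mild data-scaled direct-basis sparsity prior
#'   with an aberrator anchor (see the package vignette).
#' @param control A [pa_control].
#' @param truth Optional ground-truth thickness (profile or numeric) used
#'   only to record an error history.
#' @return An object of class `pa_fit` with components `z` (fitted
#'   thickness, m), `a` (fitted amplitude image as a matrix), `profile`
#'   ([pa_profile]), `history` (per-iteration `L`, `D`, `P` and optional
#'   `z_rmse`), `prior`, `control`, `model`, `converged`, `iterations`.
#'   Methods: `print`, `summary`, `coef`, `plot`, `predict`, `fitted`,
#'   `residuals`, `simulate`.
#' @export
pa_fit <- function(measured, model, z_init, a_init = NULL,
                   prior = NULL, control = pa_control(), truth = NULL) {
  stopifnot(inherits(measured, "pa_rf"), inherits(model, "pa_model"))
  z <- resolve_z_init(z_init, model)
  npix <- length(model$grid$x) * length(model$grid$z)
  a <- if (is.null(a_init)) numeric(npix) else as.numeric(a_init)
  theta <- pa_theta(z, a, model)
  lambda <- model$medium$cw / model$ir$f0
  z_true <- if (is.null(truth)) NULL else resolve_z_init(truth, model)

  # Amplitude scale from the least-squares back-projection of the data:
  # the adjoint image F'y divided by the energy of a single-pixel forward
  # response (approximately the diagonal of F'F), so that a_scale is in
  # amplitude units regardless of the obliquity variant's overall scale.
  b0 <- beamform_wave(measured, theta_profile(theta, model), model$medium,
                      model$array, model$grid, variant = model$variant,
                      mode = "adjoint", ir = model$ir)
  ctr <- numeric(npix)
  ctr[ceiling(npix / 2)] <- 1
  col_energy <- sum(forward_theta(pa_theta(z, ctr, model), model,
                                  measured)$traces^2)
  a_scale <- if (col_energy > 0) max(abs(b0$amplitude)) / col_energy else 1
  if (a_scale == 0) a_scale <- 1

  D0 <- sum(measured$traces^2)
  if (is.null(prior)) prior <- pa_prior(alpha = NA, beta = NA)
  # mild data-scaled defaults: see the methods vignette
  if (is.na(prior$alpha)) prior$alpha <- 0.01 * D0 / a_scale
  if (is.na(prior$beta))
    prior$beta <- 0.01 * D0 / (length(z) * lambda^2)
  if (is.null(prior$z_ref)) prior$z_ref <- z
  if (is.null(prior$dim)) prior$dim <- c(length(model$grid$x),
                                         length(model$grid$z))

  lr_z <- control$lr_z %||% (lambda / 50)
  lr_a <- control$lr_a %||% (a_scale / 20)

  # frequency-continuation schedule (guards against delay wrap-around in z)
  stages <- control$stages
  budget <- pmax(round(stages$frac * control$iterations), 1L)
  budget[nrow(stages)] <- max(control$iterations - sum(budget[-nrow(stages)]),
                              1L)
  sf <- 1 / (2 * pi * model$ir$sigma_t)

  nz <- length(theta$z)
  K <- sum(budget)
  hist_L <- hist_D <- hist_P <- numeric(K + 1L)
  hist_stage <- integer(K + 1L)
  hist_e <- if (is.null(z_true)) NULL else numeric(K + 1L)
  diverged <- 0L; converged <- FALSE; stopped <- FALSE
  it <- 0L

  for (s in seq_len(nrow(stages))) {
    sigma <- stages$sigma[s]
    last_stage <- s == nrow(stages)
    model_s <- model
    model_s$ir <- lowpass_ir(model$ir, sigma)
    meas_s <- measured
    meas_s$traces <- lowpass_traces(measured$traces, measured$fs, sigma)
    # keep the prior/data balance of the full-band problem: the band-limited
    # data term (and its gradient) scales with the in-band energy
    e_tot <- sum(measured$traces^2)
    e_ratio <- if (!is.finite(sigma) || e_tot == 0) 1
               else sum(meas_s$traces^2) / e_tot
    prior_s <- prior
    prior_s$alpha <- prior$alpha * e_ratio
    prior_s$beta <- prior$beta * e_ratio
    lr_z_s <- lr_z * min(model$ir$f0 / effective_f0(model$ir$f0, sf, sigma), 3)
    mz <- vz <- numeric(nz); ma <- va <- numeric(npix)
    flat <- 0L; stage_it <- 0L

    for (k in seq_len(budget[s])) {
      it <- it + 1L; stage_it <- stage_it + 1L
      g <- pa_loss_gradient(theta, meas_s, prior_s, model_s)
      hist_L[it] <- g$value$L; hist_D[it] <- g$value$D; hist_P[it] <- g$value$P
      hist_stage[it] <- s
      if (!is.null(z_true))
        hist_e[it] <- sqrt(mean((theta$z - z_true)^2))
      if (control$verbose)
        message(sprintf("stage %d iter %3d: L = %.6g (D = %.3g, P = %.3g)",
                        s, it - 1L, g$value$L, g$value$D, g$value$P))

      if (stage_it > 1) {
        rel <- abs(hist_L[it] - hist_L[it - 1]) / max(hist_L[it - 1], 1e-300)
        flat <- if (rel < control$tol) flat + 1L else 0L
        diverged <- if (hist_L[it] > 1e3 * hist_L[1]) diverged + 1L else 0L
        if (diverged >= 10L) {
          warning("loss diverged; returning history up to abort")
          it <- it - 1L; stopped <- TRUE
          break
        }
        if (flat >= control$patience) {       # stage plateau: advance / stop
          converged <- last_stage
          it <- it - 1L
          break
        }
      }

      b1t <- 1 - control$beta1^stage_it; b2t <- 1 - control$beta2^stage_it
      if (!(s == 1L && stage_it <= control$z_warmup)) {
        mz <- control$beta1 * mz + (1 - control$beta1) * g$z
        vz <- control$beta2 * vz + (1 - control$beta2) * g$z^2
        theta$z <- pmax(theta$z - lr_z_s * (mz / b1t) /
                          (sqrt(vz / b2t) +
                             control$eps * sqrt(mean(vz / b2t) + 1e-300)),
                        0)
      }
      ma <- control$beta1 * ma + (1 - control$beta1) * g$a
      va <- control$beta2 * va + (1 - control$beta2) * g$a^2
      theta$a <- theta$a - lr_a * (ma / b1t) /
        (sqrt(va / b2t) + control$eps * sqrt(mean(va / b2t) + 1e-300))
      if (control$nonneg_a) theta$a <- pmax(theta$a, 0)
    }
    if (stopped) break
  }

  fin <- pa_loss(theta, measured, prior, model)
  hist_L[it + 1L] <- fin$L; hist_D[it + 1L] <- fin$D; hist_P[it + 1L] <- fin$P
  hist_stage[it + 1L] <- nrow(stages)
  if (!is.null(z_true)) hist_e[it + 1L] <- sqrt(mean((theta$z - z_true)^2))
  keep <- seq_len(it + 1L)
  history <- data.frame(iter = keep - 1L, L = hist_L[keep], D = hist_D[keep],
                        P = hist_P[keep], stage = hist_stage[keep])
  if (!is.null(z_true)) history$z_rmse <- hist_e[keep]

  structure(list(z = theta$z, a = matrix(theta$a, prior$dim[1], prior$dim[2]),
                 profile = theta_profile(theta, model),
                 history = history, prior = prior,
                 control = control, model = model, measured = measured,
                 lr = c(z = lr_z, a = lr_a), a_scale = a_scale,
                 converged = converged, iterations = it,
                 call = match.call()),
            class = "pa_fit")
}
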