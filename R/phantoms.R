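#' Regular grid of point absorbers
#'
#' A rows-by-cols grid of equal-amplitude point targets centred on the array
#' axis at the given depth, mimicking the point-grid phantoms of the
#' numerical study (5 x 5 = 25 dots; 4 x 5 = 20 dots).
#'
#' @param rows,cols Grid dimensions (>= 1).
#' @param spacing Point spacing (m), both directions.
#' @param depth Depth (m) of the grid centre.
#' @param amplitude Initial pressure amplitude of every point.
#' @return A data frame with columns `x`, `z`, `a`.
#' @examples
#' nrow(make_point_grid_target(5, 5, 4e-3, 40e-3))  # 25
#' @export
make_point_grid_target <- function(rows, cols, spacing, depth,
                                   amplitude = 1) {
  stopifnot(rows >= 1, cols >= 1, spacing > 0, depth > 0)
  x <- (seq_len(cols) - (cols + 1) / 2) * spacing
  z <- depth + (seq_len(rows) - (rows + 1) / 2) * spacing
  g <- expand.grid(x = x, z = z)
  data.frame(x = g$x, z = g$z, a = amplitude)
}

#' Synthetic vessel-like target image
#'
#' Rasterizes random smooth polyline branches with Gaussian cross-sections
#' onto an image grid, optionally adding a rounded swelling (disk) at a
#' branch point.  Vessel widths may be set below the acoustic diffraction
#' limit to emulate the sub-resolution vessel phantom.  Such images are
#' strongly compressible in the Fourier domain, which is what the
#' Fourier-basis sparsity prior of [pa_prior()] exploits.
#'
#' @param grid A [pa_grid].
#' @param n_branches Number of branches.
#' @param width_range Length-2 vector of Gaussian cross-section SDs (m).
#' @param swelling Radius (m) of a rounded swelling placed on the first
#'   branch; 0 disables it.
#' @param seed Integer seed; the image is deterministic given the seed.
#' @return Amplitude matrix (`length(grid$x) x length(grid$z)`) in [0, 1].
#' @export
make_vessel_target <- function(grid, n_branches = 3,
                               width_range = c(4e-4, 1e-3),
                               swelling = 0, seed = 1) {
  px <- grid_pixels(grid)
  A <- numeric(length(px$x))
  xr <- range(grid$x); zr <- range(grid$z)
  with_seed(seed, {
    for (b in seq_len(n_branches)) {
      nc <- 4L
      cx <- sort(stats::runif(nc, xr[1], xr[2]))
      cz <- stats::runif(nc, zr[1] + 0.15 * diff(zr), zr[2] - 0.15 * diff(zr))
      u <- seq(0, 1, length.out = 200)
      bx <- stats::spline(seq(0, 1, length.out = nc), cx, xout = u,
                          method = "natural")$y
      bz <- stats::spline(seq(0, 1, length.out = nc), cz, xout = u,
                          method = "natural")$y
      w <- stats::runif(1, width_range[1], width_range[2])
      for (i in seq_along(u)) {
        d2 <- (px$x - bx[i])^2 + (px$z - bz[i])^2
        A <- pmax(A, exp(-d2 / (2 * w^2)))
      }
      if (b == 1L && swelling > 0) {
        d2 <- (px$x - bx[100])^2 + (px$z - bz[100])^2
        A <- pmax(A, exp(-(d2 / (2 * swelling^2))^2))
      }
    }
  })
  A[A < 1e-3] <- 0
  matrix(A / max(A), length(grid$x), length(grid$z))
}

#' Synthetic aberrator thickness profiles
#'
#' @param kind `"flat"` (constant thickness), `"tilt"` (linear),
#'   `"lens"` (Gaussian cap, thin at the edges and thick at the centre, as
#'   in the lens-like aberrator of the numerical study), or `"bumps"`
#'   (flat base plus a smooth sum of random Gaussian bumps).
#' @param aperture Lateral extent (m); the profile spans
#'   `[-aperture/2, aperture/2]`.
#' @param spacing Lateral sample spacing (m).
#' @param thickness Base (flat/tilt/bumps) thickness (m).
#' @param slope Thickness gradient for `"tilt"` (m per m).
#' @param edge,center Edge and centre thickness for `"lens"` (m).
#' @param n_bumps,bump_amp,bump_sigma Bump count, amplitude (m) and lateral
#'   SD (m) for `"bumps"`; amplitudes are drawn in `[-bump_amp, bump_amp]`.
#' @param seed Seed for `"bumps"`.
#' @return A [pa_profile], strictly positive over the aperture.
#' @export
make_aberrator <- function(kind = c("flat", "tilt", "lens", "bumps"),
                           aperture = 64e-3, spacing = 1e-3,
                           thickness = 10e-3, slope = 0.1,
                           edge = 5e-3, center = 15e-3,
                           n_bumps = 3, bump_amp = 3e-3, bump_sigma = 8e-3,
                           seed = 1) {
  kind <- match.arg(kind)
  x <- seq(-aperture / 2, aperture / 2, by = spacing)
  z <- switch(kind,
    flat = rep(thickness, length(x)),
    tilt = thickness + slope * x,
    lens = edge + (center - edge) * exp(-x^2 / (2 * (aperture / 5)^2)),
    bumps = {
      zz <- rep(thickness, length(x))
      with_seed(seed, {
        for (k in seq_len(n_bumps)) {
          x0 <- stats::runif(1, -aperture / 3, aperture / 3)
          amp <- stats::runif(1, -bump_amp, bump_amp)
          zz <- zz + amp * exp(-(x - x0)^2 / (2 * bump_sigma^2))
        }
      })
      zz
    })
  if (any(z <= 0)) stop("profile parameters give non-positive thickness")
  pa_profile(x, z)
}

#' Study scenarios
#'
#' Bundles medium, array, impulse response, ground-truth aberrator and
#' target, noise level and inverse-crime options into a reproducible unit
#' matching the conditions of the numerical study: water at 1540 m/s, a
#' bone-like layer at 2700 m/s, a 65-element array, a 1 MHz / 75% bandwidth
#' Gaussian sensor response and 3.0 dB mean-to-mean SNR.  Named scenarios:
#'
#' * `"points65"`: 25-point grid target behind a lens-like aberrator.
#' * `"sparse20"`: 20-point sparse target behind a flat-plus-bump aberrator
#'   (the joint-inversion benchmark; the bump perturbs the flat initial
#'   guess by two acoustic wavelengths).
#' * `"vessels"`: sub-resolution vessel image behind the lens aberrator
#'   (Fourier-basis sparsity regime).
#' * `"experiment_like"`: Perspex-like layer at 2775 m/s, 128 elements.
#'
#' Measured data for a scenario are produced by [scenario_rf()], which
#' mitigates the inverse crime by generating with a 4x finer interface
#' sampling and a different obliquity variant than the reconstruction
#' default, plus calibrated noise.
#'
#' @param name Scenario name.
#' @param seed Integer seed controlling the random ingredients and noise.
#' @return An object of class `pa_scenario`.
#' @export
make_scenario <- function(name = c("points65", "sparse20", "vessels",
                                   "experiment_like"), seed = 1) {
  name <- match.arg(name)
  medium <- pa_medium(cw = 1540, ca = if (name == "experiment_like") 2775
                                      else 2700)
  array <- pa_array(n = if (name == "experiment_like") 128L else 65L,
                    pitch = 1e-3)
  ir <- gaussian_bandpass_ir(1e6, 0.75, 20e6)
  lambda <- medium$cw / ir$f0
  aperture <- (array$n - 1) * array$pitch

  if (name == "sparse20") {
    grid <- pa_grid(seq(-16e-3, 15.5e-3, 5e-4), seq(28e-3, 59.5e-3, 5e-4))
    targets <- make_point_grid_target(4, 5, 4e-3, 42e-3)
    x <- seq(-aperture / 2, aperture / 2, array$pitch)
    profile <- pa_profile(x, 10e-3 + 2 * lambda *
                            exp(-(x - 3e-3)^2 / (2 * (8e-3)^2)))
    z_init <- rep(10e-3, length(x))
    target_image <- NULL
  } else {
    grid <- pa_grid(seq(-31.75e-3, 31.75e-3, 5e-4),
                    seq(20.25e-3, 83.75e-3, 5e-4))
    profile <- make_aberrator("lens", aperture = aperture,
                              spacing = array$pitch)
    z_init <- rep(mean(profile$z), length(profile$x))
    if (name == "vessels") {
      targets <- NULL
      target_image <- make_vessel_target(grid, n_branches = 3,
                                         width_range = c(4e-4, 8e-4),
                                         swelling = 2e-3, seed = seed)
    } else {
      targets <- make_point_grid_target(5, 5, 4e-3, 40e-3)
      target_image <- NULL
    }
  }
  structure(list(name = name, seed = as.integer(seed), medium = medium,
                 array = array, ir = ir, profile = profile,
                 targets = targets, target_image = target_image,
                 grid = grid, z_init = z_init, snr_db = 3.0,
                 inverse_crime = list(oversample = 4L,
                                      variant = "sommerfeld1"),
                 variant = "kirchhoff"),
            class = "pa_scenario")
}

#' @export
print.pa_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (seed %d)\n", x$name, x$seed))
  print(x$medium); print(x$array)
  print(x$profile)
  if (!is.null(x$targets))
    cat(sprintf("  target: %d point absorbers\n", nrow(x$targets)))
  else cat(sprintf("  target: vessel image, %d active pixels\n",
                   sum(x$target_image > 0)))
  cat(sprintf("  SNR %.1f dB; data generated with %dx interface oversampling, '%s' obliquity\n",
              x$snr_db, x$inverse_crime$oversample, x$inverse_crime$variant))
  invisible(x)
}

# point-source list of a scenario (vessel images become per-pixel sources)
scenario_targets <- function(sc) {
  if (!is.null(sc$targets)) return(sc$targets)
  a <- as.vector(sc$target_image)
  px <- grid_pixels(sc$grid)
  keep <- a > 0
  data.frame(x = px$x[keep], z = px$z[keep], a = a[keep])
}

#' Measured RF traces of a scenario
#'
#' Generates the scenario's "measured" data with inverse-crime mitigation:
#' the interface is sampled `oversample` times finer than the
#' reconstruction default, the obliquity variant differs from the
#' reconstruction variant, and calibrated Gaussian noise is added (disable
#' with `noiseless = TRUE`).  Deterministic given the scenario seed.
#'
#' @param sc A [make_scenario()] object.
#' @param noiseless Skip the noise step.
#' @return A [pa_rf].
#' @export
scenario_rf <- function(sc, noiseless = FALSE) {
  fine <- interface_points(sc$profile,
                           sc$array$pitch / sc$inverse_crime$oversample)
  rf <- simulate_rf(scenario_targets(sc), fine, sc$medium, sc$array, sc$ir,
                    variant = sc$inverse_crime$variant)
  if (!noiseless && is.finite(sc$snr_db))
    rf <- add_noise(rf, sc$snr_db, seed = sc$seed)
  rf
}

#' Forward-model configuration of a scenario
#'
#' The reconstruction-side [pa_forward_model()]: interface sampled at the
#' array pitch, obliquity variant `"kirchhoff"`.
#'
#' @param sc A [make_scenario()] object.
#' @return A `pa_model`.
#' @export
scenario_model <- function(sc) {
  pa_forward_model(sc$grid, sc$medium, sc$array, sc$ir,
                   variant = sc$variant, interface_x = sc$profile$x)
}

#' Synthetic pulse-echo acquisition from the layer's distal facet
#'
#' Builds a normal-incidence pulse-echo fixture: each element receives the
#' transmit kernel at the round-trip time `2 z(x_n)/ca`, optionally followed
#' by reverberation replicas at integer multiples with geometrically
#' decaying amplitude (`ratio^k`), the first reflection always being the
#' strongest.
#'
#' @param profile A [pa_profile].
#' @param medium A [pa_medium] (uses `ca`).
#' @param array A [pa_array].
#' @param ir Transmit kernel, a [pa_ir].
#' @param n_reverb Number of reverberation replicas (0 for none).
#' @param ratio Amplitude ratio between successive replicas (< 1).
#' @return A [pa_rf].
#' @export
simulate_pulse_echo <- function(profile, medium, array, ir,
                                n_reverb = 0, ratio = 0.3) {
  stopifnot(all(profile$z > 0), ratio < 1)
  zx <- stats::approx(profile$x, profile$z, array$x, rule = 2)$y
  tau <- 2 * zx / medium$ca
  fs <- ir$fs
  nt <- ceiling((max(tau) * (n_reverb + 1) + 5 * ir$sigma_t) * fs)
  dep <- matrix(0, nt, array$n)
  for (n in seq_len(array$n)) for (k in 0:n_reverb) {
    pos <- tau[n] * (k + 1) * fs
    i0 <- floor(pos); f <- pos - i0
    amp <- ratio^k
    dep[i0 + 1, n] <- dep[i0 + 1, n] + amp * (1 - f)
    dep[i0 + 2, n] <- dep[i0 + 2, n] + amp * f
  }
  pa_rf(convolve_traces(dep, ir), fs, 0, array$x)
}
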