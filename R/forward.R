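#' Gaussian band-pass sensor impulse response
#'
#' Builds the effective temporal impulse response of the array elements: a
#' Gaussian-envelope band-pass wavelet whose power spectrum is Gaussian,
#' centred at `f0`, with -6 dB full width equal to `bw * f0` (the usual
#' ultrasound fractional-bandwidth convention).  The sampled kernel is
#' zero-phase (symmetric about t = 0), has exactly zero mean, and unit peak
#' spectral magnitude.
#'
#' @param f0 Centre frequency (Hz).
#' @param bw Fractional bandwidth (0 < bw < 2); -6 dB full width / f0.
#' @param fs Sampling rate (Hz); must exceed `4 * f0`.
#' @return An object of class `pa_ir`: `kernel` (samples), `ic` (index of the
#'   t = 0 sample), `fs`, `f0`, `bw`, `sigma_t` (envelope SD, s).
#' @examples
#' ir <- gaussian_bandpass_ir(1e6, 0.75, 20e6)
#' @export
gaussian_bandpass_ir <- function(f0 = 1e6, bw = 0.75, fs = 20e6) {
  stopifnot(f0 > 0, bw > 0, bw < 2)
  if (fs <= 4 * f0) stop("Nyquist violation: fs must exceed 4*f0")
  # -6 dB (power) full width bw*f0 on the amplitude spectrum exp(-df^2/(2 sf^2))
  sf <- bw * f0 / (2 * sqrt(0.6 * log(10)))
  st <- 1 / (2 * pi * sf)
  k <- ceiling(4 * st * fs)
  t <- (-k:k) / fs
  env <- exp(-t^2 / (2 * st^2))
  h <- env * cos(2 * pi * f0 * t)
  h <- h - env * (sum(h) / sum(env))          # remove residual DC exactly
  # unit peak spectral magnitude
  nfft <- 2^ceiling(log2(max(4096, 8 * length(h))))
  h <- h / max(Mod(stats::fft(c(h, numeric(nfft - length(h))))))
  structure(list(kernel = h, ic = k + 1L, fs = fs, f0 = f0, bw = bw,
                 sigma_t = st),
            class = "pa_ir")
}

#' @export
print.pa_ir <- function(x, ...) {
  cat(sprintf(
    "Gaussian band-pass impulse response: f0 = %.3g MHz, %.0f%% bandwidth, fs = %.3g MHz (%d taps)\n",
    x$f0 / 1e6, 100 * x$bw, x$fs / 1e6, length(x$kernel)))
  invisible(x)
}

#' RF data container
#'
#' Per-element pressure traces with sampling metadata.
#'
#' @param traces Numeric matrix, `n_samples x n_sensors`.
#' @param fs Sampling rate (Hz).
#' @param t0 Time of the first sample (s).
#' @param sensor_x Lateral element positions (m), one per column.
#' @param units Amplitude units label (arbitrary).
#' @return An object of class `pa_rf`.
#' @export
pa_rf <- function(traces, fs, t0 = 0, sensor_x, units = "a.u.") {
  traces <- as.matrix(traces)
  stopifnot(fs > 0, length(sensor_x) == ncol(traces))
  structure(list(traces = traces, fs = fs, t0 = t0,
                 sensor_x = as.numeric(sensor_x), units = units),
            class = "pa_rf")
}

#' @export
print.pa_rf <- function(x, ...) {
  cat(sprintf("RF data: %d sensors x %d samples, fs = %.3g MHz, t0 = %.3g us\n",
              ncol(x$traces), nrow(x$traces), x$fs / 1e6, x$t0 * 1e6))
  invisible(x)
}

#' @export
dim.pa_rf <- function(x) dim(x$traces)

# time axis of an RF container
rf_time <- function(rf) rf$t0 + (seq_len(nrow(rf$traces)) - 1L) / rf$fs

# Zero-phase FFT convolution of every column with the impulse-response
# kernel (adjoint = correlation).  Circular on a padded grid, cropped back,
# so gather/correlate is the exact adjoint of deposit/convolve.
convolve_traces <- function(mat, ir, adjoint = FALSE) {
  nt <- nrow(mat); nk <- length(ir$kernel)
  L <- 2^ceiling(log2(nt + nk))
  kv <- numeric(L)
  idx <- ((seq_len(nk) - ir$ic) %% L) + 1L   # kernel centre at index 1
  for (i in seq_len(nk)) kv[idx[i]] <- kv[idx[i]] + ir$kernel[i]
  K <- stats::fft(kv)
  if (adjoint) K <- Conj(K)
  pad <- rbind(mat, matrix(0, L - nt, ncol(mat)))
  out <- Re(stats::mvfft(stats::mvfft(pad) * K, inverse = TRUE)) / L
  out[seq_len(nt), , drop = FALSE]
}

# shared geometry argument assembly for the C++ kernels
kernel_args <- function(profile, medium, array, variant) {
  spacing <- min(diff(profile$x))
  list(ix = profile$x, iz = profile$z, nx = profile$nx, nz = profile$nz,
       slope = profile$slope, ax = array$x, az = array$z,
       cw = medium$cw, ca = medium$ca,
       variant = obliquity_code(variant), quad = spacing,
       alpha_w = medium$alpha_w, alpha_a = medium$alpha_a,
       min_dist = spacing)
}

as_targets <- function(targets) {
  if (is.data.frame(targets)) {
    stopifnot(all(c("x", "z", "a") %in% names(targets)))
    return(targets[c("x", "z", "a")])
  }
  if (is.matrix(targets) && ncol(targets) == 3)
    return(data.frame(x = targets[, 1], z = targets[, 2], a = targets[, 3]))
  stop("targets must be a data.frame with columns x, z, a")
}

#' Simulate RF traces through an aberrating layer
#'
#' Synthesizes per-element pressure traces from point absorbers by the
#' modified Fresnel-Kirchhoff diffraction sum: every interface point of the
#' layer acts as a secondary wavelet source, each wavelet carrying the
#' two-segment delay `r_sj/cw + r_jn/ca`, geometric spreading `1/(r_sj r_jn)`
#' and the chosen obliquity weight.  Wavelets are deposited onto the time
#' grid (linear interpolation between the two nearest samples) and the result
#' is convolved once per element with the sensor impulse response.  The
#' output is linear in the amplitude vector.
#'
#' @param targets Data frame with columns `x`, `z` (m) and `a` (initial
#'   pressure amplitude); may have zero rows.
#' @param profile A [pa_profile] covering the array aperture.
#' @param medium A [pa_medium].
#' @param array A [pa_array].
#' @param ir A [pa_ir] impulse response (also fixes the default `fs`).
#' @param time_grid Optional list with `fs`, `t0`, `nt`; defaults to `ir$fs`,
#'   `t0 = 0` and `nt` covering the largest two-segment delay plus four
#'   envelope standard deviations of the kernel.
#' @param variant Obliquity variant, see [obliquity()].
#' @return A [pa_rf]; attribute `clipped` counts wavelets outside the window.
#' @export
simulate_rf <- function(targets, profile, medium, array, ir,
                        time_grid = NULL,
                        variant = c("kirchhoff", "sommerfeld1", "sommerfeld2",
                                    "unity")) {
  variant <- match.arg(variant)
  targets <- as_targets(targets)
  ka <- kernel_args(profile, medium, array, variant)
  kernel_tail <- 4 * ir$sigma_t

  # exact max two-segment delay: tau(s,j,n) separates over s and n for fixed j
  span_needed <- 0
  if (nrow(targets) > 0) {
    tau1 <- outer(seq_len(nrow(targets)), seq_along(profile$x),
                  function(s, j) sqrt((targets$x[s] - profile$x[j])^2 +
                                      (targets$z[s] - profile$z[j])^2) / medium$cw)
    tau2 <- outer(seq_along(profile$x), seq_along(array$x),
                  function(j, n) sqrt((profile$x[j] - array$x[n])^2 +
                                      (profile$z[j] - array$z[n])^2) / medium$ca)
    span_needed <- max(apply(tau1, 2, max) + apply(tau2, 1, max)) + kernel_tail
  }
  if (is.null(time_grid)) {
    fs <- ir$fs; t0 <- 0
    nt <- as.integer(ceiling(span_needed * fs)) + 2L
    nt <- max(nt, 16L)
  } else {
    fs <- time_grid$fs %||% ir$fs
    t0 <- time_grid$t0 %||% 0
    nt <- time_grid$nt
    if (t0 + nt / fs < span_needed)
      stop(sprintf("time window too short: need at least %.3g us from t0 = 0",
                   span_needed * 1e6))
  }

  if (nrow(targets) == 0) {
    rf <- pa_rf(matrix(0, nt, array$n), fs, t0, array$x)
    attr(rf, "clipped") <- 0
    return(rf)
  }

  dep <- cpp_deposit(targets$x, targets$z, targets$a,
                     ka$ix, ka$iz, ka$nx, ka$nz, ka$slope, ka$ax, ka$az,
                     ka$cw, ka$ca, ka$variant, ka$quad,
                     ka$alpha_w, ka$alpha_a, fs, t0, nt, ka$min_dist)
  traces <- convolve_traces(dep$deposits, ir)
  rf <- pa_rf(traces, fs, t0, array$x)
  attr(rf, "clipped") <- dep$clipped
  rf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add calibrated Gaussian noise to RF data
#'
#' Adds i.i.d. zero-mean Gaussian noise scaled so that the mean-to-mean
#' signal-to-noise ratio, `10*log10(mean(signal^2)/mean(noise^2))`, equals
#' `snr_db` in expectation.  At the 3.0 dB of the numerical study the noise
#' intensity equals 50% of the signal intensity.  `snr_db = Inf` disables
#' noise.  A fixed `seed` gives a bit-identical realization; the global RNG
#' state is left untouched.
#'
#' @param rf A [pa_rf] with non-zero content.
#' @param snr_db Mean-to-mean SNR (dB), or `Inf`.
#' @param seed Optional integer seed for reproducible noise.
#' @return A [pa_rf] with noise added.
#' @export
add_noise <- function(rf, snr_db, seed = NULL) {
  stopifnot(inherits(rf, "pa_rf"))
  if (is.infinite(snr_db) && snr_db > 0) return(rf)
  sig_pow <- mean(rf$traces^2)
  if (sig_pow == 0) stop("SNR undefined for all-zero RF data")
  sd_n <- sqrt(sig_pow * 10^(-snr_db / 10))
  noise <- with_seed(seed, stats::rnorm(length(rf$traces), sd = sd_n))
  rf$traces <- rf$traces + matrix(noise, nrow(rf$traces), ncol(rf$traces))
  rf
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Measure mean-to-mean SNR between clean and noisy RF data
#'
#' @param signal Clean [pa_rf].
#' @param noisy Noisy [pa_rf] of the same shape.
#' @return `10*log10(mean(signal^2)/mean((noisy - signal)^2))` in dB;
#'   `Inf` when the residual is exactly zero.
#' @export
measure_snr <- function(signal, noisy) {
  stopifnot(inherits(signal, "pa_rf"), inherits(noisy, "pa_rf"),
            all(dim(signal$traces) == dim(noisy$traces)))
  res_pow <- mean((noisy$traces - signal$traces)^2)
  if (res_pow == 0) return(Inf)
  10 * log10(mean(signal$traces^2) / res_pow)
}

#' Envelope of RF traces
#'
#' Magnitude of the analytic signal (Hilbert transform via FFT) of each
#' trace; used for envelope-peak arrival-time measurements.
#'
#' @param rf A [pa_rf] or a numeric matrix (samples x sensors).
#' @return Matrix of envelope values, same shape as the traces.
#' @export
rf_envelope <- function(rf) {
  m <- if (inherits(rf, "pa_rf")) rf$traces else as.matrix(rf)
  nt <- nrow(m)
  H <- stats::mvfft(m)
  w <- numeric(nt)
  if (nt %% 2 == 0) {
    w[1] <- 1; w[nt / 2 + 1] <- 1; w[2:(nt / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((nt + 1) / 2)] <- 2
  }
  Mod(stats::mvfft(H * w, inverse = TRUE) / nt)
}
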