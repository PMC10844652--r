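#' Rectangular image grid
#'
#' @param x,z Strictly increasing pixel centre coordinates (m).
#' @return An object of class `pa_grid`.
#' @export
pa_grid <- function(x, z) {
  stopifnot(all(diff(x) > 0), all(diff(z) > 0))
  structure(list(x = as.numeric(x), z = as.numeric(z)), class = "pa_grid")
}

# pixel centres as vectors, x index varying fastest (column-major image)
grid_pixels <- function(grid) {
  list(x = rep(grid$x, times = length(grid$z)),
       z = rep(grid$z, each = length(grid$x)))
}

#' Beamformed image container
#'
#' Amplitudes on a [pa_grid]; `amplitude` is an `length(x) x length(z)`
#' matrix so that `image(x, z, amplitude)` displays with x lateral and z
#' down-range.  Signed values are retained; display uses the absolute value.
#'
#' @param grid A [pa_grid].
#' @param amplitude Matrix of beamformed values.
#' @param meta Optional metadata list.
#' @return An object of class `pa_image`.
#' @export
pa_image <- function(grid, amplitude, meta = list()) {
  amplitude <- matrix(amplitude, length(grid$x), length(grid$z))
  if (!all(is.finite(amplitude))) stop("image amplitudes must be finite")
  structure(list(grid = grid, amplitude = amplitude, meta = meta),
            class = "pa_image")
}

#' @export
print.pa_image <- function(x, ...) {
  cat(sprintf("Beamformed image: %d x %d pixels, |A| in [%.3g, %.3g]\n",
              length(x$grid$x), length(x$grid$z),
              min(abs(x$amplitude)), max(abs(x$amplitude))))
  if (!is.null(x$meta$clipped_warning) && x$meta$clipped_warning)
    cat("  warning: >50% of delay lookups fell outside the recorded window\n")
  invisible(x)
}

#' @export
plot.pa_image <- function(x, main = "beamformed image", ...) {
  graphics::image(x$grid$x * 1e3, x$grid$z * 1e3, abs(x$amplitude),
                  xlab = "x (mm)", ylab = "z (mm)", ylim = rev(range(x$grid$z * 1e3)),
                  main = main, col = grDevices::hcl.colors(64, "inferno"), ...)
  invisible(x)
}

#' Position of the image maximum
#'
#' @param image A [pa_image].
#' @return Named vector `c(x, z)` of the pixel with the largest `|A|`.
#' @export
image_argmax <- function(image) {
  i <- which.max(abs(image$amplitude))
  px <- grid_pixels(image$grid)
  c(x = px$x[i], z = px$z[i])
}

clip_meta <- function(clipped, total) {
  frac <- if (total > 0) clipped / total else 0
  list(clipped = clipped, total = total, clipped_warning = frac > 0.5)
}

#' Wave-based (Fresnel-Kirchhoff) beamforming
#'
#' Back-projects RF traces through a known aberrator profile by the same
#' diffraction sum used by the forward model: each pixel collects, over every
#' sensor and every interface point, the trace value at the two-segment delay
#' `r_sj/cw + r_jn/ca` (linear interpolation in time).  Two weightings are
#' available: `"analytic"` applies `r_sj * r_jn * psi` (the analytic
#' back-projection formula), `"adjoint"` applies `psi/(r_sj * r_jn)` after
#' correlating the traces with the impulse-response kernel, making the
#' operation the exact transpose of [simulate_rf()] (useful for gradient and
#' dot-product checks).
#'
#' @param rf A [pa_rf].
#' @param profile A [pa_profile] covering the aperture.
#' @param medium A [pa_medium].
#' @param array A [pa_array].
#' @param grid A [pa_grid] in water beyond the layer.
#' @param variant Obliquity variant, see [obliquity()].
#' @param mode `"analytic"` or `"adjoint"`.
#' @param ir Impulse response, required for `mode = "adjoint"`.
#' @return A [pa_image]; out-of-window lookups contribute zero and are
#'   counted in `meta` (warning flag when more than half are clipped).
#' @export
beamform_wave <- function(rf, profile, medium, array, grid,
                          variant = c("kirchhoff", "sommerfeld1",
                                      "sommerfeld2", "unity"),
                          mode = c("analytic", "adjoint"), ir = NULL) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  ka <- kernel_args(profile, medium, array, variant)
  px <- grid_pixels(grid)
  P <- rf$traces
  if (mode == "adjoint") {
    if (is.null(ir)) stop("adjoint mode needs the impulse response")
    P <- convolve_traces(P, ir, adjoint = TRUE)
  }
  g <- cpp_gather(P, px$x, px$z, ka$ix, ka$iz, ka$nx, ka$nz, ka$slope,
                  ka$ax, ka$az, ka$cw, ka$ca, ka$variant, ka$quad,
                  if (mode == "analytic") 0L else 1L,
                  ka$alpha_w, ka$alpha_a, rf$fs, rf$t0, ka$min_dist)
  pa_image(grid, g$image, clip_meta(g$clipped, g$total))
}

# shared scaffold for the two single-delay beamformers
single_delay_image <- function(rf, grid, delay_fun, weight_fun) {
  px <- grid_pixels(grid)
  nt <- nrow(rf$traces)
  acc <- numeric(length(px$x))
  clipped <- 0; total <- 0
  for (n in seq_along(rf$sensor_x)) {
    tau <- delay_fun(px, n)
    w <- weight_fun(px, n)
    pos <- (tau - rf$t0) * rf$fs
    i0 <- floor(pos)
    ok <- !is.na(tau) & i0 >= 0 & i0 + 1 < nt
    total <- total + sum(!is.na(tau)); clipped <- clipped + sum(!ok & !is.na(tau))
    f <- pos[ok] - i0[ok]
    tr <- rf$traces[, n]
    acc[ok] <- acc[ok] +
      w[ok] * ((1 - f) * tr[i0[ok] + 1] + f * tr[i0[ok] + 2])
  }
  pa_image(grid, acc, clip_meta(clipped, total))
}

#' Conventional delay-and-sum beamforming
#'
#' Assumes a homogeneous medium at the water speed: each pixel collects the
#' trace value at `r_sn/cw`, weighted by `r_sn`.  Through a fast layer this
#' places targets at the wrong (too shallow) depth.
#'
#' @inheritParams beamform_wave
#' @return A [pa_image].
#' @export
beamform_das <- function(rf, medium, array, grid) {
  cw <- medium$cw
  single_delay_image(
    rf, grid,
    delay_fun = function(px, n)
      sqrt((px$x - array$x[n])^2 + (px$z - array$z[n])^2) / cw,
    weight_fun = function(px, n)
      sqrt((px$x - array$x[n])^2 + (px$z - array$z[n])^2))
}

#' Straight-ray layered beamforming
#'
#' Accounts for the layer's sound speed but neglects refraction: the delay
#' for a pixel-sensor pair splits the straight segment at its intersection
#' with the aberrator surface, the water part travelling at `cw` and the
#' in-layer part at `ca`.  The intersection is found by bisection on the
#' segment against the linearly interpolated profile.
#'
#' @inheritParams beamform_wave
#' @return A [pa_image]; pixels whose segment does not cross the interface
#'   (e.g. inside the layer) are skipped and counted in `meta$skipped`.
#' @export
beamform_straight_ray <- function(rf, profile, medium, array, grid) {
  zf <- function(x) stats::approx(profile$x, profile$z, x, rule = 2)$y
  skipped <- 0
  delay_fun <- function(px, n) {
    xn <- array$x[n]
    # F(u) = z_layer(x(u)) - u*z_s along sensor -> pixel; F(0+) > 0, F(1) < 0
    lo <- rep(0, length(px$x)); hi <- rep(1, length(px$x))
    bad <- px$z <= zf(px$x)              # pixel inside the layer: no crossing
    for (it in 1:45) {
      mid <- (lo + hi) / 2
      Fm <- zf(xn + mid * (px$x - xn)) - mid * px$z
      up <- Fm > 0
      lo[up] <- mid[up]; hi[!up] <- mid[!up]
    }
    u <- (lo + hi) / 2
    xj <- xn + u * (px$x - xn); zj <- u * px$z
    tau <- sqrt((px$x - xj)^2 + (px$z - zj)^2) / medium$cw +
           sqrt((xj - xn)^2 + zj^2) / medium$ca
    tau[bad] <- NA_real_
    skipped <<- skipped + sum(bad)
    tau
  }
  img <- single_delay_image(
    rf, grid, delay_fun,
    weight_fun = function(px, n)
      sqrt((px$x - array$x[n])^2 + px$z^2))
  img$meta$skipped <- skipped
  img
}

#' Echo-based aberrator profile estimate
#'
#' Estimates the layer thickness above each element from a single-transmit
#' pulse-echo acquisition: each trace is matched-filtered with the known
#' transmit kernel, the round-trip time `tau` of the strongest in-window
#' reflection from the distal facet is picked, and the thickness follows as
#' `z = ca * tau / 2`.  Restricting the search to the window implied by
#' `thickness_range` rejects reverberation replicas, which arrive later (at
#' multiples of `tau`) and weaker than the first reflection.
#'
#' @param rf Pulse-echo [pa_rf], one trace per element.
#' @param medium A [pa_medium] (uses `ca`).
#' @param array A [pa_array].
#' @param ir The transmit kernel, a [pa_ir].
#' @param thickness_range Length-2 vector, expected thickness window (m).
#' @param conf_threshold Peaks below this fraction of the median peak are
#'   marked low-confidence and their thickness interpolated from neighbours.
#' @return An object of class `pa_profile_estimate`: `x`, `z`, `confidence`,
#'   `low_confidence` (logical).  Use [as_profile()] to turn it into a
#'   [pa_profile].
#' @export
estimate_profile_echo <- function(rf, medium, array, ir, thickness_range,
                                  conf_threshold = 0.25) {
  stopifnot(length(thickness_range) == 2, ncol(rf$traces) == array$n)
  mf <- convolve_traces(rf$traces, ir, adjoint = TRUE)
  tt <- rf_time(rf)
  win <- tt >= 2 * thickness_range[1] / medium$ca &
         tt <= 2 * thickness_range[2] / medium$ca
  if (!any(win)) stop("thickness window outside the recorded traces")
  iw <- which(win)
  z <- conf <- numeric(array$n)
  for (n in seq_len(array$n)) {
    seg <- abs(mf[iw, n])
    i <- which.max(seg)
    tau <- tt[iw[i]]
    # parabolic sub-sample refinement where the peak is interior
    if (i > 1 && i < length(seg)) {
      d <- (seg[i - 1] - seg[i + 1]) / (2 * (seg[i - 1] - 2 * seg[i] + seg[i + 1]))
      if (is.finite(d) && abs(d) <= 0.5) tau <- tau + d / rf$fs
    }
    z[n] <- medium$ca * tau / 2
    conf[n] <- seg[i]
  }
  low <- conf < conf_threshold * stats::median(conf)
  if (any(low) && any(!low))
    z[low] <- stats::approx(array$x[!low], z[!low], array$x[low], rule = 2)$y
  structure(list(x = array$x, z = pmax(z, 0), confidence = conf,
                 low_confidence = low),
            class = "pa_profile_estimate")
}

#' Convert a profile estimate to a profile
#'
#' @param est A `pa_profile_estimate` from [estimate_profile_echo()].
#' @return A [pa_profile].
#' @export
as_profile <- function(est) {
  stopifnot(inherits(est, "pa_profile_estimate"))
  pa_profile(est$x, est$z)
}

#' @export
print.pa_profile_estimate <- function(x, ...) {
  cat(sprintf("Echo-based profile estimate: %d elements, thickness %.3g-%.3g mm (%d low-confidence)\n",
              length(x$x), min(x$z) * 1e3, max(x$z) * 1e3, sum(x$low_confidence)))
  invisible(x)
}
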