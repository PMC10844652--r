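#' Acoustic medium description
#'
#' Bundles the two sound speeds of the layered model -- water (background)
#' and the aberrating layer -- together with optional amplitude attenuation
#' coefficients evaluated at the array centre frequency.
#'
#' @param cw Speed of sound in water (m/s).
#' @param ca Speed of sound in the aberrating layer (m/s).
#' @param alpha_w,alpha_a Optional amplitude attenuation coefficients (Np/m)
#'   in water and in the layer, applied as `exp(-alpha_w*r_sj - alpha_a*r_jn)`
#'   per wavelet.  Default 0 (lossless).
#' @param rho_w,rho_a Mass densities (kg/m^3), carried as metadata only; the
#'   scalar-wave forward model does not use them.
#' @return An object of class `pa_medium`.
#' @examples
#' pa_medium()               # water / bone-like layer
#' pa_medium(ca = 2775)      # Perspex-like layer
#' @export
pa_medium <- function(cw = 1540, ca = 2700, alpha_w = 0, alpha_a = 0,
                      rho_w = 997, rho_a = 1180) {
  stopifnot(is.numeric(cw), length(cw) == 1L, cw > 0,
            is.numeric(ca), length(ca) == 1L, ca > 0,
            alpha_w >= 0, alpha_a >= 0)
  structure(list(cw = cw, ca = ca, alpha_w = alpha_w, alpha_a = alpha_a,
                 rho_w = rho_w, rho_a = rho_a),
            class = "pa_medium")
}

#' Linear sensor array
#'
#' A flat linear array of point detectors at depth z = 0, in contact with the
#' flat face of the aberrating layer, centred on x = 0.
#'
#' @param n Number of elements (>= 2).
#' @param pitch Element spacing (m).
#' @return An object of class `pa_array` with fields `x` (element lateral
#'   positions, m), `z` (all zero), `pitch` and `n`.
#' @examples
#' pa_array(65, 1e-3)  # 65 elements over a 64 mm aperture
#' @export
pa_array <- function(n = 65, pitch = 1e-3) {
  stopifnot(n >= 2, pitch > 0)
  x <- (seq_len(n) - (n + 1) / 2) * pitch
  structure(list(x = x, z = rep(0, n), pitch = pitch, n = as.integer(n)),
            class = "pa_array")
}

#' @export
print.pa_array <- function(x, ...) {
  cat(sprintf("Linear array: %d elements, pitch %.3g mm, aperture %.3g mm\n",
              x$n, x$pitch * 1e3, (x$n - 1) * x$pitch * 1e3))
  invisible(x)
}

#' @export
print.pa_medium <- function(x, ...) {
  cat(sprintf("Two-layer medium: cw = %g m/s (water), ca = %g m/s (aberrator)\n",
              x$cw, x$ca))
  if (x$alpha_w > 0 || x$alpha_a > 0)
    cat(sprintf("  attenuation: alpha_w = %g, alpha_a = %g Np/m\n",
                x$alpha_w, x$alpha_a))
  invisible(x)
}

#' Aberrator thickness profile
#'
#' The layer thickness z(x), measured from the array plane (z = 0) toward the
#' target, sampled at lateral positions `x`.  Surface normals at each sample
#' point toward the array (negative z) and are computed from the local surface
#' slope by centred finite differences (one-sided at the ends).
#'
#' @param x Lateral sample positions (m), strictly increasing.
#' @param z Thickness at each `x` (m), all >= 0.
#' @return An object of class `pa_profile` with fields `x`, `z`, `nx`, `nz`
#'   (unit normal components) and `slope`.
#' @examples
#' p <- pa_profile(seq(-32e-3, 32e-3, 1e-3), rep(10e-3, 65))
#' range(p$nz)  # flat: all normals (0, -1)
#' @export
pa_profile <- function(x, z) {
  x <- as.numeric(x); z <- as.numeric(z)
  if (length(x) != length(z)) stop("x and z must have equal length")
  if (length(x) < 2L) stop("profile needs at least two samples")
  if (any(diff(x) <= 0)) stop("x must be increasing")
  if (any(z < 0)) stop("thickness z must be non-negative")
  g <- profile_slope(x, z)
  s <- sqrt(1 + g^2)
  structure(list(x = x, z = z, nx = g / s, nz = -1 / s, slope = g),
            class = "pa_profile")
}

# slope dz/dx by centred differences, one-sided at the ends
profile_slope <- function(x, z) {
  n <- length(x)
  g <- numeric(n)
  if (n >= 3L)
    g[2:(n - 1)] <- (z[3:n] - z[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  g[1] <- (z[2] - z[1]) / (x[2] - x[1])
  g[n] <- (z[n] - z[n - 1]) / (x[n] - x[n - 1])
  g
}

# Jacobian dg/dz of profile_slope (n x n, sparse in structure but small)
slope_jacobian <- function(x) {
  n <- length(x)
  J <- matrix(0, n, n)
  if (n >= 3L) for (j in 2:(n - 1)) {
    h <- x[j + 1] - x[j - 1]
    J[j, j + 1] <- 1 / h
    J[j, j - 1] <- -1 / h
  }
  J[1, 2] <- 1 / (x[2] - x[1]); J[1, 1] <- -J[1, 2]
  J[n, n] <- 1 / (x[n] - x[n - 1]); J[n, n - 1] <- -J[n, n]
  J
}

#' @export
print.pa_profile <- function(x, ...) {
  cat(sprintf(
    "Aberrator profile: %d samples, x in [%.3g, %.3g] mm, thickness %.3g-%.3g mm\n",
    length(x$x), min(x$x) * 1e3, max(x$x) * 1e3, min(x$z) * 1e3, max(x$z) * 1e3))
  invisible(x)
}

#' Resample an aberrator profile to a uniform interface-point set
#'
#' Discretizes the water--aberrator interface at uniform lateral spacing, with
#' unit normals recomputed from the resampled surface.  The interpolant is a
#' natural cubic spline, so normals converge under spacing refinement.
#' Resampling a profile already on the requested grid is the identity.
#'
#' @param profile A [pa_profile].
#' @param spacing Lateral spacing of the interface points (m).
#' @return A [pa_profile] sampled at uniform spacing.
#' @examples
#' p <- pa_profile(seq(-32e-3, 32e-3, 4e-3), rep(10e-3, 17))
#' interface_points(p, 1e-3)
#' @export
interface_points <- function(profile, spacing) {
  stopifnot(inherits(profile, "pa_profile"), spacing > 0)
  aperture <- max(profile$x) - min(profile$x)
  if (spacing > aperture) stop("too few interface points")
  xs <- seq(min(profile$x), max(profile$x), by = spacing)
  if (length(xs) < 3L) stop("too few interface points")
  if (length(xs) == length(profile$x) &&
      isTRUE(all.equal(xs, profile$x, tolerance = 1e-12)))
    return(profile)
  f <- stats::splinefun(profile$x, profile$z, method = "natural")
  pa_profile(xs, pmax(f(xs), 0))
}

#' Two-segment propagation delay
#'
#' Travel time of a wavelet from a source point through an interface point to
#' a sensor element: the source--interface segment at the water speed, the
#' interface--sensor segment at the aberrator speed.
#'
#' @param source,interface,sensor Numeric length-2 positions `c(x, z)` in m.
#' @param medium A [pa_medium].
#' @return Delay in seconds: `|r_s - r_j|/cw + |r_j - r_n|/ca`.
#' @examples
#' two_segment_delay(c(0, 40e-3), c(0, 10e-3), c(0, 0), pa_medium())
#' @export
two_segment_delay <- function(source, interface, sensor, medium) {
  r_sj <- sqrt(sum((source - interface)^2))
  r_jn <- sqrt(sum((interface - sensor)^2))
  if (r_sj == 0 || r_jn == 0) stop("degenerate geometry")
  r_sj / medium$cw + r_jn / medium$ca
}

#' Obliquity factor of a secondary wavelet
#'
#' Angular weighting of the Huygens wavelet refracted at an interface point.
#' Variants: `"kirchhoff"` gives the speed-weighted two-cosine form
#' `N.r_sj/cw + N.r_jn/ca` (units s/m, kept un-normalized), `"sommerfeld1"`
#' the first Rayleigh-Sommerfeld solution `cos(phi_out)`, `"sommerfeld2"` the
#' second, `cos(phi_in)`, and `"unity"` the constant 1.  Direction vectors are
#' taken along propagation (source to interface, interface to sensor); the
#' normal must be unit length and point from the interface toward the array.
#'
#' @param source,sensor Numeric length-2 positions (m).
#' @param interface Numeric length-2 interface point (m).
#' @param normal Unit normal at the interface point.
#' @param medium A [pa_medium] (used by the Kirchhoff variant).
#' @param variant One of `"kirchhoff"`, `"sommerfeld1"`, `"sommerfeld2"`,
#'   `"unity"`.
#' @return The scalar obliquity weight.
#' @examples
#' obliquity(c(0, 40e-3), c(0, 10e-3), c(0, -1), c(0, 0), pa_medium())
#' @export
obliquity <- function(source, interface, normal, sensor, medium,
                      variant = c("kirchhoff", "sommerfeld1", "sommerfeld2",
                                  "unity")) {
  variant <- match.arg(variant)
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-8) stop("normal must be unit length")
  u <- interface - source; r1 <- sqrt(sum(u^2))
  v <- sensor - interface; r2 <- sqrt(sum(v^2))
  if (r1 == 0 || r2 == 0) stop("degenerate geometry")
  cos_in <- sum(normal * u) / r1
  cos_out <- sum(normal * v) / r2
  switch(variant,
         kirchhoff  = cos_in / medium$cw + cos_out / medium$ca,
         sommerfeld1 = cos_out,
         sommerfeld2 = cos_in,
         unity      = 1)
}

obliquity_code <- function(variant) {
  match(match.arg(variant, c("kirchhoff", "sommerfeld1", "sommerfeld2",
                             "unity")),
        c("kirchhoff", "sommerfeld1", "sommerfeld2", "unity")) - 1L
}

#' Snell refraction point on a flat interface
#'
#' For a flat interface at depth `d` between a source (in water, beyond the
#' layer) and a sensor on the array plane, finds the lateral coordinate of the
#' stationary (Fermat) refraction point by root-finding the derivative of the
#' two-segment delay.  At the solution `sin(phi_in)/cw = sin(phi_out)/ca`.
#'
#' @param source,sensor Numeric length-2 positions (m); `source[2] > d`,
#'   `sensor[2] = 0`.
#' @param d Interface depth (m), `0 < d < source[2]`.
#' @param medium A [pa_medium].
#' @return Lateral coordinate (m) of the refraction point on the plane z = d.
#' @examples
#' snell_refraction_point(c(20e-3, 40e-3), c(0, 0), 10e-3, pa_medium())
#' @export
snell_refraction_point <- function(source, sensor, d, medium) {
  xs <- source[1]; zs <- source[2]; xn <- sensor[1]
  if (!(d > 0 && d < zs)) stop("interface depth must satisfy 0 < d < z_source")
  dT <- function(x) {
    r1 <- sqrt((x - xs)^2 + (zs - d)^2)
    r2 <- sqrt((x - xn)^2 + d^2)
    (x - xs) / (r1 * medium$cw) + (x - xn) / (r2 * medium$ca)
  }
  lo <- min(xs, xn); hi <- max(xs, xn)
  if (lo == hi) return(xs)
  f_lo <- dT(lo); f_hi <- dT(hi)
  if (f_lo == 0) return(lo)
  if (f_hi == 0) return(hi)
  if (sign(f_lo) == sign(f_hi)) stop("no bracketing interval")
  stats::uniroot(dT, c(lo, hi), tol = 1e-12)$root
}
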