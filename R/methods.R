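#' @export
print.pa_fit <- function(x, ...) {
  cat("Joint aberrator/target inversion (Fresnel-Kirchhoff model)\n")
  cat(sprintf("  iterations: %d%s\n", x$iterations,
              if (x$converged) " (early stop: loss plateau)" else ""))
  n <- nrow(x$history)
  cat(sprintf("  loss: %.6g -> %.6g (data term %.6g -> %.6g)\n",
              x$history$L[1], x$history$L[n], x$history$D[1], x$history$D[n]))
  cat(sprintf("  thickness: %.3g-%.3g mm over %d interface points\n",
              min(x$z) * 1e3, max(x$z) * 1e3, length(x$z)))
  cat(sprintf("  amplitude image: %d x %d pixels, max %.3g\n",
              nrow(x$a), ncol(x$a), max(abs(x$a))))
  invisible(x)
}

#' @export
summary.pa_fit <- function(object, ...) {
  n <- nrow(object$history)
  out <- list(
    iterations = object$iterations,
    converged = object$converged,
    loss_initial = object$history$L[1],
    loss_final = object$history$L[n],
    data_term_final = object$history$D[n],
    prior_term_final = object$history$P[n],
    prior = c(alpha = object$prior$alpha, beta = object$prior$beta),
    basis = object$prior$basis,
    step_sizes = object$lr,
    z_range_mm = range(object$z) * 1e3,
    z_rmse_final = if ("z_rmse" %in% names(object$history))
      object$history$z_rmse[n] else NA_real_,
    n_active_pixels = sum(abs(object$a) > 0.1 * max(abs(object$a))))
  class(out) <- "summary.pa_fit"
  out
}

#' @export
print.summary.pa_fit <- function(x, ...) {
  cat("Joint inversion summary\n")
  cat(sprintf("  iterations run       : %d%s\n", x$iterations,
              if (x$converged) " (converged)" else ""))
  cat(sprintf("  loss                 : %.6g -> %.6g\n",
              x$loss_initial, x$loss_final))
  cat(sprintf("  final data / prior   : %.6g / %.6g\n",
              x$data_term_final, x$prior_term_final))
  cat(sprintf("  prior weights        : alpha = %.3g, beta = %.3g (%s basis)\n",
              x$prior["alpha"], x$prior["beta"], x$basis))
  cat(sprintf("  step sizes (z, a)    : %.3g m, %.3g\n",
              x$step_sizes["z"], x$step_sizes["a"]))
  cat(sprintf("  thickness range      : %.3g-%.3g mm\n",
              x$z_range_mm[1], x$z_range_mm[2]))
  if (!is.na(x$z_rmse_final))
    cat(sprintf("  thickness RMS error  : %.3g mm (vs supplied truth)\n",
                x$z_rmse_final * 1e3))
  cat(sprintf("  active pixels (>10%%) : %d\n", x$n_active_pixels))
  invisible(x)
}

#' @export
coef.pa_fit <- function(object, ...) {
  list(z = object$z, a = as.vector(object$a))
}

#' @export
fitted.pa_fit <- function(object, ...) {
  forward_theta(list(z = object$z, a = as.vector(object$a)),
                object$model, object$measured)
}

#' @export
residuals.pa_fit <- function(object, ...) {
  object$measured$traces - fitted(object)$traces
}

#' Predictions from a fitted joint inversion
#'
#' @param object A [pa_fit].
#' @param type `"rf"` for the modelled traces at the fitted parameters,
#'   `"image"` for the fitted amplitude image as a [pa_image].
#' @param ... Unused.
#' @return A [pa_rf] or a [pa_image].
#' @export
predict.pa_fit <- function(object, type = c("rf", "image"), ...) {
  type <- match.arg(type)
  if (type == "rf") return(fitted(object))
  pa_image(object$model$grid, object$a)
}

#' Simulate RF realizations from a fitted model
#'
#' @param object A [pa_fit].
#' @param nsim Number of realizations.
#' @param seed Optional seed (realization i uses `seed + i - 1`).
#' @param snr_db Mean-to-mean SNR of the added noise; `Inf` for noiseless.
#' @param ... Unused.
#' @return A list of [pa_rf] objects of length `nsim`.
#' @export
simulate.pa_fit <- function(object, nsim = 1, seed = NULL, snr_db = Inf, ...) {
  clean <- fitted(object)
  lapply(seq_len(nsim), function(i)
    add_noise(clean, snr_db, seed = if (is.null(seed)) NULL else seed + i - 1L))
}

#' Diagnostic plots for a fitted joint inversion
#'
#' @param x A [pa_fit].
#' @param type `"loss"` (loss history, log scale), `"profile"` (fitted
#'   thickness vs the initial reference), or `"image"` (fitted amplitudes).
#' @param ... Passed to the underlying plotting function.
#' @export
plot.pa_fit <- function(x, type = c("loss", "profile", "image"), ...) {
  type <- match.arg(type)
  if (type == "loss") {
    graphics::plot(x$history$iter, x$history$L, type = "l", log = "y",
                   xlab = "iteration", ylab = "loss", ...)
    graphics::lines(x$history$iter, pmax(x$history$D, .Machine$double.xmin),
                    lty = 2)
    graphics::legend("topright", c("L = D + P", "D"), lty = 1:2, bty = "n")
  } else if (type == "profile") {
    xr <- x$model$interface_x * 1e3
    graphics::plot(xr, x$z * 1e3, type = "l", col = "blue",
                   xlab = "x (mm)", ylab = "thickness (mm)", ...)
    graphics::lines(xr, x$prior$z_ref * 1e3, col = "red", lty = 2)
    graphics::legend("topright", c("fitted", "initial"), col = c("blue", "red"),
                     lty = 1:2, bty = "n")
  } else {
    plot(predict(x, "image"), main = "fitted amplitude image", ...)
  }
  invisible(x)
}
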