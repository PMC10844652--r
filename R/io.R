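# Plain-text containers for RF data, profiles and images.  JSON (full
# precision, self-describing) for the primary round-trip format, CSV/text
# mirrors for small artifacts.

#' Write / read RF data
#'
#' The container is a JSON object with fields `rf` (samples x sensors),
#' `sensor_x`, and attributes `fs`, `t0`, `units`, written at full double
#' precision so that a write-read round trip is bit-exact.
#'
#' @param rf A [pa_rf].
#' @param path File path.
#' @return `write_rf` returns `path` invisibly; `read_rf` a [pa_rf].
#' @export
write_rf <- function(rf, path) {
  stopifnot(inherits(rf, "pa_rf"))
  obj <- list(format = "pawave-rf-1", fs = rf$fs, t0 = rf$t0,
              units = rf$units, sensor_x = rf$sensor_x, rf = rf$traces)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rf
#' @export
read_rf <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("fs", "t0", "sensor_x", "rf"))
    if (is.null(obj[[field]]))
      stop(sprintf("missing attribute %s", field))
  pa_rf(obj$rf, fs = as.numeric(obj$fs), t0 = as.numeric(obj$t0),
        sensor_x = as.numeric(obj$sensor_x), units = obj$units %||% "a.u.")
}

#' CSV export / import of RF traces
#'
#' Plain CSV with one column per sensor (header `s1..sn`); sampling
#' metadata is not carried, so supply it on import.  Values keep 9+
#' significant digits.
#'
#' @param rf A [pa_rf].
#' @param path File path.
#' @param fs,t0,sensor_x Metadata for `rf_from_csv`.
#' @return `rf_to_csv` returns `path` invisibly; `rf_from_csv` a [pa_rf].
#' @export
rf_to_csv <- function(rf, path) {
  m <- rf$traces
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  utils::write.csv(signif(m, 12), path, row.names = FALSE)
  invisible(path)
}

#' @rdname rf_to_csv
#' @export
rf_from_csv <- function(path, fs, t0 = 0, sensor_x = NULL) {
  m <- as.matrix(utils::read.csv(path))
  if (is.null(sensor_x)) sensor_x <- seq_len(ncol(m))
  pa_rf(unname(m), fs, t0, sensor_x)
}

#' Write / read an aberrator profile as two-column text
#'
#' Whitespace-separated columns `x z` in metres, full double precision.
#'
#' @param profile A [pa_profile].
#' @param path File path.
#' @return `write_profile` returns `path` invisibly; `read_profile` a
#'   [pa_profile] (errors on empty files or non-increasing x).
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "pa_profile"))
  writeLines(sprintf("%.17g %.17g", profile$x, profile$z), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty profile file")
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(m) < 2 || any(is.na(m[, 1:2])))
    stop("profile file must have two numeric columns (x z)")
  pa_profile(m[, 1], m[, 2])
}

#' Write a beamformed image
#'
#' JSON container with the grid axes and the amplitude matrix (full
#' precision), or a CSV mirror of the amplitude matrix alone.
#'
#' @param image A [pa_image].
#' @param path File path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(format = "pawave-image-1", x = image$grid$x,
                              z = image$grid$z, amplitude = image$amplitude),
                         path, digits = I(17), auto_unbox = TRUE)
  } else {
    utils::write.csv(image$amplitude, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("x", "z", "amplitude"))
    if (is.null(obj[[field]])) stop(sprintf("missing attribute %s", field))
  pa_image(pa_grid(obj$x, obj$z), obj$amplitude)
}

#' Serialize / restore a scenario
#'
#' Round-trips every ingredient of a [make_scenario()] object through JSON
#' at full precision.
#'
#' @param sc A `pa_scenario`.
#' @param path File path.
#' @return `write_scenario` returns `path` invisibly; `read_scenario` the
#'   restored `pa_scenario`.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "pa_scenario"))
  obj <- list(format = "pawave-scenario-1", name = sc$name, seed = sc$seed,
              cw = sc$medium$cw, ca = sc$medium$ca,
              n_elements = sc$array$n, pitch = sc$array$pitch,
              f0 = sc$ir$f0, bw = sc$ir$bw, fs = sc$ir$fs,
              profile_x = sc$profile$x, profile_z = sc$profile$z,
              targets = sc$targets, target_image = sc$target_image,
              grid_x = sc$grid$x, grid_z = sc$grid$z, z_init = sc$z_init,
              snr_db = sc$snr_db, oversample = sc$inverse_crime$oversample,
              data_variant = sc$inverse_crime$variant, variant = sc$variant)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(o$format) || o$format != "pawave-scenario-1")
    stop("not a pawave scenario file")
  structure(list(name = o$name, seed = as.integer(o$seed),
                 medium = pa_medium(o$cw, o$ca),
                 array = pa_array(o$n_elements, o$pitch),
                 ir = gaussian_bandpass_ir(o$f0, o$bw, o$fs),
                 profile = pa_profile(o$profile_x, o$profile_z),
                 targets = if (is.null(o$targets)) NULL
                           else as.data.frame(o$targets),
                 target_image = if (is.null(o$target_image)) NULL
                                else as.matrix(o$target_image),
                 grid = pa_grid(o$grid_x, o$grid_z), z_init = o$z_init,
                 snr_db = if (is.null(o$snr_db)) Inf else o$snr_db,
                 inverse_crime = list(oversample = o$oversample,
                                      variant = o$data_variant),
                 variant = o$variant),
            class = "pa_scenario")
}
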