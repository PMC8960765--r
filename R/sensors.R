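#' Sensor profiles
#'
#' The pipeline consumes two harmonized sensors: a coarse 9-band 30 m sensor
#' with red-edge and SWIR coverage (Sentinel-2-like, irregular revisit) and a
#' fine 4-band 3 m daily sensor (harmonized CubeSat-like). Band labels encode
#' the band-center wavelength in nm (`b490`, `b560`, ...); the fine sensor's
#' band centers are a subset of the coarse sensor's.
#'
#' @param name sensor name.
#' @param wavelengths named numeric vector, label -> center wavelength (nm).
#' @param resolution ground sampling distance in m.
#' @param revisit `"daily"` or `"irregular"`.
#' @return An object of class `sensor_profile`.
#' @export
sensor_profile <- function(name, wavelengths, resolution, revisit = c("daily", "irregular")) {
  revisit <- match.arg(revisit)
  if (is.null(names(wavelengths)) || any(!nzchar(names(wavelengths))))
    stopf("`wavelengths` must be a named vector (band labels)")
  structure(list(name = name, bands = names(wavelengths),
                 wavelengths = wavelengths, resolution = resolution,
                 revisit = revisit),
            class = "sensor_profile")
}

#' @rdname sensor_profile
#' @export
coarse_sensor <- function(resolution = 30) {
  sensor_profile("coarse",
    c(b490 = 490, b560 = 560, b665 = 665, b704 = 704, b740 = 740,
      b783 = 783, b865 = 865, b1614 = 1614, b2202 = 2202),
    resolution, "irregular")
}

#' @rdname sensor_profile
#' @export
fine_sensor <- function(resolution = 3) {
  sensor_profile("fine",
    c(b490 = 490, b560 = 560, b665 = 665, b865 = 865),
    resolution, "daily")
}

#' @export
print.sensor_profile <- function(x, ...) {
  cat(sprintf("<sensor_profile> %s: %d bands @ %g m, %s revisit\n",
              x$name, length(x$bands), x$resolution, x$revisit))
  cat(" ", paste(sprintf("%s(%gnm)", x$bands, x$wavelengths), collapse = " "), "\n")
  invisible(x)
}
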