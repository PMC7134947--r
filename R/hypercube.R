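#' Construct a hyperspectral image cube
#'
#' A `hypercube` holds a push-broom hyperspectral image as a 3-D array with
#' spatial dimensions `lines x samples` and a spectral dimension `bands`,
#' together with the band-center wavelengths and the radiometric state of the
#' values (raw digital numbers, at-sensor radiance, or reflectance).
#'
#' @param data Numeric 3-D array `[lines, samples, bands]`, all values finite
#'   and non-negative.
#' @param wavelengths_nm Strictly increasing numeric vector of band-center
#'   wavelengths (nm); length must equal `dim(data)[3]`.
#' @param unit One of `"DN"`, `"radiance"`, `"reflectance"`.
#' @param camera_id Free-form camera identifier (e.g. `"vnir"`).
#' @param interleave On-disk band interleave used when the cube is written:
#'   `"BIL"` (push-broom native, default), `"BIP"`, or `"BSQ"`.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths_nm, unit = c("DN", "radiance", "reflectance"),
                      camera_id = "camera", interleave = c("BIL", "BIP", "BSQ")) {
  unit <- match.arg(unit)
  interleave <- match.arg(interleave)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array [lines, samples, bands]", call. = FALSE)
  }
  storage.mode(data) <- "double"
  if (any(!is.finite(data))) stop("cube values must all be finite", call. = FALSE)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) != dim(data)[3L]) {
    stop("length(wavelengths_nm) must equal the number of bands", call. = FALSE)
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  structure(
    list(data = data, wavelengths_nm = wavelengths_nm, unit = unit,
         camera_id = as.character(camera_id), interleave = interleave),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d lines x %d samples x %d bands [%s]\n",
              d[1L], d[2L], d[3L], x$unit))
  cat(sprintf("  camera: %s | %.1f-%.1f nm | interleave %s\n",
              x$camera_id, min(x$wavelengths_nm), max(x$wavelengths_nm),
              x$interleave))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Radiometric calibration profile
#'
#' Gain/offset/dark-frame coefficients converting raw digital numbers to
#' absolute radiance. Gain and dark may be per-band vectors or
#' `samples x bands` matrices (per-spatial-channel calibration); both shapes
#' are broadcast over the cube.
#'
#' @param gain Positive per-band vector or `samples x bands` matrix, radiance
#'   per DN per unit integration time.
#' @param offset Per-band vector or matrix added after scaling (radiance units).
#' @param dark_frame DN dark-current frame, per-band vector or matrix.
#' @param integration_time Positive scalar integration time (ms).
#' @return An object of class `calibration_profile`.
#' @export
calibration_profile <- function(gain, offset = 0, dark_frame = 0, integration_time = 1) {
  if (any(gain <= 0)) stop("gain must be positive everywhere", call. = FALSE)
  if (length(integration_time) != 1L || integration_time <= 0) {
    stop("integration_time must be a positive scalar", call. = FALSE)
  }
  structure(
    list(gain = gain, offset = offset, dark_frame = dark_frame,
         integration_time = as.numeric(integration_time)),
    class = "calibration_profile"
  )
}

# Broadcast a per-band vector or samples x bands matrix onto the cube layout.
# Returns a [lines, samples, bands] array.
broadcast_cal <- function(x, d) {
  if (length(x) == 1L) return(array(x, d))
  if (is.matrix(x)) {
    if (!all(dim(x) == d[2:3])) {
      stop("calibration matrix must be samples x bands", call. = FALSE)
    }
    return(aperm(array(rep(t(x), each = d[1L]), c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L)))
  }
  if (length(x) != d[3L]) {
    stop("per-band calibration vector length must equal bands", call. = FALSE)
  }
  aperm(array(rep(x, each = d[1L] * d[2L]), d), c(1L, 2L, 3L))
}

#' Convert a raw digital-number cube to absolute radiance
#'
#' Applies the affine radiometric model
#' `L = (DN - dark) * gain / integration_time + offset`, clipped below at
#' zero. Under unit gain, zero dark/offset and unit integration time the
#' transform is the identity.
#'
#' @param raw A [hypercube] with `unit == "DN"`.
#' @param cal A [calibration_profile].
#' @return A [hypercube] with `unit == "radiance"`; wavelengths unchanged.
#' @export
calibrate_to_radiance <- function(raw, cal) {
  stopifnot(inherits(raw, "hypercube"), inherits(cal, "calibration_profile"))
  if (raw$unit != "DN") {
    stop("cube is already in unit '", raw$unit, "'; calibration needs DN input",
         call. = FALSE)
  }
  d <- dim(raw$data)
  gain <- broadcast_cal(cal$gain, d)
  dark <- broadcast_cal(cal$dark_frame, d)
  off <- broadcast_cal(cal$offset, d)
  L <- (raw$data - dark) * gain / cal$integration_time + off
  L[L < 0] <- 0
  hypercube(L, raw$wavelengths_nm, unit = "radiance",
            camera_id = raw$camera_id, interleave = raw$interleave)
}
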