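# Radiance-to-reflectance conversion against the in-scene white reference
# panel, Savitzky-Golay smoothing, noisy/water band masking, two-camera
# joining, and aggregation of sunlit-leaf pixels to one plot spectrum.

#' A single spectrum
#'
#' @param wavelengths_nm Strictly increasing band centers (nm).
#' @param values Per-band values (reflectance fraction or radiance).
#' @param unit `"reflectance"`, `"radiance"` or `"DN"`.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelengths_nm, values, unit = "reflectance") {
  if (length(wavelengths_nm) != length(values)) {
    stop("wavelengths and values lengths differ", call. = FALSE)
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  structure(list(wavelengths_nm = as.numeric(wavelengths_nm),
                 values = as.numeric(values), unit = unit),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d bands, %.1f-%.1f nm [%s]\n",
              length(x$values), min(x$wavelengths_nm), max(x$wavelengths_nm),
              x$unit))
  invisible(x)
}

#' Convert sunlit-leaf radiance to reflectance against the panel
#'
#' Per band and pixel, `R = (S_sunlit / S_ref) * R_ref`, where `S_ref` is
#' the in-scene white panel radiance and `R_ref` the lab-calibrated panel
#' reflectance. The ratio cancels the illumination, so reflectance is
#' invariant to global brightness changes.
#'
#' @param sunlit Per-pixel radiance spectra: a pixels x bands matrix (or a
#'   single [spectrum]).
#' @param panel Panel radiance: a [spectrum] or plain per-band vector; must
#'   be strictly positive at every band.
#' @param panel_reference Lab-calibrated panel reflectance, scalar or
#'   per-band fraction (default 0.99).
#' @return Pixels x bands reflectance matrix (a [spectrum] in, a
#'   [spectrum] out).
#' @export
to_reflectance <- function(sunlit, panel, panel_reference = 0.99) {
  panel_v <- if (inherits(panel, "spectrum")) panel$values else as.numeric(panel)
  bad <- which(panel_v <= 0)
  if (length(bad) > 0) {
    stop("panel radiance is non-positive at band index ", bad[1L],
         "; cannot form the reflectance ratio", call. = FALSE)
  }
  scale <- panel_reference / panel_v
  if (inherits(sunlit, "spectrum")) {
    if (length(sunlit$values) != length(panel_v)) {
      stop("sunlit and panel wavelength grids differ", call. = FALSE)
    }
    return(spectrum(sunlit$wavelengths_nm, sunlit$values * scale, "reflectance"))
  }
  if (ncol(sunlit) != length(panel_v)) {
    stop("sunlit and panel wavelength grids differ", call. = FALSE)
  }
  sweep(sunlit, 2L, scale, `*`)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with the standard symmetric
#' kernel on interior points. At the edges the polynomial is fit to the
#' truncated window actually available (no padding artifacts), so spectra
#' that are globally polynomial of degree <= `polyorder` pass through
#' unchanged everywhere.
#'
#' @param s A [spectrum] (or plain numeric vector).
#' @param window Odd window length in bands (default 11).
#' @param polyorder Polynomial order (default 2); must be below `window`.
#' @return Smoothed spectrum of the same type; wavelengths unchanged.
#' @export
savgol_smooth <- function(s, window = 11, polyorder = 2) {
  v <- if (inherits(s, "spectrum")) s$values else as.numeric(s)
  n <- length(v)
  if (window %% 2 != 1 || window <= polyorder) {
    stop("window must be odd and larger than polyorder", call. = FALSE)
  }
  if (n < window) {
    stop("spectrum shorter than the smoothing window", call. = FALSE)
  }
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  # interior: one shared kernel (least-squares design-matrix solution)
  z <- (-h):h
  G <- outer(z, 0:polyorder, `^`)
  kern <- solve(crossprod(G), t(G))[1L, ]  # row for the window-center estimate
  for (i in seq_len(n)) {
    if (i > h && i <= n - h) {
      out[i] <- sum(kern * v[(i - h):(i + h)])
    } else {
      lo <- max(1L, i - h); hi <- min(n, i + h)
      zz <- (lo:hi) - i
      Ge <- outer(zz, 0:polyorder, `^`)
      out[i] <- solve(crossprod(Ge), crossprod(Ge, v[lo:hi]))[1L]
    }
  }
  if (inherits(s, "spectrum")) spectrum(s$wavelengths_nm, out, s$unit) else out
}

#' Mask noisy and water-absorption bands
#'
#' Retains bands inside `keep` (inclusive) and outside every `drop` interval
#' (inclusive): by default bands below 450 nm and above 1700 nm are removed
#' as excess-noise regions and 1313-1440 nm as the atmospheric
#' water-absorption window.
#'
#' @param s A [spectrum].
#' @param keep Length-2 retained range (nm).
#' @param drop List of length-2 removed ranges (nm).
#' @return The masked [spectrum]; also carries the logical mask as
#'   attribute `"mask"` (TRUE = retained, relative to the input grid).
#' @export
mask_bands <- function(s, keep = c(450, 1700), drop = list(c(1313, 1440))) {
  stopifnot(inherits(s, "spectrum"))
  wl <- s$wavelengths_nm
  m <- wl >= keep[1L] & wl <= keep[2L]
  for (dr in drop) m <- m & !(wl >= dr[1L] & wl <= dr[2L])
  if (!any(m)) stop("all bands masked; nothing retained", call. = FALSE)
  out <- spectrum(wl[m], s$values[m], s$unit)
  attr(out, "mask") <- m
  out
}

#' Join VNIR and NIR camera spectra
#'
#' Concatenates the two camera spectra sorted by wavelength. In any overlap,
#' VNIR bands win below the crossover wavelength and NIR bands at/above it,
#' so each camera contributes only its own spectral domain.
#'
#' @param vnir,nir [spectrum] objects from the two cameras (same unit).
#' @param crossover Crossover wavelength (nm), default 900.
#' @return The joined [spectrum] on the union grid (strictly increasing).
#' @export
join_cameras <- function(vnir, nir, crossover = 900) {
  stopifnot(inherits(vnir, "spectrum"), inherits(nir, "spectrum"))
  if (vnir$unit != nir$unit) stop("camera spectra differ in unit", call. = FALSE)
  keep_v <- vnir$wavelengths_nm < crossover
  keep_n <- nir$wavelengths_nm >= crossover
  wl <- c(vnir$wavelengths_nm[keep_v], nir$wavelengths_nm[keep_n])
  vals <- c(vnir$values[keep_v], nir$values[keep_n])
  ord <- order(wl)
  wl <- wl[ord]; vals <- vals[ord]
  if (any(diff(wl) <= 0)) {
    stop("duplicate wavelengths remain after crossover resolution", call. = FALSE)
  }
  spectrum(wl, vals, vnir$unit)
}

#' Aggregate sunlit-leaf pixels to one plot spectrum
#'
#' Per-band arithmetic mean and population standard deviation over all
#' pixels of a plot.
#'
#' @param pixels Pixels x bands reflectance matrix (>= 1 row).
#' @param wavelengths_nm Band centers of the columns.
#' @param plot_id Plot identifier.
#' @return An object of class `plot_spectrum`: `mean` ([spectrum]), `sd`
#'   per band, `n_pixels`, `band_mask` (all TRUE until [mask_bands()] is
#'   applied), `plot_id`.
#' @export
aggregate_plot <- function(pixels, wavelengths_nm, plot_id = "plot") {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, 1L)
  if (nrow(pixels) < 1L) {
    stop("no sunlit pixels to aggregate for plot '", plot_id, "'", call. = FALSE)
  }
  m <- colMeans(pixels)
  sd_pop <- sqrt(colMeans(sweep(pixels, 2L, m)^2))
  structure(
    list(mean = spectrum(wavelengths_nm, m, "reflectance"), sd = sd_pop,
         n_pixels = nrow(pixels),
         band_mask = rep(TRUE, length(wavelengths_nm)),
         plot_id = as.character(plot_id)),
    class = "plot_spectrum"
  )
}

#' @export
print.plot_spectrum <- function(x, ...) {
  cat(sprintf("<plot_spectrum> plot %s: %d px, %d bands (%d retained)\n",
              x$plot_id, x$n_pixels, length(x$mean$values), sum(x$band_mask)))
  invisible(x)
}

#' Run the full plot pipeline on one scene
#'
#' Classification -> semantics -> panel-referenced reflectance ->
#' per-camera aggregation -> camera joining -> Savitzky-Golay smoothing of
#' the plot-mean spectrum -> band masking. Smoothing operates on the plot
#' mean (identical in expectation to per-pixel smoothing at a fraction of
#' the cost); masking follows smoothing so the filter never straddles the
#' deleted water window.
#'
#' The NIR cube reuses the class map segmented on the VNIR cube (the
#' cameras image the same co-registered scene), since the vegetation index
#' used for labeling needs red/NIR bands only the VNIR camera has.
#'
#' @param vnir_cube Radiance [hypercube] from the VNIR camera.
#' @param nir_cube Optional radiance [hypercube] from the NIR camera, same
#'   spatial shape.
#' @param panel_reference Lab panel reflectance (scalar fraction).
#' @param plot_id Plot identifier.
#' @param k,seed,n_init Segmentation controls, see [kmeans_segment()].
#' @param smooth,window,polyorder Smoothing controls, see [savgol_smooth()].
#' @param mask Apply [mask_bands()]? `keep`/`drop` follow the two-camera
#'   defaults, or `c(450, 900)` with no water window for VNIR-only runs.
#' @return A `plot_spectrum` (mean, per-band SD on the joined grid before
#'   masking, pixel count, retained-band mask).
#' @export
process_plot <- function(vnir_cube, nir_cube = NULL, panel_reference = 0.99,
                         plot_id = "plot", k = 6, seed = 1, n_init = 10,
                         smooth = TRUE, window = 11, polyorder = 2,
                         mask = TRUE) {
  map <- assign_semantics(kmeans_segment(vnir_cube, k = k, seed = seed,
                                         n_init = n_init))
  camera_mean <- function(cube) {
    sunlit <- extract_class_spectra(cube, map, "sunlit_leaf")
    panel_px <- extract_class_spectra(cube, map, "panel")
    if (nrow(sunlit) == 0) stop("no sunlit pixels in plot '", plot_id, "'",
                                call. = FALSE)
    panel_mean <- colMeans(panel_px)
    refl <- to_reflectance(sunlit, panel_mean, panel_reference)
    aggregate_plot(refl, cube$wavelengths_nm, plot_id)
  }
  agg_v <- camera_mean(vnir_cube)
  if (!is.null(nir_cube)) {
    if (!all(dim(nir_cube$data)[1:2] == dim(vnir_cube$data)[1:2])) {
      stop("VNIR and NIR cubes must share the spatial grid", call. = FALSE)
    }
    agg_n <- camera_mean(nir_cube)
    joined <- join_cameras(agg_v$mean, agg_n$mean)
    keep_v <- agg_v$mean$wavelengths_nm < 900
    keep_n <- agg_n$mean$wavelengths_nm >= 900
    sd_joined <- c(agg_v$sd[keep_v], agg_n$sd[keep_n])
    keep_range <- c(450, 1700)
    drop_ranges <- list(c(1313, 1440))
  } else {
    joined <- agg_v$mean
    sd_joined <- agg_v$sd
    keep_range <- c(450, 900)
    drop_ranges <- list()
  }
  if (smooth) joined <- savgol_smooth(joined, window, polyorder)
  band_mask <- rep(TRUE, length(joined$values))
  if (mask) {
    masked <- mask_bands(joined, keep = keep_range, drop = drop_ranges)
    band_mask <- attr(masked, "mask")
    joined <- masked
  }
  structure(
    list(mean = joined, sd = sd_joined[band_mask], n_pixels = agg_v$n_pixels,
         band_mask = band_mask, plot_id = as.character(plot_id),
         class_map = map),
    class = "plot_spectrum"
  )
}
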