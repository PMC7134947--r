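# QC and aggregation of leaf-clip spectroradiometer spectra: detector splice
# correction, seal-check and deviation-based replicate filtering, and
# replicate/leaf averaging up to the plot level.

#' A leaf sample with replicate spectra
#'
#' Nominally six leaf-clip reflectance spectra recorded at different spots
#' of one leaf. QC ([qc_replicates()]) flags replicates rather than
#' deleting them; the leaf mean exists only while at least `min_viable`
#' replicates survive.
#'
#' @param leaf_id,plot_id Identifiers.
#' @param replicates List of [spectrum] objects on a common grid.
#' @return An object of class `leaf_sample`.
#' @export
leaf_sample <- function(leaf_id, plot_id, replicates) {
  if (length(replicates) < 1) stop("need at least one replicate", call. = FALSE)
  wl <- replicates[[1L]]$wavelengths_nm
  for (r in replicates) {
    if (!inherits(r, "spectrum") || !identical(r$wavelengths_nm, wl)) {
      stop("replicates must be spectra on a common wavelength grid", call. = FALSE)
    }
  }
  structure(list(leaf_id = as.character(leaf_id), plot_id = as.character(plot_id),
                 replicates = replicates,
                 viable = rep(NA, length(replicates)),
                 mean_spectrum = NULL, accepted = NA, reasons = character(0)),
            class = "leaf_sample")
}

#' Detector splice correction
#'
#' Spectroradiometers with multiple internal detectors show small offsets at
#' the detector junction wavelengths (heat drift). Outer detector segments
#' are shifted by an additive offset so that the band adjacent to each
#' junction matches the linear extrapolation of the `n_ref` reference-side
#' bands nearest that junction. The reference segment is the central (NIR)
#' detector between the two default junctions; it is never modified. The
#' correction is idempotent.
#'
#' @param s A [spectrum] spanning the junctions.
#' @param junctions_nm Junction wavelengths, default `c(1000, 1800)`
#'   (VNIR|NIR and NIR|SWIR detector boundaries).
#' @param n_ref Number of reference-segment bands used for the
#'   extrapolation line.
#' @return The splice-corrected [spectrum].
#' @export
splice_correct <- function(s, junctions_nm = c(1000, 1800), n_ref = 5) {
  stopifnot(inherits(s, "spectrum"))
  wl <- s$wavelengths_nm
  v <- s$values
  junctions_nm <- sort(junctions_nm)
  if (any(junctions_nm <= min(wl)) || any(junctions_nm >= max(wl))) {
    stop("junction wavelengths must be interior to the spectrum grid", call. = FALSE)
  }
  # segment index per band: 1 .. length(junctions)+1, band <= junction is left
  seg <- findInterval(wl, junctions_nm, left.open = TRUE) + 1L
  ref_seg <- 2L  # segment immediately above the first junction
  extrap <- function(ref_idx, at_wl) {
    fit <- stats::lm(v[ref_idx] ~ wl[ref_idx])
    unname(fit$coefficients[1L] + fit$coefficients[2L] * at_wl)
  }
  # segments below the reference, corrected outward from the reference
  for (sg in rev(seq_len(ref_seg - 1L))) {
    idx <- which(seg == sg)
    ref_idx <- utils::head(which(seg == sg + 1L), n_ref)
    adj <- idx[length(idx)]
    v[idx] <- v[idx] + (extrap(ref_idx, wl[adj]) - v[adj])
  }
  # segments above the reference, corrected outward
  for (sg in (ref_seg + 1L):max(seg)) {
    if (sg > max(seg)) break
    idx <- which(seg == sg)
    if (length(idx) == 0) next
    ref_idx <- utils::tail(which(seg == sg - 1L), n_ref)
    adj <- idx[1L]
    v[idx] <- v[idx] + (extrap(ref_idx, wl[adj]) - v[adj])
  }
  spectrum(wl, v, s$unit)
}

#' Quality-control leaf replicates
#'
#' Single-pass QC mirroring field spectroscopy practice: (a) the seal
#' check -- replicates whose reflectance at 450 nm exceeds
#' `seal_threshold` are flagged (light leaking into the leaf clip);
#' (b) the deviation check -- the replicate-mean spectrum of the remaining
#' replicates is computed, and replicates whose mean absolute deviation
#' from it (averaged over bands) exceeds `deviation_threshold` reflectance
#' units are flagged; (c) the leaf is rejected (no mean spectrum) when
#' fewer than `min_viable` replicates survive, otherwise its mean spectrum
#' is the average of the viable replicates. Spectra themselves are never
#' modified.
#'
#' @param sample A [leaf_sample()].
#' @param seal_threshold Absolute reflectance bound at 450 nm (default 0.10).
#' @param deviation_threshold Band-averaged mean absolute deviation bound,
#'   reflectance units (default 0.02, i.e. 2 percentage points).
#' @param min_viable Minimum surviving replicates for acceptance (default 4).
#' @return The `leaf_sample` with `viable` flags, `accepted`, `reasons`, and
#'   `mean_spectrum` (NULL when rejected).
#' @export
qc_replicates <- function(sample, seal_threshold = 0.10,
                          deviation_threshold = 0.02, min_viable = 4) {
  stopifnot(inherits(sample, "leaf_sample"))
  wl <- sample$replicates[[1L]]$wavelengths_nm
  vals <- vapply(sample$replicates, function(r) r$values, numeric(length(wl)))
  vals <- matrix(vals, ncol = length(sample$replicates))  # bands x reps
  i450 <- which.min(abs(wl - 450))
  viable <- vals[i450, ] <= seal_threshold
  reasons <- ifelse(viable, "", "seal_check_450nm")
  if (any(viable)) {
    ref_mean <- rowMeans(vals[, viable, drop = FALSE])
    mad_bands <- colMeans(abs(vals - ref_mean))
    dev_fail <- viable & mad_bands > deviation_threshold
    reasons[dev_fail] <- "deviation_gt_threshold"
    viable <- viable & !dev_fail
  }
  sample$viable <- viable
  sample$reasons <- reasons
  sample$accepted <- sum(viable) >= min_viable
  sample$mean_spectrum <- if (sample$accepted) {
    spectrum(wl, rowMeans(vals[, viable, drop = FALSE]), "reflectance")
  } else NULL
  sample
}

#' Average accepted leaves to a plot-level spectrum
#'
#' Unweighted mean over the accepted leaves of one plot. The same averaging
#' applies to the plot's ground-truth trait values via [average_traits()].
#'
#' @param samples List of QC'd [leaf_sample()] objects (same plot).
#' @return The plot-mean [spectrum].
#' @export
average_leaves_to_plot <- function(samples) {
  ok <- Filter(function(s) isTRUE(s$accepted), samples)
  if (length(ok) == 0) {
    stop("empty plot: no accepted leaves to average", call. = FALSE)
  }
  wl <- ok[[1L]]$mean_spectrum$wavelengths_nm
  vals <- vapply(ok, function(s) s$mean_spectrum$values, numeric(length(wl)))
  spectrum(wl, rowMeans(matrix(vals, ncol = length(ok))), "reflectance")
}

#' Average leaf trait values to a plot value
#'
#' @param trait_values Numeric vector of per-leaf trait measurements.
#' @return Their unweighted mean (NAs dropped).
#' @export
average_traits <- function(trait_values) {
  mean(trait_values, na.rm = TRUE)
}
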