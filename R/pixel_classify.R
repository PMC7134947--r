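# K-means segmentation of radiance cubes into material clusters, and the
# brightness/vegetation-index rules that attach semantic class names
# (sunlit leaf, shaded leaf, soil, white panel, platform shadow,
# non-biological matter) to the clusters.

#' Segment a radiance cube by K-means clustering
#'
#' Runs Lloyd's algorithm on the per-pixel spectra (Euclidean metric) from a
#' k-means++ start, keeping the best of `n_init` restarts by within-cluster
#' sum of squares. Deterministic under a fixed seed. Cluster semantics are
#' initialized to `"unassigned"`; see [assign_semantics()].
#'
#' @param cube A [hypercube] in radiance.
#' @param k Number of clusters (default 6, the number of material classes a
#'   plot scene contains).
#' @param seed Integer RNG seed.
#' @param n_init Number of k-means++ restarts.
#' @param max_iter Lloyd iteration cap per restart.
#' @return An object of class `pixel_class_map`: `labels` (lines x samples
#'   integer matrix in 1..k), `k`, `centroids` (k x bands), `semantic`
#'   (cluster -> class name), `wss`, `wavelengths_nm`, `seed`.
#' @export
kmeans_segment <- function(cube, k = 6, seed = 1, n_init = 10, max_iter = 100) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  X <- matrix(cube$data, d[1L] * d[2L], d[3L])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    centers <- kmeanspp_init(X, k)
    fit <- suppressWarnings(
      stats::kmeans(X, centers = centers, iter.max = max_iter,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  structure(
    list(labels = matrix(best$cluster, d[1L], d[2L]), k = as.integer(k),
         centroids = best$centers,
         semantic = setNames(rep("unassigned", k), seq_len(k)),
         wss = best$tot.withinss, wavelengths_nm = cube$wavelengths_nm,
         seed = as.integer(seed)),
    class = "pixel_class_map"
  )
}

# k-means++ seeding: first center uniform, subsequent centers with
# probability proportional to squared distance to the nearest chosen center.
# Errors if fewer than k spectrally distinct pixels exist.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  if (n < k) stop("degenerate clustering: fewer pixels than clusters", call. = FALSE)
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in 2:k) {
    if (all(d2 <= 0)) {
      stop("degenerate clustering: fewer than k spectrally distinct pixels",
           call. = FALSE)
    }
    idx <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

#' Attach semantic class names to K-means clusters
#'
#' Physics-based labeling rules: the cluster with the highest mean broadband
#' radiance is the white reference panel. A vegetation index
#' `(R_nir - R_red) / (R_nir + R_red)` is evaluated on each remaining
#' centroid at the nearest available bands; clusters above `veg_threshold`
#' are vegetation, split by brightness into sunlit (above the vegetation
#' brightness median, or the single brightest) and shaded leaves. Among the
#' non-vegetation clusters the darkest is platform shadow; of the rest,
#' index below `soil_threshold` means soil and anything else is
#' non-biological matter. Brightness ties break toward the lower cluster id.
#'
#' @param map A `pixel_class_map` from [kmeans_segment()].
#' @param red_nm,nir_nm Index wavelengths (nearest available bands are used).
#' @param veg_threshold Vegetation-index threshold for vegetation clusters.
#' @param soil_threshold Vegetation-index threshold separating soil from
#'   other non-biological matter.
#' @return The map with its `semantic` slot filled in.
#' @export
assign_semantics <- function(map, red_nm = 670, nir_nm = 800,
                             veg_threshold = 0.5, soil_threshold = 0.3) {
  stopifnot(inherits(map, "pixel_class_map"))
  wl <- map$wavelengths_nm
  i_red <- which.min(abs(wl - red_nm))
  i_nir <- which.min(abs(wl - nir_nm))
  cen <- map$centroids
  brightness <- rowMeans(cen)
  ndvi <- (cen[, i_nir] - cen[, i_red]) / (cen[, i_nir] + cen[, i_red])

  semantic <- setNames(rep("unassigned", map$k), seq_len(map$k))
  panel <- which(brightness == max(brightness))[1L]
  semantic[panel] <- "panel"

  rest <- setdiff(seq_len(map$k), panel)
  veg <- rest[ndvi[rest] > veg_threshold]
  if (length(veg) == 0) {
    stop("labeling error: no vegetation cluster found (non-vegetated scene?)",
         call. = FALSE)
  }
  med <- stats::median(brightness[veg])
  sunlit <- veg[brightness[veg] > med]
  if (length(sunlit) == 0) sunlit <- veg[which.max(brightness[veg])]
  semantic[sunlit] <- "sunlit_leaf"
  semantic[setdiff(veg, sunlit)] <- "shaded_leaf"

  nonveg <- setdiff(rest, veg)
  if (length(nonveg) > 0) {
    shadow <- nonveg[which.min(brightness[nonveg])]
    semantic[shadow] <- "platform_shadow"
    others <- setdiff(nonveg, shadow)
    semantic[others] <- ifelse(ndvi[others] < soil_threshold,
                               "soil", "non_biological")
  }
  map$semantic <- semantic
  map
}

#' Extract per-pixel spectra of one semantic class
#'
#' @param cube The [hypercube] the map was computed from.
#' @param map A `pixel_class_map` with semantics assigned.
#' @param which Semantic class name (e.g. `"sunlit_leaf"`, `"panel"`).
#' @return Matrix of per-pixel spectra (pixels x bands); zero rows (with a
#'   warning) when the class maps to no cluster or no pixels.
#' @export
extract_class_spectra <- function(cube, map, which) {
  stopifnot(inherits(cube, "hypercube"), inherits(map, "pixel_class_map"))
  d <- dim(cube$data)
  if (!all(dim(map$labels) == d[1:2])) {
    stop("class map and cube have different spatial shapes", call. = FALSE)
  }
  clusters <- as.integer(names(map$semantic)[map$semantic == which])
  X <- matrix(cube$data, d[1L] * d[2L], d[3L])
  sel <- as.vector(map$labels) %in% clusters
  if (length(clusters) == 0 || !any(sel)) {
    warning("no pixels for class '", which, "'; returning an empty set")
    return(X[integer(0), , drop = FALSE])
  }
  X[sel, , drop = FALSE]
}
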