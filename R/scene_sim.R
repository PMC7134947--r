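# Synthetic plot scenes, trait-coupled spectral datasets and gas-exchange
# curves with known ground truth. Every downstream stage of the pipeline is
# testable against the truth these generators emit.

SCENE_CLASSES <- c("sunlit_leaf", "shaded_leaf", "soil", "panel",
                   "platform_shadow", "non_biological")

#' Camera wavelength grids
#'
#' Band-center grids of the two push-broom cameras: a VNIR camera covering
#' 400-900 nm in 2.1 nm contiguous bands and a NIR camera covering
#' 900-1800 nm in 4.9 nm contiguous bands.
#'
#' @return Numeric vector of band centers (nm).
#' @export
vnir_wavelengths <- function() 400 + 2.1 * 0:239

#' @rdname vnir_wavelengths
#' @export
nir_wavelengths <- function() 900 + 4.9 * 0:183

#' Built-in endmember reflectance spectra
#'
#' Smooth parametric reflectance fractions for the default scene materials:
#' a green-leaf spectrum (chlorophyll absorption, 550 nm green peak,
#' red edge, NIR plateau, water-absorption dips), a bare-soil ramp, a
#' senesced/non-biological material with moderate red/NIR contrast, and a
#' near-unity white reference panel.
#'
#' @param wavelengths_nm Wavelength grid (nm).
#' @return Reflectance fraction per band, in (0, 1).
#' @export
leaf_reflectance_default <- function(wavelengths_nm) {
  wl <- wavelengths_nm
  vis <- 0.04 + 0.09 * exp(-(wl - 550)^2 / (2 * 28^2))
  plateau <- 0.45 / (1 + exp(-(wl - 715) / 14))
  water <- 0.035 * exp(-(wl - 970)^2 / (2 * 25^2)) +
    0.080 * exp(-(wl - 1200)^2 / (2 * 35^2)) +
    0.250 * exp(-(wl - 1450)^2 / (2 * 45^2)) +
    0.120 * exp(-(wl - 1800)^2 / (2 * 70^2))
  r <- vis + plateau - water
  pmin(pmax(r, 0.01), 0.99)
}

#' @rdname leaf_reflectance_default
#' @export
soil_reflectance_default <- function(wavelengths_nm) {
  pmin(0.12 + 1e-4 * (wavelengths_nm - 450), 0.35)
}

#' @rdname leaf_reflectance_default
#' @export
non_bio_reflectance_default <- function(wavelengths_nm) {
  # senesced-material-like: moderate red/NIR contrast, far weaker than a leaf
  0.12 + 0.26 / (1 + exp(-(wavelengths_nm - 720) / 30))
}

#' @rdname leaf_reflectance_default
#' @export
panel_reflectance_default <- function(wavelengths_nm) {
  rep(0.99, length(wavelengths_nm))
}

#' Scene configuration for the plot simulator
#'
#' Describes a simulated ~2 m x 2 m plot scene: the areal fraction of each
#' material class, per-band endmember reflectances on both camera grids, the
#' sunlit/shaded illumination contrast, and the relative radiometric noise.
#'
#' @param lines,samples Spatial extent of the simulated image.
#' @param class_fractions Named non-negative fractions over
#'   `sunlit_leaf, shaded_leaf, soil, panel, platform_shadow, non_biological`,
#'   summing to 1. Classes with fraction 0 are absent from the scene.
#' @param sunlit_illumination,shaded_illumination Positive illumination
#'   scalars (radiance per unit reflectance); shaded < sunlit.
#' @param noise_sd Relative (multiplicative) Gaussian noise SD on radiance.
#' @param seed Integer RNG seed; the whole scene is deterministic given it.
#' @param vnir_grid,nir_grid Camera wavelength grids.
#' @param leaf_reflectance,soil_reflectance,non_bio_reflectance,panel_reflectance
#'   Functions of wavelength returning per-band reflectance fractions; the
#'   panel must dominate every other endmember at every band.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(lines = 100, samples = 100,
                         class_fractions = c(sunlit_leaf = 0.4, shaded_leaf = 0.2,
                                             soil = 0.2, panel = 0.1,
                                             platform_shadow = 0.05,
                                             non_biological = 0.05),
                         sunlit_illumination = 1000, shaded_illumination = 300,
                         noise_sd = 0, seed = 1,
                         vnir_grid = vnir_wavelengths(), nir_grid = nir_wavelengths(),
                         leaf_reflectance = leaf_reflectance_default,
                         soil_reflectance = soil_reflectance_default,
                         non_bio_reflectance = non_bio_reflectance_default,
                         panel_reflectance = panel_reflectance_default) {
  if (!all(names(class_fractions) %in% SCENE_CLASSES) ||
      anyDuplicated(names(class_fractions))) {
    stop("class_fractions must be named over the six scene classes", call. = FALSE)
  }
  fr <- setNames(numeric(length(SCENE_CLASSES)), SCENE_CLASSES)
  fr[names(class_fractions)] <- class_fractions
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("class fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (shaded_illumination >= sunlit_illumination) {
    stop("shaded_illumination must be below sunlit_illumination", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(
    list(lines = as.integer(lines), samples = as.integer(samples),
         class_fractions = fr,
         sunlit_illumination = sunlit_illumination,
         shaded_illumination = shaded_illumination,
         noise_sd = noise_sd, seed = as.integer(seed),
         vnir_grid = vnir_grid, nir_grid = nir_grid,
         leaf_reflectance = leaf_reflectance,
         soil_reflectance = soil_reflectance,
         non_bio_reflectance = non_bio_reflectance,
         panel_reflectance = panel_reflectance),
    class = "scene_config"
  )
}

# Endmember reflectance table: classes x bands. Shadow pixels are soil seen
# under shaded illumination; shaded leaves share the leaf endmember.
scene_endmember_reflectance <- function(config, wl) {
  refl <- rbind(
    sunlit_leaf = config$leaf_reflectance(wl),
    shaded_leaf = config$leaf_reflectance(wl),
    soil = config$soil_reflectance(wl),
    panel = config$panel_reflectance(wl),
    platform_shadow = config$soil_reflectance(wl),
    non_biological = config$non_bio_reflectance(wl)
  )
  if (any(refl["panel", ] < apply(refl[setdiff(SCENE_CLASSES, "panel"), , drop = FALSE], 2, max))) {
    stop("panel reflectance must dominate every other endmember per band",
         call. = FALSE)
  }
  refl
}

scene_illumination <- function(config) {
  c(sunlit_leaf = config$sunlit_illumination,
    shaded_leaf = config$shaded_illumination,
    soil = config$sunlit_illumination,
    panel = config$sunlit_illumination,
    platform_shadow = config$shaded_illumination,
    non_biological = config$sunlit_illumination)
}

# Integer class counts matching fractions to within one pixel (largest
# remainder apportionment).
apportion_counts <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    take <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[take] <- counts[take] + 1L
  }
  as.integer(counts)
}

#' Simulate a plot scene on both camera grids
#'
#' Draws a class map matching the configured areal fractions, then renders a
#' radiance cube per camera as
#' `radiance = illumination(class) * endmember_reflectance(class) * (1 + e)`,
#' with `e ~ Normal(0, noise_sd)` i.i.d. per pixel and band. Panel pixels are
#' always sunlit. Both cubes share the same class map (co-registered cameras).
#'
#' @param config A [scene_config].
#' @return A list with elements `vnir` and `nir` ([hypercube]s in radiance)
#'   and `truth`: a list holding `class_map` (lines x samples character
#'   matrix), per-camera endmember radiance tables, the endmember
#'   reflectances, and the illumination scalars.
#' @export
simulate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  n <- config$lines * config$samples
  counts <- apportion_counts(config$class_fractions, n)
  labels <- rep(SCENE_CLASSES, counts)
  illum <- scene_illumination(config)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  labels <- sample(labels)
  class_map <- matrix(labels, config$lines, config$samples)

  render <- function(wl, camera_id) {
    refl <- scene_endmember_reflectance(config, wl)
    base <- refl[labels, , drop = FALSE] * illum[labels]
    if (config$noise_sd > 0) {
      base <- base * (1 + matrix(stats::rnorm(length(base), 0, config$noise_sd),
                                 nrow(base), ncol(base)))
    }
    base[base < 0] <- 0
    hypercube(array(base, c(config$lines, config$samples, length(wl))),
              wl, unit = "radiance", camera_id = camera_id)
  }
  vnir <- render(config$vnir_grid, "vnir")
  nir <- render(config$nir_grid, "nir")
  truth <- list(
    class_map = class_map,
    counts = setNames(counts, SCENE_CLASSES),
    reflectance = list(vnir = scene_endmember_reflectance(config, config$vnir_grid),
                       nir = scene_endmember_reflectance(config, config$nir_grid)),
    endmember_radiance = list(
      vnir = scene_endmember_reflectance(config, config$vnir_grid) * illum[SCENE_CLASSES],
      nir = scene_endmember_reflectance(config, config$nir_grid) * illum[SCENE_CLASSES]),
    illumination = illum
  )
  list(vnir = vnir, nir = nir, truth = truth)
}

# Save/restore the global RNG state so seeded generators do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Band-localized linear trait coupling
#'
#' Defines the ground-truth linear map from a reflectance spectrum to a trait
#' value: `y = intercept + sum_j beta_j * R_j + noise`. The support is the
#' set of bands with non-zero coefficients.
#'
#' @param wavelengths_nm Wavelength grid the coupling lives on.
#' @param support_nm Wavelengths (nm) of the non-zero coefficients; each is
#'   snapped to the nearest grid band.
#' @param beta Coefficient values at the support bands (recycled).
#' @param intercept Trait intercept.
#' @param noise_sd_y Additive Gaussian trait noise SD (ignored when
#'   `r2_true` is given to [simulate_trait_dataset()]).
#' @return An object of class `trait_coupling`.
#' @export
trait_coupling <- function(wavelengths_nm, support_nm, beta, intercept = 0,
                           noise_sd_y = 0) {
  idx <- vapply(support_nm, function(w) which.min(abs(wavelengths_nm - w)), 0L)
  if (anyDuplicated(idx)) stop("support wavelengths collapse onto duplicate bands",
                               call. = FALSE)
  full <- numeric(length(wavelengths_nm))
  full[idx] <- rep_len(beta, length(idx))
  structure(
    list(wavelengths_nm = wavelengths_nm, beta = full,
         support_bands = sort(idx), intercept = intercept,
         noise_sd_y = noise_sd_y),
    class = "trait_coupling"
  )
}

#' Simulate a plot-spectra + trait dataset
#'
#' Draws `n_plots` smooth, collinear reflectance spectra (low-order spline
#' bumps and a multiplicative brightness factor around the mean vegetation
#' spectrum -- the collinear regime PLSR exists for) and couples a trait to
#' them through the ground-truth linear model in `coupling`.
#'
#' @param n_plots Number of plots (>= 4, so models remain cross-validatable).
#' @param coupling A [trait_coupling].
#' @param seed Integer RNG seed.
#' @param bump_df Degrees of freedom of the B-spline bump basis.
#' @param bump_sd SD of the random bump coefficients (reflectance units).
#' @param brightness_sd SD of the per-plot multiplicative brightness factor.
#' @param r2_true If given, overrides `coupling$noise_sd_y` so that the true
#'   linear signal explains this fraction of trait variance in the sample.
#' @return A list: `spectra` (n_plots x bands matrix, wavelength column
#'   names), `y` (trait vector) and `truth` (beta, support bands, intercept,
#'   realized noise SD).
#' @export
simulate_trait_dataset <- function(n_plots, coupling, seed = 1, bump_df = 25,
                                   bump_sd = 0.02, brightness_sd = 0.05,
                                   r2_true = NULL) {
  stopifnot(inherits(coupling, "trait_coupling"))
  if (n_plots < 4) stop("need n_plots >= 4 to cross-validate", call. = FALSE)
  wl <- coupling$wavelengths_nm
  p <- length(wl)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  basis <- splines::bs(wl, df = bump_df, intercept = TRUE)
  mean_spec <- leaf_reflectance_default(wl)
  coefs <- matrix(stats::rnorm(n_plots * ncol(basis), 0, bump_sd),
                  n_plots, ncol(basis))
  bright <- 1 + stats::rnorm(n_plots, 0, brightness_sd)
  spectra <- (coefs %*% t(basis)) + outer(bright, mean_spec)
  spectra[spectra < 0.005] <- 0.005
  colnames(spectra) <- sprintf("%.1f", wl)

  signal <- drop(spectra %*% coupling$beta)
  sd_y <- coupling$noise_sd_y
  if (!is.null(r2_true)) {
    if (r2_true <= 0 || r2_true > 1) stop("r2_true must be in (0, 1]", call. = FALSE)
    vs <- stats::var(signal)
    sd_y <- sqrt(vs * (1 - r2_true) / r2_true)
  }
  y <- coupling$intercept + signal +
    if (sd_y > 0) stats::rnorm(n_plots, 0, sd_y) else 0
  list(spectra = spectra, y = y,
       truth = list(beta = coupling$beta, support_bands = coupling$support_bands,
                    intercept = coupling$intercept, noise_sd_y = sd_y,
                    signal = signal))
}

#' Simulate a gas-exchange response curve
#'
#' Forward-simulates an A/Ci curve from the Farquhar-von Caemmerer-Berry
#' model or an A/Q light-response curve from the non-rectangular hyperbola,
#' on the standard measurement step sequences, with additive Gaussian noise.
#'
#' @param kind `"ACi"` or `"AQ"`.
#' @param params For `"ACi"`: list with `vcmax`, `j`, `rd` (micromol m-2 s-1);
#'   for `"AQ"`: list with `phi` (mol CO2 mol-1 photons), `theta` in (0, 1],
#'   `pmax`, `rd`.
#' @param steps Driver step sequence. Defaults: CO2 steps
#'   `400, 200, 50, 100, 300, 400, 600, 900, 1200, 1500, 1800, 2000`
#'   (micromol mol-1) for A/Ci; irradiance steps
#'   `2000, 1800, 1400, 1000, 600, 400, 200, 150, 100, 75, 50, 0`
#'   (micromol m-2 s-1) for A/Q.
#' @param noise_sd Additive Gaussian noise SD on A (micromol m-2 s-1).
#' @param seed Integer RNG seed.
#' @param leaf_T Leaf temperature (degrees C).
#' @param absorptance Leaf absorptance used to convert Q to absorbed
#'   irradiance for A/Q curves.
#' @param constants FvCB kinetic constants, see [fvcb_constants()].
#' @return A `gas_exchange_curve` object; see [gas_exchange_curve()].
#' @export
simulate_gas_exchange <- function(kind = c("ACi", "AQ"), params,
                                  steps = NULL, noise_sd = 0, seed = 1,
                                  leaf_T = 25, absorptance = 0.85,
                                  constants = fvcb_constants()) {
  kind <- match.arg(kind)
  if (kind == "ACi") {
    if (is.null(steps)) steps <- c(400, 200, 50, 100, 300, 400, 600, 900,
                                   1200, 1500, 1800, 2000)
    if (any(c(params$vcmax, params$j) <= 0) || params$rd < 0) {
      stop("FvCB parameters must be positive (rd >= 0)", call. = FALSE)
    }
    fwd <- fvcb_forward(ci = steps, vcmax = params$vcmax, j = params$j,
                        rd = params$rd, leaf_T = leaf_T, constants = constants)
    A <- fwd$A
  } else {
    if (is.null(steps)) steps <- c(2000, 1800, 1400, 1000, 600, 400, 200,
                                   150, 100, 75, 50, 0)
    if (params$theta <= 0 || params$theta > 1 || params$phi <= 0 ||
        params$pmax <= 0 || params$rd < 0) {
      stop("light-response parameters out of physical range", call. = FALSE)
    }
    Ia <- correct_absorbed_irradiance(steps, absorptance)
    A <- nrh_forward(Ia, phi = params$phi, theta = params$theta,
                     pmax = params$pmax, rd = params$rd)
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    A <- A + stats::rnorm(length(A), 0, noise_sd)
  }
  if (kind == "ACi") {
    gas_exchange_curve(kind = "ACi", A = A, driver = steps, leaf_T = leaf_T,
                       metadata = list(RH = 65, PAR = 1800, truth = params))
  } else {
    gas_exchange_curve(kind = "AQ", A = A, driver = steps, leaf_T = leaf_T,
                       Ia = correct_absorbed_irradiance(steps, absorptance),
                       metadata = list(RH = 65, CO2 = 400, truth = params,
                                       absorptance = absorptance))
  }
}
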