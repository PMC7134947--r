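test_that("reflectance ratio identities hold", {
  wl <- c(500, 600)
  # S_sunlit == S_ref recovers the panel reference itself
  s <- spectrum(wl, c(100, 80), "radiance")
  out <- to_reflectance(s, s, 0.99)
  expect_equal(out$values, c(0.99, 0.99))
  # zero radiance maps to zero reflectance
  z <- to_reflectance(spectrum(wl, c(0, 0), "radiance"), s, 0.99)
  expect_equal(z$values, c(0, 0))
  # direct arithmetic: (20/100, 40/80) * 0.99
  r <- to_reflectance(spectrum(wl, c(20, 40), "radiance"),
                      spectrum(wl, c(100, 80), "radiance"), 0.99)
  expect_equal(r$values, c(0.198, 0.495))
  # non-positive panel band names the offender
  expect_error(to_reflectance(s, spectrum(wl, c(100, 0), "radiance")),
               "band index 2")
})

test_that("reflectance is invariant to global illumination scaling", {
  wl <- seq(500, 590, by = 10)
  sun <- matrix(runif(30, 10, 50), 3, 10)
  panel <- runif(10, 80, 120)
  r1 <- to_reflectance(sun, panel, 0.99)
  r2 <- to_reflectance(sun * 3.7, panel * 3.7, 0.99)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("Savitzky-Golay reproduces low-order polynomials everywhere", {
  wl <- seq(400, 800, by = 4)
  n <- length(wl)
  # constant
  expect_equal(savgol_smooth(spectrum(wl, rep(0.3, n)))$values, rep(0.3, n))
  # exact quadratic in band index, including the edges (truncated-window fit)
  v <- 0.2 + 0.01 * seq_len(n) - 1e-4 * seq_len(n)^2
  sm <- savgol_smooth(spectrum(wl, v))$values
  expect_equal(sm, v, tolerance = 1e-10)
  expect_error(savgol_smooth(spectrum(wl[1:5], v[1:5]), window = 11), "shorter")
  expect_error(savgol_smooth(spectrum(wl, v), window = 10), "odd")
})

test_that("interior smoothing kernel matches the signal-package oracle and
           shrinks white-noise variance by the squared kernel norm", {
  # independent kernel oracle: center row of signal::sgolay(2, 11)
  kern <- signal::sgolay(p = 2, n = 11)[6, ]
  set.seed(42)
  n <- 1e5
  x <- rnorm(n)  # unit-variance white noise
  sm <- savgol_smooth(x)
  emp <- var(sm[6:(n - 5)])
  expect_equal(emp, sum(kern^2), tolerance = 0.05)
  # direct kernel comparison at one interior point
  expect_equal(sm[500], sum(kern * x[495:505]), tolerance = 1e-10)
})

test_that("band masking follows the keep/drop boundary conventions", {
  # VNIR grid: retained set is exactly the lambda >= 450 sub-grid
  wl <- vnir_wavelengths()
  s <- spectrum(wl, seq_along(wl) / 1000)
  m <- mask_bands(s, keep = c(450, 900), drop = list())
  keep_oracle <- wl[vapply(wl, function(l) l >= 450 && l <= 900, TRUE)]
  expect_equal(m$wavelengths_nm, keep_oracle)
  # grid fully inside the retained window is untouched
  s2 <- spectrum(seq(500, 1200, by = 50), rep(0.5, 15))
  expect_equal(mask_bands(s2)$wavelengths_nm, s2$wavelengths_nm)
  # water-window boundaries are drop-inclusive
  s3 <- spectrum(c(1310, 1313, 1440, 1443), rep(0.4, 4))
  expect_equal(mask_bands(s3)$wavelengths_nm, c(1310, 1443))
  expect_error(mask_bands(spectrum(c(100, 200), c(1, 1))), "all bands")
})

test_that("camera joining applies the 900 nm crossover rule", {
  v <- spectrum(c(850, 880, 899.5), c(0.4, 0.41, 0.42))
  n <- spectrum(c(900, 950), c(0.43, 0.44))
  j <- join_cameras(v, n)
  expect_equal(j$wavelengths_nm, c(850, 880, 899.5, 900, 950))
  # a VNIR band at exactly 900 loses to the NIR band there
  v2 <- spectrum(c(850, 900), c(0.4, 9.9))
  j2 <- join_cameras(v2, n)
  expect_equal(j2$values[j2$wavelengths_nm == 900], 0.43)
  # disjoint grids concatenate sorted
  j3 <- join_cameras(spectrum(c(500, 600), c(1, 2)),
                     spectrum(c(1000, 1100), c(3, 4)))
  expect_equal(j3$wavelengths_nm, c(500, 600, 1000, 1100))
})

test_that("joined noiseless two-camera spectra sit on the endmember with no
           step at the crossover", {
  cfg <- scene_config(lines = 30, samples = 30, noise_sd = 0, seed = 5)
  sc <- simulate_scene(cfg)
  ps <- process_plot(sc$vnir, sc$nir, smooth = FALSE, mask = FALSE, seed = 2)
  grid <- ps$mean$wavelengths_nm
  truthv <- leaf_reflectance_default(grid)
  expect_lt(max(abs(ps$mean$values - truthv)), 1e-6)
})

test_that("plot aggregation computes mean and population SD", {
  wl <- 500
  m <- aggregate_plot(matrix(c(0.2, 0.4), 2, 1), wl, "p")
  expect_equal(m$mean$values, 0.3)
  expect_equal(m$sd, 0.1)  # population SD, not sample SD
  expect_identical(m$n_pixels, 2L)
  # identical pixels: zero SD
  m2 <- aggregate_plot(matrix(0.5, 7, 1), wl)
  expect_equal(m2$sd, 0)
  expect_error(aggregate_plot(matrix(0, 0, 1), wl), "no sunlit")
})

test_that("panel pixels reconstruct the panel reference (self-consistency)", {
  cfg <- scene_config(lines = 30, samples = 30, noise_sd = 0, seed = 9)
  sc <- simulate_scene(cfg)
  map <- assign_semantics(kmeans_segment(sc$vnir, seed = 1))
  pan <- extract_class_spectra(sc$vnir, map, "panel")
  r <- to_reflectance(pan, colMeans(pan), 0.99)
  expect_lt(max(abs(r - 0.99)), 1e-9)
})

test_that("smoothing and masking do not commute and the pipeline order is
           smoothing first", {
  wl <- seq(1200, 1500, by = 10)
  set.seed(1)
  v <- 0.4 + cumsum(rnorm(length(wl), 0, 0.01))
  s <- spectrum(wl, v)
  a <- mask_bands(savgol_smooth(s), keep = c(1200, 1500))
  b <- savgol_smooth(mask_bands(s, keep = c(1200, 1500)))
  expect_false(isTRUE(all.equal(a$values, b$values)))
  ps <- process_plot(simulate_scene(scene_config(lines = 20, samples = 20,
                                                 seed = 3))$vnir,
                     seed = 1)
  # VNIR-only masking window
  expect_true(all(ps$mean$wavelengths_nm >= 450 & ps$mean$wavelengths_nm <= 900))
})
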