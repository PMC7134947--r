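test_that("the gm-temperature line evaluates, warns and clips as contracted", {
  expect_equal(gm_at_temperature(25), 1.01)
  expect_equal(gm_at_temperature(30), -0.44 + 0.058 * 30)
  # strictly increasing in T
  Ts <- seq(10, 40, by = 5)
  expect_true(all(diff(suppressWarnings(gm_at_temperature(Ts))) > 0))
  expect_warning(gm_at_temperature(46), "calibration range")
  expect_warning(g <- gm_at_temperature(6), "clipping")
  expect_equal(suppressWarnings(gm_at_temperature(6)), 0.05)
})

test_that("FvCB forward model honors the compensation point and monotonicity", {
  k <- fvcb_constants()
  gm <- gm_at_temperature(25)
  rd <- 1.5
  gamma_star <- 42.75  # 25 C value
  # Ci chosen so Cc = gamma*: net A equals -Rd
  ci_star <- gamma_star - rd / gm
  fwd <- fvcb_forward(ci_star, vcmax = 100, j = 150, rd = rd, leaf_T = 25)
  expect_equal(fwd$A, -rd, tolerance = 1e-9)
  # non-decreasing in Ci
  ci <- seq(50, 2000, by = 50)
  A <- fvcb_forward(ci, vcmax = 100, j = 150, rd = rd, leaf_T = 25)$A
  expect_true(all(diff(A) > -1e-12))
  # infinite gm reduces to the Ci-based closed form
  Km <- k$Kc25 * (1 + k$O / k$Ko25)
  closed <- pmin(100 * (ci - gamma_star) / (ci + Km),
                 150 * (ci - gamma_star) / (4 * ci + 8 * gamma_star)) - rd
  Ainf <- fvcb_forward(ci, vcmax = 100, j = 150, rd = rd, leaf_T = 25,
                       gm = Inf)$A
  expect_equal(Ainf, closed, tolerance = 1e-6)
})

test_that("noiseless A/Ci curves on the measurement grid are recovered
           within 1 percent", {
  for (par in list(list(vcmax = 100, j = 150, rd = 1.5),
                   list(vcmax = 60, j = 120, rd = 1.0),
                   list(vcmax = 150, j = 240, rd = 2.0))) {
    curve <- simulate_gas_exchange("ACi", par, noise_sd = 0)
    fit <- fit_aci(curve)
    expect_lt(abs(fit$vcmax - par$vcmax) / par$vcmax, 0.01)
    expect_lt(abs(fit$j1800 - par$j) / par$j, 0.01)
  }
})

test_that("curves that never leave Rubisco limitation flag J1800 unavailable", {
  curve <- simulate_gas_exchange("ACi", list(vcmax = 40, j = 2000, rd = 1.0),
                                 noise_sd = 0)
  fit <- fit_aci(curve)
  expect_true(is.na(fit$j1800))
  expect_lt(abs(fit$vcmax - 40) / 40, 0.02)
  expect_true(all(fit$limitation_state == "Rubisco"))
})

test_that("noisy A/Ci fitting keeps the median Vcmax error below 5 percent", {
  errs <- vapply(1:30, function(s) {
    curve <- simulate_gas_exchange("ACi", list(vcmax = 100, j = 150, rd = 1.5),
                                   noise_sd = 0.5, seed = s)
    abs(fit_aci(curve)$vcmax - 100) / 100
  }, 0)
  expect_lt(median(errs), 0.05)
})

test_that("fit_aci RSS on noiseless data beats the truth's own RSS bound", {
  curve <- simulate_gas_exchange("ACi", list(vcmax = 100, j = 150, rd = 1.5),
                                 noise_sd = 0)
  fit <- fit_aci(curve)
  truth_rss <- sum((curve$A - fvcb_forward(curve$driver, 100, 150, 1.5)$A)^2)
  expect_lte(fit$rss, truth_rss + 1e-8)
})

test_that("absorbed-irradiance correction is a positive scaling", {
  expect_equal(correct_absorbed_irradiance(2000, 0.85), 1700)
  Q <- c(0, 50, 150, 600, 2000)
  Ia <- correct_absorbed_irradiance(Q, 1)
  expect_identical(Ia, Q)
  expect_identical(order(correct_absorbed_irradiance(Q, 0.7)), order(Q))
  expect_error(correct_absorbed_irradiance(Q, 1.2), "absorptance")
  expect_error(correct_absorbed_irradiance(Q, 0), "absorptance")
})

test_that("the non-rectangular hyperbola has the right limits", {
  # theta -> 0 equals the rectangular hyperbola (the residual curvature term
  # scales linearly in theta, so it is negligible by 1e-7)
  Ia <- c(0, 50, 200, 800, 2000)
  rect <- 0.06 * Ia * 30 / (0.06 * Ia + 30) - 1.5
  expect_lt(max(abs(nrh_forward(Ia, 0.06, 1e-7, 30, 1.5) - rect)), 1e-6)
  # saturating light tends to Pmax - Rd
  expect_equal(nrh_forward(1e9, 0.06, 0.7, 30, 1.5), 30 - 1.5, tolerance = 1e-3)
  # darkness gives -Rd
  expect_equal(nrh_forward(0, 0.06, 0.7, 30, 1.5), -1.5)
})

test_that("noiseless light-response curves are recovered within 0.5 percent", {
  truth <- list(phi = 0.06, theta = 0.7, pmax = 30, rd = 1.5)
  curve <- simulate_gas_exchange("AQ", truth, noise_sd = 0)
  fit <- fit_light_response(curve)
  expect_lt(abs(fit$phi - truth$phi) / truth$phi, 0.005)
  expect_lt(abs(fit$theta - truth$theta) / truth$theta, 0.005)
  expect_lt(abs(fit$pmax - truth$pmax) / truth$pmax, 0.005)
  expect_lt(abs(fit$rd - truth$rd) / truth$rd, 0.005)
  # the initial-slope estimate never exceeds the fitted quantum yield
  expect_lte(fit$phi_co2, fit$phi)
})

test_that("phi_co2 is the OLS slope restricted to Ia < 150", {
  Ia <- c(0, 42.5, 63.75, 85, 127.5)
  A <- 0.05 * Ia - 1.0
  curve <- gas_exchange_curve("AQ", A = c(A, 20.2), driver = c(Ia, 2000) / 0.85,
                              Ia = c(Ia, 2000))
  expect_equal(phi_co2(curve), 0.05, tolerance = 1e-12)
  # appending more saturated points does not move the slope
  curve2 <- gas_exchange_curve("AQ", A = c(A, 20.2, 21, 21.3),
                               driver = c(Ia, 2000, 1800, 1400) / 0.85,
                               Ia = c(Ia, 2000, 1800, 1400))
  expect_equal(phi_co2(curve2), phi_co2(curve), tolerance = 1e-12)
  # hand OLS oracle on the qualifying points
  ols <- sum((Ia - mean(Ia)) * (A - mean(A))) / sum((Ia - mean(Ia))^2)
  expect_equal(phi_co2(curve), ols, tolerance = 1e-12)
  # fewer than 3 qualifying points is an error
  short <- gas_exchange_curve("AQ", A = c(-1, 2, 10, 15, 18, 20),
                              driver = c(0, 100, 400, 800, 1400, 2000),
                              Ia = c(0, 100, 400, 800, 1400, 2000))
  expect_error(phi_co2(short), "insufficient")
})
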