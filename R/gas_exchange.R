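# Leaf gas-exchange ground-truth fitters: Farquhar-von Caemmerer-Berry (FvCB)
# A/Ci analysis for Vc,max and J1800 with a temperature-constrained mesophyll
# conductance, and non-rectangular hyperbola light-response analysis for
# Pmax, phi, theta, Rd and the apparent quantum yield of CO2 fixation.

#' A gas-exchange response curve
#'
#' @param kind `"ACi"` (assimilation vs intercellular CO2) or `"AQ"`
#'   (assimilation vs irradiance).
#' @param A Net CO2 assimilation (micromol m-2 s-1).
#' @param driver `Ci` (micromol mol-1) for A/Ci, incident `Q`
#'   (micromol m-2 s-1) for A/Q.
#' @param leaf_T Leaf temperature (degrees C).
#' @param Ia Absorbed irradiance (A/Q only), micromol m-2 s-1.
#' @param metadata Free-form environment metadata (RH, PAR or CO2 setpoint).
#' @return An object of class `gas_exchange_curve`.
#' @export
gas_exchange_curve <- function(kind = c("ACi", "AQ"), A, driver, leaf_T = 25,
                               Ia = NULL, metadata = list()) {
  kind <- match.arg(kind)
  if (length(A) != length(driver)) stop("A and driver lengths differ", call. = FALSE)
  if (length(A) < 6) stop("a response curve needs at least 6 points", call. = FALSE)
  if (!is.finite(leaf_T)) stop("leaf temperature must be finite", call. = FALSE)
  if (kind == "ACi" && any(driver <= 0)) {
    stop("Ci values must be strictly positive", call. = FALSE)
  }
  if (kind == "AQ" && any(driver < 0)) {
    stop("Q values must be non-negative", call. = FALSE)
  }
  structure(list(kind = kind, A = as.numeric(A), driver = as.numeric(driver),
                 leaf_T = leaf_T, Ia = Ia, metadata = metadata),
            class = "gas_exchange_curve")
}

#' FvCB kinetic constants and their temperature responses
#'
#' Michaelis constants of Rubisco for CO2 (`Kc`) and O2 (`Ko`), the CO2
#' photocompensation point (`gamma_star`), their Arrhenius activation
#' energies, and the oxygen partial pressure. Defaults are the standard
#' tobacco-derived 25 degree C values and temperature responses used by
#' common A/Ci fitting utilities; all are editable.
#'
#' @param Kc25 Kc at 25 C (micromol mol-1). @param Ea_Kc kJ mol-1.
#' @param Ko25 Ko at 25 C (mmol mol-1). @param Ea_Ko kJ mol-1.
#' @param gamma_star25 Photocompensation point at 25 C (micromol mol-1).
#' @param Ea_gamma_star kJ mol-1.
#' @param O Oxygen concentration (mmol mol-1).
#' @return A list of class `fvcb_constants`.
#' @export
fvcb_constants <- function(Kc25 = 404.9, Ea_Kc = 79.43,
                           Ko25 = 278.4, Ea_Ko = 36.38,
                           gamma_star25 = 42.75, Ea_gamma_star = 37.83,
                           O = 210) {
  k <- list(Kc25 = Kc25, Ea_Kc = Ea_Kc, Ko25 = Ko25, Ea_Ko = Ea_Ko,
            gamma_star25 = gamma_star25, Ea_gamma_star = Ea_gamma_star, O = O)
  if (any(unlist(k) <= 0)) stop("FvCB constants must all be positive", call. = FALSE)
  structure(k, class = "fvcb_constants")
}

# Arrhenius temperature scaling from 25 C. Ea in kJ mol-1, T in C.
arrhenius <- function(k25, Ea, leaf_T) {
  R <- 8.314e-3  # kJ mol-1 K-1
  k25 * exp(Ea * (leaf_T - 25) / (298.15 * R * (leaf_T + 273.15)))
}

fvcb_constants_at <- function(constants, leaf_T) {
  list(
    Kc = arrhenius(constants$Kc25, constants$Ea_Kc, leaf_T),
    Ko = arrhenius(constants$Ko25, constants$Ea_Ko, leaf_T),
    gamma_star = arrhenius(constants$gamma_star25, constants$Ea_gamma_star, leaf_T),
    O = constants$O
  )
}

#' Mesophyll conductance constrained by leaf temperature
#'
#' The linear temperature dependency `gm = -0.44 + 0.058 T` (mol m-2 s-1
#' bar-1, T in degrees C) used to constrain gm during A/Ci fitting.
#'
#' @param leaf_T Leaf temperature (degrees C); values outside 5-45 C raise a
#'   warning but are still evaluated.
#' @param floor Lower clip applied (with a warning) when the line would give
#'   a non-physical conductance at low temperature.
#' @return Mesophyll conductance (mol m-2 s-1 bar-1).
#' @export
gm_at_temperature <- function(leaf_T, floor = 0.05) {
  if (any(leaf_T < 5 | leaf_T > 45)) {
    warning("leaf temperature outside the 5-45 C calibration range of the gm line")
  }
  gm <- -0.44 + 0.058 * leaf_T
  if (any(gm < floor)) {
    warning(sprintf("gm line gives <= %.2f mol m-2 s-1 bar-1; clipping to floor", floor))
    gm <- pmax(gm, floor)
  }
  gm
}

# Net assimilation for one limitation, solving Cc = Ci - A/gm
# self-consistently (Ethier-type quadratic). x1 = Vcmax (with x2 = Km) for
# the Rubisco-limited rate, x1 = J/4 (with x2 = 2 gamma_star) for the
# RuBP-regeneration-limited rate. gm = Inf gives the Ci-based closed form.
fvcb_limited_rate <- function(ci, x1, x2, gamma_star, rd, gm) {
  if (!is.finite(gm)) {
    return(x1 * (ci - gamma_star) / (ci + x2) - rd)
  }
  p <- gm * (ci + x2) + x1 - rd
  q <- gm * (x1 * (ci - gamma_star) - rd * (ci + x2))
  disc <- p^2 - 4 * q
  if (any(disc < 0)) stop("non-convergent Cc solution (negative discriminant)",
                          call. = FALSE)
  (p - sqrt(disc)) / 2
}

#' Forward FvCB model on a Ci grid
#'
#' Net assimilation `A = min(Ac, Aj)` with
#' `Ac = Vcmax (Cc - gamma*) / (Cc + Kc (1 + O/Ko)) - Rd` and
#' `Aj = J (Cc - gamma*) / (4 Cc + 8 gamma*) - Rd`, where the chloroplastic
#' CO2 `Cc = Ci - A/gm` is solved self-consistently per limitation and the
#' kinetic constants are adjusted to leaf temperature.
#'
#' @param ci Intercellular CO2 (micromol mol-1, treated as microbar at ~1 bar).
#' @param vcmax,j,rd FvCB parameters (micromol m-2 s-1).
#' @param leaf_T Leaf temperature (degrees C).
#' @param gm Mesophyll conductance; default from [gm_at_temperature()].
#'   Use `Inf` for the Ci-based model.
#' @param constants [fvcb_constants()].
#' @return List with `A` (net assimilation) and `limitation`
#'   (`"Rubisco"`/`"RuBP"` per point).
#' @export
fvcb_forward <- function(ci, vcmax, j, rd, leaf_T = 25, gm = NULL,
                         constants = fvcb_constants()) {
  if (vcmax <= 0 || j <= 0 || rd < 0) {
    stop("FvCB parameters must be positive (rd >= 0)", call. = FALSE)
  }
  if (is.null(gm)) gm <- gm_at_temperature(leaf_T)
  k <- fvcb_constants_at(constants, leaf_T)
  Km <- k$Kc * (1 + k$O / k$Ko)
  Ac <- fvcb_limited_rate(ci, vcmax, Km, k$gamma_star, rd, gm)
  Aj <- fvcb_limited_rate(ci, j / 4, 2 * k$gamma_star, k$gamma_star, rd, gm)
  A <- pmin(Ac, Aj)
  list(A = A, limitation = ifelse(Ac <= Aj, "Rubisco", "RuBP"))
}

#' Fit the FvCB model to an A/Ci curve
#'
#' Mesophyll conductance is fixed by [gm_at_temperature()] at the curve's
#' leaf temperature. The Ci cutover between the Rubisco-limited (low Ci) and
#' RuBP-regeneration-limited (high Ci) regions is enumerated; for every
#' candidate assignment `(Vcmax, J, Rd)` are estimated by least squares, and
#' the assignment with minimum residual sum of squares wins (ties broken
#' toward more Rubisco-limited points). `J1800` (the electron transport rate
#' at the 1800 micromol m-2 s-1 measurement light level) is reported only
#' when at least two points are RuBP-limited; curves that never leave
#' Rubisco limitation yield `j1800 = NA`.
#'
#' @param curve A [gas_exchange_curve()] of kind `"ACi"`.
#' @param constants [fvcb_constants()].
#' @param min_rubisco Minimum number of low-Ci points that must be available
#'   as Rubisco-limited candidates.
#' @return An object of class `fvcb_fit`: `vcmax`, `j1800` (NA when
#'   unidentifiable), `rd`, `gm`, `limitation_state` per point (in input
#'   order), `rss`, and `fitted` values.
#' @export
fit_aci <- function(curve, constants = fvcb_constants(), min_rubisco = 4) {
  stopifnot(inherits(curve, "gas_exchange_curve"))
  if (curve$kind != "ACi") stop("fit_aci needs an A/Ci curve", call. = FALSE)
  ord <- order(curve$driver)
  ci <- curve$driver[ord]
  A <- curve$A[ord]
  n <- length(ci)
  if (n < min_rubisco) {
    stop("unidentifiable Vcmax: fewer than ", min_rubisco,
         " Rubisco-limited candidate points", call. = FALSE)
  }
  gm <- gm_at_temperature(curve$leaf_T)
  k <- fvcb_constants_at(constants, curve$leaf_T)
  Km <- k$Kc * (1 + k$O / k$Ko)

  rd0 <- max(0.1, -min(A), 1)
  fit_assignment <- function(n_rub) {
    rub <- seq_len(n_rub)
    rubp <- setdiff(seq_len(n), rub)
    has_j <- length(rubp) > 0
    # start values: invert the Rubisco form at the top Rubisco point, the
    # RuBP form at the highest-Ci point
    ci_r <- ci[n_rub]
    v0 <- max(10, (A[n_rub] + rd0) * (ci_r + Km) / max(ci_r - k$gamma_star, 1))
    j0 <- if (has_j) {
      ci_j <- ci[n]
      max(20, 4 * (A[n] + rd0) * (ci_j + 2 * k$gamma_star) /
            max(ci_j - k$gamma_star, 1))
    } else 0
    resid_fn <- function(par) {
      vcmax <- par[1]; rd <- par[3]
      r <- A[rub] - fvcb_limited_rate(ci[rub], vcmax, Km, k$gamma_star, rd, gm)
      if (has_j) {
        jj <- par[2]
        r <- c(r, A[rubp] - fvcb_limited_rate(ci[rubp], jj / 4, 2 * k$gamma_star,
                                              k$gamma_star, rd, gm))
      }
      r
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(v0, max(j0, 1), rd0), fn = resid_fn,
                         lower = c(1, 1, 0), upper = c(2000, 3000, 50),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(n_rub = n_rub, par = fit$par, rss = sum(resid_fn(fit$par)^2),
         n_rubp = length(rubp))
  }

  cands <- Filter(Negate(is.null), lapply(min_rubisco:n, fit_assignment))
  if (length(cands) == 0) stop("A/Ci fit failed for every limitation assignment",
                               call. = FALSE)
  rss <- vapply(cands, `[[`, 0, "rss")
  nr <- vapply(cands, `[[`, 0, "n_rub")
  # minimum RSS; ties (within solver tolerance) toward more Rubisco points
  best <- cands[[order(round(rss, 10), -nr)[1L]]]

  limitation <- rep("Rubisco", n)
  if (best$n_rub < n) limitation[(best$n_rub + 1):n] <- "RuBP"
  vcmax <- best$par[1]; jj <- best$par[2]; rd <- best$par[3]
  j1800 <- if (best$n_rubp >= 2) jj else NA_real_
  fitted <- numeric(n)
  fitted[limitation == "Rubisco"] <-
    fvcb_limited_rate(ci[limitation == "Rubisco"], vcmax, Km, k$gamma_star, rd, gm)
  if (any(limitation == "RuBP")) {
    fitted[limitation == "RuBP"] <-
      fvcb_limited_rate(ci[limitation == "RuBP"], jj / 4, 2 * k$gamma_star,
                        k$gamma_star, rd, gm)
  }
  state <- character(n)
  state[ord] <- limitation  # back to input order
  fitted_input <- numeric(n)
  fitted_input[ord] <- fitted
  structure(list(vcmax = vcmax, j1800 = j1800, rd = rd, gm = gm,
                 limitation_state = state, rss = best$rss,
                 fitted = fitted_input,
                 leaf_T = curve$leaf_T),
            class = "fvcb_fit")
}

#' Absorbed irradiance from incident irradiance
#'
#' @param Q Incident irradiance (micromol m-2 s-1).
#' @param absorptance Leaf absorptance fraction in (0, 1].
#' @return Absorbed irradiance `Ia = Q * absorptance`.
#' @export
correct_absorbed_irradiance <- function(Q, absorptance) {
  if (length(absorptance) != 1L || absorptance <= 0 || absorptance > 1) {
    stop("absorptance must be a scalar in (0, 1]", call. = FALSE)
  }
  Q * absorptance
}

#' Non-rectangular hyperbola light-response model
#'
#' `A(Ia) = (phi Ia + Pmax - sqrt((phi Ia + Pmax)^2 - 4 phi Ia theta Pmax))
#' / (2 theta) - Rd`. As `theta -> 0` this tends to the rectangular
#' hyperbola `phi Ia Pmax / (phi Ia + Pmax) - Rd`; at `Ia -> Inf` it
#' saturates at `Pmax - Rd`.
#'
#' @param Ia Absorbed irradiance (micromol m-2 s-1).
#' @param phi Apparent quantum yield (mol CO2 mol-1 photons).
#' @param theta Curvature factor in (0, 1].
#' @param pmax Maximum gross light-saturated photosynthesis (micromol m-2 s-1).
#' @param rd Dark respiration (micromol m-2 s-1).
#' @return Net assimilation at each `Ia`.
#' @export
nrh_forward <- function(Ia, phi, theta, pmax, rd) {
  if (theta < 1e-9) {
    return(phi * Ia * pmax / (phi * Ia + pmax) - rd)
  }
  s <- phi * Ia + pmax
  (s - sqrt(s^2 - 4 * phi * Ia * theta * pmax)) / (2 * theta) - rd
}

#' Fit the non-rectangular hyperbola to an A/Q curve
#'
#' Bounded least squares over `(phi, theta, Pmax, Rd)` on absorbed
#' irradiance, initialized from the data: `phi0` from the low-light slope,
#' `Rd0 = -A(Q = 0)`, `Pmax0 = max(A) + Rd0`, `theta0 = 0.7`.
#'
#' @param curve A [gas_exchange_curve()] of kind `"AQ"` carrying `Ia`.
#' @return An object of class `nrh_fit` with `phi`, `theta`, `pmax`, `rd`,
#'   `phi_co2` (independent low-light OLS slope, see [phi_co2()]), `rss` and
#'   `fitted` values.
#' @export
fit_light_response <- function(curve) {
  stopifnot(inherits(curve, "gas_exchange_curve"))
  if (curve$kind != "AQ") stop("fit_light_response needs an A/Q curve", call. = FALSE)
  if (is.null(curve$Ia)) stop("curve carries no absorbed irradiance Ia", call. = FALSE)
  Ia <- curve$Ia
  A <- curve$A
  if (length(Ia) < 8) {
    stop("need at least 8 points spanning darkness to near-saturating light",
         call. = FALSE)
  }
  rd0 <- max(0, -A[which.min(Ia)])
  low <- Ia < 150 & Ia > 0
  phi0 <- if (sum(low) >= 2) {
    max(0.02, min(0.12, stats::coef(stats::lm(A[low] ~ Ia[low]))[2]))
  } else 0.05
  pmax0 <- max(A) + rd0
  resid_fn <- function(par) {
    A - nrh_forward(Ia, phi = par[1], theta = par[2], pmax = par[3], rd = par[4])
  }
  fit <- minpack.lm::nls.lm(
    par = c(phi0, 0.7, pmax0, max(rd0, 0.01)), fn = resid_fn,
    lower = c(0.01, 0.01, 0.1, 0), upper = c(0.125, 1, 200, 50),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  if (fit$info == 0 || fit$info == 5) {
    stop("light-response fit did not converge; residual norm ",
         format(sqrt(fit$deviance)), call. = FALSE)
  }
  par <- fit$par
  slope <- tryCatch(phi_co2(curve), error = function(e) NA_real_)
  structure(list(phi = par[1], theta = par[2], pmax = par[3], rd = par[4],
                 phi_co2 = slope, rss = fit$deviance,
                 fitted = nrh_forward(Ia, par[1], par[2], par[3], par[4])),
            class = "nrh_fit")
}

#' Apparent quantum yield of CO2 fixation
#'
#' Ordinary least-squares slope (intercept free) of net assimilation on
#' absorbed irradiance, restricted to the low-light region `Ia < 150`
#' micromol m-2 s-1.
#'
#' @param curve A [gas_exchange_curve()] of kind `"AQ"` carrying `Ia`.
#' @param cutoff Upper `Ia` bound of the low-light region.
#' @return The slope (mol CO2 mol-1 photons).
#' @export
phi_co2 <- function(curve, cutoff = 150) {
  stopifnot(inherits(curve, "gas_exchange_curve"))
  if (is.null(curve$Ia)) stop("curve carries no absorbed irradiance Ia", call. = FALSE)
  sel <- curve$Ia < cutoff
  if (sum(sel) < 3) {
    stop("insufficient low-light data: need >= 3 points with Ia < ", cutoff,
         call. = FALSE)
  }
  unname(stats::coef(stats::lm(curve$A[sel] ~ curve$Ia[sel]))[2])
}
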