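#' Coded geometry of the 31-run central composite design
#'
#' 16 factorial (+/-1), 8 axial (+/-2) and 7 centre runs in the same row
#' order and train/test split pattern as the packaged example dataset.
#'
#' @return list with \code{coded} (31 x 4 matrix) and \code{split}
#'   (character vector).
#' @keywords internal
ccd_design_geometry <- function() {
  fixture <- table2_ccd()
  list(coded = coded_matrix(fixture), split = fixture$runs$split)
}

#' Simulate a CCD experiment from a quadratic surface
#'
#' Emits the 31-point central composite geometry with response = surface
#' value + iid Gaussian noise, clamped to [0, 100] as a percentage. A fixed
#' seed reproduces the dataset exactly; zero noise lies exactly on the
#' surface, so refitting recovers the generating coefficients.
#'
#' @param surface a \code{\link{quadratic_surface}} supplying the true
#'   response (coded units).
#' @param noise_sd Gaussian noise standard deviation in response units
#'   (default 0).
#' @param seed integer seed.
#' @return a \code{\link{ccd_dataset}}.
#' @examples
#' truth <- quadratic_surface(90, c(5, 0, 2, -3), c(-4, -9, -2, -1),
#'                            rep(0, 6))
#' sim <- simulate_ccd(truth, noise_sd = 2, seed = 1)
#' @export
simulate_ccd <- function(surface, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(surface, "quadratic_surface"), noise_sd >= 0)
  geom <- ccd_design_geometry()
  y <- predict(surface, geom$coded)
  y <- with_seed(seed, function() y + rnorm(length(y), 0, noise_sd))
  y <- pmin(pmax(y, 0), 100)
  actual <- mapply(function(j, spec) decode_factor(geom$coded[, j], spec),
                   1:4, surface$factor_specs)
  runs <- data.frame(dose = actual[, 1], ph = actual[, 2],
                     temp = actual[, 3], conc = actual[, 4],
                     removal_obs = y, split = geom$split)
  ccd_dataset(runs, surface$factor_specs)
}

#' Simulate equilibrium isotherm data
#'
#' Langmuir: \code{qe = Qo b Ce / (1 + b Ce)}; Freundlich:
#' \code{qe = KF Ce^(1/n)}. Noise is additive Gaussian on \code{qe},
#' truncated below at a small positive value so fits on log/linearised
#' coordinates stay defined.
#'
#' @param model \code{"langmuir"} or \code{"freundlich"}.
#' @param params named list: Langmuir \code{Qo}, \code{b}; Freundlich
#'   \code{KF}, \code{inv_n}.
#' @param Ce equilibrium concentrations, mg/L.
#' @param noise_sd Gaussian noise sd on qe (default 0).
#' @param seed integer seed.
#' @return data frame with \code{Ce}, \code{qe}.
#' @export
simulate_isotherm <- function(model = c("langmuir", "freundlich"), params,
                              Ce = seq(0.1, 1.1, by = 0.1),
                              noise_sd = 0, seed = NULL) {
  model <- match.arg(model)
  stopifnot(all(Ce > 0), noise_sd >= 0)
  qe <- switch(model,
               langmuir = params$Qo * params$b * Ce / (1 + params$b * Ce),
               freundlich = params$KF * Ce^params$inv_n)
  qe <- with_seed(seed, function() qe + rnorm(length(qe), 0, noise_sd))
  data.frame(Ce = Ce, qe = pmax(qe, 1e-9))
}

#' Simulate sorption kinetic series
#'
#' Pseudo-second order: \code{qt = qe^2 k2' t / (1 + qe k2' t)};
#' pseudo-first order: \code{qt = qe (1 - exp(-ks t))}.
#'
#' @param model \code{"pso"} or \code{"pfo"}.
#' @param params named list: PSO \code{k2p}, \code{qe}; PFO \code{ks},
#'   \code{qe}.
#' @param t sampling times, min.
#' @param noise_sd Gaussian noise sd on qt (default 0).
#' @param seed integer seed.
#' @return data frame with \code{t}, \code{qt}.
#' @export
simulate_kinetics <- function(model = c("pso", "pfo"), params,
                              t = seq(5, 135, by = 10),
                              noise_sd = 0, seed = NULL) {
  model <- match.arg(model)
  stopifnot(all(t > 0), noise_sd >= 0)
  qt <- switch(model,
               pso = params$qe^2 * params$k2p * t /
                 (1 + params$qe * params$k2p * t),
               pfo = params$qe * (1 - exp(-params$ks * t)))
  qt <- with_seed(seed, function() qt + rnorm(length(qt), 0, noise_sd))
  data.frame(t = t, qt = pmax(qt, 1e-9))
}

#' Simulate Van't Hoff equilibrium constants
#'
#' \code{ln Kc = -dH/(R T) + dS/R} evaluated at the given temperatures,
#' with optional Gaussian noise on \code{ln Kc}.
#'
#' @param dH enthalpy change, kJ/mol.
#' @param dS entropy change, kJ/mol/K.
#' @param T_K temperatures, K.
#' @param noise_sd noise sd on ln Kc (default 0).
#' @param seed integer seed.
#' @return data frame with \code{T_K}, \code{Kc}.
#' @export
simulate_vanthoff <- function(dH, dS, T_K = seq(293, 318, by = 5),
                              noise_sd = 0, seed = NULL) {
  stopifnot(all(T_K > 0), noise_sd >= 0)
  lnKc <- -dH * 1000 / (GAS_CONSTANT * T_K) + dS * 1000 / GAS_CONSTANT
  lnKc <- with_seed(seed, function() lnKc + rnorm(length(lnKc), 0, noise_sd))
  data.frame(T_K = T_K, Kc = exp(lnKc))
}

#' Simulate a logistic breakthrough front
#'
#' \code{Ct = C0 / (1 + exp(-r (t - t50)))}: a monotone S-shaped outlet
#' concentration rising from ~0 to the inlet level, the canonical shape of
#' a fixed-bed breakthrough curve. The time at which the front crosses any
#' level \code{c} has the closed form
#' \code{t50 - log(C0/c - 1)/r}, used as the oracle for crossing-time
#' tests. Noise is additive Gaussian, clamped to \code{[0, C0]}.
#'
#' @param C0 inlet concentration, mg/L.
#' @param t50 midpoint time (Ct = C0/2), min.
#' @param r front steepness, 1/min.
#' @param t sampling times, min.
#' @param noise_sd noise sd on Ct (default 0).
#' @param seed integer seed.
#' @return data frame with \code{t}, \code{Ct}.
#' @export
simulate_breakthrough <- function(C0, t50, r,
                                  t = seq(0, 2 * t50, length.out = 101),
                                  noise_sd = 0, seed = NULL) {
  stopifnot(C0 > 0, r > 0, noise_sd >= 0)
  Ct <- C0 / (1 + exp(-r * (t - t50)))
  Ct <- with_seed(seed, function() Ct + rnorm(length(Ct), 0, noise_sd))
  data.frame(t = t, Ct = pmin(pmax(Ct, 0), C0))
}

#' Closed-form crossing time of the logistic breakthrough front
#'
#' @param C0,t50,r logistic front parameters as in
#'   \code{\link{simulate_breakthrough}}.
#' @param level concentration level, mg/L, in (0, C0).
#' @return time at which \code{Ct} equals \code{level}, min.
#' @export
logistic_crossing_time <- function(C0, t50, r, level) {
  stopifnot(level > 0, level < C0)
  t50 - log(C0 / level - 1) / r
}
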