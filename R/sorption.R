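#' Batch uptake capacity and percentage removal
#'
#' \code{qt = (Ci - Ct) * V / W} (mg solute per g sorbent) and
#' \code{removal = (Ci - Ct) / Ci * 100}.
#'
#' @param Ci initial solute concentration, mg/L.
#' @param Ct remaining concentration at time t, mg/L.
#' @param V solution volume, L.
#' @param W sorbent mass, g.
#' @return list with \code{qt} (mg/g) and \code{removal} (percent).
#' @examples
#' uptake_and_removal(Ci = 1, Ct = 1 - 0.924, V = 1, W = 0.7)  # ~1.32 mg/g
#' @export
uptake_and_removal <- function(Ci, Ct, V, W) {
  if (any(W <= 0) || any(Ci <= 0))
    stop("Ci and W must be positive", call. = FALSE)
  if (any(Ct < 0) || any(Ct > Ci))
    stop("Ct must lie in [0, Ci]", call. = FALSE)
  list(qt = (Ci - Ct) * V / W, removal = (Ci - Ct) / Ci * 100)
}

# R^2 of a fitted lm without summary.lm's perfect-fit warning; an
# all-equal response counts as a perfect fit of the constant model
lin_r2 <- function(fit) {
  y <- fit$model[[1]]
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  1 - sum(residuals(fit)^2) / ss_tot
}

new_isotherm_fit <- function(model, Qo = NULL, b = NULL, KF = NULL,
                             inv_n = NULL, r2) {
  structure(list(model = model, Qo = Qo, b = b, KF = KF, inv_n = inv_n,
                 r2 = r2),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  if (x$model == "langmuir")
    cat(sprintf("<isotherm_fit> Langmuir: Qo = %.4g mg/g, b = %.4g L/mg, R2 = %.4f\n",
                x$Qo, x$b, x$r2))
  else
    cat(sprintf("<isotherm_fit> Freundlich: KF = %.4g mg/g, 1/n = %.4g, R2 = %.4f\n",
                x$KF, x$inv_n, x$r2))
  invisible(x)
}

check_isotherm_points <- function(Ce, qe) {
  stopifnot(length(Ce) == length(qe))
  if (length(Ce) < 3)
    stop("need at least 3 equilibrium points", call. = FALSE)
  bad <- which(Ce <= 0 | qe <= 0)
  if (length(bad))
    stop("nonpositive Ce or qe at point(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
}

#' Fit the Langmuir isotherm (linearised)
#'
#' Ordinary least squares on the linearised form
#' \code{Ce/qe = 1/(Qo b) + Ce/Qo}: the slope gives 1/Qo and the intercept
#' 1/(Qo b). Qo (mg/g) is the monolayer sorption capacity and b (L/mg) the
#' affinity constant.
#'
#' @param Ce equilibrium solute concentrations, mg/L (> 0).
#' @param qe equilibrium uptakes, mg/g (> 0).
#' @return an \code{isotherm_fit} with \code{Qo}, \code{b} and the
#'   \code{r2} of the linearised regression.
#' @export
fit_langmuir <- function(Ce, qe) {
  check_isotherm_points(Ce, qe)
  fit <- lm(I(Ce / qe) ~ Ce)
  slope <- coef(fit)[[2]]; intercept <- coef(fit)[[1]]
  new_isotherm_fit("langmuir", Qo = 1 / slope,
                   b = slope / intercept,
                   r2 = lin_r2(fit))
}

#' Fit the Freundlich isotherm (linearised)
#'
#' Least squares on \code{log10(qe) = log10(KF) + (1/n) log10(Ce)}. KF
#' (mg/g) indicates uptake capacity and 1/n the sorption intensity.
#'
#' @inheritParams fit_langmuir
#' @return an \code{isotherm_fit} with \code{KF}, \code{inv_n}, \code{r2}.
#' @export
fit_freundlich <- function(Ce, qe) {
  check_isotherm_points(Ce, qe)
  fit <- lm(log10(qe) ~ log10(Ce))
  new_isotherm_fit("freundlich", KF = 10^coef(fit)[[1]],
                   inv_n = coef(fit)[[2]],
                   r2 = lin_r2(fit))
}

new_kinetic_fit <- function(model, ks = NULL, k2p = NULL, qe, h = NULL, r2,
                            degenerate = FALSE) {
  structure(list(model = model, ks = ks, k2p = k2p, qe = qe, h = h, r2 = r2,
                 degenerate = degenerate),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (x$model == "pso")
    cat(sprintf("<kinetic_fit> PSO: k2' = %.4g g/mg/min, qe = %.4g mg/g, h = %.4g mg/g/min, R2 = %.4f\n",
                x$k2p, x$qe, x$h, x$r2))
  else
    cat(sprintf("<kinetic_fit> PFO: ks = %.4g 1/min, qe = %.4g mg/g, R2 = %.4f\n",
                x$ks, x$qe, x$r2))
  invisible(x)
}

#' Pseudo-first-order kinetic fit (linearised)
#'
#' Least squares on \code{log10(qe_obs - qt) = log10(qe) - ks t / 2.303}.
#' Points with \code{qt >= qe_obs} (log undefined) are dropped with a
#' warning.
#'
#' @param t contact times, min.
#' @param qt uptake at each time, mg/g.
#' @param qe_obs observed equilibrium uptake, mg/g.
#' @return a \code{kinetic_fit} with rate constant \code{ks} (1/min), the
#'   fitted \code{qe}, and \code{r2}.
#' @export
fit_pfo <- function(t, qt, qe_obs) {
  stopifnot(length(t) == length(qt), qe_obs > 0)
  keep <- qt < qe_obs
  if (!all(keep))
    warning(sum(!keep), " point(s) with qt >= qe_obs excluded from PFO fit")
  t <- t[keep]; qt <- qt[keep]
  if (length(t) < 3)
    stop("fewer than 3 usable points for PFO fit", call. = FALSE)
  fit <- lm(log10(qe_obs - qt) ~ t)
  new_kinetic_fit("pfo", ks = -coef(fit)[[2]] * 2.303,
                  qe = 10^coef(fit)[[1]],
                  r2 = lin_r2(fit))
}

#' Pseudo-second-order kinetic fit (linearised)
#'
#' Least squares on \code{t/qt = 1/(k2' qe^2) + t/qe}; also returns the
#' initial sorption rate \code{h = k2' qe^2} (mg/g/min), which satisfies
#' that identity exactly by construction. A non-positive intercept (e.g. a
#' flat, equilibrium-only series) has no finite rate constant and is
#' flagged \code{degenerate}.
#'
#' @param t contact times, min (> 0).
#' @param qt uptake at each time, mg/g (> 0).
#' @return a \code{kinetic_fit} with \code{k2p} (g/mg/min), \code{qe},
#'   \code{h} and \code{r2}.
#' @export
fit_pso <- function(t, qt) {
  stopifnot(length(t) == length(qt))
  if (length(t) < 3) stop("need at least 3 points", call. = FALSE)
  if (any(t <= 0) || any(qt <= 0))
    stop("PSO fit needs t > 0 and qt > 0", call. = FALSE)
  fit <- lm(I(t / qt) ~ t)
  slope <- coef(fit)[[2]]; intercept <- coef(fit)[[1]]
  qe <- 1 / slope
  # an intercept indistinguishable from 0 (relative to the fitted line)
  # means k2' -> Inf: equilibrium-only data
  if (intercept <= sqrt(.Machine$double.eps) * abs(slope) * mean(t)) {
    warning("non-positive PSO intercept: rate constant unidentifiable ",
            "(equilibrium-only data?)")
    return(new_kinetic_fit("pso", k2p = Inf, qe = qe, h = Inf,
                           r2 = lin_r2(fit), degenerate = TRUE))
  }
  k2p <- 1 / (intercept * qe^2)
  new_kinetic_fit("pso", k2p = k2p, qe = qe, h = k2p * qe^2,
                  r2 = lin_r2(fit))
}

GAS_CONSTANT <- 8.314  # J/(mol K)

#' Van't Hoff sorption thermodynamics
#'
#' Per temperature, the Gibbs free energy change is
#' \code{dG = -R T ln(Kc)}; the enthalpy and entropy changes come from
#' least squares of \code{ln(Kc)} on \code{1/T}
#' (\code{ln Kc = -dH/(R T) + dS/R}). All energies are reported in kJ.
#'
#' @param T_K absolute temperatures, K (at least 3).
#' @param Kc dimensionless sorption equilibrium constants
#'   (sorbed/solution concentration ratio), > 0.
#' @return object of class \code{thermo_result}: data frame \code{per_T}
#'   with \code{T_K}, \code{Kc}, \code{dG_kJ_mol}; scalars \code{dH_kJ_mol},
#'   \code{dS_kJ_mol_K}; \code{r2_vanthoff}.
#' @examples
#' vant_hoff(c(298, 308, 318), c(2, 3.1, 4.6))
#' @export
vant_hoff <- function(T_K, Kc) {
  stopifnot(length(T_K) == length(Kc))
  if (length(T_K) < 3) stop("need at least 3 temperatures", call. = FALSE)
  if (any(Kc <= 0)) stop("Kc must be positive", call. = FALSE)
  if (any(T_K <= 0)) stop("temperatures must be in kelvin", call. = FALSE)
  dG <- -GAS_CONSTANT * T_K * log(Kc) / 1000
  fit <- lm(log(Kc) ~ I(1 / T_K))
  dH <- -coef(fit)[[2]] * GAS_CONSTANT / 1000
  dS <- coef(fit)[[1]] * GAS_CONSTANT / 1000
  structure(list(per_T = data.frame(T_K = T_K, Kc = Kc, dG_kJ_mol = dG),
                 dH_kJ_mol = dH, dS_kJ_mol_K = dS,
                 r2_vanthoff = lin_r2(fit)),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result> dH = %.3f kJ/mol, dS = %.4g kJ/mol/K, R2 = %.4f\n",
              x$dH_kJ_mol, x$dS_kJ_mol_K, x$r2_vanthoff))
  print(x$per_T, row.names = FALSE)
  invisible(x)
}

#' Convert Celsius to kelvin
#' @param temp_C temperature(s) in degrees Celsius.
#' @return temperature(s) in kelvin.
#' @export
celsius_to_kelvin <- function(temp_C) temp_C + 273.15
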