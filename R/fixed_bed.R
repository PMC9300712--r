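#' Packed-bed column configuration
#'
#' @param diameter internal column diameter, cm.
#' @param Z bed height, cm.
#' @param Q volumetric flow rate, mL/min.
#' @param C0 inlet solute concentration, mg/L.
#' @param M sorbent mass in the bed, g.
#' @param Cb breakthrough threshold concentration, mg/L (must be below
#'   \code{C0}).
#' @param rho packed sorbent density, g/cm^3 (optional).
#' @return list of class \code{column_config}.
#' @export
column_config <- function(diameter, Z, Q, C0, M, Cb, rho = NULL) {
  stopifnot(diameter > 0, Z > 0, Q > 0, C0 > 0, M > 0, Cb > 0, Cb < C0)
  structure(list(diameter = diameter, Z = Z, Q = Q, C0 = C0, M = M,
                 Cb = Cb, rho = rho),
            class = "column_config")
}

#' Effluent volume treated up to a time
#'
#' \code{V_eff = Q * t}.
#'
#' @param Q flow rate, mL/min.
#' @param t time, min.
#' @return volume, mL.
#' @examples
#' effluent_volume(1.66, 1350)  # 2241 mL
#' @export
effluent_volume <- function(Q, t) {
  stopifnot(Q >= 0, all(t >= 0))
  Q * t
}

#' Breakthrough and exhaustion times of a breakthrough curve
#'
#' Breakthrough time \code{tb} is the first time the outlet concentration
#' reaches \code{Cb}; exhaustion time \code{te} the first time it reaches
#' \code{Ce_frac * C0}. Both are linearly interpolated between samples. A
#' threshold the series never reaches yields \code{NA} with
#' \code{exhausted = FALSE} rather than an error.
#'
#' @param t sampling times, min, strictly increasing.
#' @param Ct outlet concentrations, mg/L, within \code{[0, C0]}.
#' @param C0 inlet concentration, mg/L.
#' @param Cb breakthrough threshold, mg/L.
#' @param Ce_frac exhaustion fraction of \code{C0} (default 0.95).
#' @return list with \code{tb}, \code{te} (min, possibly \code{NA}),
#'   \code{broken_through} and \code{exhausted} flags.
#' @export
find_breakthrough <- function(t, Ct, C0, Cb, Ce_frac = 0.95) {
  stopifnot(length(t) == length(Ct), length(t) >= 2,
            all(diff(t) > 0), C0 > 0, Cb > 0, Cb < C0,
            Ce_frac > 0, Ce_frac <= 1)
  if (any(Ct < 0) || any(Ct > C0 + 1e-9))
    stop("Ct must lie in [0, C0]", call. = FALSE)
  cross <- function(level) {
    i <- which(Ct >= level)
    if (!length(i)) return(NA_real_)
    i <- i[1]
    if (i == 1 || Ct[i] == level) return(t[i])
    # linear interpolation on the rising segment
    t[i - 1] + (level - Ct[i - 1]) / (Ct[i] - Ct[i - 1]) * (t[i] - t[i - 1])
  }
  tb <- cross(Cb)
  te <- cross(Ce_frac * C0)
  list(tb = tb, te = te,
       broken_through = !is.na(tb), exhausted = !is.na(te))
}

#' Total metal fed to the column
#'
#' \code{X = C0 * Q * te / 1000} (mg).
#'
#' @param C0 inlet concentration, mg/L.
#' @param Q flow rate, mL/min.
#' @param te bed exhaustion time, min.
#' @return mg of solute fed.
#' @examples
#' metal_fed(1.0, 1.66, 1980)  # 3.2868 mg
#' @export
metal_fed <- function(C0, Q, te) {
  stopifnot(C0 > 0, Q > 0, te >= 0)
  C0 * Q * te / 1000
}

#' Total metal sorbed (area under the breakthrough curve)
#'
#' Trapezoidal integral of \code{(C0 - Ct)} over time, times \code{Q/1000}:
#' the mass removed from the stream up to the end of the series.
#'
#' @inheritParams find_breakthrough
#' @param Q flow rate, mL/min.
#' @return \code{qtot}, mg.
#' @export
total_sorbed <- function(t, Ct, C0, Q) {
  stopifnot(length(t) == length(Ct), length(t) >= 2, all(diff(t) > 0),
            C0 > 0, Q > 0)
  if (any(Ct < 0) || any(Ct > C0 + 1e-9))
    stop("Ct must lie in [0, C0]", call. = FALSE)
  Q / 1000 * pracma::trapz(t, C0 - Ct)
}

#' Column uptake capacity
#'
#' \code{q = qtot / M} (mg sorbed per g of bed sorbent).
#'
#' @param qtot total sorbed mass, mg.
#' @param M sorbent mass, g.
#' @return mg/g.
#' @export
column_uptake <- function(qtot, M) {
  if (M <= 0) stop("sorbent mass must be positive", call. = FALSE)
  qtot / M
}

#' Column removal percentage and elution efficiency
#'
#' \code{column_removal = qtot / X * 100};
#' \code{elution_efficiency = md / qtot * 100} where \code{md} is the mass
#' desorbed during regeneration (from the elution curve).
#'
#' @param qtot total sorbed mass, mg.
#' @param X total mass fed, mg.
#' @param md desorbed mass, mg.
#' @return percentage.
#' @export
column_removal <- function(qtot, X) {
  stopifnot(X > 0, qtot >= 0)
  qtot / X * 100
}

#' @rdname column_removal
#' @export
elution_efficiency <- function(md, qtot) {
  stopifnot(qtot > 0, md >= 0)
  md / qtot * 100
}

#' Empty bed contact time
#'
#' \code{EBCT = Ac * Z / Q} with cross-section
#' \code{Ac = pi * (diameter/2)^2}.
#'
#' @param diameter column diameter, cm.
#' @param Z bed height, cm.
#' @param Q flow rate, mL/min.
#' @return minutes.
#' @examples
#' ebct(2, 25, 1.66)  # ~47.3 min
#' @export
ebct <- function(diameter, Z, Q) {
  stopifnot(diameter > 0, Z >= 0, Q > 0)
  pi * (diameter / 2)^2 * Z / Q
}

#' Sorbent usage rate
#'
#' \code{Ur = M / Vb} expressed in g of sorbent per litre treated at
#' breakthrough.
#'
#' @param M sorbent mass, g.
#' @param Vb volume treated up to breakthrough, mL.
#' @return g/L.
#' @export
usage_rate <- function(M, Vb) {
  stopifnot(M > 0, Vb > 0)
  M / Vb * 1000
}

#' BDST critical bed height
#'
#' The bed-depth service-time model's minimum bed height giving nonzero
#' service time at breakthrough threshold \code{Cb}:
#' \code{Z0 = u / (ka N0) * ln(C0/Cb - 1)}. When \code{Cb >= C0/2} the
#' logarithm's argument drops to 1 or below and the model degenerates
#' (\code{Z0 <= 0}); the value is returned with a warning.
#'
#' @param u linear flow velocity, cm/min.
#' @param ka BDST rate constant, L/mg/min.
#' @param N0 bed sorption capacity, mg/L.
#' @param C0 inlet concentration, mg/L.
#' @param Cb breakthrough threshold, mg/L.
#' @return critical height, cm.
#' @export
bdst_critical_height <- function(u, ka, N0, C0, Cb) {
  stopifnot(u > 0, ka > 0, N0 > 0, C0 > Cb, Cb > 0)
  z0 <- u / (ka * N0) * log(C0 / Cb - 1)
  if (z0 <= 0)
    warning("Cb >= C0/2: BDST critical height is not positive (degenerate)")
  z0
}

#' Full breakthrough-curve analysis of a packed-bed run
#'
#' Combines the individual fixed-bed formulas into one metrics set for a
#' measured breakthrough series.
#'
#' @param config a \code{\link{column_config}}.
#' @param t,Ct breakthrough series (min, mg/L).
#' @param Ce_frac exhaustion fraction of \code{C0} (default 0.95).
#' @return list of class \code{column_metrics}: \code{tb}, \code{te},
#'   \code{Vb}, \code{Ve}, \code{X}, \code{qtot}, \code{q},
#'   \code{removal}, \code{EBCT}, \code{Ur}, \code{Nb} (bed volumes at
#'   breakthrough) and \code{exhausted}.
#' @export
analyze_column <- function(config, t, Ct, Ce_frac = 0.95) {
  stopifnot(inherits(config, "column_config"))
  bt <- find_breakthrough(t, Ct, config$C0, config$Cb, Ce_frac)
  te <- if (bt$exhausted) bt$te else max(t)
  Vb <- if (bt$broken_through) effluent_volume(config$Q, bt$tb) else NA_real_
  Ve <- effluent_volume(config$Q, te)
  keep <- t <= te
  X <- metal_fed(config$C0, config$Q, te)
  qtot <- total_sorbed(t[keep], Ct[keep], config$C0, config$Q)
  bed_volume <- pi * (config$diameter / 2)^2 * config$Z
  structure(list(
    tb = bt$tb, te = te, Vb = Vb, Ve = Ve, X = X, qtot = qtot,
    q = column_uptake(qtot, config$M),
    removal = column_removal(qtot, X),
    EBCT = ebct(config$diameter, config$Z, config$Q),
    Ur = if (bt$broken_through) usage_rate(config$M, Vb) else NA_real_,
    Nb = if (bt$broken_through) Vb / bed_volume else NA_real_,
    exhausted = bt$exhausted),
    class = "column_metrics")
}

#' @export
print.column_metrics <- function(x, ...) {
  cat("<column_metrics>\n")
  cat(sprintf("  tb %.1f min, te %.1f min%s\n", x$tb, x$te,
              if (x$exhausted) "" else " (bed not exhausted)"))
  cat(sprintf("  Vb %.1f mL, Ve %.1f mL\n", x$Vb, x$Ve))
  cat(sprintf("  X %.3f mg fed, qtot %.3f mg sorbed (q %.3f mg/g)\n",
              x$X, x$qtot, x$q))
  cat(sprintf("  removal %.2f%%, EBCT %.2f min, Ur %.2f g/L\n",
              x$removal, x$EBCT, x$Ur))
  invisible(x)
}
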