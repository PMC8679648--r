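#' Experimental property series
#'
#' A curated set of literature measurements for one compound/property pair:
#' temperature, value, source label and a manual exclusion flag.  Outlier
#' handling is manual-flag only; no automatic rejection rule is applied.
#'
#' @param compound compound identifier.
#' @param property property name (e.g. "density", "vapor_pressure").
#' @param T temperatures (K, > 0).
#' @param value measured values.
#' @param source source label per point.
#' @param excluded logical exclusion flags (default none).
#' @param units unit string.
#' @return an object of class \code{"propertySeries"}.
#' @export
propertySeries <- function(compound, property, T, value,
                           source = "unknown", excluded = FALSE,
                           units = "") {
  stopifnot(length(T) == length(value), all(T > 0))
  n <- length(T)
  structure(list(compound = compound, property = property,
                 points = data.frame(T = T, value = value,
                                     source = rep_len(source, n),
                                     excluded = rep_len(excluded, n)),
                 units = units),
            class = "propertySeries")
}

#' @export
print.propertySeries <- function(x, ...) {
  cat(sprintf("propertySeries: %s %s, %d points (%d excluded) from %d source(s)\n",
              x$compound, x$property, nrow(x$points), sum(x$points$excluded),
              length(unique(x$points$source))))
  invisible(x)
}

#' Temperature regression of a density series
#'
#' Fits a straight line through each source's non-excluded points,
#' evaluates every fit at the reference temperature and averages the
#' per-source slopes into a correction factor that can be applied to
#' single-temperature literature values reported away from the reference.
#' Isothermal sources contribute their mean value and are flagged as
#' non-fittable (zero slope).
#'
#' @param series a \code{\link{propertySeries}}.
#' @param Tref reference temperature (K).
#' @return list with \code{value} (average over sources at Tref),
#'   \code{perSource} data.frame (source, intercept, slope, atRef, r2, n,
#'   fittable) and \code{slope} (average of fitted slopes, the correction
#'   factor).
#' @export
#' @examples
#' s <- propertySeries("x", "density", c(293, 303), c(800, 790))
#' fitDensitySeries(s)$value   # 795 at 298 K
fitDensitySeries <- function(series, Tref = 298) {
  stopifnot(inherits(series, "propertySeries"))
  pts <- series$points[!series$points$excluded, , drop = FALSE]
  if (!nrow(pts)) stop("all points are excluded")
  out <- NULL
  for (src in unique(pts$source)) {
    p <- pts[pts$source == src, , drop = FALSE]
    if (length(unique(p$T)) >= 2) {
      fit <- stats::lm(value ~ T, data = p)
      out <- rbind(out, data.frame(
        source = src, intercept = stats::coef(fit)[[1]],
        slope = stats::coef(fit)[[2]],
        atRef = unname(stats::predict(fit, data.frame(T = Tref))),
        r2 = suppressWarnings(summary(fit))$r.squared, n = nrow(p), fittable = TRUE))
    } else {
      out <- rbind(out, data.frame(
        source = src, intercept = mean(p$value), slope = 0,
        atRef = mean(p$value), r2 = NA_real_, n = nrow(p), fittable = FALSE))
    }
  }
  list(value = mean(out$atRef),
       perSource = out,
       slope = if (any(out$fittable)) mean(out$slope[out$fittable]) else NA_real_)
}

#' Fit vapor-pressure data to the Clausius-Clapeyron form
#'
#' Each source's non-excluded points are fitted independently to
#' \deqn{\ln p = A + B/T} with pressure in mmHg and temperature in Kelvin.
#' Whenever possible a narrow temperature window centered on the reference
#' temperature should be selected before fitting (pass \code{window}).
#'
#' @param series a \code{\link{propertySeries}} whose values are pressures.
#' @param units unit of the stored pressures (converted to mmHg internally).
#' @param window optional c(Tmin, Tmax) restriction (K).
#' @return an object of class \code{"vaporPressureFit"}: data.frame
#'   \code{fits} with per-source coefficients \code{A}, \code{B} (K),
#'   the fitted window's \code{meanT}, and \code{r2}.
#' @export
fitVaporPressure <- function(series, units = "mmHg", window = NULL) {
  stopifnot(inherits(series, "propertySeries"))
  pts <- series$points[!series$points$excluded, , drop = FALSE]
  if (!is.null(window))
    pts <- pts[pts$T >= window[1] & pts$T <= window[2], , drop = FALSE]
  if (any(pts$value <= 0)) stop("non-positive pressures cannot be fitted")
  pts$p <- convertPressure(pts$value, units, "mmHg")
  fits <- NULL
  for (src in unique(pts$source)) {
    p <- pts[pts$source == src, , drop = FALSE]
    if (nrow(p) < 2) next
    invT <- 1 / p$T
    fit <- stats::lm(log(p$p) ~ invT)
    r2 <- if (nrow(p) == 2) 1 else suppressWarnings(summary(fit))$r.squared
    fits <- rbind(fits, data.frame(
      source = src, A = stats::coef(fit)[[1]], B = stats::coef(fit)[[2]],
      meanT = mean(p$T), Tmin = min(p$T), Tmax = max(p$T),
      r2 = r2, n = nrow(p)))
  }
  if (is.null(fits)) stop("no source has at least two points to fit")
  structure(list(compound = series$compound, fits = fits),
            class = "vaporPressureFit")
}

#' @export
print.vaporPressureFit <- function(x, ...) {
  cat(sprintf("vaporPressureFit (%s): %d source fits of ln p[mmHg] = A + B/T\n",
              x$compound, nrow(x$fits)))
  print(x$fits, row.names = FALSE)
  invisible(x)
}

#' Enthalpy of vaporization from a vapor-pressure fit
#'
#' The Clausius-Clapeyron slope gives \eqn{\Delta H_{Vap} = -R B} for each
#' fitted source (B is the slope of ln p against 1/T, in K).  Each estimate
#' is tagged with the mean temperature of its fitted window, since windows
#' from different sources cover different ranges.
#'
#' @param fit a \code{\link{fitVaporPressure}} result.
#' @return data.frame(source, dHvap (kJ/mol), meanT).
#' @export
#' @examples
#' # slope -3031.6 K -> 25.2 kJ/mol
#' -8.314462618 * -3031.6 / 1000
hvapFromFit <- function(fit) {
  stopifnot(inherits(fit, "vaporPressureFit"))
  data.frame(source = fit$fits$source,
             dHvap = -orgsilConstants()$R * fit$fits$B / 1000,
             meanT = fit$fits$meanT)
}

#' Temperature correction of an enthalpy of vaporization
#'
#' Moves an enthalpy measured at temperature T to the reference
#' temperature.  Available strategies: \code{"none"} (identity),
#' \code{"constant-correlation-derivative"} (a constant dH/dT taken from a
#' published temperature correlation) and \code{"heat-capacity-difference"}
#' (Kirchhoff: the gas-liquid heat-capacity difference).  Both corrections
#' are first order:
#' \eqn{\Delta H(T_{ref}) = \Delta H(T) + c (T_{ref} - T)} with c the
#' supplied derivative (kJ mol^-1 K^-1).
#'
#' @param dH enthalpy at T (kJ/mol).
#' @param T measurement temperature (K).
#' @param Tref reference temperature (K).
#' @param strategy correction strategy.
#' @param derivative dH/dT for the correlation strategy (kJ mol^-1 K^-1).
#' @param dCp Cp(gas) - Cp(liquid) for the heat-capacity strategy
#'   (kJ mol^-1 K^-1, typically negative).
#' @return corrected enthalpy with an \code{"audit"} attribute recording the
#'   strategy and inputs.
#' @export
adjustHvapTemperature <- function(dH, T, Tref = 298.15,
                                  strategy = c("none",
                                               "constant-correlation-derivative",
                                               "heat-capacity-difference"),
                                  derivative = NULL, dCp = NULL) {
  strategy <- match.arg(strategy)
  c0 <- switch(strategy,
    none = 0,
    `constant-correlation-derivative` = {
      if (is.null(derivative)) stop("supply 'derivative' for this strategy")
      derivative
    },
    `heat-capacity-difference` = {
      if (is.null(dCp)) stop("supply 'dCp' for this strategy")
      dCp
    })
  out <- dH + c0 * (Tref - T)
  attr(out, "audit") <- list(strategy = strategy, T = T, Tref = Tref,
                             derivative = c0)
  out
}

#' Vapor pressure at the reference temperature from the boiling point
#'
#' Integrates the Clausius-Clapeyron equation between the normal boiling
#' point (where p = 1 atm) and the reference temperature, assuming a
#' constant enthalpy of vaporization:
#' \deqn{p(T) = 1\,\mathrm{atm} \cdot \exp\left[-\frac{\Delta H_{Vap}}{R}
#'  \left(\frac{1}{T} - \frac{1}{T_b}\right)\right]}
#'
#' @param Tb normal boiling point (K).
#' @param dHvap enthalpy of vaporization (kJ/mol).
#' @param T target temperature (K).
#' @return vapor pressure (bar).
#' @export
#' @examples
#' pvapAtReference(298.15, 40)   # 1 atm: the boiling point is at 298.15 K
pvapAtReference <- function(Tb, dHvap, T = 298.15) {
  if (Tb <= 0) stop("boiling point must be positive")
  cst <- orgsilConstants()
  cst$atm * exp(-dHvap * 1000 / cst$R * (1 / T - 1 / Tb))
}

#' Self-solvation free energy from the vapor pressure
#'
#' Free energy of transferring a molecule from its saturated vapor into its
#' own pure liquid at equal concentrations:
#' \deqn{\Delta G_{Solv} = -RT \ln\frac{\rho R T}{M_W\, p_{Vapor}}}
#' with the density in kg/m^3, the molecular weight in g/mol and the vapor
#' pressure in bar.  The result is zero when the vapor molar concentration
#' equals the liquid molar concentration, and decreases by RT ln 2 for each
#' halving of the vapor pressure.
#'
#' @param rho liquid density (kg/m^3).
#' @param MW molecular weight (g/mol).
#' @param p vapor pressure (bar, > 0).
#' @param T temperature (K).
#' @return self-solvation free energy (kJ/mol).
#' @export
#' @examples
#' gsolvFromVaporPressure(758.4, 162.38, 0.0555)   # about -19 kJ/mol
gsolvFromVaporPressure <- function(rho, MW, p, T = 298.15) {
  if (any(c(rho, MW, T) <= 0)) stop("density, weight and temperature must be positive")
  if (p <= 0) stop("vapor pressure must be positive")
  R <- orgsilConstants()$R
  cLiq <- rho / (MW / 1000)               # mol/m^3
  cGas <- (p * 1e5) / (R * T)             # mol/m^3
  -R * T / 1000 * log(cLiq / cGas)
}

#' Aggregate repeated measurements
#'
#' Mean over the available values, with the uncertainty reported as twice
#' the standard error of the mean (about a 95 percent confidence interval)
#' when two or more points exist.  With a single point no uncertainty is
#' reported.
#'
#' @param values numeric vector of measurements (n >= 1).
#' @param sources optional source labels.
#' @return an object of class \code{"aggregateValue"} with \code{mean},
#'   \code{uncertainty} (NA for n = 1), \code{n} and \code{sources}.
#' @export
#' @examples
#' aggregateMeasurements(c(1, 2, 3))$uncertainty   # 2/sqrt(3)
aggregateMeasurements <- function(values, sources = NULL) {
  if (!length(values)) stop("empty input")
  n <- length(values)
  structure(list(mean = mean(values),
                 uncertainty = if (n >= 2) 2 * stats::sd(values) / sqrt(n)
                               else NA_real_,
                 n = n, sources = sources),
            class = "aggregateValue")
}

#' @export
print.aggregateValue <- function(x, ...) {
  if (is.na(x$uncertainty))
    cat(sprintf("%.6g (n = 1, no uncertainty reported)\n", x$mean))
  else
    cat(sprintf("%.6g +/- %.3g (2 SEM, n = %d)\n", x$mean, x$uncertainty, x$n))
  invisible(x)
}
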