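#' Electronic properties of a compound
#'
#' Per-compound electronic data used by the polarization calculus: gas-phase
#' dipole moment, polarizability volume, static dielectric constant and
#' refractive index at the sodium D line.  The infinite-frequency dielectric
#' constant is always derived as \eqn{\epsilon_\infty = n_D^2}; no
#' independent value is accepted, to avoid inconsistent inputs.
#'
#' @param muGas gas-phase dipole moment (debye).
#' @param alpha polarizability volume (Angstrom^3).
#' @param eps static dielectric constant of the liquid (>= 1).
#' @param nD refractive index at the sodium D line (>= 1).
#' @return an object of class \code{"electronicProperties"} with derived
#'   \code{epsInf}.
#' @export
#' @examples
#' w <- electronicProperties(muGas = 1.85, alpha = 1.44, eps = 78.4,
#'                           nD = sqrt(1.78))
electronicProperties <- function(muGas, alpha, eps, nD) {
  if (eps < 1) stop("static dielectric constant must be >= 1")
  if (nD < 1) stop("refractive index must be >= 1")
  if (alpha <= 0) stop("polarizability must be positive")
  structure(list(muGas = muGas, alpha = alpha, eps = eps, nD = nD,
                 epsInf = nD^2),
            class = "electronicProperties")
}

#' @export
print.electronicProperties <- function(x, ...) {
  cat(sprintf("electronicProperties: mu_gas %.3f D, alpha %.3f A^3, eps %.3f, n_D %.4f (eps_inf %.4f)\n",
              x$muGas, x$alpha, x$eps, x$nD, x$epsInf))
  invisible(x)
}

#' Liquid-phase dipole moment from the Onsager continuum model
#'
#' Estimates the dipole moment of a molecule in its own liquid by treating
#' the surroundings as a dielectric continuum, with the cavity radius
#' handled self-consistently so it drops out of the final expression:
#' \deqn{\mu_{Liq} = \mu_{Gas} \frac{(2\epsilon + 1)(\epsilon_\infty + 2)}
#'   {3 (2\epsilon + \epsilon_\infty)}}
#' The enhancement is 1 when \eqn{\epsilon = \epsilon_\infty = 1} (no
#' dielectric response) and grows monotonically with the static dielectric
#' constant.
#'
#' @param props an \code{\link{electronicProperties}} object, or a gas-phase
#'   dipole (D) if \code{eps} and \code{epsInf} are given explicitly.
#' @param eps,epsInf optional explicit dielectric constants (both >= 1).
#' @return liquid-phase dipole moment (debye).
#' @export
#' @examples
#' liquidDipole(1.85, eps = 78.4, epsInf = 1.78)   # water-like enhancement
liquidDipole <- function(props, eps = NULL, epsInf = NULL) {
  if (inherits(props, "electronicProperties")) {
    muGas <- props$muGas
    eps <- eps %||% props$eps
    epsInf <- epsInf %||% props$epsInf
  } else muGas <- props
  if (eps < 1 || epsInf < 1) stop("dielectric constants must be >= 1")
  muGas * (2 * eps + 1) * (epsInf + 2) / (3 * (2 * eps + epsInf))
}

#' Polarization energy of the gas-to-liquid transfer
#'
#' Additive correction for the polarization physics a fixed-charge model
#' cannot represent, with two components:
#' \deqn{E_{Pol} = \frac{(\mu_{Liq} - \mu_{Gas})^2}{2\alpha} -
#'  \frac{\mu_{Liq}^2}{\alpha}
#'  \frac{(\epsilon_\infty - 1)^2}{(2\epsilon_\infty + 1)(\epsilon_\infty + 2)}}
#' The first term is the positive distortion energy, the cost of distorting
#' the molecular wave function from its unpolarized gas state to the
#' polarized liquid state; the second is the negative electronic energy, the
#' favorable interaction of the polarized molecule with the electron clouds
#' of the surrounding liquid, from the Onsager reaction field of a dipole in
#' a spherical cavity with the cavity radius eliminated self-consistently
#' through the polarizability.  Signs refer to a transfer from the gas to
#' the liquid phase.
#'
#' @param props an \code{\link{electronicProperties}} object.
#' @param muLiq liquid dipole moment (D); computed with
#'   \code{\link{liquidDipole}} if omitted.
#' @return an object of class \code{"polarizationResult"} with components
#'   \code{muLiq} (D), \code{distortion} (kJ/mol, >= 0), \code{electronic}
#'   (kJ/mol, <= 0) and \code{ePol} (kJ/mol).
#' @export
polarizationEnergy <- function(props, muLiq = liquidDipole(props)) {
  stopifnot(inherits(props, "electronicProperties"))
  if (props$alpha <= 0) stop("polarizability must be positive")
  k <- orgsilConstants()$kD2A3
  ei <- props$epsInf
  distortion <- k * (muLiq - props$muGas)^2 / (2 * props$alpha)
  electronic <- -k * muLiq^2 * (ei - 1)^2 /
    (props$alpha * (2 * ei + 1) * (ei + 2))
  structure(list(muLiq = muLiq, distortion = distortion,
                 electronic = electronic, ePol = distortion + electronic),
            class = "polarizationResult")
}

#' @export
print.polarizationResult <- function(x, ...) {
  cat(sprintf("polarizationResult: mu_liq %.3f D; distortion %+.3f, electronic %+.3f, E_Pol %+.3f kJ/mol\n",
              x$muLiq, x$distortion, x$electronic, x$ePol))
  invisible(x)
}

#' Simulation summary container
#'
#' Tabular results exported by an external molecular-dynamics engine that
#' the post-processing functions consume: ensemble-average potential
#' energies, box volume, box-dipole samples, mean-square displacement
#' series and box lengths.
#'
#' @param uLiq,uGas average potential energy per mole in the liquid and gas
#'   phases (kJ/mol).
#' @param T temperature (K).
#' @param V box volume (nm^3).
#' @param M box-dipole samples (matrix with 3 columns, debye) or NULL.
#' @param msd optional data.frame(t_ps, msd_nm2).
#' @param L optional vector of box lengths (nm).
#' @return an object of class \code{"simulationSummary"}.
#' @export
simulationSummary <- function(uLiq, uGas, T = 298.15, V = NA_real_,
                              M = NULL, msd = NULL, L = NULL) {
  if (!is.na(V) && V <= 0) stop("box volume must be positive")
  if (T <= 0) stop("temperature must be positive")
  structure(list(uLiq = uLiq, uGas = uGas, T = T, V = V, M = M,
                 msd = msd, L = L),
            class = "simulationSummary")
}

#' Enthalpy of vaporization with polarization correction
#'
#' \deqn{\Delta H_{Vap} = \langle U_{Gas}\rangle - \langle U_{Liq}\rangle +
#'   RT - E_{Pol}}
#' where the potential energies are per mole, RT is the ideal-gas
#' pressure-volume term and \eqn{E_{Pol}} is the gas-to-liquid polarization
#' correction of \code{\link{polarizationEnergy}} (usually negative, so the
#' correction raises the enthalpy of polar liquids).
#'
#' @param summary a \code{\link{simulationSummary}} (needs \code{uLiq},
#'   \code{uGas}, \code{T}).
#' @param ePol polarization energy (kJ/mol) or a
#'   \code{"polarizationResult"}.
#' @return enthalpy of vaporization (kJ/mol).
#' @export
#' @examples
#' s <- simulationSummary(uLiq = -10, uGas = -10, T = 298.15)
#' enthalpyOfVaporization(s, 0)   # just RT = 2.479
enthalpyOfVaporization <- function(summary, ePol = 0) {
  stopifnot(inherits(summary, "simulationSummary"))
  if (is.null(summary$uGas) || is.na(summary$uGas))
    stop("gas-phase potential energy is required")
  if (inherits(ePol, "polarizationResult")) ePol <- ePol$ePol
  RT <- orgsilConstants()$R * summary$T / 1000
  summary$uGas - summary$uLiq + RT - ePol
}

#' Polarization-corrected dielectric constant
#'
#' A fixed-charge simulation measures the dielectric response of the
#' effective model dipole and misses the purely electronic response of the
#' medium.  The corrected estimate rescales the orientational part by the
#' squared ratio of the real liquid dipole to the model dipole and restores
#' the electronic part through \eqn{\epsilon_\infty}:
#' \deqn{\epsilon = \epsilon_\infty +
#'   \left(\frac{\mu_{Liq}}{\mu_{Model}}\right)^2 (\epsilon_{Simul} - 1)}
#' With \eqn{\epsilon_\infty = 1} and a model dipole equal to the real
#' liquid dipole the correction is the identity.
#'
#' @param epsSimul dielectric constant from the simulation (>= 1).
#' @param epsInf infinite-frequency dielectric constant (squared refractive
#'   index).
#' @param muLiq real liquid dipole moment (D).
#' @param muModel dipole moment of the model molecule (D).  For nonpolar
#'   molecules (both dipoles below \code{tol}) the ratio is taken as 1.
#' @param tol dipole magnitude below which a molecule counts as nonpolar.
#' @return corrected dielectric constant.
#' @export
#' @examples
#' correctDielectric(1.5, epsInf = 1, muLiq = 2, muModel = 2)  # identity
correctDielectric <- function(epsSimul, epsInf, muLiq, muModel, tol = 1e-9) {
  if (epsSimul < 1) stop("simulated dielectric constant must be >= 1")
  if (epsInf < 1) stop("epsilon_infinity must be >= 1")
  ratio2 <- if (abs(muLiq) < tol && abs(muModel) < tol) 1
            else (muLiq / muModel)^2
  epsInf + ratio2 * (epsSimul - 1)
}

#' Polarization-corrected solvation free energy
#'
#' Adds the gas-to-liquid polarization energy to an alchemically computed
#' solvation free energy: \eqn{\Delta G_{Solv} = \Delta G_{Simul} + E_{Pol}}.
#'
#' @param dGSimul solvation free energy from simulation (kJ/mol).
#' @param ePol polarization energy (kJ/mol) or a
#'   \code{"polarizationResult"}.
#' @return corrected solvation free energy (kJ/mol).
#' @export
correctSolvationFreeEnergy <- function(dGSimul, ePol) {
  if (inherits(ePol, "polarizationResult")) ePol <- ePol$ePol
  dGSimul + ePol
}

#' Dielectric constant from box-dipole fluctuations
#'
#' \deqn{\epsilon_{Simul} = 1 + \frac{\langle M^2\rangle - \langle M\rangle^2}
#'   {3 \epsilon_0 V k_B T}}
#' where M is the dipole moment of the entire simulation box.  The
#' uncertainty is estimated by block averaging (five blocks, twice the
#' standard error of the block means).
#'
#' @param M box-dipole samples: matrix with three columns (D) or a numeric
#'   vector treated as a single component with the other two zero.
#' @param V box volume (nm^3).
#' @param T temperature (K).
#' @param blocks number of blocks for the uncertainty estimate.
#' @return list with \code{eps}, \code{uncertainty} and \code{n}.
#' @export
dielectricFromBoxDipole <- function(M, V, T = 298.15, blocks = 5) {
  if (V <= 0) stop("box volume must be positive")
  if (is.vector(M)) M <- cbind(M, 0, 0)
  n <- nrow(M)
  if (n < 2) stop("need at least two dipole samples")
  cst <- orgsilConstants()
  prefac <- cst$debye^2 / (3 * cst$eps0 * (V * 1e-27) * cst$kB * T)
  fluct <- function(m) {
    mu2 <- mean(rowSums(m^2))
    mbar <- colMeans(m)
    mu2 - sum(mbar^2)
  }
  eps <- 1 + prefac * fluct(M)
  bs <- split(seq_len(n), cut(seq_len(n), blocks, labels = FALSE))
  be <- vapply(bs, function(ix) 1 + prefac * fluct(M[ix, , drop = FALSE]), 0)
  list(eps = eps, uncertainty = 2 * stats::sd(be) / sqrt(length(be)), n = n)
}

#' Self-diffusion coefficient from the mean-square displacement
#'
#' Einstein relation: the diffusion coefficient is one sixth of the slope of
#' the mean-square displacement against time over the fitted window.
#'
#' @param t time (ps).
#' @param msd mean-square displacement (nm^2).
#' @param window optional c(tmin, tmax) restricting the fit (ps).
#' @return list with \code{D} (m^2/s), \code{se} (fit standard error of D)
#'   and \code{slope} (nm^2/ps).
#' @export
#' @examples
#' t <- 0:100
#' diffusionFromMSD(t, 6 * 3.8e-3 * t)$D   # 3.8e-9 m^2/s
diffusionFromMSD <- function(t, msd, window = NULL) {
  stopifnot(length(t) == length(msd))
  if (any(msd < 0)) stop("MSD must be non-negative")
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; msd <- msd[keep]
  }
  if (length(t) < 2) stop("fit window too short (need at least two points)")
  fit <- stats::lm(msd ~ t)
  slope <- stats::coef(fit)[["t"]]
  se <- suppressWarnings(summary(fit))$coefficients["t", "Std. Error"]
  ## nm^2/ps = 1e-6 m^2/s
  list(D = slope / 6 * 1e-6, se = se / 6 * 1e-6, slope = slope)
}

#' Extrapolate diffusion to infinite box size
#'
#' Periodic boundary conditions depress the self-diffusion coefficient in
#' proportion to the inverse box length.  Fitting D against 1/L and taking
#' the intercept at 1/L = 0 removes the finite-size effect.
#'
#' @param L box lengths (nm), at least two distinct values.
#' @param D diffusion coefficients at each L (m^2/s).
#' @return list with \code{Dinf}, \code{se} (intercept standard error; NA
#'   for a two-point fit) and \code{slope}.
#' @export
#' @examples
#' extrapolateDiffusionInfiniteBox(c(2, 4, 8), c(1.5, 1.75, 1.875))$Dinf  # 2
extrapolateDiffusionInfiniteBox <- function(L, D) {
  stopifnot(length(L) == length(D))
  if (length(unique(L)) < 2) stop("need at least two distinct box lengths")
  invL <- 1 / L
  fit <- stats::lm(D ~ invL)
  co <- suppressWarnings(summary(fit))$coefficients
  list(Dinf = stats::coef(fit)[["(Intercept)"]],
       se = if (nrow(co) && length(L) > 2) co["(Intercept)", "Std. Error"] else NA_real_,
       slope = stats::coef(fit)[["invL"]])
}
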