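#' Torsion scan container
#'
#' Bundles a quantum-chemical dihedral energy scan with the molecule's
#' topology and the dihedral being parametrized.  The default protocol is 12
#' points in 30-degree increments over the full 360-degree range.
#'
#' @param topology a \code{\linkS4class{UATopology}}.
#' @param dihedral integer vector c(i, j, k, l) naming the scanned dihedral.
#' @param angle numeric vector of scan angles (degrees).
#' @param energy QM energies at each angle (kJ/mol).
#' @return an object of class \code{"torsionScan"}.
#' @export
torsionScan <- function(topology, dihedral, angle, energy) {
  stopifnot(length(angle) == length(energy), all(is.finite(energy)))
  if (diff(range(angle)) < 330 - 1e-9)
    warning("scan grid does not cover the full 360-degree range")
  structure(list(topology = topology, dihedral = dihedral,
                 angle = angle, energy = energy),
            class = "torsionScan")
}

#' @export
print.torsionScan <- function(x, ...) {
  cat(sprintf("torsionScan: %d points on %s, dihedral %s\n",
              length(x$angle), x$topology@name,
              paste(x$dihedral, collapse = "-")))
  invisible(x)
}

#' Isolate the torsional target from a QM energy scan
#'
#' Subtracts from the QM profile every classical contribution that is not
#' the dihedral being fitted: the non-excluded intramolecular
#' Lennard-Jones and Coulomb energies along the scan, and the energies of
#' already-parametrized torsion classes that rotate with the scanned bond.
#' The residual is shifted so that its minimum is zero (profiles are
#' normalized before fitting; the constant is absorbed by C0).
#'
#' @param scan a \code{\link{torsionScan}}.
#' @param fitted character vector of dihedral classes whose coefficients are
#'   available; defaults to every class present in the topology.  If a
#'   non-target torsion in the scan belongs to a class not listed here, a
#'   dependency error is raised (that class must be fitted first).
#' @return data.frame with columns \code{angle}, \code{residual} and the
#'   subtracted components \code{E_LJ}, \code{E_Coulomb}, \code{E_other}.
#' @export
isolateTorsionTarget <- function(scan, fitted = NULL) {
  stopifnot(inherits(scan, "torsionScan"))
  top <- scan$topology
  d <- scan$dihedral
  tr <- top@torsions
  target <- which(tr$i == d[1] & tr$j == d[2] & tr$k == d[3] & tr$l == d[4] |
                  tr$i == d[4] & tr$j == d[3] & tr$k == d[2] & tr$l == d[1])
  if (!length(target))
    stop("scanned dihedral not found among the topology torsions")
  target <- target[1]
  others <- setdiff(seq_len(nrow(tr)), target)
  if (!is.null(fitted)) {
    missing <- setdiff(unique(tr$class[others]), fitted)
    if (length(missing))
      stop("dependency error: torsion class(es) not yet fitted: ",
           paste(missing, collapse = ", "))
  }
  coords <- buildConformation(top)
  out <- data.frame(angle = scan$angle, residual = NA_real_,
                    E_LJ = NA_real_, E_Coulomb = NA_real_, E_other = NA_real_)
  for (r in seq_along(scan$angle)) {
    xyz <- setDihedral(top, coords, d, scan$angle[r])
    nb <- intramolecularNonbonded(top, xyz)
    eo <- torsionEnergy(top, xyz, skip = target)
    out$E_LJ[r] <- nb$lj
    out$E_Coulomb[r] <- nb$coulomb
    out$E_other[r] <- eo
    out$residual[r] <- scan$energy[r] - nb$total - eo
  }
  out$residual <- out$residual - min(out$residual)
  out
}

#' Fit Ryckaert-Bellemans coefficients to a torsion profile
#'
#' Unweighted least squares of the six-coefficient cosine power series on a
#' residual profile.  With 12 distinct scan angles the design has full rank
#' (seven distinct cosine values) and profiles generated from the model class
#' are recovered exactly.
#'
#' @param angle dihedral angles (degrees); at least 6 distinct values.
#' @param energy profile energies (kJ/mol).
#' @param fixZero optional integer vector of coefficient orders (0..5)
#'   constrained to zero, e.g. \code{c(4, 5)} for a reproduction study.
#' @return list with \code{C} (length-6 coefficient vector), \code{rms}
#'   residual, \code{fitted} values and \code{residuals}.
#' @export
#' @examples
#' C <- c(1.364, 4.093, 0, -5.457, 0, 0)
#' grid <- seq(0, 330, 30)
#' fit <- fitRBCoefficients(grid, rbEnergy(grid, C))
#' max(abs(fit$C - C)) < 1e-10
fitRBCoefficients <- function(angle, energy, fixZero = integer()) {
  stopifnot(length(angle) == length(energy))
  if (length(unique(round(angle, 9))) < 6 - length(fixZero))
    stop("need at least as many distinct angles as free coefficients")
  x <- cos((angle - 180) * pi / 180)
  X <- outer(x, 0:5, `^`)
  free <- setdiff(0:5, fixZero)
  Xf <- X[, free + 1, drop = FALSE]
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf))
    stop("rank-deficient design: scan angles make cosine powers collide; add angles or constrain coefficients")
  beta <- qr.coef(qrX, energy)
  C <- numeric(6)
  C[free + 1] <- beta
  fittedv <- as.numeric(X %*% C)
  res <- energy - fittedv
  list(C = C, rms = sqrt(mean(res^2)), fitted = fittedv, residuals = res)
}

#' Fit a dihedral class from a QM scan
#'
#' Convenience wrapper: isolates the torsional residual of a scan with
#' \code{\link{isolateTorsionTarget}} and fits it with
#' \code{\link{fitRBCoefficients}}.
#'
#' @inheritParams isolateTorsionTarget
#' @inheritParams fitRBCoefficients
#' @return the fit list, with the residual profile attached as
#'   \code{$profile}.
#' @export
fitDihedralFromScan <- function(scan, fitted = NULL, fixZero = integer()) {
  prof <- isolateTorsionTarget(scan, fitted = fitted)
  fit <- fitRBCoefficients(prof$angle, prof$residual, fixZero = fixZero)
  fit$profile <- prof
  fit
}
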