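#' Lorentz-Berthelot combination of Lennard-Jones parameters
#'
#' Unlike-pair parameters: arithmetic mean of the collision diameters and
#' geometric mean of the well depths.
#'
#' @param sigma1,epsilon1,sigma2,epsilon2 per-site parameters (nm, kJ/mol);
#'   vectorized.
#' @return list with \code{sigma} and \code{epsilon}.
#' @export
#' @examples
#' combineLJ(0.580, 0.108, 0.235, 1.344)  # sigma 0.4075, epsilon 0.38099
combineLJ <- function(sigma1, epsilon1, sigma2, epsilon2) {
  if (any(c(sigma1, sigma2, epsilon1, epsilon2) < 0))
    stop("LJ parameters must be non-negative")
  list(sigma = (sigma1 + sigma2) / 2,
       epsilon = sqrt(epsilon1 * epsilon2))
}

#' Ryckaert-Bellemans torsion energy
#'
#' Power series in the cosine of the dihedral angle,
#' \eqn{E(\phi) = \sum_{n=0}^{5} C_n \cos^n(\psi)} with \eqn{\psi = \phi - 180^\circ},
#' so that the trans conformation sits at \eqn{\phi = 180^\circ}
#' (\eqn{\cos\psi = 1}).  This is the convention of the exported topology
#' dialect, so fitted coefficients round-trip through the files unchanged.
#'
#' @param phi dihedral angle(s) in degrees.
#' @param C numeric vector of six coefficients C0..C5 (kJ/mol).
#' @return energy (kJ/mol), vectorized over \code{phi}.
#' @export
#' @examples
#' rbEnergy(180, c(1.224, 3.672, 0, -4.895, 0, 0))  # ~0 at trans
rbEnergy <- function(phi, C) {
  stopifnot(length(C) == 6, all(is.finite(C)))
  x <- cos((phi - 180) * pi / 180)
  C[1] + C[2] * x + C[3] * x^2 + C[4] * x^3 + C[5] * x^4 + C[6] * x^5
}

#' Intramolecular nonbonded energy of a conformation
#'
#' Sums the 12-6 Lennard-Jones and Coulomb energies over all non-excluded
#' intramolecular pairs (pairs separated by more than three bonds), using
#' Lorentz-Berthelot combination and the fixed point charges.  No cutoff and
#' no periodicity: this evaluator serves single-molecule scans and tests;
#' bulk simulation is delegated to an external engine.
#'
#' @param topology a \code{\linkS4class{UATopology}}.
#' @param coords n x 3 coordinate matrix (nm).
#' @param fCoulomb Coulomb prefactor (kJ mol^-1 nm e^-2); the CODATA value
#'   by default, configurable for cross-checks.
#' @return list with components \code{lj}, \code{coulomb} and \code{total}
#'   (kJ/mol).
#' @export
intramolecularNonbonded <- function(topology, coords,
                                    fCoulomb = orgsilConstants()$fCoulomb) {
  pairs <- nonbondedPairs(topology)
  eLJ <- 0; eC <- 0
  s <- topology@sites
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    rij <- .norm(coords[i, ] - coords[j, ])
    if (rij < 1e-6)
      stop(sprintf("overlapping sites %d and %d (r = %.2g nm)", i, j, rij))
    p <- combineLJ(s$sigma[i], s$epsilon[i], s$sigma[j], s$epsilon[j])
    if (p$epsilon > 0) {
      sr6 <- (p$sigma / rij)^6
      eLJ <- eLJ + 4 * p$epsilon * (sr6^2 - sr6)
    }
    eC <- eC + fCoulomb * s$charge[i] * s$charge[j] / rij
  }
  list(lj = eLJ, coulomb = eC, total = eLJ + eC)
}

#' Total torsion energy of a conformation
#'
#' @param topology a \code{\linkS4class{UATopology}}.
#' @param coords n x 3 coordinate matrix (nm).
#' @param skip optional integer vector of torsion rows to leave out (used
#'   when isolating a target dihedral from a scan).
#' @return torsion energy (kJ/mol).
#' @export
torsionEnergy <- function(topology, coords, skip = integer()) {
  tr <- topology@torsions
  total <- 0
  for (r in setdiff(seq_len(nrow(tr)), skip)) {
    phi <- measureDihedral(coords, tr$i[r], tr$j[r], tr$k[r], tr$l[r])
    total <- total + rbEnergy(phi, topology@torsionC[r, ])
  }
  total
}

#' Classical torsion profile of a rotatable bond
#'
#' Rigidly rotates the molecule about the central bond of the given dihedral
#' over an angle grid (default 12 points in 30-degree steps over the full
#' 360-degree range) and evaluates the total classical energy at each point,
#' decomposed into torsion, Lennard-Jones and Coulomb components.  Bond and
#' angle terms are constant over a rigid scan and are omitted.
#'
#' @param topology a \code{\linkS4class{UATopology}}.
#' @param dihedral integer vector c(i, j, k, l).
#' @param angles grid of dihedral angles (degrees).
#' @param coords starting conformation; equilibrium embedding by default.
#' @return data.frame with columns \code{angle}, \code{E_total},
#'   \code{E_torsion}, \code{E_LJ}, \code{E_Coulomb} (kJ/mol).
#' @export
torsionProfile <- function(topology, dihedral, angles = seq(0, 330, by = 30),
                           coords = buildConformation(topology)) {
  out <- data.frame(angle = angles, E_total = NA_real_, E_torsion = NA_real_,
                    E_LJ = NA_real_, E_Coulomb = NA_real_)
  for (r in seq_along(angles)) {
    xyz <- setDihedral(topology, coords, dihedral, angles[r])
    nb <- intramolecularNonbonded(topology, xyz)
    et <- torsionEnergy(topology, xyz)
    out$E_torsion[r] <- et
    out$E_LJ[r] <- nb$lj
    out$E_Coulomb[r] <- nb$coulomb
    out$E_total[r] <- et + nb$total
  }
  out
}
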