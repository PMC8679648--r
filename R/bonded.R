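#' Enumerate and parametrize bonded terms
#'
#' Maps every bond of a typed united-atom graph to a rigid-constraint length,
#' every bonded triple to a harmonic angle term and every bonded quadruple to
#' a Ryckaert-Bellemans torsion class.  Bonds are treated as rigid
#' constraints (the stretching force constant is effectively infinite), so
#' only the length is assigned.  A bonded term with no table entry raises a
#' "missing parameter" error naming the offending atom-type tuple.
#'
#' @param typed a typed united-atom \code{\linkS4class{MoleculeGraph}}.
#' @param params a \code{\linkS4class{ParameterSet}}.
#' @return list with data.frames \code{bonds} (i, j, r0, key),
#'   \code{angles} (i, j, k, theta0, kAngle, key), \code{torsions}
#'   (i, j, k, l, class) and matrix \code{torsionC} (C0..C5 per torsion).
#' @export
assignBondedTerms <- function(typed, params = defaultParameters()) {
  stopifnot(is(typed, "MoleculeGraph"))
  if (!any(nzchar(typed@types))) stop("run assignAtomTypes() first")
  ty <- typed@types
  n <- length(ty)
  adj <- .adjacency(n, typed@bonds)
  b <- typed@bonds

  bonds <- data.frame(i = integer(), j = integer(), r0 = numeric(),
                      key = character())
  for (r in seq_len(nrow(b))) {
    i <- b[r, 1]; j <- b[r, 2]
    bonds <- rbind(bonds, data.frame(
      i = min(i, j), j = max(i, j),
      r0 = .lookupBond(params, ty[i], ty[j]),
      key = .bondKey(ty[i], ty[j])))
  }

  angles <- data.frame(i = integer(), j = integer(), k = integer(),
                       theta0 = numeric(), kAngle = numeric(), key = character())
  for (j in seq_len(n)) {
    nb <- sort(adj[[j]])
    if (length(nb) < 2L) next
    for (a in seq_len(length(nb) - 1L)) for (c3 in (a + 1L):length(nb)) {
      i <- nb[a]; k <- nb[c3]
      p <- .lookupAngle(params, ty[i], ty[j], ty[k])
      angles <- rbind(angles, data.frame(
        i = i, j = j, k = k, theta0 = p$theta0, kAngle = p$kAngle,
        key = paste(.bondedClass(c(ty[i], ty[j], ty[k])), collapse = "-")))
    }
  }

  tors <- data.frame(i = integer(), j = integer(), k = integer(),
                     l = integer(), class = character())
  torsC <- matrix(numeric(), ncol = 6)
  for (r in seq_len(nrow(b))) {
    j <- b[r, 1]; k <- b[r, 2]
    for (i in adj[[j]]) {
      if (i == k) next
      for (l in adj[[k]]) {
        if (l == j || l == i) next
        p <- .lookupTorsion(params, ty[i], ty[j], ty[k], ty[l])
        tors <- rbind(tors, data.frame(i = i, j = j, k = k, l = l,
                                       class = p$class))
        torsC <- rbind(torsC, p$C)
      }
    }
  }
  rownames(tors) <- NULL
  colnames(torsC) <- paste0("C", 0:5)
  list(bonds = bonds, angles = angles, torsions = tors, torsionC = torsC)
}

#' Assign per-site Lennard-Jones parameters
#'
#' Silicon draws its entry from the tabulated Si^k series matching its count
#' of oxygenated substituents (the table stores the sigma-scaled values
#' verbatim); the oxygen types take their tabulated entries; CH_x sites take
#' the carried-over alkane constants; the hydroxyl hydrogen is a charge-only
#' site (sigma = epsilon = 0).
#'
#' @param typed a typed united-atom \code{\linkS4class{MoleculeGraph}}.
#' @param params a \code{\linkS4class{ParameterSet}}.
#' @return data.frame with columns \code{sigma} (nm), \code{epsilon}
#'   (kJ/mol), one row per site.
#' @export
assignLJ <- function(typed, params = defaultParameters()) {
  stopifnot(is(typed, "MoleculeGraph"))
  if (!any(nzchar(typed@types))) stop("run assignAtomTypes() first")
  ty <- typed@types
  n <- length(ty)
  sigma <- numeric(n); eps <- numeric(n)
  carbon <- c("CH3", "CH2", "CH", "C")
  for (i in seq_len(n)) {
    t <- ty[i]
    if (t == "Si") {
      k <- typed@siK[i]
      idx <- match(paste0("Si", k), params@lj$type)
      if (is.na(idx))
        stop(sprintf("no LJ entry for silicon with %d oxygenated substituents", k))
      sigma[i] <- params@lj$sigma[idx]; eps[i] <- params@lj$epsilon[idx]
    } else if (t %in% c("O_C", "O_H", "O_B", "H_O")) {
      idx <- match(t, params@lj$type)
      sigma[i] <- params@lj$sigma[idx]; eps[i] <- params@lj$epsilon[idx]
    } else if (t %in% carbon) {
      idx <- match(t, params@alkaneLJ$type)
      if (is.na(idx))
        stop(sprintf("missing alkane LJ constants for %s: supply them in the alkane_lj block of the parameter configuration", t))
      sigma[i] <- params@alkaneLJ$sigma[idx]; eps[i] <- params@alkaneLJ$epsilon[idx]
    } else stop("untyped site ", i)
  }
  data.frame(sigma = sigma, epsilon = eps)
}
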