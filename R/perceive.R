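#' Collapse aliphatic hydrogens into united-atom sites
#'
#' Merges every hydrogen bonded to a carbon into that carbon, relabelling the
#' carbon \code{CH3}, \code{CH2}, \code{CH} or \code{C} by the number of
#' hydrogens absorbed.  Hydroxyl hydrogens (bonded to oxygen) remain explicit
#' interaction sites labelled \code{H_O}.  Heavy-atom connectivity is
#' preserved.
#'
#' @param graph a \code{\linkS4class{MoleculeGraph}} with explicit hydrogens.
#' @return a united-atom \code{\linkS4class{MoleculeGraph}} whose
#'   \code{labels} slot is filled.
#' @export
#' @examples
#' ua <- perceiveUnitedAtoms(siliconMolecule("Met3SiOH"))
#' natoms(ua)  # Si + 3 CH3 + O + H
perceiveUnitedAtoms <- function(graph) {
  stopifnot(is(graph, "MoleculeGraph"))
  el <- graph@elements
  n <- length(el)
  adj <- .adjacency(n, graph@bonds)
  hIdx <- which(el == "H")
  labels <- character(n)
  for (h in hIdx) {
    nb <- adj[[h]]
    if (length(nb) != 1L)
      stop(sprintf("malformed input: hydrogen %d bonded to %d atoms",
                   h, length(nb)))
    if (el[nb] == "Si")
      stop(sprintf("out of scope: hydrogen %d bonded to silicon (SiH_x groups are not supported)", h))
    if (el[nb] == "H")
      stop("malformed input: H-H bond")
  }
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (el[i] == "C") {
      hs <- adj[[i]][el[adj[[i]]] == "H"]
      keep[hs] <- FALSE
      labels[i] <- c("C", "CH", "CH2", "CH3", "CH4")[length(hs) + 1L]
      if (labels[i] == "CH4") stop("methane is not an organosilicon site")
    } else if (el[i] == "Si") {
      labels[i] <- "Si"
    } else if (el[i] == "O") {
      labels[i] <- "O"
    } else if (el[i] == "H") {
      nb <- adj[[i]]
      if (el[nb] == "O") labels[i] <- "H_O"   # retained explicit hydroxyl H
    }
  }
  newIdx <- cumsum(keep)
  b <- graph@bonds
  bKeep <- keep[b[, 1]] & keep[b[, 2]]
  newBonds <- cbind(newIdx[b[bKeep, 1]], newIdx[b[bKeep, 2]])
  out <- moleculeGraph(graph@name, el[keep],
                       matrix(as.integer(newBonds), ncol = 2),
                       coords = if (!is.null(graph@coords)) graph@coords[keep, , drop = FALSE])
  out@labels <- labels[keep]
  out
}

#' Assign organosilicon atom types
#'
#' Classifies every oxygen of a united-atom graph as silanol (\code{O_H},
#' Si-O-H), alkoxy (\code{O_C}, Si-O-C) or bridging siloxane (\code{O_B},
#' Si-O-Si), and annotates every silicon with the number \code{k} of
#' oxygen-containing substituent groups (so \code{Si^3} is a silicon with
#' three oxygenated substituents).  CH_x labels carry through unchanged; the
#' charge rules read their context (silicon- or alkoxy-adjacency) off the
#' typed graph.
#'
#' @param ua a united-atom \code{\linkS4class{MoleculeGraph}} from
#'   \code{\link{perceiveUnitedAtoms}}.
#' @return the graph with \code{types} and \code{siK} filled.
#' @export
#' @examples
#' typed <- assignAtomTypes(perceiveUnitedAtoms(siliconMolecule("SiOMet4")))
#' typed@siK[typed@types == "Si"]  # 4 oxygenated substituents
assignAtomTypes <- function(ua) {
  stopifnot(is(ua, "MoleculeGraph"))
  if (!any(nzchar(ua@labels)))
    stop("run perceiveUnitedAtoms() before atom typing")
  lab <- ua@labels
  n <- length(lab)
  adj <- .adjacency(n, ua@bonds)
  types <- lab
  carbon <- c("CH3", "CH2", "CH", "C")
  for (i in which(lab == "O")) {
    nb <- adj[[i]]
    if (length(nb) != 2L)
      stop(sprintf("atom %d: oxygen with valence %d (expected 2)", i, length(nb)))
    nbl <- lab[nb]
    if (!any(nbl == "Si"))
      stop(sprintf("out of scope: oxygen %d is not bonded to silicon", i))
    other <- nbl[which(nbl != "Si")[1]]
    if (sum(nbl == "Si") == 2L) types[i] <- "O_B"
    else if (other == "H_O") types[i] <- "O_H"
    else if (other %in% carbon) types[i] <- "O_C"
    else stop(sprintf("out of scope: oxygen %d bonded to unsupported neighbor %s",
                      i, other))
  }
  siK <- rep(NA_integer_, n)
  for (i in which(lab == "Si")) {
    nb <- adj[[i]]
    if (length(nb) != 4L)
      stop(sprintf("out of scope: silicon %d has %d substituents (must be tetrahedral)",
                   i, length(nb)))
    nbl <- lab[nb]
    bad <- nb[!(nbl %in% c(carbon, "O"))]
    if (length(bad))
      stop(sprintf("out of scope: silicon %d bonded to unsupported atom %d (%s)",
                   i, bad[1], lab[bad[1]]))
    siK[i] <- sum(nbl == "O")
  }
  ua@types <- types
  ua@siK <- siK
  validObject(ua)
  ua
}
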