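#' Build a complete united-atom topology
#'
#' Composes the full parametrization pipeline: united-atom perception, atom
#' typing, point-charge assignment with the silicon neutrality closure,
#' bonded-term enumeration, Lennard-Jones assignment and generation of the
#' nonbonded exclusion list.  All pairs of sites separated by three bonds or
#' fewer are excluded (1-4 interactions are removed from the force field);
#' 1-5 and more distant intramolecular pairs interact through the ordinary
#' nonbonded potentials.
#'
#' @param graph a \code{\linkS4class{MoleculeGraph}}; either all-atom (with
#'   explicit hydrogens) or already united-atom and typed.
#' @param params a \code{\linkS4class{ParameterSet}}.
#' @return a validated \code{\linkS4class{UATopology}} carrying a
#'   \code{"report"} attribute with the neutrality residual and term counts.
#' @export
#' @examples
#' top <- buildTopology(siliconMolecule("Met4Si"))
#' sum(charges(top))     # 0
#' nrow(top@torsions)    # 0: every pair is within three bonds
buildTopology <- function(graph, params = defaultParameters()) {
  stopifnot(is(graph, "MoleculeGraph"))
  withCallingHandlers({
    if (any(graph@elements == "H" & !nzchar(graph@labels)))
      graph <- perceiveUnitedAtoms(graph)
    else if (!any(nzchar(graph@labels)))
      graph@labels <- graph@elements   # heavy-atom-only input
    if (!any(nzchar(graph@types))) graph <- assignAtomTypes(graph)
    q <- assignCharges(graph, params)
    bonded <- assignBondedTerms(graph, params)
    lj <- assignLJ(graph, params)
  }, error = function(e) {
    stop(sprintf("[%s] %s", graph@name, conditionMessage(e)), call. = FALSE)
  })

  n <- length(graph@types)
  excl <- excludedPairs(graph@bonds, n)

  sitesDf <- data.frame(type = graph@types, siK = graph@siK,
                        charge = q, sigma = lj$sigma, epsilon = lj$epsilon)
  top <- new("UATopology", name = graph@name, sites = sitesDf,
             bonds = bonded$bonds, angles = bonded$angles,
             torsions = bonded$torsions, torsionC = bonded$torsionC,
             exclusions = excl, validated = TRUE)
  attr(top, "report") <- list(
    molecule = graph@name,
    netCharge = sum(q),
    nSites = n,
    nConstraints = nrow(bonded$bonds),
    nAngles = nrow(bonded$angles),
    nTorsions = nrow(bonded$torsions),
    nExclusions = nrow(excl))
  top
}

#' Nonbonded exclusion list of a bond graph
#'
#' All unordered site pairs separated by \code{depth} bonds or fewer.
#' With the default depth of 3 this removes 1-2, 1-3 and 1-4 interactions
#' from the nonbonded sums; on a path graph of n sites the list has exactly
#' (n-1) + (n-2) + (n-3) pairs.
#'
#' @param bonds two-column integer matrix of bonds.
#' @param n number of sites.
#' @param depth maximum bond separation to exclude.
#' @return two-column integer matrix of excluded pairs (i < j).
#' @export
#' @examples
#' excludedPairs(cbind(1:3, 2:4), 4)   # path of 4: all 6 pairs excluded
excludedPairs <- function(bonds, n, depth = 3L) {
  adj <- .adjacency(n, bonds)
  excl <- matrix(integer(), ncol = 2)
  for (i in seq_len(n)) {
    d <- .graphDistances(adj, i)
    js <- which(d >= 1 & d <= depth & seq_len(n) > i)
    if (length(js)) excl <- rbind(excl, cbind(i, js))
  }
  colnames(excl) <- c("i", "j")
  excl
}

#' Nonbonded (non-excluded) intramolecular pairs
#'
#' @param topology a \code{\linkS4class{UATopology}}.
#' @return two-column matrix of site pairs (i < j) that interact through the
#'   Lennard-Jones and Coulomb potentials.
#' @export
nonbondedPairs <- function(topology) {
  n <- nrow(topology@sites)
  if (n < 2) return(matrix(integer(), ncol = 2))
  all <- t(utils::combn(n, 2))
  key <- function(m) paste(m[, 1], m[, 2])
  keep <- !(key(all) %in% key(topology@exclusions))
  all[keep, , drop = FALSE]
}
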