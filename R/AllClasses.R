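#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Chemical graph of a molecule
#'
#' A \code{MoleculeGraph} holds the element symbols, the covalent bond list
#' and (optionally) coordinates of a molecule.  The same class carries the
#' molecule through the topology-building pipeline: after united-atom
#' perception the \code{labels} slot holds the interaction-site labels
#' (\code{CH3}, \code{CH2}, \code{CH}, \code{C}, \code{Si}, \code{O}, \code{H_O}),
#' and after atom typing the \code{types} slot refines oxygens into
#' \code{O_C} (alkoxy), \code{O_H} (silanol) and \code{O_B} (bridging
#' siloxane) and annotates each silicon with its count of oxygenated
#' substituents in \code{siK}.
#'
#' Scope restriction: silicon atoms must be tetrahedrally substituted (four
#' heavy-atom substituents, no Si-H).
#'
#' @slot name molecule name.
#' @slot elements character vector of element symbols ("Si", "O", "C", "H").
#' @slot bonds integer matrix with two columns, one row per bond.
#' @slot coords numeric matrix (n x 3, nm) or NULL.
#' @slot labels character vector of united-atom site labels ("" before
#'   perception).
#' @slot types character vector of final atom types ("" before typing).
#' @slot siK integer vector: for silicon sites, the number of oxygenated
#'   substituent groups; NA elsewhere.
#' @export
setClass("MoleculeGraph",
  representation(
    name = "character",
    elements = "character",
    bonds = "matrix",
    coords = "matrixOrNULL",
    labels = "character",
    types = "character",
    siK = "integer"
  ),
  prototype(coords = NULL)
)

setValidity("MoleculeGraph", function(object) {
  n <- length(object@elements)
  msgs <- character()
  b <- object@bonds
  if (n == 0L) msgs <- c(msgs, "molecule has no atoms")
  if (length(b) && (any(b < 1L) || any(b > n)))
    return("bond indices reference atoms outside the molecule")
  if (length(b) && any(b[, 1] == b[, 2]))
    msgs <- c(msgs, "an atom cannot be bonded to itself")
  if (n > 1L && !.isConnected(n, b))
    msgs <- c(msgs, "molecule graph is not connected")
  if (!is.null(object@coords) && nrow(object@coords) != n)
    msgs <- c(msgs, "coordinate count does not match atom count")
  if (length(object@labels) != n || length(object@types) != n ||
      length(object@siK) != n)
    msgs <- c(msgs, "annotation slots must match the atom count")
  if (length(msgs)) msgs else TRUE
})

#' Fully parametrized united-atom topology
#'
#' The end product of \code{\link{buildTopology}}: interaction sites with
#' point charges and Lennard-Jones parameters, rigid-bond constraints,
#' harmonic angles, Ryckaert-Bellemans torsions and the nonbonded exclusion
#' list (all pairs separated by three bonds or fewer).
#'
#' @slot name molecule name.
#' @slot sites data.frame with columns \code{type}, \code{siK},
#'   \code{charge} (e), \code{sigma} (nm), \code{epsilon} (kJ/mol).
#' @slot bonds data.frame with columns \code{i}, \code{j}, \code{r0} (nm),
#'   \code{key}; bonds are treated as rigid constraints.
#' @slot angles data.frame with columns \code{i}, \code{j}, \code{k},
#'   \code{theta0} (deg), \code{kAngle} (kJ mol^-1 rad^-2), \code{key}.
#' @slot torsions data.frame with columns \code{i}, \code{j}, \code{k},
#'   \code{l}, \code{class}.
#' @slot torsionC numeric matrix (one row per torsion, columns C0..C5, kJ/mol).
#' @slot exclusions integer matrix with two columns (i < j).
#' @slot validated logical, set by \code{\link{buildTopology}} once the
#'   completeness and neutrality checks have passed.
#' @export
setClass("UATopology",
  representation(
    name = "character",
    sites = "data.frame",
    bonds = "data.frame",
    angles = "data.frame",
    torsions = "data.frame",
    torsionC = "matrix",
    exclusions = "matrix",
    validated = "logical"
  ),
  prototype(validated = FALSE)
)

setValidity("UATopology", function(object) {
  msgs <- character()
  s <- object@sites
  need <- c("type", "siK", "charge", "sigma", "epsilon")
  if (!all(need %in% names(s)))
    return(paste("sites must have columns", paste(need, collapse = ", ")))
  ok <- c("CH3", "CH2", "CH", "C", "Si", "O_C", "O_H", "O_B", "H_O")
  if (!all(s$type %in% ok))
    msgs <- c(msgs, "unknown site type in topology")
  if (nrow(s) && abs(sum(s$charge)) > 1e-12)
    msgs <- c(msgs, sprintf("net charge %.3e exceeds neutrality tolerance",
                            sum(s$charge)))
  if (nrow(s) && (any(!is.finite(s$sigma)) || any(!is.finite(s$epsilon)) ||
                  any(!is.finite(s$charge))))
    msgs <- c(msgs, "every site must carry finite charge and LJ parameters")
  if (nrow(object@torsions) != nrow(object@torsionC))
    msgs <- c(msgs, "torsion coefficient rows must match the torsion list")
  if (length(msgs)) msgs else TRUE
})

#' Force-field parameter set
#'
#' Container for the packaged constants of the organosilicon force field:
#' point-charge rules per substituent environment, rigid bond lengths,
#' harmonic angle terms, Ryckaert-Bellemans torsion coefficients per dihedral
#' class, Lennard-Jones parameters per atom type (including the silicon
#' series Si0..Si4) and the carried-over alkane CH_x constants.  Load the
#' shipped set with \code{\link{defaultParameters}} or an edited copy with
#' \code{\link{readParameters}}.
#'
#' @slot charges named numeric vector of substituent charge rules (e).
#' @slot bonds data.frame(key, r0) of constraint lengths (nm).
#' @slot angles data.frame(key, theta0, kAngle).
#' @slot torsions data.frame(class, C0..C5) (kJ/mol).
#' @slot lj data.frame(type, sigma, epsilon) for Si^k and oxygen types.
#' @slot alkaneLJ data.frame(type, sigma, epsilon) for CH_x sites, carried
#'   over from the alkane parametrization (editable).
#' @slot sigmaScale per-oxygenated-substituent fractional reduction of the
#'   silicon sigma (default 0.05).
#' @slot source provenance string of the loaded configuration.
#' @export
setClass("ParameterSet",
  representation(
    charges = "numeric",
    bonds = "data.frame",
    angles = "data.frame",
    torsions = "data.frame",
    lj = "data.frame",
    alkaneLJ = "data.frame",
    sigmaScale = "numeric",
    source = "character"
  )
)

setValidity("ParameterSet", function(object) {
  msgs <- character()
  if (any(object@lj$epsilon < 0) || any(object@lj$sigma < 0))
    msgs <- c(msgs, "LJ parameters must be non-negative")
  if (any(object@alkaneLJ$epsilon <= 0) || any(object@alkaneLJ$sigma <= 0))
    msgs <- c(msgs, "alkane LJ parameters must be positive")
  ## silicon series must obey the sigma-scaling law to printed precision
  si0 <- object@lj$sigma[object@lj$type == "Si0"]
  for (k in 0:4) {
    sik <- object@lj$sigma[object@lj$type == paste0("Si", k)]
    if (length(sik) && length(si0) &&
        abs(sik - round(si0 * (1 - object@sigmaScale * k), 3)) > 5e-4)
      msgs <- c(msgs, sprintf("Si%d sigma violates the scaling law", k))
  }
  if (length(msgs)) msgs else TRUE
})

## ---- generics -------------------------------------------------------------

#' @rdname MoleculeGraph-class
#' @param object,x a \code{MoleculeGraph} or \code{UATopology}.
#' @export
setGeneric("natoms", function(x) standardGeneric("natoms"))
#' @rdname MoleculeGraph-class
#' @export
setGeneric("bondList", function(x) standardGeneric("bondList"))
#' @rdname UATopology-class
#' @param x a \code{UATopology}.
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))
#' @rdname UATopology-class
#' @export
setGeneric("charges", function(x) standardGeneric("charges"))
#' @rdname UATopology-class
#' @export
setGeneric("ljParams", function(x) standardGeneric("ljParams"))
#' @rdname UATopology-class
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))
#' @rdname UATopology-class
#' @export
setGeneric("torsions", function(x) standardGeneric("torsions"))

#' @export
setMethod("natoms", "MoleculeGraph", function(x) length(x@elements))
#' @export
setMethod("natoms", "UATopology", function(x) nrow(x@sites))
#' @export
setMethod("bondList", "MoleculeGraph", function(x) x@bonds)
#' @export
setMethod("bondList", "UATopology", function(x) as.matrix(x@bonds[, c("i", "j")]))
#' @export
setMethod("sites", "UATopology", function(x) x@sites)
#' @export
setMethod("charges", "UATopology", function(x) x@sites$charge)
#' @export
setMethod("ljParams", "UATopology", function(x) x@sites[, c("sigma", "epsilon")])
#' @export
setMethod("exclusions", "UATopology", function(x) x@exclusions)
#' @export
setMethod("torsions", "UATopology", function(x) cbind(x@torsions, x@torsionC))

setMethod("show", "MoleculeGraph", function(object) {
  cat(sprintf("MoleculeGraph '%s': %d atoms, %d bonds\n",
              object@name, natoms(object), nrow(object@bonds)))
  tab <- table(object@elements)
  cat("  composition:", paste(sprintf("%s%d", names(tab), tab), collapse = " "), "\n")
  if (any(nzchar(object@types)))
    cat("  typed sites:", paste(unique(object@types[nzchar(object@types)]),
                                collapse = " "), "\n")
  invisible(object)
})

setMethod("show", "UATopology", function(object) {
  cat(sprintf("UATopology '%s': %d sites, %d constraints, %d angles, %d torsions\n",
              object@name, nrow(object@sites), nrow(object@bonds),
              nrow(object@angles), nrow(object@torsions)))
  cat(sprintf("  net charge %.3g e; %d excluded pairs; validated: %s\n",
              sum(object@sites$charge), nrow(object@exclusions),
              object@validated))
  invisible(object)
})

setMethod("show", "ParameterSet", function(object) {
  cat(sprintf("ParameterSet [%s]\n", object@source))
  cat(sprintf("  %d charge rules, %d bond lengths, %d angle terms, %d torsion classes, %d+%d LJ types\n",
              length(object@charges), nrow(object@bonds), nrow(object@angles),
              nrow(object@torsions), nrow(object@lj), nrow(object@alkaneLJ)))
  invisible(object)
})

## ---- internal graph utilities --------------------------------------------

.adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  if (length(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

.isConnected <- function(n, bonds) {
  if (n <= 1L) return(TRUE)
  adj <- .adjacency(n, bonds)
  seen <- logical(n)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

## BFS graph distances from one vertex (Inf if unreachable)
.graphDistances <- function(adj, from) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!is.finite(d[w])) { d[w] <- d[v] + 1; queue <- c(queue, w) }
  }
  d
}
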