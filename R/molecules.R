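#' Construct a molecule graph
#'
#' Low-level constructor for a \code{\linkS4class{MoleculeGraph}} from element
#' symbols and a bond list.  Hydrogens are explicit at this stage; use
#' \code{\link{perceiveUnitedAtoms}} to collapse aliphatic CH_x groups.
#'
#' @param name molecule name.
#' @param elements character vector of element symbols.
#' @param bonds two-column integer matrix (or data.frame) of bonded pairs.
#' @param coords optional n x 3 coordinate matrix (nm).
#' @return a \code{\linkS4class{MoleculeGraph}}.
#' @export
#' @examples
#' ethane <- moleculeGraph("ethane",
#'   c("C", "C", rep("H", 6)),
#'   rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 6), c(2, 7), c(2, 8)))
moleculeGraph <- function(name, elements, bonds, coords = NULL) {
  bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 2)
  ok <- c("Si", "O", "C", "H")
  if (!all(elements %in% ok))
    stop("unknown element(s): ",
         paste(setdiff(unique(elements), ok), collapse = ", "))
  n <- length(elements)
  new("MoleculeGraph", name = name, elements = elements, bonds = bonds,
      coords = coords, labels = character(n), types = character(n),
      siK = rep(NA_integer_, n))
}

## mutable builder used by the programmatic constructors
.newBuilder <- function() {
  env <- new.env(parent = emptyenv())
  env$elements <- character()
  env$bonds <- matrix(integer(), ncol = 2)
  env$add <- function(element, bondTo = integer()) {
    env$elements <- c(env$elements, element)
    idx <- length(env$elements)
    for (b in bondTo) env$bonds <- rbind(env$bonds, c(b, idx))
    idx
  }
  env
}

.addSubstituent <- function(b, at, kind) {
  addH <- function(c, n) for (i in seq_len(n)) b$add("H", c)
  switch(kind,
    methyl = {
      c1 <- b$add("C", at); addH(c1, 3)
    },
    ethyl = {
      c1 <- b$add("C", at); addH(c1, 2)
      c2 <- b$add("C", c1); addH(c2, 3)
    },
    methoxy = {
      o <- b$add("O", at)
      c1 <- b$add("C", o); addH(c1, 3)
    },
    ethoxy = {
      o <- b$add("O", at)
      c1 <- b$add("C", o); addH(c1, 2)
      c2 <- b$add("C", c1); addH(c2, 3)
    },
    hydroxyl = {
      o <- b$add("O", at); b$add("H", o)
    },
    stop("unknown substituent kind: ", kind)
  )
  invisible(NULL)
}

#' Build a tetrahedrally substituted silane
#'
#' Constructs the all-atom graph of a silicon bearing four substituent
#' groups chosen from \code{"methyl"}, \code{"ethyl"}, \code{"methoxy"},
#' \code{"ethoxy"} and \code{"hydroxyl"}.
#'
#' @param substituents character vector of length 4.
#' @param name optional molecule name (derived from the substituents if
#'   omitted).
#' @return a \code{\linkS4class{MoleculeGraph}} with explicit hydrogens.
#' @export
#' @examples
#' tms <- silane(rep("methyl", 4))      # tetramethylsilane
#' teos <- silane(rep("ethoxy", 4))     # tetraethoxysilane
silane <- function(substituents, name = NULL) {
  stopifnot(length(substituents) == 4L)
  b <- .newBuilder()
  si <- b$add("Si")
  for (s in substituents) .addSubstituent(b, si, s)
  name <- name %||% paste0(paste(substituents, collapse = "-"), "-silane")
  moleculeGraph(name, b$elements, b$bonds)
}

#' Build a disiloxane (Si-O-Si) molecule
#'
#' Two silicon atoms joined by a bridging oxygen, each carrying three
#' substituent groups.
#'
#' @param left,right character vectors of length 3 of substituent kinds.
#' @param name optional molecule name.
#' @return a \code{\linkS4class{MoleculeGraph}} with explicit hydrogens.
#' @export
#' @examples
#' hmdso <- disiloxane(rep("methyl", 3), rep("methyl", 3))
disiloxane <- function(left, right, name = NULL) {
  stopifnot(length(left) == 3L, length(right) == 3L)
  b <- .newBuilder()
  si1 <- b$add("Si")
  ob <- b$add("O", si1)
  si2 <- b$add("Si", ob)
  for (s in left) .addSubstituent(b, si1, s)
  for (s in right) .addSubstituent(b, si2, s)
  moleculeGraph(name %||% "disiloxane", b$elements, b$bonds)
}

#' Build a linear alkane
#'
#' @param n number of carbons (>= 1).
#' @param name optional name.
#' @return a \code{\linkS4class{MoleculeGraph}} with explicit hydrogens.
#' @export
alkane <- function(n, name = NULL) {
  stopifnot(n >= 1)
  b <- .newBuilder()
  prev <- NULL
  for (i in seq_len(n)) {
    c1 <- b$add("C", if (is.null(prev)) integer() else prev)
    nh <- if (n == 1) 4 else if (i == 1 || i == n) 3 else 2
    for (h in seq_len(nh)) b$add("H", c1)
    prev <- c1
  }
  moleculeGraph(name %||% paste0("C", n, "-alkane"), b$elements, b$bonds)
}

#' Named organosilicon molecules
#'
#' Programmatic registry of the organosilicon molecules used for charge
#' assignment and validation, addressable by common name or by the compact
#' abbreviation (e.g. \code{"Met4Si"} for tetramethylsilane,
#' \code{"SiOEth4"} for tetraethoxysilane, \code{"M3SiOE"} for
#' trimethylethoxysilane).
#'
#' @param name molecule identifier; see \code{siliconMoleculeNames()}.
#' @return a \code{\linkS4class{MoleculeGraph}} with explicit hydrogens.
#' @export
#' @examples
#' siliconMolecule("Met3SiOH")    # trimethylsilanol
siliconMolecule <- function(name) {
  reg <- .siliconRegistry()
  key <- names(reg)[match(tolower(name), tolower(names(reg)))]
  if (is.na(key)) stop("unknown molecule: ", name,
                       "; see siliconMoleculeNames()")
  reg[[key]]()
}

#' @rdname siliconMolecule
#' @export
siliconMoleculeNames <- function() names(.siliconRegistry())

.siliconRegistry <- function() {
  m <- function(subs, nm) function() silane(subs, name = nm)
  list(
    Met4Si   = m(rep("methyl", 4), "tetramethylsilane"),
    Eth4Si   = m(rep("ethyl", 4), "tetraethylsilane"),
    EthMet3Si = m(c("ethyl", rep("methyl", 3)), "ethyltrimethylsilane"),
    Eth2Met2Si = m(c(rep("ethyl", 2), rep("methyl", 2)), "diethyldimethylsilane"),
    Eth3MetSi = m(c(rep("ethyl", 3), "methyl"), "triethylmethylsilane"),
    Met3SiOH = m(c(rep("methyl", 3), "hydroxyl"), "trimethylsilanol"),
    Eth3SiOH = m(c(rep("ethyl", 3), "hydroxyl"), "triethylsilanol"),
    Met6Si2O = function() disiloxane(rep("methyl", 3), rep("methyl", 3),
                                     name = "hexamethyldisiloxane"),
    SiOMet4  = m(rep("methoxy", 4), "tetramethoxysilane"),
    SiOEth4  = m(rep("ethoxy", 4), "tetraethoxysilane"),
    M3SiOE   = m(c(rep("methyl", 3), "ethoxy"), "trimethylethoxysilane"),
    M2ESiOE  = m(c(rep("methyl", 2), "ethyl", "ethoxy"), "dimethylethylethoxysilane"),
    ME2SiOE  = m(c("methyl", rep("ethyl", 2), "ethoxy"), "methyldiethylethoxysilane"),
    E3SiOE   = m(c(rep("ethyl", 3), "ethoxy"), "triethylethoxysilane"),
    M3SiOM   = m(c(rep("methyl", 3), "methoxy"), "methoxytrimethylsilane"),
    M2SiOM2  = m(c(rep("methyl", 2), rep("methoxy", 2)), "dimethyldimethoxysilane")
  )
}
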