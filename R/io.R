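#' Read a molecule specification file
#'
#' The molecule specification is a small YAML document with a \code{name},
#' an \code{atoms} list of element symbols, a \code{bonds} list of 1-based
#' index pairs and an optional \code{coords} list of xyz triples (nm).  It
#' round-trips losslessly through \code{\link{writeMoleculeSpec}}.
#'
#' @param path path to a specification file.
#' @return a \code{\linkS4class{MoleculeGraph}}.
#' @export
readMoleculeSpec <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$atoms) || is.null(doc$bonds))
    stop("molecule spec must contain 'atoms' and 'bonds'")
  bonds <- do.call(rbind, lapply(doc$bonds, as.integer))
  coords <- if (!is.null(doc$coords))
    do.call(rbind, lapply(doc$coords, as.numeric))
  moleculeGraph(doc$name %||% basename(path), unlist(doc$atoms), bonds,
                coords = coords)
}

#' @rdname readMoleculeSpec
#' @param graph a \code{\linkS4class{MoleculeGraph}} to write.
#' @export
writeMoleculeSpec <- function(graph, path) {
  doc <- list(name = graph@name,
              atoms = as.list(graph@elements),
              bonds = lapply(seq_len(nrow(graph@bonds)),
                             function(r) as.integer(graph@bonds[r, ])))
  if (!is.null(graph@coords))
    doc$coords <- lapply(seq_len(nrow(graph@coords)),
                         function(r) as.numeric(graph@coords[r, ]))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Write a torsion profile as a delimited table
#'
#' @param profile a \code{\link{torsionProfile}} data.frame.
#' @param path output path (tab-separated, angle in degrees, energies in
#'   kJ/mol).
#' @export
writeProfileTable <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a torsion-scan energy table
#'
#' Delimited text with columns \code{angle} (degrees) and \code{energy}
#' (kJ/mol).
#'
#' @param path input path.
#' @return data.frame(angle, energy).
#' @export
readScanTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("angle", "energy") %in% names(df)))
    stop("scan table needs 'angle' and 'energy' columns")
  df
}

#' Topology export dialect
#'
#' Describes how topologies are serialized.  The only shipped dialect is
#' the GROMACS one: rigid bonds as constraints, harmonic angles,
#' Ryckaert-Bellemans dihedrals evaluated with the cosine argument
#' \eqn{\psi = \phi - 180^\circ}, exclusion depth 3 (\code{nrexcl 3}) and no
#' 1-4 pair section.
#'
#' @param name dialect identifier.
#' @return an object of class \code{"exportDialect"}.
#' @export
exportDialect <- function(name = "gromacs") {
  name <- match.arg(name, "gromacs")
  structure(list(name = name, dihedralConvention = "RB, psi = phi - 180",
                 constraintBonds = TRUE, exclusionDepth = 3L),
            class = "exportDialect")
}

#' Read an electronic-properties table
#'
#' Tab-separated table with columns \code{compound}, \code{mu_gas} (D),
#' \code{alpha} (Angstrom^3), \code{eps} and \code{n_D}.  A synthetic
#' stand-in table for a few organosilicon liquids ships at
#' \code{inst/extdata/electronic/}.
#'
#' @param path table path; the shipped synthetic table by default.
#' @return named list of \code{\link{electronicProperties}} objects.
#' @export
readElectronicProperties <- function(path = system.file(
    "extdata", "electronic", "electronic_properties_synthetic.tsv",
    package = "orgsil", mustWork = TRUE)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  out <- lapply(seq_len(nrow(df)), function(i)
    electronicProperties(df$mu_gas[i], df$alpha[i], df$eps[i], df$n_D[i]))
  names(out) <- df$compound
  out
}
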