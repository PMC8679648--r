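## GROMACS-dialect topology and coordinate writers.  Output is deterministic
## (fixed formats, no timestamps), so identical inputs give byte-identical
## files.

.siteMass <- function(type) {
  switch(type,
         CH3 = 15.0345, CH2 = 14.0266, CH = 13.0186, C = 12.011,
         Si = 28.0855, O_C = 15.9994, O_H = 15.9994, O_B = 15.9994,
         H_O = 1.008,
         stop("no mass for site type ", type))
}

.atomTypeName <- function(type, siK) {
  ifelse(type == "Si", paste0("Si", siK), sub("_", "", type))
}

#' Write a GROMACS topology
#'
#' Serializes a validated topology as a self-contained GROMACS .itp/.top
#' text file: an \code{[ atomtypes ]} section with the Lennard-Jones
#' parameters, \code{[ atoms ]} with the point charges, all bonds as
#' \code{[ constraints ]} (funct 1; bonds are rigid), harmonic
#' \code{[ angles ]} (funct 1) and Ryckaert-Bellemans \code{[ dihedrals ]}
#' (funct 3).  \code{nrexcl} is 3 and no \code{[ pairs ]} section is
#' written: 1-4 interactions are excluded from the force field entirely.
#'
#' @param topology a validated \code{\linkS4class{UATopology}}.
#' @param path output path (.itp or .top).
#' @param dialect an \code{\link{exportDialect}}.
#' @param system if TRUE append \code{[ system ]}/\code{[ molecules ]}
#'   sections (a runnable .top for a one-molecule system).
#' @param nmols molecule count for the \code{[ molecules ]} section.
#' @return the path, invisibly.
#' @export
#' @examples
#' top <- buildTopology(siliconMolecule("Met4Si"))
#' f <- tempfile(fileext = ".itp")
#' writeGromacsTopology(top, f)
writeGromacsTopology <- function(topology, path, dialect = exportDialect(),
                                 system = FALSE, nmols = 1L) {
  stopifnot(is(topology, "UATopology"))
  if (!isTRUE(topology@validated))
    stop("refusing to export an unvalidated topology; use buildTopology()")
  stopifnot(inherits(dialect, "exportDialect"))
  s <- topology@sites
  tn <- .atomTypeName(s$type, s$siK)
  lines <- c(
    sprintf("; %s - united-atom organosilicon topology (orgsil)", topology@name),
    sprintf("; dihedral convention: %s; exclusion depth %d; no 1-4 pairs",
            dialect$dihedralConvention, dialect$exclusionDepth),
    "", "[ atomtypes ]",
    "; name  at.num     mass   charge  ptype      sigma    epsilon")
  for (u in unique(tn)) {
    i <- match(u, tn)
    lines <- c(lines, sprintf("%6s %7d %8.4f %8.4f %6s %10.5f %10.5f",
                              u, 0L, .siteMass(s$type[i]), 0, "A",
                              s$sigma[i], s$epsilon[i]))
  }
  lines <- c(lines, "", "[ moleculetype ]", "; name  nrexcl",
             sprintf("%s  %d", gsub("[^A-Za-z0-9]", "_", topology@name),
                     dialect$exclusionDepth),
             "", "[ atoms ]",
             ";  nr   type  resnr  residue  atom  cgnr     charge       mass")
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf("%5d %6s %6d %8s %5s %5d %10.6f %10.4f",
                              i, tn[i], 1L, "MOL",
                              paste0(sub("_", "", s$type[i]), i), i,
                              s$charge[i], .siteMass(s$type[i])))
  }
  if (nrow(topology@bonds)) {
    lines <- c(lines, "", "[ constraints ]", ";  ai    aj  funct     length")
    b <- topology@bonds
    for (r in seq_len(nrow(b)))
      lines <- c(lines, sprintf("%5d %5d %6d %10.4f", b$i[r], b$j[r], 1L, b$r0[r]))
  }
  if (nrow(topology@angles)) {
    lines <- c(lines, "", "[ angles ]",
               ";  ai    aj    ak  funct     theta0          k")
    a <- topology@angles
    for (r in seq_len(nrow(a)))
      lines <- c(lines, sprintf("%5d %5d %5d %6d %10.2f %10.2f",
                                a$i[r], a$j[r], a$k[r], 1L,
                                a$theta0[r], a$kAngle[r]))
  }
  if (nrow(topology@torsions)) {
    lines <- c(lines, "", "[ dihedrals ]",
               ";  ai    aj    ak    al  funct         C0         C1         C2         C3         C4         C5")
    tr <- topology@torsions
    for (r in seq_len(nrow(tr)))
      lines <- c(lines, sprintf("%5d %5d %5d %5d %6d %10.4f %10.4f %10.4f %10.4f %10.4f %10.4f",
                                tr$i[r], tr$j[r], tr$k[r], tr$l[r], 3L,
                                topology@torsionC[r, 1], topology@torsionC[r, 2],
                                topology@torsionC[r, 3], topology@torsionC[r, 4],
                                topology@torsionC[r, 5], topology@torsionC[r, 6]))
  }
  if (system) {
    lines <- c(lines, "", "[ system ]", topology@name, "", "[ molecules ]",
               sprintf("%s  %d", gsub("[^A-Za-z0-9]", "_", topology@name),
                       as.integer(nmols)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse atoms, constraints and dihedrals back out of a written topology
#'
#' Minimal reader for round-trip checks of the package's own exporter:
#' returns per-site charges, constraint lengths and Ryckaert-Bellemans
#' coefficient rows as written.
#'
#' @param path a topology file written by \code{\link{writeGromacsTopology}}.
#' @return list with \code{charges}, \code{constraints} and
#'   \code{dihedralC}.
#' @export
readGromacsTopology <- function(path) {
  lines <- readLines(path)
  section <- ""
  charges <- numeric(); constraints <- NULL; dihedralC <- NULL
  for (ln in lines) {
    ln2 <- trimws(sub(";.*", "", ln))
    if (!nzchar(ln2)) next
    if (grepl("^\\[", ln2)) {
      section <- gsub("[][ ]", "", ln2)
      next
    }
    f <- strsplit(ln2, "\\s+")[[1]]
    if (section == "atoms") charges <- c(charges, as.numeric(f[7]))
    if (section == "constraints")
      constraints <- rbind(constraints,
                           data.frame(i = as.integer(f[1]), j = as.integer(f[2]),
                                      r0 = as.numeric(f[4])))
    if (section == "dihedrals")
      dihedralC <- rbind(dihedralC, as.numeric(f[6:11]))
  }
  list(charges = charges, constraints = constraints, dihedralC = dihedralC)
}

#' Write a GROMACS coordinate (.gro) file
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param names site names (length n).
#' @param box cubic box length (nm).
#' @param path output path.
#' @param title file title line.
#' @param resids residue number per site (one per molecule when packing).
#' @return the path, invisibly.
#' @export
writeGro <- function(coords, names, box, path, title = "orgsil configuration",
                     resids = rep(1L, nrow(coords))) {
  n <- nrow(coords)
  lines <- c(title, sprintf("%5d", n))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              resids[i] %% 100000L, "MOL",
                              substr(names[i], 1, 5), i %% 100000L,
                              coords[i, 1], coords[i, 2], coords[i, 3]))
  }
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", box, box, box))
  writeLines(lines, path)
  invisible(path)
}
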