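#' Load a force-field parameter configuration
#'
#' Reads a YAML parameter file mirroring the packaged constant tables
#' (charge rules, bond lengths, angle terms, torsion classes, Lennard-Jones
#' types and the carried-over alkane CH_x constants) into a
#' \code{\linkS4class{ParameterSet}}.
#'
#' @param path path to a YAML parameter file.
#' @return a \code{\linkS4class{ParameterSet}}.
#' @seealso \code{\link{defaultParameters}} for the shipped set.
#' @export
readParameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  cfg <- yaml::read_yaml(path)
  tors <- cfg$torsions
  torsDf <- data.frame(class = names(tors),
                       do.call(rbind, lapply(tors, as.numeric)))
  names(torsDf)[2:7] <- paste0("C", 0:5)
  rownames(torsDf) <- NULL
  ang <- cfg$angles
  angDf <- data.frame(key = names(ang),
                      theta0 = vapply(ang, function(a) a[[1]], 0),
                      kAngle = vapply(ang, function(a) a[[2]], 0))
  rownames(angDf) <- NULL
  ljDf <- data.frame(type = names(cfg$lj),
                     sigma = vapply(cfg$lj, function(a) a[[1]], 0),
                     epsilon = vapply(cfg$lj, function(a) a[[2]], 0))
  rownames(ljDf) <- NULL
  alkDf <- data.frame(type = names(cfg$alkane_lj),
                      sigma = vapply(cfg$alkane_lj, function(a) a[[1]], 0),
                      epsilon = vapply(cfg$alkane_lj, function(a) a[[2]], 0))
  rownames(alkDf) <- NULL
  new("ParameterSet",
      charges = unlist(cfg$charges),
      bonds = data.frame(key = names(cfg$bonds),
                         r0 = unlist(cfg$bonds), row.names = NULL),
      angles = angDf,
      torsions = torsDf,
      lj = ljDf,
      alkaneLJ = alkDf,
      sigmaScale = cfg$sigma_scale_per_oxygen %||% 0.05,
      source = path)
}

#' Default organosilicon parameter set
#'
#' Loads the parameter configuration shipped with the package
#' (\code{inst/extdata/params/organosilicon.yaml}).  Edit a copy and load it
#' with \code{\link{readParameters}} to change, e.g., the alkane CH_x
#' constants.
#'
#' @return a \code{\linkS4class{ParameterSet}}.
#' @export
#' @examples
#' p <- defaultParameters()
#' siliconSigma(p, k = 4)
defaultParameters <- function() {
  readParameters(system.file("extdata", "params", "organosilicon.yaml",
                             package = "orgsil", mustWork = TRUE))
}

#' Silicon sigma under the oxygenated-substituent scaling rule
#'
#' The Lennard-Jones collision diameter of silicon is reduced by a fixed
#' fraction (default 5\%) for each oxygen-containing substituent group
#' (silanol, alkoxy or siloxane): \eqn{\sigma(Si^k) = \sigma(Si^0) (1 - 0.05 k)}.
#' A silicon with four alkoxy groups therefore has its sigma scaled down by
#' 20\%, one with a single alkoxy substituent by only 5\%.
#'
#' @param params a \code{\linkS4class{ParameterSet}}.
#' @param k number of oxygenated substituent groups (0..4).
#' @param fromBase if TRUE (default) apply the scaling law to the base
#'   alkylsilane value \eqn{\sigma(Si^0)}; if FALSE return the stored table
#'   entry verbatim.
#' @return sigma in nm.
#' @export
siliconSigma <- function(params, k, fromBase = TRUE) {
  stopifnot(is(params, "ParameterSet"))
  if (any(k < 0 | k != round(k))) stop("k must be a non-negative integer count")
  si0 <- params@lj$sigma[params@lj$type == "Si0"]
  if (fromBase) return(si0 * (1 - params@sigmaScale * k))
  idx <- match(paste0("Si", k), params@lj$type)
  if (anyNA(idx)) stop("no stored LJ entry for Si with k = ",
                       paste(k[is.na(idx)], collapse = ", "),
                       "; use fromBase = TRUE to extrapolate")
  params@lj$sigma[idx]
}

## Internal lookup helpers ---------------------------------------------------

## map a site type to its bonded-term element class
.bondedClass <- function(type) {
  out <- type
  out[type %in% c("CH3", "CH2", "CH", "C")] <- "C"
  out[type == "H_O"] <- "H"
  out
}

.bondKey <- function(t1, t2) {
  a <- .bondedClass(t1); b <- .bondedClass(t2)
  paste(sort(c(a, b)), collapse = "-")
}

## canonical bond keys as stored in the table (Si first, then C, O_x, H)
.lookupBond <- function(params, t1, t2) {
  a <- .bondedClass(t1); b <- .bondedClass(t2)
  keys <- c(paste(a, b, sep = "-"), paste(b, a, sep = "-"))
  idx <- match(keys, params@bonds$key)
  idx <- idx[!is.na(idx)]
  if (!length(idx))
    stop(sprintf("missing bond parameter for type pair (%s, %s)", t1, t2))
  params@bonds$r0[idx[1L]]
}

.lookupAngle <- function(params, t1, t2, t3) {
  a <- .bondedClass(t1); b <- .bondedClass(t2); c3 <- .bondedClass(t3)
  keys <- c(paste(a, b, c3, sep = "-"), paste(c3, b, a, sep = "-"))
  idx <- match(keys, params@angles$key)
  idx <- idx[!is.na(idx)]
  if (!length(idx))
    stop(sprintf("missing angle parameter for type triple (%s, %s, %s)",
                 t1, t2, t3))
  params@angles[idx[1L], c("theta0", "kAngle")]
}

.lookupTorsion <- function(params, t1, t2, t3, t4) {
  cls <- .bondedClass(c(t1, t2, t3, t4))
  fwd <- paste(cls, collapse = "-")
  rev <- paste(rev(cls), collapse = "-")
  idx <- match(c(fwd, rev), params@torsions$class)
  idx <- idx[!is.na(idx)]
  if (!length(idx))
    stop(sprintf("missing torsion parameter for type quadruple (%s-%s-%s-%s)",
                 t1, t2, t3, t4))
  list(class = params@torsions$class[idx[1L]],
       C = as.numeric(params@torsions[idx[1L], paste0("C", 0:5)]))
}

#' Torsion coefficients for a dihedral class
#'
#' @param params a \code{\linkS4class{ParameterSet}}.
#' @param class dihedral class name, e.g. \code{"C-C-Si-C"}.
#' @return numeric vector C0..C5 (kJ/mol).
#' @export
torsionCoefficients <- function(params, class) {
  idx <- match(class, params@torsions$class)
  if (is.na(idx)) stop("unknown torsion class: ", class)
  as.numeric(params@torsions[idx, paste0("C", 0:5)])
}
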