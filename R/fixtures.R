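#' Generate deterministic synthetic fixtures
#'
#' Writes small synthetic data sets with known ground truth for exercising
#' the analysis pipelines: torsion scans assembled from planted
#' Ryckaert-Bellemans coefficients plus the molecule's real 1-5 classical
#' terms, quadratic property response surfaces over a design grid, property
#' series from planted linear models (with one flagged outlier), and
#' molecule specification files.  Every fixture is a pure function of its
#' seed; the planted truth is recorded alongside the data.
#'
#' @param kind one of \code{"torsion_scan"}, \code{"response_surface"},
#'   \code{"property_series"}, \code{"molecules"}.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return invisible list of written paths plus the planted ground truth.
#' @export
#' @examples
#' fx <- generateFixtures("property_series", seed = 7, dir = tempdir())
generateFixtures <- function(kind, seed, dir) {
  kind <- match.arg(kind, c("torsion_scan", "response_surface",
                            "property_series", "molecules"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  switch(kind,
    torsion_scan = .fixtureTorsionScan(dir),
    response_surface = .fixtureResponseSurface(dir),
    property_series = .fixturePropertySeries(dir),
    molecules = .fixtureMolecules(dir))
}

.fixtureTorsionScan <- function(dir) {
  params <- defaultParameters()
  top <- buildTopology(siliconMolecule("Eth4Si"), params)
  tr <- top@torsions
  d <- as.integer(tr[1, c("i", "j", "k", "l")])
  C <- torsionCoefficients(params, "C-C-Si-C")
  angles <- seq(0, 330, 30)
  ## synthetic "QM" profile: planted RB target plus all other classical terms
  coords <- buildConformation(top)
  energy <- vapply(angles, function(a) {
    xyz <- setDihedral(top, coords, d, a)
    rbEnergy(a0 <- measureDihedral(xyz, d[1], d[2], d[3], d[4]), C) +
      intramolecularNonbonded(top, xyz)$total +
      torsionEnergy(top, xyz, skip = 1L)
  }, 0)
  scanPath <- file.path(dir, "torsion_scan.tsv")
  utils::write.table(data.frame(angle = angles, energy = energy), scanPath,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truthPath <- file.path(dir, "torsion_scan_truth.yaml")
  yaml::write_yaml(list(molecule = "Eth4Si", dihedral = d,
                        class = "C-C-Si-C", C = C), truthPath)
  invisible(list(paths = c(scanPath, truthPath),
                 truth = list(dihedral = d, C = C)))
}

.fixtureResponseSurface <- function(dir) {
  grid <- buildDesignGrid(seq(0.5, 0.625, 0.025), seq(0.05, 0.175, 0.025))
  ## planted convex quadratics whose joint minimum sits inside the grid
  xopt <- stats::runif(2, -0.6, 0.6)
  mk <- function(scale, y0) {
    b <- c(y0 + scale * sum(xopt^2), -2 * scale * xopt[1], -2 * scale * xopt[2],
           scale, scale, 0)
    names(b) <- c("b0", "b1", "b2", "b11", "b22", "b12")
    b
  }
  bDens <- mk(40, 760); bHvap <- mk(5, 42)
  evalq2 <- function(b, x1, x2)
    b[1] + b[2] * x1 + b[3] * x2 + b[4] * x1^2 + b[5] * x2^2 + b[6] * x1 * x2
  resp <- data.frame(
    density = evalq2(bDens, grid$points$x1, grid$points$x2),
    dHvap = evalq2(bHvap, grid$points$x1, grid$points$x2))
  surfPath <- file.path(dir, "response_surface.tsv")
  utils::write.table(cbind(grid$points, resp), surfPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truthPath <- file.path(dir, "response_surface_truth.yaml")
  yaml::write_yaml(list(xopt = xopt,
                        targets = list(density = 760, dHvap = 42),
                        coefficients = list(density = as.list(bDens),
                                            dHvap = as.list(bHvap))),
                   truthPath)
  invisible(list(paths = c(surfPath, truthPath),
                 truth = list(xopt = xopt, grid = grid)))
}

.fixturePropertySeries <- function(dir) {
  ## density: planted line with one flagged outlier
  a <- stats::runif(1, 900, 1100); b <- -stats::runif(1, 0.7, 1.1)
  T <- seq(283, 323, 10)
  dens <- a + b * T
  dens[length(dens)] <- dens[length(dens)] + 25      # injected outlier
  densDf <- data.frame(T = T, value = dens, source = "planted",
                       excluded = c(rep(FALSE, length(T) - 1), TRUE))
  ## vapor pressure: exact Clausius-Clapeyron line
  A <- stats::runif(1, 15, 20); B <- -stats::runif(1, 2500, 4000)
  Tp <- seq(273, 323, 10)
  pDf <- data.frame(T = Tp, value = exp(A + B / Tp), source = "planted",
                    excluded = FALSE)
  p1 <- file.path(dir, "density_series.tsv")
  p2 <- file.path(dir, "vapor_pressure_series.tsv")
  utils::write.table(densDf, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pDf, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  truthPath <- file.path(dir, "property_series_truth.yaml")
  yaml::write_yaml(list(density = list(intercept = a, slope = b),
                        vapor_pressure = list(A = A, B = B,
                                              dHvap = -8.314462618 * B / 1000)),
                   truthPath)
  invisible(list(paths = c(p1, p2, truthPath),
                 truth = list(density = c(a, b), vp = c(A, B))))
}

.fixtureMolecules <- function(dir) {
  paths <- character()
  for (nm in c("Met4Si", "Met3SiOH", "SiOEth4", "Met6Si2O")) {
    p <- file.path(dir, paste0(tolower(nm), ".yaml"))
    writeMoleculeSpec(siliconMolecule(nm), p)
    paths <- c(paths, p)
  }
  invisible(list(paths = paths, truth = NULL))
}

#' Read a property series from a delimited table
#'
#' Expects columns \code{T}, \code{value} and optionally \code{source} and
#' \code{excluded} (as written by \code{\link{generateFixtures}}).
#'
#' @param path input path.
#' @param compound,property identifiers for the returned series.
#' @param units unit string.
#' @return a \code{\link{propertySeries}}.
#' @export
readPropertySeries <- function(path, compound = basename(path),
                               property = "property", units = "") {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  propertySeries(compound, property, df$T, df$value,
                 source = if ("source" %in% names(df)) df$source else "unknown",
                 excluded = if ("excluded" %in% names(df)) df$excluded else FALSE,
                 units = units)
}
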