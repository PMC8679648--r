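#' Pack molecules into a cubic periodic box
#'
#' Places \code{count} copies of a molecule at random positions and
#' orientations in a cubic box, rejecting placements that bring any two
#' sites of different molecules closer than \code{threshold} under the
#' minimum-image convention.  Placement is reproducible under a seed.
#'
#' @param topology a \code{\linkS4class{UATopology}}.
#' @param count number of molecules.
#' @param box cubic box length (nm).
#' @param seed integer seed.
#' @param threshold minimum allowed intermolecular site-site distance (nm).
#' @param maxAttempts placement attempts per molecule before giving up.
#' @return list with \code{coords} (count*nsites x 3), \code{resids},
#'   \code{names}, \code{box}.
#' @export
#' @examples
#' top <- buildTopology(siliconMolecule("Met4Si"))
#' pk <- packBox(top, count = 10, box = 3.1, seed = 1)
packBox <- function(topology, count, box, seed, threshold = 0.2,
                    maxAttempts = 2000) {
  stopifnot(count >= 1, box > 0)
  mol <- buildConformation(topology)
  mol <- sweep(mol, 2, colMeans(mol))          # center the template
  nS <- nrow(mol)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (count == 1) {
    coords <- sweep(mol, 2, rep(box / 2, 3), `+`)
    return(list(coords = coords, resids = rep(1L, nS),
                names = .atomTypeName(topology@sites$type, topology@sites$siK),
                box = box))
  }
  placed <- matrix(numeric(), ncol = 3)
  resids <- integer()
  minImage <- function(d) d - box * round(d / box)
  for (m in seq_len(count)) {
    ok <- FALSE
    for (att in seq_len(maxAttempts)) {
      ## uniform random rotation from a normalized quaternion
      q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
      R <- matrix(c(
        1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
        2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
        2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
        3, 3, byrow = TRUE)
      cand <- mol %*% t(R)
      cand <- sweep(cand, 2, stats::runif(3, 0, box), `+`)
      if (!nrow(placed)) { ok <- TRUE; break }
      clash <- FALSE
      for (i in seq_len(nS)) {
        d <- sweep(placed, 2, cand[i, ])
        d <- minImage(d)
        if (min(rowSums(d^2)) < threshold^2) { clash <- TRUE; break }
      }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf("packing failed: could not place molecule %d of %d after %d attempts (box %.2f nm, threshold %.2f nm)",
                   m, count, maxAttempts, box, threshold))
    placed <- rbind(placed, cand)
    resids <- c(resids, rep(m, nS))
  }
  placed <- placed %% box
  list(coords = placed, resids = resids,
       names = rep(.atomTypeName(topology@sites$type, topology@sites$siK), count),
       box = box)
}
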