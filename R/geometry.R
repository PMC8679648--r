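## Internal-coordinate embedding of topologies and rigid dihedral rotation.
## Coordinates are in nm; angles in degrees at the interface, radians inside.

.cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
.norm <- function(v) sqrt(sum(v * v))
.unit <- function(v) v / .norm(v)

.bondR0 <- function(top, i, j) {
  b <- top@bonds
  hit <- (b$i == min(i, j)) & (b$j == max(i, j))
  if (!any(hit)) stop(sprintf("no bond between sites %d and %d", i, j))
  b$r0[which(hit)[1]]
}

.angleTheta0 <- function(top, i, j, k) {
  a <- top@angles
  hit <- (a$j == j) & ((a$i == i & a$k == k) | (a$i == k & a$k == i))
  if (!any(hit)) return(109.47)    # tetrahedral fallback
  a$theta0[which(hit)[1]]
}

## Natural-extension placement: position of d given a-b-c, bond length r(c-d),
## angle theta(b-c-d) and dihedral phi(a-b-c-d), all in radians.
.placeAtom <- function(A, B, C, r, theta, phi) {
  b2 <- .unit(C - B)
  nv <- .cross(B - A, b2)
  if (.norm(nv) < 1e-10) nv <- .cross(c(0, 0, 1), b2)
  if (.norm(nv) < 1e-10) nv <- .cross(c(0, 1, 0), b2)
  nv <- .unit(nv)
  m <- .cross(nv, b2)
  d2 <- r * c(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
  C + d2[1] * b2 + d2[2] * m + d2[3] * nv
}

#' Measure a dihedral angle
#'
#' Standard signed dihedral of the chain i-j-k-l, in degrees in (-180, 180].
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param i,j,k,l site indices along the dihedral.
#' @return angle in degrees.
#' @export
measureDihedral <- function(coords, i, j, k, l) {
  b1 <- coords[j, ] - coords[i, ]
  b2 <- coords[k, ] - coords[j, ]
  b3 <- coords[l, ] - coords[k, ]
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  ang * 180 / pi
}

#' Measure a bond angle
#'
#' @param coords n x 3 coordinate matrix.
#' @param i,j,k site indices; j is the vertex.
#' @return angle in degrees.
#' @export
measureAngle <- function(coords, i, j, k) {
  v1 <- .unit(coords[i, ] - coords[j, ])
  v2 <- .unit(coords[k, ] - coords[j, ])
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

#' Build an equilibrium-geometry conformation
#'
#' Embeds a topology in 3D from its internal coordinates: constraint bond
#' lengths, equilibrium angles and staggered dihedrals (successive branches
#' at a center are spaced 120 degrees apart).  The embedding serves
#' single-molecule work - torsion scans, model dipole moments, box packing -
#' not as a minimized structure.
#'
#' @param topology a \code{\linkS4class{UATopology}}.
#' @return n x 3 coordinate matrix (nm).
#' @export
#' @examples
#' top <- buildTopology(siliconMolecule("Met4Si"))
#' xyz <- buildConformation(top)
buildConformation <- function(topology) {
  n <- nrow(topology@sites)
  bonds <- as.matrix(topology@bonds[, c("i", "j")])
  adj <- .adjacency(n, bonds)
  coords <- matrix(NA_real_, n, 3)
  if (n == 0) return(coords)
  root <- which.max(lengths(adj))
  coords[root, ] <- c(0, 0, 0)
  placed <- rep(FALSE, n); placed[root] <- TRUE
  parent <- rep(NA_integer_, n)
  childCount <- integer(n)
  queue <- root
  ## a four-substituent root whose pairwise angle parameters are all equal
  ## (e.g. tetramethylsilane) is embedded at the exact tetrahedral
  ## directions, preserving its symmetry
  rootNb <- adj[[root]]
  if (length(rootNb) == 4L) {
    th <- outer(rootNb, rootNb, Vectorize(function(a, b)
      if (a == b) NA_real_ else .angleTheta0(topology, a, root, b)))
    if (max(th, na.rm = TRUE) - min(th, na.rm = TRUE) < 1e-9) {
      dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
      for (ii in seq_len(4L)) {
        d <- rootNb[ii]
        coords[d, ] <- dirs[ii, ] * .bondR0(topology, root, d)
        parent[d] <- root; placed[d] <- TRUE
        childCount[root] <- childCount[root] + 1L
        queue <- c(queue, d)
      }
    }
  }
  while (length(queue)) {
    c0 <- queue[1L]; queue <- queue[-1L]
    for (d in adj[[c0]]) {
      if (placed[d]) next
      r <- .bondR0(topology, c0, d)
      if (is.na(parent[c0])) {
        ## children of the root
        if (childCount[c0] == 0L) {
          coords[d, ] <- coords[c0, ] + c(r, 0, 0)
        } else {
          b <- adj[[c0]][placed[adj[[c0]]]][1L]
          theta <- .angleTheta0(topology, d, c0, b) * pi / 180
          phi <- (180 - 120 * (childCount[c0] - 1L)) * pi / 180
          A <- coords[b, ] + c(0, 0, 1)
          coords[d, ] <- .placeAtom(A, coords[b, ], coords[c0, ], r, theta, phi)
        }
      } else {
        b <- parent[c0]
        theta <- .angleTheta0(topology, d, c0, b) * pi / 180
        a <- parent[b]
        if (is.na(a)) {
          others <- setdiff(adj[[b]][placed[adj[[b]]]], c0)
          a <- if (length(others)) others[1L] else NA_integer_
        }
        A <- if (is.na(a)) coords[b, ] + c(0, 0, 1) else coords[a, ]
        phi <- (180 - 120 * childCount[c0]) * pi / 180
        coords[d, ] <- .placeAtom(A, coords[b, ], coords[c0, ], r, theta, phi)
      }
      childCount[c0] <- childCount[c0] + 1L
      parent[d] <- c0
      placed[d] <- TRUE
      queue <- c(queue, d)
    }
  }
  coords
}

#' Rotate a dihedral to a target angle
#'
#' Rigidly rotates the part of the molecule on the k-side of the central
#' bond j-k about the bond axis so that the dihedral i-j-k-l takes the
#' requested value.  Bond lengths and angles are untouched.
#'
#' @param topology a \code{\linkS4class{UATopology}}.
#' @param coords n x 3 coordinate matrix.
#' @param dihedral integer vector c(i, j, k, l); consecutive entries must be
#'   bonded.
#' @param target target dihedral angle in degrees.
#' @return rotated coordinate matrix.
#' @export
setDihedral <- function(topology, coords, dihedral, target) {
  stopifnot(length(dihedral) == 4)
  i <- dihedral[1]; j <- dihedral[2]; k <- dihedral[3]; l <- dihedral[4]
  bonds <- as.matrix(topology@bonds[, c("i", "j")])
  hasBond <- function(a, b) any((bonds[, 1] == min(a, b)) & (bonds[, 2] == max(a, b)))
  if (!hasBond(i, j) || !hasBond(j, k) || !hasBond(k, l))
    stop("dihedral spec atoms are not bonded in sequence")
  n <- nrow(coords)
  keep <- bonds[!((bonds[, 1] == min(j, k)) & (bonds[, 2] == max(j, k))), ,
                drop = FALSE]
  adj <- .adjacency(n, keep)
  side <- is.finite(.graphDistances(adj, k))
  if (side[j]) stop("central bond lies on a ring; rigid rotation is undefined")
  cur <- measureDihedral(coords, i, j, k, l)
  delta <- (cur - target) * pi / 180
  axis <- .unit(coords[k, ] - coords[j, ])
  origin <- coords[j, ]
  rot <- .rotationMatrix(axis, delta)
  idx <- which(side)
  coords[idx, ] <- sweep(sweep(coords[idx, , drop = FALSE], 2, origin) %*% t(rot),
                         2, origin, `+`)
  coords
}

.rotationMatrix <- function(axis, angle) {
  u <- .unit(axis); c0 <- cos(angle); s0 <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * c0 + s0 * ux + (1 - c0) * (u %o% u)
}

#' Model dipole moment of a conformation
#'
#' Computes the point-charge dipole moment of the model,
#' \eqn{\mu = \sum_i q_i r_i}, in debye.  Meaningful for neutral molecules
#' (origin-independent).
#'
#' @param topology a \code{\linkS4class{UATopology}}.
#' @param coords n x 3 coordinate matrix (nm); built from the equilibrium
#'   geometry if omitted.
#' @return list with \code{vector} (D, length 3) and \code{magnitude} (D).
#' @export
dipoleMoment <- function(topology, coords = buildConformation(topology)) {
  q <- topology@sites$charge
  eNm2D <- 1.602176634e-28 / orgsilConstants()$debye   # e nm -> D
  v <- colSums(coords * q) * eNm2D
  list(vector = v, magnitude = .norm(v))
}
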