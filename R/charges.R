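#' Assign point charges with silicon neutrality closure
#'
#' Substituent charges come from the packaged charge rules: alkyl CH_x
#' bonded to an all-alkyl silicon take -0.24 e; CH3/CH2 bonded to a silicon
#' that also carries oxygenated substituents take -0.32/-0.27 e; CH_x bonded
#' to an alkoxy oxygen take +0.25 e; chain CH_x not adjacent to Si or O_C are
#' neutral; the oxygen and hydroxyl-hydrogen types take their tabulated
#' values.  The silicon charge is never tabulated ("bespoke"): each silicon
#' closes overall charge neutrality over its own substituents, and is kept at
#' full precision rather than rounded.  In multi-silicon molecules every
#' non-silicon atom contributes to its nearest silicon, with atoms
#' equidistant from several silicons (e.g. a bridging O_B) split equally
#' between them.
#'
#' @param typed a typed united-atom \code{\linkS4class{MoleculeGraph}} from
#'   \code{\link{assignAtomTypes}}.
#' @param params a \code{\linkS4class{ParameterSet}}.
#' @return numeric vector of per-site charges (e), summing to zero.
#' @export
#' @examples
#' g <- assignAtomTypes(perceiveUnitedAtoms(siliconMolecule("Met4Si")))
#' q <- assignCharges(g, defaultParameters())
#' q[g@types == "Si"]   # +0.96
assignCharges <- function(typed, params = defaultParameters()) {
  stopifnot(is(typed, "MoleculeGraph"))
  if (!any(nzchar(typed@types))) stop("run assignAtomTypes() first")
  ty <- typed@types
  n <- length(ty)
  adj <- .adjacency(n, typed@bonds)
  rules <- params@charges
  carbon <- c("CH3", "CH2", "CH", "C")
  q <- numeric(n)
  for (i in seq_len(n)) {
    t <- ty[i]
    if (t %in% c("O_C", "O_H", "O_B", "H_O")) {
      q[i] <- rules[[t]]
    } else if (t %in% carbon) {
      nbt <- ty[adj[[i]]]
      siNb <- adj[[i]][nbt == "Si"]
      if (length(siNb)) {
        k <- typed@siK[siNb[1]]
        if (k == 0L) {
          q[i] <- rules[["CHx_Si_alkyl"]]
        } else if (t == "CH3") {
          q[i] <- rules[["CH3_Si_oxy"]]
        } else if (t == "CH2") {
          q[i] <- rules[["CH2_Si_oxy"]]
        } else {
          stop(sprintf("no charge rule for %s bonded to an oxygenated silicon (atom %d)", t, i))
        }
      } else if (any(nbt == "O_C")) {
        q[i] <- rules[["CHx_OC"]]
      } else {
        q[i] <- 0
      }
    }
  }
  siIdx <- which(ty == "Si")
  if (!length(siIdx)) {
    if (abs(sum(q)) > 1e-12)
      stop(sprintf("no silicon to close neutrality; residual %.4g e", sum(q)))
    return(q)
  }
  ## distance of every atom to each silicon; split each atom's charge
  ## equally over its nearest silicon(s)
  dSi <- vapply(siIdx, function(s) .graphDistances(adj, s), numeric(n))
  dSi <- matrix(dSi, nrow = n)
  for (i in setdiff(seq_len(n), siIdx)) {
    dmin <- min(dSi[i, ])
    owners <- siIdx[dSi[i, ] == dmin]
    q[owners] <- q[owners] - q[i] / length(owners)
  }
  if (abs(sum(q)) > 1e-12)
    stop(sprintf("charge neutrality closure failed; residual %.4g e", sum(q)))
  q
}
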