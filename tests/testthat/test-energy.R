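params <- defaultParameters()

test_that("Lorentz-Berthelot combination is correct and symmetric", {
  same <- combineLJ(0.375, 0.8148, 0.375, 0.8148)
  expect_equal(same$sigma, 0.375)
  expect_equal(same$epsilon, 0.8148)
  mix <- combineLJ(0.580, 0.108, 0.235, 1.344)
  expect_equal(mix$sigma, 0.4075)
  expect_equal(mix$epsilon, sqrt(0.108 * 1.344), tolerance = 1e-12)
  expect_equal(mix$epsilon, 0.38099, tolerance = 1e-4)
  ## symmetry and annihilator
  rev <- combineLJ(0.235, 1.344, 0.580, 0.108)
  expect_identical(mix$sigma, rev$sigma)
  expect_identical(mix$epsilon, rev$epsilon)
  expect_equal(combineLJ(0.3, 0, 0.5, 2)$epsilon, 0)
  expect_error(combineLJ(-0.1, 1, 0.3, 1), "non-negative")
})

test_that("Ryckaert-Bellemans series matches a brute-force cosine-power oracle", {
  expect_equal(rbEnergy(seq(0, 360, 10), rep(0, 6)), rep(0, 37))
  expect_equal(rbEnergy(seq(0, 360, 10), c(1, 0, 0, 0, 0, 0)), rep(1, 37))
  ## trans value of the alkylsilane backbone class is its own self-check
  expect_equal(rbEnergy(180, c(1.224, 3.672, 0, -4.895, 0, 0)), 0.001,
               tolerance = 1e-12)
  set.seed(5)
  for (r in 1:1000) {
    C <- stats::runif(6, -20, 20)
    phi <- stats::runif(1, -720, 720)
    oracle <- sum(C * cos((phi - 180) * pi / 180)^(0:5))
    expect_equal(rbEnergy(phi, C), oracle, tolerance = 1e-12)
  }
})

test_that("intramolecular nonbonded sums run over non-excluded pairs only", {
  tms <- buildTopology(siliconMolecule("Met4Si"), params)
  e <- intramolecularNonbonded(tms, buildConformation(tms))
  expect_identical(e$lj, 0)
  expect_identical(e$coulomb, 0)

  ## single-pair oracle on a hand-built two-site topology
  two <- new("UATopology", name = "pair",
             sites = data.frame(type = c("O_C", "CH3"), siK = NA_integer_,
                                charge = c(-0.68, 0.25 + 0.43), sigma = c(0.3, 0.3),
                                epsilon = c(1, 1)),
             bonds = data.frame(i = integer(), j = integer(), r0 = numeric(),
                                key = character()),
             angles = data.frame(), torsions = data.frame(),
             torsionC = matrix(numeric(), ncol = 6),
             exclusions = matrix(integer(), ncol = 2), validated = TRUE)
  ## note: charges chosen to sum to zero to satisfy the validity check
  r <- 0.47
  xy <- rbind(c(0, 0, 0), c(r, 0, 0))
  e <- intramolecularNonbonded(two, xy)
  expect_equal(e$coulomb, 138.935458 * (-0.68) * 0.68 / r, tolerance = 1e-12)
  expect_equal(e$lj, 4 * 1 * ((0.3 / r)^12 - (0.3 / r)^6), tolerance = 1e-12)
  ## LJ root at r = sigma
  xy2 <- rbind(c(0, 0, 0), c(0.3, 0, 0))
  two@sites$charge <- c(0, 0)
  expect_equal(intramolecularNonbonded(two, xy2)$lj, 0, tolerance = 1e-12)
  ## overlap reported, not returned as infinity
  expect_error(intramolecularNonbonded(two, rbind(c(0, 0, 0), c(0, 0, 1e-9))),
               "overlapping")
})

test_that("nonbonded sums equal an all-pairs oracle minus excluded pairs", {
  skip_if_not_installed("igraph")
  set.seed(21)
  top <- buildTopology(siliconMolecule("SiOEth4"), params)
  xyz <- buildConformation(top)
  s <- sites(top)
  ig <- igraph::graph_from_edgelist(bondList(top), directed = FALSE)
  d <- igraph::distances(ig)
  oracle <- c(lj = 0, coul = 0)
  for (i in 1:(nrow(s) - 1)) for (j in (i + 1):nrow(s)) {
    if (d[i, j] <= 3) next
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    p <- combineLJ(s$sigma[i], s$epsilon[i], s$sigma[j], s$epsilon[j])
    sr6 <- (p$sigma / r)^6
    oracle["lj"] <- oracle["lj"] + 4 * p$epsilon * (sr6^2 - sr6)
    oracle["coul"] <- oracle["coul"] + 138.935458 * s$charge[i] * s$charge[j] / r
  }
  e <- intramolecularNonbonded(top, xyz)
  expect_equal(e$lj, unname(oracle["lj"]), tolerance = 1e-12)
  expect_equal(e$coulomb, unname(oracle["coul"]), tolerance = 1e-12)
})

test_that("energies are invariant under rigid translation and rotation", {
  set.seed(31)
  top <- buildTopology(siliconMolecule("M2SiOM2"), params)
  xyz <- buildConformation(top)
  e0 <- intramolecularNonbonded(top, xyz)$total
  t0 <- torsionEnergy(top, xyz)
  for (rep in 1:5) {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    R <- orgsil:::.rotationMatrix(ax, stats::runif(1, 0, 2 * pi))
    xyz2 <- sweep(xyz %*% t(R), 2, stats::rnorm(3), `+`)
    expect_equal(intramolecularNonbonded(top, xyz2)$total, e0, tolerance = 1e-9)
    expect_equal(torsionEnergy(top, xyz2), t0, tolerance = 1e-9)
  }
})

test_that("conformation embedding honors constraints and equilibrium angles", {
  for (nm in c("Eth4Si", "Met3SiOH", "SiOMet4", "Met6Si2O")) {
    top <- buildTopology(siliconMolecule(nm), params)
    xyz <- buildConformation(top)
    b <- top@bonds
    lens <- vapply(seq_len(nrow(b)), function(r)
      sqrt(sum((xyz[b$i[r], ] - xyz[b$j[r], ])^2)), 0)
    expect_equal(lens, b$r0, tolerance = 1e-9)
    a <- top@angles
    ths <- vapply(seq_len(nrow(a)), function(r)
      measureAngle(xyz, a$i[r], a$j[r], a$k[r]), 0)
    ## branch placement keeps angles within a few degrees of theta0
    expect_lt(max(abs(ths - a$theta0)), 8)
  }
})

test_that("torsion profiles are periodic and reduce to the RB curve in isolation", {
  ## hand-built 4-site chain with one torsion and no nonbonded pairs
  C <- c(1.224, 3.672, 0, -4.895, 0, 0)
  chain <- new("UATopology", name = "chain",
               sites = data.frame(type = c("CH3", "CH2", "Si", "CH3"),
                                  siK = NA_integer_, charge = 0,
                                  sigma = 0.1, epsilon = 0),
               bonds = data.frame(i = 1:3, j = 2:4, r0 = c(0.154, 0.1875, 0.1875),
                                  key = c("C-C", "C-Si", "C-Si")),
               angles = data.frame(), torsions = data.frame(i = 1L, j = 2L,
                                                            k = 3L, l = 4L,
                                                            class = "C-C-Si-C"),
               torsionC = matrix(C, 1), exclusions = excludedPairs(cbind(1:3, 2:4), 4),
               validated = TRUE)
  prof <- torsionProfile(chain, c(1, 2, 3, 4))
  expect_equal(prof$E_total, rbEnergy(prof$angle, C), tolerance = 1e-9)
  expect_equal(prof$E_LJ, rep(0, 12))
  ## periodicity
  xyz <- buildConformation(chain)
  p0 <- torsionProfile(chain, c(1, 2, 3, 4), angles = 35, coords = xyz)
  p360 <- torsionProfile(chain, c(1, 2, 3, 4), angles = 35 + 360, coords = xyz)
  expect_equal(p0$E_total, p360$E_total, tolerance = 1e-9)
  ## bad dihedral spec
  expect_error(torsionProfile(chain, c(1, 3, 2, 4)), "not bonded in sequence")
})

test_that("the alkoxysilane scan carries nonzero 1-5 LJ and Coulomb terms", {
  top <- buildTopology(siliconMolecule("M2SiOM2"), params)
  tr <- top@torsions
  i <- which(tr$class == "C-O_C-Si-O_C")[1]
  d <- as.integer(tr[i, c("i", "j", "k", "l")])
  prof <- torsionProfile(top, d)
  expect_gt(diff(range(prof$E_LJ)), 1e-6)
  expect_gt(diff(range(prof$E_Coulomb)), 1e-6)
})
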