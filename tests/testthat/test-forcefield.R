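params <- defaultParameters()

test_that("united-atom perception merges aliphatic hydrogens and keeps hydroxyl H", {
  ua <- perceiveUnitedAtoms(alkane(2))
  expect_equal(natoms(ua), 2L)
  expect_equal(ua@labels, c("CH3", "CH3"))

  ua <- perceiveUnitedAtoms(siliconMolecule("Met3SiOH"))
  expect_equal(natoms(ua), 6L)
  expect_equal(sort(table(ua@labels), decreasing = TRUE),
               sort(table(c("Si", "CH3", "CH3", "CH3", "O", "H_O")),
                    decreasing = TRUE))

  ua <- perceiveUnitedAtoms(siliconMolecule("SiOEth4"))
  expect_equal(natoms(ua), 13L)
  expect_equal(sum(ua@labels == "CH2"), 4L)
  expect_equal(sum(ua@labels == "CH3"), 4L)
  expect_equal(sum(ua@labels == "O"), 4L)
})

test_that("perception rejects Si-H and malformed hydrogens", {
  sih <- moleculeGraph("silane-like", c("Si", "H", "H", "H", "H"),
                       cbind(1L, 2:5))
  expect_error(perceiveUnitedAtoms(sih), "out of scope")
  bad <- moleculeGraph("bridging-H", c("C", "C", "H", "H", "H", "H", "H", "H", "H"),
                       rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5),
                             c(2, 6), c(2, 7), c(2, 8), c(1, 9), c(2, 9)))
  expect_error(perceiveUnitedAtoms(bad), "malformed")
})

test_that("atom typing classifies oxygens and counts oxygenated substituents", {
  g <- assignAtomTypes(perceiveUnitedAtoms(siliconMolecule("SiOMet4")))
  expect_equal(g@siK[g@types == "Si"], 4L)
  expect_true(all(g@types[grepl("^O", g@labels)] == "O_C"))

  g <- assignAtomTypes(perceiveUnitedAtoms(siliconMolecule("Met6Si2O")))
  expect_equal(unname(g@siK[g@types == "Si"]), c(1L, 1L))
  expect_equal(sum(g@types == "O_B"), 1L)

  g <- assignAtomTypes(perceiveUnitedAtoms(siliconMolecule("Eth3SiOH")))
  expect_equal(g@siK[g@types == "Si"], 1L)
  expect_equal(sum(g@types == "O_H"), 1L)
  adjSi <- which(g@types == "Si")
  ch2 <- which(g@types == "CH2")
  onSi <- vapply(ch2, function(i) any(g@bonds[g@bonds[, 1] == i, 2] == adjSi |
                                      g@bonds[g@bonds[, 2] == i, 1] == adjSi), TRUE)
  expect_equal(sum(onSi), 3L)
  expect_equal(sum(g@types == "CH3"), 3L)
})

test_that("charge assignment closes neutrality on silicon", {
  q <- modelChargesByRole("Met4Si", params)
  expect_equal(unname(q["Si"]), 0.96, tolerance = 1e-12)
  expect_equal(unname(q["CH3_Si"]), -0.24)

  q <- modelChargesByRole("Met6Si2O", params)
  expect_equal(unname(q["Si"]), 1.40, tolerance = 1e-12)

  q <- modelChargesByRole("SiOEth4", params)
  expect_equal(unname(q["Si"]), 1.72, tolerance = 1e-12)
  expect_equal(unname(q["CHx_O"]), 0.25)
  expect_equal(unname(q["CH3_CH2O"]), 0)
})

test_that("every generated topology is neutral with all parameters assigned", {
  for (nm in siliconMoleculeNames()) {
    top <- buildTopology(siliconMolecule(nm), params)
    s <- sites(top)
    expect_lt(abs(sum(s$charge)), 1e-12)
    expect_true(all(is.finite(s$sigma)) && all(is.finite(s$epsilon)))
    expect_true(all(s$epsilon >= 0))
  }
})

test_that("bonded-term enumeration matches the combinatorial count", {
  top <- buildTopology(siliconMolecule("Eth4Si"), params)
  expect_equal(natoms(top), 9L)
  expect_equal(nrow(top@bonds), 8L)
  expect_equal(nrow(top@angles), 10L)   # 6 C-Si-C + 4 Si-C-C
  expect_equal(sum(top@angles$key == "C-Si-C"), 6L)
  expect_equal(sum(top@angles$key == "Si-C-C"), 4L)
  expect_equal(nrow(top@torsions), 12L)
  expect_true(all(top@torsions$class == "C-C-Si-C"))
  ## bond length and angle parameter examples
  expect_true(all(top@bonds$r0[top@bonds$key == "C-Si"] == 0.1875))
  hm <- buildTopology(siliconMolecule("Met6Si2O"), params)
  bridging <- hm@angles[hm@angles$key == "Si-O_B-Si", ]
  expect_equal(bridging$theta0, 149.5)
  expect_equal(bridging$kAngle, 61.3)
})

test_that("missing bonded parameters raise a named error", {
  p2 <- params
  p2@angles <- p2@angles[p2@angles$key != "Si-O_B-Si", ]
  expect_error(buildTopology(siliconMolecule("Met6Si2O"), p2),
               "missing angle parameter.*Si.*O_B.*Si")
})

test_that("LJ assignment follows the silicon sigma series and alkane carry-over", {
  top <- buildTopology(siliconMolecule("Met4Si"), params)
  si <- sites(top)[sites(top)$type == "Si", ]
  expect_equal(si$sigma, 0.580)
  expect_equal(si$epsilon, 0.108)
  top <- buildTopology(siliconMolecule("Met3SiOH"), params)
  expect_equal(sites(top)$sigma[sites(top)$type == "Si"], 0.551)
  top <- buildTopology(siliconMolecule("SiOMet4"), params)
  expect_equal(sites(top)$sigma[sites(top)$type == "Si"], 0.464)
  ## hydroxyl hydrogen is charge-only
  top <- buildTopology(siliconMolecule("Eth3SiOH"), params)
  ho <- sites(top)[sites(top)$type == "H_O", ]
  expect_equal(ho$sigma, 0)
  expect_equal(ho$epsilon, 0)
  ## absent alkane constants are a hard, instructive error
  p2 <- params
  p2@alkaneLJ <- p2@alkaneLJ[p2@alkaneLJ$type != "CH2", ]
  expect_error(buildTopology(siliconMolecule("Eth4Si"), p2),
               "alkane LJ constants")
})

test_that("sigma scaling law extrapolates and validates the stored table", {
  expect_equal(siliconSigma(params, 0:4),
               0.580 * (1 - 0.05 * (0:4)))
  expect_equal(round(siliconSigma(params, 0:4), 3),
               siliconSigma(params, 0:4, fromBase = FALSE))
  expect_error(siliconSigma(params, 5, fromBase = FALSE), "no stored LJ entry")
  expect_error(siliconSigma(params, -1), "non-negative")
})

test_that("typing and charges are invariant under atom reindexing", {
  set.seed(11)
  for (nm in c("Eth3SiOH", "SiOEth4", "Met6Si2O")) {
    g <- siliconMolecule(nm)
    perm <- sample(natoms(g))
    inv <- order(perm)
    g2 <- moleculeGraph(g@name, g@elements[inv],
                        matrix(perm[as.integer(g@bonds)], ncol = 2))
    t1 <- buildTopology(g, params)
    t2 <- buildTopology(g2, params)
    expect_equal(sort(sites(t1)$type), sort(sites(t2)$type))
    expect_equal(sort(charges(t1)), sort(charges(t2)))
    expect_equal(sort(sites(t1)$sigma), sort(sites(t2)$sigma))
    expect_equal(nrow(t1@torsions), nrow(t2@torsions))
  }
})

test_that("exclusions cover exactly the pairs within three bonds", {
  ## path-graph count: (n-1) + (n-2) + (n-3)
  for (n in 4:7) {
    bonds <- cbind(seq_len(n - 1), 2:n)
    expect_equal(nrow(excludedPairs(bonds, n)), (n - 1) + (n - 2) + (n - 3))
  }
  ## butane-like chain: the 1-4 pair is excluded
  ex <- excludedPairs(cbind(1:3, 2:4), 4)
  expect_true(any(ex[, 1] == 1 & ex[, 2] == 4))
  ## tetramethylsilane: every pair within three bonds, no nonbonded pairs
  tms <- buildTopology(siliconMolecule("Met4Si"), params)
  expect_equal(nrow(exclusions(tms)), choose(5, 2))
  expect_equal(nrow(nonbondedPairs(tms)), 0L)
  ## dimethyldimethoxysilane keeps the 1-5 methoxy-carbon pair nonbonded
  dm <- buildTopology(siliconMolecule("M2SiOM2"), params)
  ty <- sites(dm)$type
  termC <- which(ty == "CH3" & vapply(seq_along(ty), function(i) {
    nb <- c(dm@bonds$j[dm@bonds$i == i], dm@bonds$i[dm@bonds$j == i])
    any(ty[nb] == "O_C")
  }, TRUE))
  expect_length(termC, 2L)
  nb <- nonbondedPairs(dm)
  expect_true(any(nb[, 1] == min(termC) & nb[, 2] == max(termC)))
})

test_that("exclusion list agrees with an independent graph-distance oracle", {
  skip_if_not_installed("igraph")
  g <- siliconMolecule("SiOEth4")
  top <- buildTopology(g, params)
  ig <- igraph::graph_from_edgelist(bondList(top), directed = FALSE)
  d <- igraph::distances(ig)
  oracle <- which(d >= 1 & d <= 3 & upper.tri(d), arr.ind = TRUE)
  oracle <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
  ex <- exclusions(top)
  ex <- ex[order(ex[, 1], ex[, 2]), , drop = FALSE]
  expect_equal(unname(ex), unname(oracle))
})

test_that("parameter configuration round-trips through an edited copy", {
  f <- tempfile(fileext = ".yaml")
  file.copy(system.file("extdata", "params", "organosilicon.yaml",
                        package = "orgsil"), f)
  p2 <- readParameters(f)
  expect_equal(p2@charges, params@charges)
  expect_equal(p2@torsions, params@torsions)
  expect_equal(p2@sigmaScale, 0.05)
})
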