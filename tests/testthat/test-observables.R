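test_that("liquid dipole follows the continuum enhancement", {
  expect_equal(liquidDipole(0, eps = 20, epsInf = 2), 0)
  expect_equal(liquidDipole(1.7, eps = 1, epsInf = 1), 1.7)
  ## water-like check against an independent hand evaluation of the factor
  f <- (2 * 78.4 + 1) * (1.78 + 2) / (3 * (2 * 78.4 + 1.78))
  expect_equal(liquidDipole(1.85, eps = 78.4, epsInf = 1.78), 1.85 * f,
               tolerance = 1e-12)
  expect_equal(1.85 * f, 2.3196, tolerance = 1e-4)
  ## monotone in eps at fixed epsInf
  eps <- seq(1, 80, length.out = 40)
  mu <- vapply(eps, function(e) liquidDipole(1.7, eps = e, epsInf = 1.9), 0)
  expect_true(all(diff(mu) >= 0))
  ## enhancement whenever eps > epsInf > 1
  expect_gt(liquidDipole(1, eps = 10, epsInf = 2), 1)
  expect_error(liquidDipole(1, eps = 0.5, epsInf = 1), ">= 1")
})

test_that("polarization energy has the documented signs and limits", {
  pr <- electronicProperties(muGas = 1.7, alpha = 11, eps = 7, nD = 1.39)
  ## no-response limit: mu_liq = mu_gas and eps_inf = 1
  pr0 <- electronicProperties(muGas = 1.7, alpha = 11, eps = 1, nD = 1)
  z <- polarizationEnergy(pr0)
  expect_equal(z$muLiq, 1.7)
  expect_identical(z$distortion, 0)
  expect_identical(z$electronic, 0)
  expect_identical(z$ePol, 0)
  ## distortion positive, electronic zero when eps_inf = 1 but mu enhanced
  prA <- electronicProperties(muGas = 1.7, alpha = 11, eps = 10, nD = 1)
  a <- polarizationEnergy(prA, muLiq = 2.1)
  expect_gt(a$distortion, 0)
  expect_identical(a$electronic, 0)
  ## general case: distortion >= 0, electronic <= 0
  g <- polarizationEnergy(pr)
  expect_gte(g$distortion, 0)
  expect_lte(g$electronic, 0)
  ## doubling both dipoles quadruples the distortion term
  g2 <- polarizationEnergy(
    electronicProperties(muGas = 3.4, alpha = 11, eps = 7, nD = 1.39),
    muLiq = 2 * g$muLiq)
  expect_equal(g2$distortion, 4 * g$distortion, tolerance = 1e-12)
  ## unit oracle: 1 D^2/A^3 of (mu_liq - mu_gas)^2 / (2 alpha) is
  ## 60.2214/2 kJ/mol
  pu <- polarizationEnergy(
    electronicProperties(muGas = 0, alpha = 1, eps = 1, nD = 1), muLiq = 1)
  expect_equal(pu$distortion, 60.2214076 / 2, tolerance = 1e-6)
})

test_that("enthalpy of vaporization assembles energies, RT and E_Pol", {
  s <- simulationSummary(uLiq = -10, uGas = -10, T = 298.15)
  expect_equal(enthalpyOfVaporization(s, 0), 8.314462618 * 298.15 / 1000,
               tolerance = 1e-12)
  expect_equal(enthalpyOfVaporization(s, 0), 2.479, tolerance = 1e-3)
  ## linear in the liquid energy
  s2 <- simulationSummary(uLiq = -10 + 1.5, uGas = -10, T = 298.15)
  expect_equal(enthalpyOfVaporization(s, 0) - enthalpyOfVaporization(s2, 0),
               1.5, tolerance = 1e-12)
  ## a negative (stabilizing) polarization energy raises the enthalpy
  expect_equal(enthalpyOfVaporization(s, -2.5) - enthalpyOfVaporization(s, 0),
               2.5, tolerance = 1e-12)
  expect_error(enthalpyOfVaporization(simulationSummary(-10, NA)), "gas-phase")
})

test_that("dielectric correction is the identity in the perfect-model limit", {
  expect_equal(correctDielectric(1.5, epsInf = 1, muLiq = 2, muModel = 2), 1.5)
  expect_equal(correctDielectric(1, epsInf = 1.8, muLiq = 2, muModel = 2), 1.8)
  ## adds electronic response when epsInf > 1
  expect_gte(correctDielectric(2, epsInf = 1.9, muLiq = 2, muModel = 2), 2)
  ## nonpolar molecules reduce to epsInf + (eps_sim - 1)
  expect_equal(correctDielectric(1.02, epsInf = 1.85, muLiq = 0, muModel = 0),
               1.87)
  expect_error(correctDielectric(0.9, 1.5, 1, 1), ">= 1")
})

test_that("solvation free-energy correction is plain addition", {
  expect_equal(correctSolvationFreeEnergy(-20, 0), -20)
  expect_equal(correctSolvationFreeEnergy(-20, -2.5), -22.5)
  expect_equal(correctSolvationFreeEnergy(0, 1), 1)
})

test_that("box-dipole fluctuations give the dielectric constant", {
  ## constant dipole: no fluctuation
  M <- matrix(rep(c(3, -1, 2), each = 50), ncol = 3)
  expect_equal(dielectricFromBoxDipole(M, V = 30)$eps, 1)
  ## synthetic Gaussian dipoles against the closed-form evaluation
  set.seed(12)
  sd0 <- 5
  M <- matrix(stats::rnorm(3 * 20000, sd = sd0), ncol = 3)
  r <- dielectricFromBoxDipole(M, V = 30, T = 298.15)
  cst <- orgsilConstants()
  expected <- 1 + 3 * sd0^2 * cst$debye^2 /
    (3 * cst$eps0 * 30e-27 * cst$kB * 298.15)
  expect_equal(r$eps, expected, tolerance = 0.03)
  expect_gt(r$uncertainty, 0)
  ## doubling the volume halves (eps - 1)
  r2 <- dielectricFromBoxDipole(M, V = 60, T = 298.15)
  expect_equal(r2$eps - 1, (r$eps - 1) / 2, tolerance = 1e-12)
  expect_error(dielectricFromBoxDipole(M, V = 0), "positive")
})

test_that("sampling error of the fluctuation dielectric shrinks as 1/sqrt(N)", {
  set.seed(33)
  cst <- orgsilConstants()
  sd0 <- 5
  expected <- 3 * sd0^2 * cst$debye^2 / (3 * cst$eps0 * 30e-27 * cst$kB * 298.15)
  err <- vapply(c(200, 2000, 20000), function(n) {
    e <- replicate(20, {
      M <- matrix(stats::rnorm(3 * n, sd = sd0), ncol = 3)
      dielectricFromBoxDipole(M, V = 30, T = 298.15)$eps - 1
    })
    sqrt(mean((e - expected)^2))
  }, 0)
  ## each tenfold increase in samples shrinks the error by roughly sqrt(10)
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[2])
})

test_that("Einstein diffusion and finite-size extrapolation recover planted values", {
  t <- 0:100
  expect_equal(diffusionFromMSD(t, 6 * 3.8e-3 * t)$D, 3.8e-9, tolerance = 1e-12)
  expect_equal(diffusionFromMSD(t, rep(2, 101))$D, 0)
  ## noisy planted slope recovered within its fit standard error
  set.seed(9)
  ok <- 0
  for (r in 1:20) {
    msd <- 6 * 3.8e-3 * t + stats::rnorm(101, sd = 0.05)
    msd <- pmax(msd, 0)
    fit <- diffusionFromMSD(t, msd, window = c(10, 100))
    if (abs(fit$D - 3.8e-9) < 2 * fit$se) ok <- ok + 1
  }
  expect_gte(ok, 17)   # about 95 percent coverage
  ## collinear finite-size data: exact intercept
  ex <- extrapolateDiffusionInfiniteBox(c(2, 4, 8), c(1.5, 1.75, 1.875))
  expect_equal(ex$Dinf, 2, tolerance = 1e-12)
  expect_equal(extrapolateDiffusionInfiniteBox(c(2, 3, 5), rep(4, 3))$Dinf, 4)
  expect_error(extrapolateDiffusionInfiniteBox(c(2, 2), c(1, 2)), "distinct")
  ## Monte-Carlo: intercept within twice its standard error most of the time
  set.seed(14)
  L <- c(2.5, 3.1, 4.2)
  ok <- 0
  for (r in 1:200) {
    D <- 3.8 - 2 / L + stats::rnorm(3, sd = 0.05)
    fit <- extrapolateDiffusionInfiniteBox(L, D)
    if (abs(fit$Dinf - 3.8) < 2 * fit$se) ok <- ok + 1
  }
  expect_gte(ok, 120)
})

test_that("model dipole of the rigid geometry is stable and origin-free", {
  top <- buildTopology(siliconMolecule("Met3SiOH"))
  d1 <- dipoleMoment(top)
  xyz <- buildConformation(top)
  d2 <- dipoleMoment(top, sweep(xyz, 2, c(1, -2, 0.5), `+`))
  expect_equal(d1$magnitude, d2$magnitude, tolerance = 1e-9)
  expect_gt(d1$magnitude, 1)   # silanols are polar
  tms <- buildTopology(siliconMolecule("Met4Si"))
  expect_lt(dipoleMoment(tms)$magnitude, 1e-9)   # tetramethylsilane is not
})
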