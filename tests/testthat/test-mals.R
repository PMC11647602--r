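# forward-model helpers kept independent of the analysis path: signals are
# built directly from Beer-Lambert / RI / Rayleigh algebra
forwardUvRi <- function(cp, cd, optics = componentOptics(), l = 1) {
  list(a260 = l * (optics$proteinE260 * cp + optics$dnaE260 * cd),
       a280 = l * (optics$proteinE280 * cp + optics$dnaE280 * cd),
       ri = optics$dndcProtein * cp + optics$dndcDna * cd)
}

kstarOf <- function(dndc, constants = opticalConstants()) {
  lam <- constants$wavelength * 1e-7
  4 * pi^2 * constants$solventRI^2 * dndc^2 / (lam^4 * 6.02214076e23)
}

sphereRayleigh <- function(M, cTotal, dndc, radius,
                           constants = opticalConstants()) {
  q <- 4 * pi * constants$solventRI *
    sin(constants$angles / 2 * pi / 180) / constants$wavelength
  x <- q * radius
  P <- ifelse(x < 1e-8, 1, (3 * (sin(x) - x * cos(x)) / x^3)^2)
  kstarOf(dndc, constants) * (cTotal * 1e-3) * M * P
}

test_that("conjugate decomposition recovers pure components exactly", {
  op <- componentOptics()
  s <- forwardUvRi(0.1, 0, op)
  out <- conjugateConcentrations(s$a260, s$a280, s$ri, op)
  expect_equal(out$cProtein, 0.1, tolerance = 1e-12)
  expect_equal(out$cDna, 0, tolerance = 1e-12)
  expect_equal(out$dndcConjugate, op$dndcProtein)

  s2 <- forwardUvRi(0, 0.05, op)
  out2 <- conjugateConcentrations(s2$a260, s2$a280, s2$ri, op)
  expect_equal(out2$cProtein, 0, tolerance = 1e-12)
  expect_equal(out2$cDna, 0.05, tolerance = 1e-12)
})

test_that("conjugate decomposition survives 1% detector noise within 5%", {
  op <- componentOptics()
  s <- forwardUvRi(0.08, 0.02, op)
  set.seed(3)
  out1 <- conjugateConcentrations(s$a260 * (1 + rnorm(1, 0, 0.01)),
                                  s$a280 * (1 + rnorm(1, 0, 0.01)),
                                  s$ri * (1 + rnorm(1, 0, 0.01)), op)
  expect_lt(percentDifference(out1$cProtein, 0.08), 5)
  expect_lt(percentDifference(out1$cDna, 0.02), 5)
  ## the typical (median) error over repeated draws is well inside 5%
  errs <- replicate(20, {
    out <- conjugateConcentrations(s$a260 * (1 + rnorm(1, 0, 0.01)),
                                   s$a280 * (1 + rnorm(1, 0, 0.01)),
                                   s$ri * (1 + rnorm(1, 0, 0.01)), op)
    max(percentDifference(out$cProtein, 0.08),
        percentDifference(out$cDna, 0.02))
  })
  expect_lt(median(errs), 5)
  ## a negative least-squares solution clamps to zero with refit
  s3 <- forwardUvRi(0.1, 0, op)
  out3 <- conjugateConcentrations(s3$a260 * 0.98, s3$a280, s3$ri * 1.02, op)
  expect_gte(out3$cDna, 0)
  expect_gte(out3$cProtein, 0)
  ## proportional component spectra are rejected
  degenerate <- componentOptics(dndcProtein = 0.185, dndcDna = 0.185,
                                proteinE260 = 1, proteinE280 = 2,
                                dnaE260 = 1, dnaE280 = 2)
  expect_error(conjugateConcentrations(1, 2, 0.1, degenerate), "singular")
})

test_that("Zimm intercept gives M and the slope gives Rg", {
  cst <- opticalConstants()
  ## isotropic scatterer: flat angular profile, Rg reported 0
  R <- sphereRayleigh(4.2e6, 0.2, 0.18, 0, cst)
  out <- sliceMolarMass(R, 0.2, 0.18, cst)
  expect_equal(out$molarMass, 4.2e6, tolerance = 1e-3)
  expect_lt(abs(out$rg), 0.01)
  expect_true(out$valid)

  ## uniform sphere: Rg = sqrt(3/5) R within 5% despite Zimm linearisation
  R2 <- sphereRayleigh(4.2e6, 0.2, 0.18, 12.5, cst)
  out2 <- sliceMolarMass(R2, 0.2, 0.18, cst)
  expect_equal(out2$rg, sqrt(3 / 5) * 12.5, tolerance = 0.05)

  ## doubling concentration at fixed R(theta) halves the apparent mass
  out3 <- sliceMolarMass(R, 0.4, 0.18, cst)
  expect_equal(out3$molarMass, out$molarMass / 2, tolerance = 1e-9)

  expect_error(sliceMolarMass(R[1:2], 0.2, 0.18, cst), "one column per")
})

test_that("molar mass is invariant to the configured wavelength", {
  for (wl in c(660, 690)) {
    cst <- opticalConstants(wavelength = wl)
    R <- sphereRayleigh(4.2e6, 0.15, 0.18, 12.5, cst)
    out <- sliceMolarMass(R, 0.15, 0.18, cst)
    expect_equal(out$molarMass, 4.2e6, tolerance = 2e-3)
    expect_equal(out$rg, sqrt(3 / 5) * 12.5, tolerance = 0.05)
  }
})

test_that("peak summary computes the weight-average mass and flatness", {
  sl <- data.frame(time = c(6.1, 6.2, 6.3), cTotal = c(1, 1, 1),
                   molarMass = rep(4.2e6, 3), rg = rep(12, 3),
                   fitResidual = 0, valid = TRUE)
  ms <- peakMALSSummary(sl, list(start = 6, end = 7))
  expect_equal(ms$mw, 4.2e6)
  expect_identical(ms$flatness, 0)
  expect_true(ms$monodisperse)

  sl2 <- data.frame(time = c(6.1, 6.2, 6.25, 6.3), cTotal = c(1, 1, 1, 1),
                    molarMass = c(4e6, 8e6, 4e6, 8e6), rg = 12,
                    fitResidual = 0, valid = TRUE)
  expect_equal(peakMALSSummary(sl2, list(start = 6, end = 7))$mw, 6e6)
  expect_error(peakMALSSummary(sl[1:2, ], list(start = 6, end = 7)),
               "fewer than 3")
})

test_that("a full MALS run recovers monomer mass, radius and HMW character", {
  run <- generateScenario("mals_run", list(noise = FALSE), seed = 1)$run
  sl <- analyzeMALSRun(run)
  tru <- runMetadata(run)
  ms <- peakMALSSummary(sl, list(start = 6.0, end = 7.0))
  expect_lt(percentDifference(ms$mw, tru$true_mw_monomer), 0.1)
  expect_lt(percentDifference(ms$rg, tru$true_rg_monomer), 5)
  expect_true(ms$monodisperse)
  hm <- peakMALSSummary(sl, list(start = 4.0, end = 5.8))
  expect_false(hm$monodisperse)
  expect_gt(max(sl$molarMass[sl$valid & sl$time < 5.8], na.rm = TRUE), 8e6)
  ## molar-mass route to the fill fraction closes the loop
  expect_equal(feFromMolarMass(ms$mw), tru$true_fill, tolerance = 0.01)
})

test_that("uncalibrated LS traces are refused", {
  run <- generateScenario("mals_run", list(noise = FALSE), seed = 1)$run
  run@lsCalibrated <- FALSE
  expect_error(analyzeMALSRun(run), "uncalibrated")
})

test_that("experimental mass EC is recovered from UV and conjugate slices", {
  ## empty capsid with true mass e280 = 1.78 (and e260 via the 0.59 factor)
  op <- componentOptics(proteinE260 = 0.59 * 1.78, proteinE280 = 1.78)
  fm <- componentFillModel(op)
  mk <- function(fill) generateChromatogram(
    list(speciesSpec("capsid", fill = fill, concentration = 0.25,
                     apex = 6.5, id = "m")),
    noise = NULL, fillModel = fm, optics = op,
    channels = c("UV260", "UV280", "FLD", "RI",
                 names(opticalConstants()$angles)))
  peak <- list(start = 6.0, end = 7.0)
  empty <- mk(0)
  slE <- analyzeMALSRun(empty, optics = op)
  expect_lt(percentDifference(
    experimentalMassEC(empty, slE, peak, "UV280"), 1.78), 2)

  ## full capsid tuned so the conjugate e280 is 3.88
  me <- defaultEmptyCapsidMw(); mg <- defaultGenomeMw(); mf <- me + mg
  dnaE280 <- (3.88 * mf - me * 1.78) / mg
  op2 <- componentOptics(proteinE260 = 0.59 * 1.78, proteinE280 = 1.78,
                         dnaE280 = dnaE280)
  fm2 <- componentFillModel(op2)
  full <- generateChromatogram(
    list(speciesSpec("capsid", fill = 1, concentration = 0.25, apex = 6.5,
                     id = "m")),
    noise = NULL, fillModel = fm2, optics = op2,
    channels = c("UV260", "UV280", "FLD", "RI",
                 names(opticalConstants()$angles)))
  slF <- analyzeMALSRun(full, optics = op2)
  expect_lt(percentDifference(
    experimentalMassEC(full, slF, peak, "UV280"), 3.88), 2)

  ## ratio invariance: doubling absorbance and concentration leaves e fixed
  empty2 <- generateChromatogram(
    list(speciesSpec("capsid", fill = 0, concentration = 0.5, apex = 6.5,
                     id = "m")),
    noise = NULL, fillModel = fm, optics = op,
    channels = c("UV260", "UV280", "FLD", "RI",
                 names(opticalConstants()$angles)))
  sl2 <- analyzeMALSRun(empty2, optics = op)
  expect_equal(experimentalMassEC(empty2, sl2, peak, "UV280"),
               experimentalMassEC(empty, slE, peak, "UV280"),
               tolerance = 1e-6)
})

test_that("fill from molar mass is the clamped mass excess over the shell", {
  expect_identical(feFromMolarMass(3.7e6, 3.7e6, 1.2e6), 0)
  expect_identical(feFromMolarMass(4.9e6, 3.7e6, 1.2e6), 1)
  expect_equal(feFromMolarMass(4.2e6, 3.7e6, 1.2e6), 0.5 / 1.2, tolerance = 1e-9)
  expect_identical(feFromMolarMass(2e6, 3.7e6, 1.2e6), 0)
  expect_error(feFromMolarMass(4e6, 3.7e6, 0), "genomeMw")
})
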