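test_that("DNA-containing-capsid molar coefficients follow the linear model", {
  ## DNA-free limit: the capsid constants alone
  expect_equal(unname(molarECFullCapsid(0, 1)), c(3.72e6, 6.31e6))
  ## direct arithmetic at 1 MDa genome
  expect_equal(unname(molarECFullCapsid(1.0e6, 1)), c(2.372e7, 1.741e7))
  ## large-genome limit of the 260/280 ratio is the coefficient ratio
  e <- molarECFullCapsid(1e12, 1)
  expect_equal(e[["e260"]] / e[["e280"]], 20.0 / 11.1, tolerance = 1e-6)
  expect_gte(20.0 / 11.1, 1.8)
  expect_error(molarECFullCapsid(-1, 1), "mwDna")
  expect_error(molarECFullCapsid(1e6, 0.5), "vpVg")
})

test_that("ratio of the molar model stays inside the coefficient-ratio band", {
  for (mw in c(0, 10^seq(3, 9, by = 0.5))) {
    e <- molarECFullCapsid(mw, 1)
    r <- e[["e260"]] / e[["e280"]]
    expect_gte(r, 3.72 / 6.31 - 1e-12)
    expect_lte(r, 20.0 / 11.1 + 1e-12)
  }
})

test_that("empty-capsid e280 sums aromatic absorptivities over the 60-mer", {
  uniform <- CapsidComposition(aromatics = rbind(c(10, 30, 0), c(10, 30, 0),
                                                 c(10, 30, 0)))
  expect_equal(emptyCapsidE280(uniform), 60 * (10 * 5500 + 30 * 1490))
  ## a single Trp per monomer under the standard coefficient set
  oneTrp <- CapsidComposition(aromatics = rbind(c(1, 0, 0), c(1, 0, 0),
                                                c(1, 0, 0)))
  expect_equal(emptyCapsidE280(oneTrp) / 60, 5500)
  none <- CapsidComposition(aromatics = matrix(0, 3, 3))
  expect_equal(emptyCapsidE280(none), 0)
  ## per-VP route: count-weighted coefficients
  perVp <- CapsidComposition(perVpE280 = c(1.3e5, 1.2e5, 1.05e5))
  expect_equal(emptyCapsidE280(perVp), 5 * 1.3e5 + 5 * 1.2e5 + 50 * 1.05e5)
  expect_error(CapsidComposition(), "aromatic counts or per-VP")
})

test_that("the 0.59 conversion factor maps e280 to e260", {
  expect_equal(emptyCapsidE260(1.68), 0.9912)
  expect_equal(emptyCapsidE260(1.0), 0.59)
  expect_error(emptyCapsidE260(1.68, factor = 0), "factor")
  expect_error(emptyCapsidE260(-1), "e280")
})

test_that("molar/mass conversion is division by the species mass", {
  ## the mass that turns the DNA-free molar e280 into the printed 1.68
  expect_equal(massFromMolar(6.31e6, defaultEmptyCapsidMw()), 1.68)
  expect_equal(massFromMolar(0, 1e6), 0)
  e <- massFromMolar(4.07e6, 2.5e6)
  expect_equal(e * 2.5e6, 4.07e6, tolerance = 1e-12)
  expect_error(massFromMolar(1e6, 0), "mw")
})

test_that("interpolated coefficients hit the printed endpoint sets", {
  fm <- defaultFillModel()
  expect_equal(unname(ecAtFill(0, fm)), c(0.98, 1.68))
  expect_equal(unname(ecAtFill(1, fm)), c(5.65, 4.0))
  ## at the closed-form crossover the two wavelengths agree
  fstar <- (1.68 - 0.98) / ((1.68 - 0.98) + (5.65 - 4.0))
  e <- ecAtFill(fstar, fm)
  expect_lt(abs(e[["e260"]] - e[["e280"]]), 1e-12)
  expect_error(ecAtFill(1.2, fm), "fill fraction")
})

test_that("crossover fill sits near 30% for the printed sets", {
  fm <- defaultFillModel()
  expect_equal(crossoverFill(fm), 0.7 / 2.35, tolerance = 1e-12)
  ## symmetric toy model crosses at one half
  toy <- FillModel(ExtinctionSet(e260Mass = 1, e280Mass = 2, speciesMw = 1e6),
                   ExtinctionSet(e260Mass = 2, e280Mass = 1, speciesMw = 1e6))
  expect_equal(crossoverFill(toy), 0.5)
  ## mass weighting with equal masses reduces to the linear answer
  toyMw <- FillModel(toy@empty, toy@full, interpolation = "mass_weighted")
  expect_equal(crossoverFill(toyMw), 0.5, tolerance = 1e-10)
  ## crossover consistency: ratio there is 1
  expect_equal(ratioAtFill(crossoverFill(fm), fm), 1, tolerance = 1e-9)
  mw <- defaultFillModel("mass_weighted")
  expect_equal(ratioAtFill(crossoverFill(mw), mw), 1, tolerance = 1e-9)
})

test_that("ratio endpoints match the published empty/full signatures", {
  fm <- defaultFillModel()
  expect_equal(ratioAtFill(1, fm), 5.65 / 4.0)   # ~1.41, the full-capsid mark
  expect_equal(ratioAtFill(0, fm), 0.98 / 1.68)
  ## under the conversion-factor construction the empty ratio is the factor
  emptyCF <- ExtinctionSet(e260Mass = emptyCapsidE260(1.68), e280Mass = 1.68,
                           speciesMw = defaultEmptyCapsidMw())
  cf <- FillModel(emptyCF, fm@full)
  expect_equal(ratioAtFill(0, cf), 0.59)
})

test_that("fill from ratio inverts the ratio curve", {
  fm <- defaultFillModel()
  expect_equal(fillFromRatio(1.20, fm), 0.549, tolerance = 1e-3)
  grid <- seq(0, 1, length.out = 100)
  for (model in list(fm, defaultFillModel("mass_weighted"))) {
    r <- ratioAtFill(grid, model)
    expect_true(all(diff(r) > 0))                       # strictly increasing
    expect_lt(max(abs(fillFromRatio(r, model) - grid)), 1e-9)
  }
  expect_error(fillFromRatio(2.0, fm), "attainable band")
  expect_error(fillFromRatio(0.4, fm), "attainable band")
})

test_that("extinction-set and fill-model validity catch inconsistent input", {
  expect_error(new("ExtinctionSet", e260Molar = 1e6, e280Molar = 2e6,
                   e260Mass = 1, e280Mass = 2, speciesMw = 3e6),
               "1 part in 1e9")
  expect_error(FillModel(ExtinctionSet(e260Mass = 2, e280Mass = 1, speciesMw = 1e6),
                         ExtinctionSet(e260Mass = 2, e280Mass = 1, speciesMw = 1e6)),
               "empty capsid")
})

test_that("the YAML fixture reproduces the default model", {
  cfg <- readCapsidConfig(system.file("extdata",
                                      "synthetic_capsid_composition.yaml",
                                      package = "secmam"))
  expect_s4_class(cfg$fillModel, "FillModel")
  expect_equal(crossoverFill(cfg$fillModel), crossoverFill(defaultFillModel()))
  expect_s4_class(cfg$composition, "CapsidComposition")
  ## the synthetic aromatic counts land near the packaged molar e280
  e <- emptyCapsidE280(cfg$composition)
  expect_lt(percentDifference(e, 6.31e6), 5)
})
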