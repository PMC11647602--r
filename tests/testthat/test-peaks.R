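test_that("baseline correction removes constants and linear drift exactly", {
  t <- seq(0, 30, 0.01)
  flat <- Trace("FLD", t, rep(5, length(t)))
  expect_equal(traceValues(correctBaseline(flat)), rep(0, length(t)))
  drift <- Trace("FLD", t, 2.5 + 0.3 * t)
  resid <- traceValues(correctBaseline(drift))
  expect_lt(max(abs(resid)), 1e-9 * max(2.5 + 0.3 * t))
  expect_error(correctBaseline(flat, list(c(40, 50))), "quiet window")
})

test_that("a Gaussian riding on drift integrates to its analytic area", {
  t <- seq(0, 30, 0.01)
  H <- 10; sig <- 0.05
  tr <- Trace("FLD", t, H * exp(-(t - 6.5)^2 / (2 * sig^2)) + 1 + 0.2 * t)
  corr <- correctBaseline(tr)
  b <- detectPeaks(corr, minHeight = 1)
  pt <- integratePeaks(Chromatogram(list(corr)), b, detectionChannel = "FLD")
  expect_equal(unname(totalAreas(pt)[["FLD"]]), H * sig * sqrt(2 * pi),
               tolerance = 0.005)
})

test_that("peak detection finds resolved Gaussians and nothing in noise", {
  t <- seq(0, 30, 0.01)
  one <- Trace("FLD", t, 10 * exp(-(t - 6.5)^2 / (2 * 0.05^2)))
  b <- detectPeaks(one, minHeight = 1)
  expect_identical(nrow(b), 1L)
  expect_lte(abs(b$apex - 6.5), 0.01)

  two <- Trace("FLD", t, 10 * exp(-(t - 5.0)^2 / (2 * 0.05^2)) +
                          8 * exp(-(t - 6.5)^2 / (2 * 0.05^2)))
  b2 <- detectPeaks(two, minHeight = 1)
  expect_identical(nrow(b2), 2L)
  expect_equal(b2$apex, c(5.0, 6.5), tolerance = 0.011)
  ## shared boundary at the inter-peak minimum
  expect_identical(b2$end[1], b2$start[2])
  expect_gt(b2$start[2], 5.0); expect_lt(b2$start[2], 6.5)

  for (s in 1:10) {
    set.seed(s)
    noise <- Trace("FLD", t, rnorm(length(t), 0, 0.01))
    expect_identical(nrow(detectPeaks(noise, minHeight = 1)), 0L)
  }
})

test_that("trapezoidal integration matches the analytic Gaussian area", {
  t <- seq(0, 30, 0.01)
  tr <- Trace("FLD", t, exp(-(t - 6.5)^2 / (2 * 0.05^2)))
  b <- detectPeaks(tr, minHeight = 0.1)
  pt <- integratePeaks(Chromatogram(list(tr)), b, detectionChannel = "FLD")
  expect_equal(unname(peakAreas(pt)[1, "FLD"]), 0.05 * sqrt(2 * pi),
               tolerance = 1e-3)

  ## two identical peaks split the percent area evenly
  tr2 <- Trace("FLD", t, exp(-(t - 5.0)^2 / (2 * 0.05^2)) +
                          exp(-(t - 6.5)^2 / (2 * 0.05^2)))
  b2 <- detectPeaks(tr2, minHeight = 0.1)
  pt2 <- integratePeaks(Chromatogram(list(tr2)), b2, detectionChannel = "FLD")
  expect_equal(unname(percentAreas(pt2)[, "FLD"]), c(50, 50), tolerance = 1e-6)
  expect_error(
    integratePeaks(Chromatogram(list(tr2)),
                   data.frame(start = c(4, 4.5), apex = c(5, 6.5),
                              end = c(6, 7)), detectionChannel = "FLD"),
    "overlap")
})

test_that("relative trapezoid error stays below 1e-3 for sigma >= 5 cells", {
  t <- seq(0, 30, 0.01)
  for (sig in c(0.05, 0.1, 0.2)) {
    tr <- Trace("FLD", t, 3 * exp(-(t - 10)^2 / (2 * sig^2)))
    b <- detectPeaks(tr, minHeight = 0.3)
    pt <- integratePeaks(Chromatogram(list(tr)), b, detectionChannel = "FLD")
    expect_lt(abs(peakAreas(pt)[1, "FLD"] / (3 * sig * sqrt(2 * pi)) - 1),
              1e-3)
  }
})

test_that("a 45% HMW mixture reports 45% HMW fluorescence area", {
  sp <- list(
    speciesSpec("capsid", fill = 0.6, concentration = 0.55, apex = 6.5,
                id = "monomer"),
    speciesSpec("capsid", fill = 0.6, concentration = 0.45,
                molarMass = 2 * defaultFullCapsidMw(), apex = 5.5,
                sigma = 0.07, id = "dimer"))
  ch <- generateChromatogram(sp, noise = NULL)
  expect_equal(unname(fldPurity(ch)[["HMW"]]), 45, tolerance = 1)
})

test_that("classification windows assign the documented labels", {
  t <- seq(0, 30, 0.01)
  tr <- Trace("FLD", t, 5 * exp(-(t - 5.0)^2 / (2 * 0.05^2)) +
                         9 * exp(-(t - 6.5)^2 / (2 * 0.05^2)) +
                         2 * exp(-(t - 12.0)^2 / (2 * 0.3^2)))
  b <- detectPeaks(tr, minHeight = 0.5)
  pt <- classifyPeaks(integratePeaks(Chromatogram(list(tr)), b,
                                     detectionChannel = "FLD"))
  expect_identical(peakData(pt)$label, c("HMW", "monomer", "LMW_impurity"))
  expect_error(classifyPeaks(pt, list(a = c(4, 6), b = c(5, 7))), "overlap")
})

test_that("summed peak areas never exceed the total trace trapezoid", {
  ch <- generateScenario("inprocess_panel", list(), seed = 7)$cell_lysate
  fl <- correctBaseline(getTrace(alignTraces(ch), "FLD"))
  b <- detectPeaks(fl)
  pt <- integratePeaks(Chromatogram(list(fl)), b, detectionChannel = "FLD")
  v <- traceValues(fl); x <- traceTimes(fl)
  total <- sum(diff(x) * (pmax(v[-1], 0) + pmax(v[-length(v)], 0))) / 2
  expect_lte(sum(peakAreas(pt)[, "FLD"]), total * (1 + 1e-9))
})

test_that("detection is shift-equivariant", {
  t <- seq(0, 30, 0.01)
  shape <- function(s) 7 * exp(-(t - 6.0 - s)^2 / (2 * 0.06^2)) +
                       3 * exp(-(t - 5.0 - s)^2 / (2 * 0.06^2))
  b0 <- detectPeaks(Trace("FLD", t, shape(0)), minHeight = 1)
  b1 <- detectPeaks(Trace("FLD", t, shape(1.37)), minHeight = 1)
  expect_identical(nrow(b1), nrow(b0))
  expect_equal(b1$apex, b0$apex + 1.37, tolerance = 0.011)
})
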