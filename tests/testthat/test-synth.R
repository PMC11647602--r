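test_that("the EMG profile has unit area and a Gaussian tau=0 limit", {
  t <- seq(0, 30, 0.001)
  for (tau in c(0, 0.01, 0.03, 0.2)) {
    p <- emgProfile(t, 6.5, 0.05, tau)
    expect_true(all(is.finite(p)))
    expect_equal(sum(p) * 0.001, 1, tolerance = 1e-6)
  }
  expect_equal(emgProfile(t, 6.5, 0.05, 0), dnorm(t, 6.5, 0.05))
  ## tailing shifts mass to later times
  p <- emgProfile(t, 6.5, 0.05, 0.03)
  expect_gt(sum(p[t > 6.5]), sum(p[t < 6.5]))
})

test_that("generation is deterministic per seed and seed-free when noise-free", {
  sp <- list(speciesSpec("capsid", fill = 0.5, concentration = 0.3,
                         id = "m"))
  a <- generateChromatogram(sp, noise = noiseSpec(seed = 42))
  b <- generateChromatogram(sp, noise = noiseSpec(seed = 42))
  expect_identical(traceValues(getTrace(a, "UV260")),
                   traceValues(getTrace(b, "UV260")))
  c2 <- generateChromatogram(sp, noise = noiseSpec(seed = 43))
  expect_false(identical(traceValues(getTrace(a, "UV260")),
                         traceValues(getTrace(c2, "UV260"))))
  n1 <- generateChromatogram(sp, noise = NULL)
  set.seed(999)   # global RNG state must not matter
  n2 <- generateChromatogram(sp, noise = NULL)
  expect_identical(traceValues(getTrace(n1, "UV260")),
                   traceValues(getTrace(n2, "UV260")))
  expect_error(generateChromatogram(c(sp, sp)), "unique")
  expect_error(generateChromatogram(
    list(speciesSpec("capsid", concentration = 1, apex = 40))),
    "inside the run window")
})

test_that("noise-free UV area ratio equals the model ratio at the true fill", {
  for (f in c(0, 0.3, 0.62)) {
    ch <- generateChromatogram(
      list(speciesSpec("capsid", fill = f, concentration = 0.3, id = "m")),
      noise = NULL)
    a260 <- sum(traceValues(getTrace(ch, "UV260")))
    a280 <- sum(traceValues(getTrace(ch, "UV280")))
    expect_equal(a260 / a280, ratioAtFill(f), tolerance = 1e-6)
  }
})

test_that("free DNA is fluorescence-dark and impurities are DNA-free", {
  dnaOnly <- generateChromatogram(
    list(speciesSpec("free_dna", concentration = 0.1, apex = 5.5, id = "d")),
    noise = NULL, channels = c("UV260", "UV280", "FLD", "RI"))
  expect_identical(max(traceValues(getTrace(dnaOnly, "FLD"))), 0)
  expect_gt(max(traceValues(getTrace(dnaOnly, "UV260"))), 0)
  r <- sum(traceValues(getTrace(dnaOnly, "UV260"))) /
    sum(traceValues(getTrace(dnaOnly, "UV280")))
  expect_equal(r, 20 / 11.1, tolerance = 1e-6)
})

test_that("titer-mode concentration follows the particle-mass conversion", {
  titer <- 2e13
  M <- defaultEmptyCapsidMw() + 0.5 * defaultGenomeMw()
  byTiter <- generateChromatogram(
    list(speciesSpec("capsid", fill = 0.5, titer = titer, id = "m")),
    noise = NULL)
  byConc <- generateChromatogram(
    list(speciesSpec("capsid", fill = 0.5,
                     concentration = titer * M / 6.02214076e23 * 1e3,
                     id = "m")),
    noise = NULL)
  expect_equal(traceValues(getTrace(byTiter, "FLD")),
               traceValues(getTrace(byConc, "FLD")))
})

test_that("noise-free dilution series areas form an exact geometric sequence", {
  ds <- generateScenario("dilution_series", list(noise = FALSE), seed = 1)
  expect_length(ds, 7L)
  areas <- vapply(ds, function(ch)
    sum(traceValues(getTrace(ch, "FLD"))) * 0.01, numeric(1))
  expect_equal(unname(areas[-7] / areas[-1]), rep(2, 6), tolerance = 1e-9)
})

test_that("thermal series conserves total DNA mass (independent UV audit)", {
  ## spectrally exact free DNA (ratio 20/11.1) + component-consistent capsid
  ## UV lets a 2x2 Beer-Lambert solve recover protein and DNA mass per run
  th <- generateScenario("thermal_series",
                         list(noise = FALSE, dnaRatio = 20 / 11.1), seed = 1)
  op <- componentOptics()
  dnaMass <- vapply(th, function(ch) {
    a260 <- sum(traceValues(getTrace(ch, "UV260"))) * 0.01 / 1000
    a280 <- sum(traceValues(getTrace(ch, "UV280"))) * 0.01 / 1000
    A <- rbind(c(op$proteinE260, op$dnaE260), c(op$proteinE280, op$dnaE280))
    solve(A, c(a260, a280))[2L]
  }, numeric(1))
  expect_lt(max(abs(dnaMass / dnaMass[1L] - 1)), 1e-6)
  ## and the embedded ground truth agrees with the audit's proportions
  truth <- vapply(th, function(ch) runMetadata(ch)$true_total_dna, numeric(1))
  expect_lt(max(abs(truth / truth[1L] - 1)), 1e-12)
})

test_that("thermal members match the stated fill and amplitude program", {
  th <- generateScenario("thermal_series", list(noise = FALSE, f0 = 0.6),
                         seed = 1)
  fills <- vapply(th, function(ch) runMetadata(ch)$true_fill, numeric(1))
  expect_equal(unname(fills), c(0.6, 0.6, 0.45, 0.3, 0.15, 0))
  amps <- vapply(th, function(ch) runMetadata(ch)$true_amp, numeric(1))
  expect_equal(unname(amps), c(1, 1, 0.75, 0.5, 0.25, 0))
})

test_that("the in-process panel shows impurities early and purity at the end", {
  ip <- generateScenario("inprocess_panel", list(), seed = 3)
  expect_named(ip, c("cell_lysate", "clarified_lysate", "affinity_eluate",
                     "mixed_mode_ft", "purified_product"))
  lysate <- correctBaseline(getTrace(alignTraces(ip$cell_lysate), "FLD"))
  bl <- detectPeaks(lysate)
  expect_true(any(bl$apex > 8 & bl$apex < 16))
  final <- correctBaseline(getTrace(alignTraces(ip$purified_product), "FLD"))
  bf <- detectPeaks(final)
  expect_false(any(bf$apex > 8 & bf$apex < 16))
  expect_gte(unname(fldPurity(ip$purified_product)[["monomer"]]), 98)
})

test_that("aggregate-spiking ground truth matches volumetric mixing", {
  sc <- generateScenario("aggregate_spiking", list(replicates = 1), seed = 1)
  truths <- vapply(sc, function(ch) runMetadata(ch)$true_hmw_pct, numeric(1))
  expect_equal(unname(truths), c(0, 0.25, 0.5, 1) * 45)
})
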