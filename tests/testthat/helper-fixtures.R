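# shared helpers: small analytic traces and the one-channel purity pipeline

gaussTrace <- function(channel = "FLD", apex = 6.5, H = 10, sigma = 0.05,
                       from = 0, to = 30, dt = 0.01) {
  t <- seq(from, to, by = dt)
  Trace(channel, t, H * exp(-(t - apex)^2 / (2 * sigma^2)))
}

# %HMW / %monomer on the FLD channel of a generated chromatogram
fldPurity <- function(chrom) {
  fl <- correctBaseline(getTrace(alignTraces(chrom), "FLD"))
  b <- detectPeaks(fl)
  pt <- classifyPeaks(integratePeaks(Chromatogram(list(fl)),
                                     b, detectionChannel = "FLD"))
  c(monomer = labelPercent(pt, "monomer", "FLD"),
    HMW = labelPercent(pt, "HMW", "FLD"))
}

# UV-ratio fill estimate over the monomer peak (boundaries from UV280)
uvFill <- function(chrom, model = defaultFillModel()) {
  ch <- alignTraces(chrom)
  u280 <- correctBaseline(getTrace(ch, "UV280"))
  u260 <- correctBaseline(getTrace(ch, "UV260"))
  b <- detectPeaks(u280)
  pt <- classifyPeaks(integratePeaks(Chromatogram(list(u260, u280)), b,
                                     detectionChannel = "UV280"))
  feFromPeakAreas(sum(peakAreas(pt)[, "UV260"]),
                  sum(peakAreas(pt)[, "UV280"]), model)
}
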