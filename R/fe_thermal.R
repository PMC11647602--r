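#' @include AllClasses.R
NULL

#' Full/empty fraction from 260/280 peak areas
#'
#' Under Beer-Lambert detection, peak areas at 260 and 280 nm integrated
#' over identical time boundaries are proportional to the corresponding
#' extinction coefficients, so the area ratio maps to a fill fraction
#' through the inverse of the model's ratio curve.  Ratios outside the
#' attainable band clamp to the nearest bound with `inRange = FALSE`, and
#' fractions above 0.8 are flagged `inRange = FALSE` as well — the UV-ratio
#' method loses discrimination in the 80-100% full range.
#'
#' @param area260,area280 peak areas (> 0) over identical boundaries.
#' @param model a [FillModel-class].
#' @return list with `fractionFull`, `ratioA260A280`, `method = "uv_ratio"`,
#'   `inRange`.
#' @export
#' @examples
#' feFromPeakAreas(1, 1)   # the crossover: ~0.30 with the default model
feFromPeakAreas <- function(area260, area280, model = defaultFillModel()) {
  if (any(c(area260, area280) <= 0)) stop("peak areas must be > 0")
  r <- area260 / area280
  r0 <- ratioAtFill(0, model); r1 <- ratioAtFill(1, model)
  inRange <- r >= r0 & r <= r1
  f <- fillFromRatio(pmin(pmax(r, r0), r1), model)
  inRange <- inRange & f <= 0.8
  list(fractionFull = f, ratioA260A280 = r, method = "uv_ratio",
       inRange = inRange)
}

#' Classify a 260/280 ratio as protein- or nucleic-acid-like
#'
#' Ratios at or above 1.8 (the large-genome limit of the capsid extinction
#' equations, 20.0/11.1) are nucleic-acid-like; ratios at or below the
#' model's empty-capsid endpoint are protein-like; anything between is a
#' mixed protein+DNA spectrum.
#'
#' @param ratio A260/A280 ratio(s), > 0.
#' @param model a [FillModel-class] supplying the protein-like endpoint.
#' @return character vector in `{"protein_like", "mixed",
#'   "nucleic_acid_like"}`.
#' @export
uvSpectrumCheck <- function(ratio, model = defaultFillModel()) {
  if (any(ratio <= 0)) stop("ratio must be > 0")
  r0 <- ratioAtFill(0, model)
  ifelse(ratio >= 1.8, "nucleic_acid_like",
         ifelse(ratio <= r0, "protein_like", "mixed"))
}

#' Analyse a thermal-stress series
#'
#' For each temperature the monomer peak is located on the 280-nm trace,
#' integrated over UV260/UV280 with shared boundaries, and summarised by its
#' percent area (at 280 nm) and its A260/A280 area ratio; the free-DNA peak
#' in the nucleic-acid window (5.3-5.7 min) is tracked the same way.
#' Genome-ejection **onset** is the lowest temperature at which the monomer
#' ratio falls more than `ratioTol` (relative, default 5%) below the
#' baseline-temperature ratio *or* the monomer percent area falls more than
#' `areaTol` (relative, default 10%) below baseline, whichever triggers
#' first; **completion** is the lowest temperature at which the monomer
#' percent area drops below 5% of baseline (a vanished monomer counts).
#' Undefined transitions are reported as `NA`.
#'
#' @param series list of [Chromatogram-class] objects with `temperature` set
#'   and UV260/UV280 present, or a list of `list(temperature=, chrom=)`.
#' @param baselineT baseline (native) temperature, default the lowest.
#' @param windows classification windows, default [thermalPeakWindows()].
#' @param quietWindows baseline-fit windows.
#' @param ratioTol,areaTol relative onset tolerances.
#' @return list with `table` (data.frame: temperature, monomerPctArea,
#'   monomerRatio, naPctArea, naRatio), `onsetT`, `completionT`.
#' @export
analyzeThermalSeries <- function(series, baselineT = NULL,
                                 windows = thermalPeakWindows(),
                                 quietWindows = defaultQuietWindows(),
                                 ratioTol = 0.05, areaTol = 0.10) {
  chroms <- lapply(series, function(el)
    if (is(el, "Chromatogram")) el else el$chrom)
  temps <- vapply(chroms, temperatureLabel, numeric(1))
  if (anyNA(temps)) stop("every chromatogram needs a temperature label")
  o <- order(temps)
  chroms <- chroms[o]; temps <- temps[o]
  if (length(temps) < 3L) stop("a thermal series needs >= 3 temperatures")
  if (is.null(baselineT)) baselineT <- temps[1L]
  if (!baselineT %in% temps) stop("baselineT is not among the series temperatures")

  rows <- lapply(chroms, function(ch) {
    ch <- alignTraces(ch)
    u280 <- correctBaseline(getTrace(ch, "UV280"), quietWindows)
    u260 <- correctBaseline(getTrace(ch, "UV260"), quietWindows)
    aligned <- Chromatogram(list(u260, u280), sampleId = sampleId(ch))
    b <- detectPeaks(u280, quietWindows = quietWindows)
    if (!nrow(b))
      return(data.frame(monomerPctArea = 0, monomerRatio = NA_real_,
                        naPctArea = 0, naRatio = NA_real_))
    pt <- classifyPeaks(integratePeaks(aligned, b, detectionChannel = "UV280"),
                        windows)
    data.frame(monomerPctArea = labelPercent(pt, "monomer", "UV280"),
               monomerRatio = labelRatio260280(pt, "monomer"),
               naPctArea = labelPercent(pt, "nucleic_acid", "UV280"),
               naRatio = labelRatio260280(pt, "nucleic_acid"))
  })
  tab <- cbind(temperature = temps, do.call(rbind, rows))

  base <- tab[tab$temperature == baselineT, ]
  if (base$monomerPctArea <= 0 || is.na(base$monomerRatio))
    stop("monomer peak undetected at the baseline temperature")
  above <- tab[tab$temperature > baselineT, ]
  ratioDrop <- !is.na(above$monomerRatio) &
    above$monomerRatio < (1 - ratioTol) * base$monomerRatio
  areaDrop <- above$monomerPctArea < (1 - areaTol) * base$monomerPctArea
  onset <- above$temperature[ratioDrop | areaDrop]
  gone <- above$temperature[above$monomerPctArea < 0.05 * base$monomerPctArea]
  list(table = tab,
       onsetT = if (length(onset)) min(onset) else NA_real_,
       completionT = if (length(gone)) min(gone) else NA_real_)
}
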