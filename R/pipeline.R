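#' @include AllClasses.R
NULL

#' Configuration for a multi-attribute run
#'
#' Bundles everything [runMAM()] needs: the full/empty extinction model,
#' optional capsid (FLD) and genome (UV260) calibration curves, peak class
#' windows, detection thresholds and the MALS optics.  `NULL` thresholds
#' mean noise-adaptive defaults.
#'
#' @param fillModel a [FillModel-class].
#' @param capsidCurve,genomeCurve optional [CalibrationCurve-class] objects
#'   (FLD area vs vp/mL; UV260 area vs vg/mL).
#' @param windows peak class windows, see [defaultPeakWindows()].
#' @param quietWindows baseline windows, see [defaultQuietWindows()].
#' @param minHeight,minProminence detection thresholds, signal units.
#' @param optics a [componentOptics()] list.
#' @param constants an [opticalConstants()] list, or `NULL` to take angles
#'   from the chromatogram.
#' @param emptyCapsidMw,genomeMw capsid masses for the molar-mass F/E
#'   route, Da.
#' @return list with class `MAMConfig`.
#' @export
mamConfig <- function(fillModel = defaultFillModel(), capsidCurve = NULL,
                      genomeCurve = NULL, windows = defaultPeakWindows(),
                      quietWindows = defaultQuietWindows(),
                      minHeight = NULL, minProminence = NULL,
                      optics = componentOptics(), constants = NULL,
                      emptyCapsidMw = defaultEmptyCapsidMw(),
                      genomeMw = defaultGenomeMw()) {
  structure(list(fillModel = fillModel, capsidCurve = capsidCurve,
                 genomeCurve = genomeCurve, windows = windows,
                 quietWindows = quietWindows, minHeight = minHeight,
                 minProminence = minProminence, optics = optics,
                 constants = constants, emptyCapsidMw = emptyCapsidMw,
                 genomeMw = genomeMw),
            class = "MAMConfig")
}

#' Run the full multi-attribute analysis on one injection
#'
#' Executes align, baseline correction, peak detection (on FLD when
#' present, else UV280), integration over all channels with shared
#' boundaries, classification, and then every attribute the available
#' channels support: %monomer/%HMW purity (FLD), capsid titer (FLD area +
#' calibration), genome titer (UV260 area + calibration), UV-ratio
#' full/empty fraction, and — when RI and LS channels are present — MALS
#' molar mass, Rg and the molar-mass full/empty fraction.  A missing
#' channel never crashes the run: the attribute is reported `NA` with a
#' warning entry.
#'
#' @param chrom a [Chromatogram-class].
#' @param config a [mamConfig()].
#' @return an object of class `MAMReport`: a list with `sampleId`,
#'   `purity` (monomerPct, hmwPct), `capsidTiter` / `genomeTiter`
#'   (titer, belowLoq), `feUv` (fractionFull, ratio, inRange), `mals`
#'   (mw, rg, fractionFull, monodisperse) or `NULL`, `peakTable`,
#'   `warnings`, and a structured `log` of key=value stage lines.
#' @export
runMAM <- function(chrom, config = mamConfig()) {
  stopifnot(is(chrom, "Chromatogram"), inherits(config, "MAMConfig"))
  warnings <- character()
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  warn <- function(msg) {
    warnings <<- c(warnings, msg)
    note("stage=warning message=\"%s\"", msg)
  }

  chrom <- alignTraces(chrom)
  note("stage=align channels=%s n=%d",
       paste(channelNames(chrom), collapse = "+"),
       length(traceTimes(chrom@traces[[1L]])))

  detCh <- if ("FLD" %in% channelNames(chrom)) "FLD" else
    if ("UV280" %in% channelNames(chrom)) "UV280" else
      channelNames(chrom)[1L]
  corrected <- lapply(chrom@traces, correctBaseline,
                      quietWindows = config$quietWindows)
  cChrom <- Chromatogram(corrected, sampleId = sampleId(chrom),
                         injectionVolume = injectionVolume(chrom),
                         dilutionFactor = dilutionFactor(chrom),
                         temperature = temperatureLabel(chrom),
                         angles = scatteringAngles(chrom),
                         lsCalibrated = chrom@lsCalibrated,
                         metadata = runMetadata(chrom))
  b <- detectPeaks(cChrom@traces[[detCh]],
                   minHeight = config$minHeight,
                   minProminence = config$minProminence,
                   quietWindows = config$quietWindows)
  note("stage=detect channel=%s peaks=%d", detCh, nrow(b))
  if (!nrow(b)) stop("no peaks detected on ", detCh)
  pt <- classifyPeaks(integratePeaks(cChrom, b, detectionChannel = detCh),
                      config$windows)

  ## purity from FLD
  purity <- list(monomerPct = NA_real_, hmwPct = NA_real_)
  if ("FLD" %in% channelNames(chrom)) {
    purity$monomerPct <- labelPercent(pt, "monomer", "FLD")
    purity$hmwPct <- labelPercent(pt, "HMW", "FLD")
    note("stage=purity monomer=%.3f hmw=%.3f", purity$monomerPct,
         purity$hmwPct)
  } else warn("FLD channel absent; purity not reported")

  titerOf <- function(curve, channel, what) {
    if (is.null(curve)) { warn(sprintf("no %s calibration curve", what)); return(NULL) }
    if (!channel %in% channelNames(chrom)) {
      warn(sprintf("%s channel absent; %s titer not reported", channel, what))
      return(NULL)
    }
    sel <- pt@peaks$label %in% c("monomer", "HMW")
    resp <- sum(pt@areas[sel, channel])
    res <- predictTiter(curve, resp, dilutionFactor(chrom))
    note("stage=titer kind=%s response=%.6g titer=%.6g belowLoq=%s",
         what, resp, res$titer, res$belowLoq)
    res
  }
  capsidTiter <- titerOf(config$capsidCurve, "FLD", "capsid")
  genomeTiter <- titerOf(config$genomeCurve, "UV260", "genome")

  ## UV-ratio full/empty on the monomer peak
  feUv <- NULL
  if (all(c("UV260", "UV280") %in% channelNames(chrom))) {
    sel <- pt@peaks$label == "monomer"
    if (any(sel)) {
      a260 <- sum(pt@areas[sel, "UV260"]); a280 <- sum(pt@areas[sel, "UV280"])
      if (a260 > 0 && a280 > 0) {
        feUv <- feFromPeakAreas(a260, a280, config$fillModel)
        note("stage=fe_uv ratio=%.4f fraction=%.4f inRange=%s",
             feUv$ratioA260A280, feUv$fractionFull, feUv$inRange)
      } else warn("monomer UV areas not positive; UV-ratio F/E not reported")
    } else warn("no monomer peak; UV-ratio F/E not reported")
  } else warn("UV260/UV280 absent; UV-ratio F/E not reported")

  ## MALS attributes
  mals <- NULL
  lsPresent <- sum(.isLsChannel(channelNames(chrom))) >= 3L
  if (lsPresent && all(c("RI", "UV260", "UV280") %in% channelNames(chrom))) {
    slices <- analyzeMALSRun(chrom, constants = config$constants,
                             optics = config$optics,
                             quietWindows = config$quietWindows)
    sel <- pt@peaks$label == "monomer"
    if (any(sel)) {
      peak <- list(start = min(pt@peaks$start[sel]),
                   end = max(pt@peaks$end[sel]))
      ms <- peakMALSSummary(slices, peak)
      mals <- list(mw = ms$mw, rg = ms$rg,
                   fractionFull = feFromMolarMass(ms$mw, config$emptyCapsidMw,
                                                  config$genomeMw),
                   monodisperse = ms$monodisperse)
      note("stage=mals mw=%.5g rg=%.3f fraction=%.4f", ms$mw, ms$rg,
           mals$fractionFull)
    } else warn("no monomer peak; MALS summary not reported")
  } else if (!lsPresent)
    warn("LS/RI channels absent; MALS attributes not reported")

  structure(list(sampleId = sampleId(chrom), purity = purity,
                 capsidTiter = capsidTiter, genomeTiter = genomeTiter,
                 feUv = feUv, mals = mals, peakTable = pt,
                 warnings = warnings, log = log),
            class = "MAMReport")
}

#' @export
print.MAMReport <- function(x, ...) {
  cat("MAM report for", x$sampleId, "\n")
  cat(sprintf("  purity: monomer %.2f%%, HMW %.2f%%\n",
              x$purity$monomerPct, x$purity$hmwPct))
  fmtTiter <- function(t, what) if (!is.null(t))
    cat(sprintf("  %s titer: %.3g%s\n", what, t$titer,
                if (t$belowLoq) " (below LOQ)" else ""))
  fmtTiter(x$capsidTiter, "capsid")
  fmtTiter(x$genomeTiter, "genome")
  if (!is.null(x$feUv))
    cat(sprintf("  F/E (UV ratio): %.3f (A260/A280 = %.3f)%s\n",
                x$feUv$fractionFull, x$feUv$ratioA260A280,
                if (x$feUv$inRange) "" else " [out of range]"))
  if (!is.null(x$mals))
    cat(sprintf("  MALS: Mw %.3g g/mol, Rg %.1f nm, F/E %.3f%s\n",
                x$mals$mw, x$mals$rg, x$mals$fractionFull,
                if (x$mals$monodisperse) " (monodisperse)" else ""))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Flatten a MAM report to one data.frame row
#'
#' @param x an `MAMReport`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return one-row data.frame with all numeric attributes and their flags.
#' @export
as.data.frame.MAMReport <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    sampleId = x$sampleId,
    monomerPct = x$purity$monomerPct, hmwPct = x$purity$hmwPct,
    capsidTiter = if (!is.null(x$capsidTiter)) x$capsidTiter$titer else NA_real_,
    capsidBelowLoq = if (!is.null(x$capsidTiter)) x$capsidTiter$belowLoq else NA,
    genomeTiter = if (!is.null(x$genomeTiter)) x$genomeTiter$titer else NA_real_,
    genomeBelowLoq = if (!is.null(x$genomeTiter)) x$genomeTiter$belowLoq else NA,
    feUvFraction = if (!is.null(x$feUv)) x$feUv$fractionFull else NA_real_,
    feUvRatio = if (!is.null(x$feUv)) x$feUv$ratioA260A280 else NA_real_,
    feUvInRange = if (!is.null(x$feUv)) x$feUv$inRange else NA,
    malsMw = if (!is.null(x$mals)) x$mals$mw else NA_real_,
    malsRg = if (!is.null(x$mals)) x$mals$rg else NA_real_,
    malsFraction = if (!is.null(x$mals)) x$mals$fractionFull else NA_real_,
    nWarnings = length(x$warnings),
    stringsAsFactors = FALSE)
}

#' Write a MAM report to CSV or JSON
#'
#' @param report an `MAMReport`.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
writeMAMReport <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  } else {
    out <- unclass(report)
    out$peakTable <- peakData(report$peakTable)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}
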