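#' @import methods
NULL

## Channels recognised in the chromatogram dialect.  LS00..LS17 are the
## multi-angle light-scattering photodiodes of an 18-angle detector.
.lsChannels <- sprintf("LS%02d", 0:17)
.knownChannels <- c("UV260", "UV280", "FLD", "RI", .lsChannels)

.isLsChannel <- function(ch) ch %in% .lsChannels

#' Trace: a single detector channel of an SEC run
#'
#' A `Trace` holds one detector signal sampled on a strictly increasing,
#' uniform time grid (minutes).  Signal units depend on the channel: mAU for
#' UV260/UV280, arbitrary fluorescence units for FLD, scaled refractive-index
#' units for RI (the package convention is dn/dc (mL/g) times mass
#' concentration (mg/mL), i.e. 1e3 x delta-n), and excess Rayleigh ratio
#' (cm^-1) for LS channels.  `delayOffset` is the detector dead-volume lag in
#' minutes relative to the first detector of the train.
#'
#' @slot channel character(1), one of UV260, UV280, FLD, RI, LS00..LS17.
#' @slot times numeric, elution time in minutes.
#' @slot values numeric, detector signal.
#' @slot delayOffset numeric(1), minutes.
#'
#' @exportClass Trace
setClass("Trace",
  representation(channel = "character", times = "numeric",
                 values = "numeric", delayOffset = "numeric"),
  prototype(delayOffset = 0))

setValidity("Trace", function(object) {
  msg <- character()
  if (length(object@channel) != 1L || !(object@channel %in% .knownChannels))
    msg <- c(msg, sprintf("unknown channel '%s'",
                          paste(object@channel, collapse = ",")))
  n <- length(object@times)
  if (n < 2L) msg <- c(msg, "a trace needs at least 2 points")
  if (length(object@values) != n)
    msg <- c(msg, "times and values must have the same length")
  if (n >= 2L) {
    dt <- diff(object@times)
    if (any(dt <= 0)) msg <- c(msg, "times must be strictly increasing")
    else if (any(abs(dt - dt[1L]) > dt[1L] * 1e-6))
      msg <- c(msg, "time grid must be uniform to 1 part in 1e6")
  }
  if (length(object@delayOffset) != 1L || !is.finite(object@delayOffset))
    msg <- c(msg, "delayOffset must be a finite scalar")
  if (length(msg)) msg else TRUE
})

#' Chromatogram: all detector traces of one injection
#'
#' Container for the aligned (or alignable) multi-detector traces of a single
#' SEC injection, together with sample metadata.  At most one trace per
#' channel.  `angles` maps LS channel names to scattering angles in degrees;
#' `lsCalibrated` records whether LS traces are in excess Rayleigh units
#' (cm^-1) — un-normalised raw signals are refused by the MALS reduction.
#' `metadata` carries free-form numeric/character key-value pairs, including
#' the `true_*` ground-truth keys written by the synthetic generator.
#'
#' @slot sampleId character(1).
#' @slot traces list of [Trace-class] objects named by channel.
#' @slot injectionVolume numeric(1), microlitres.
#' @slot dilutionFactor numeric(1), >= 1.
#' @slot temperature numeric(1), degrees C; `NA` outside thermal series.
#' @slot angles named numeric, degrees, one entry per LS channel present.
#' @slot lsCalibrated logical(1).
#' @slot metadata list.
#'
#' @exportClass Chromatogram
setClass("Chromatogram",
  representation(sampleId = "character", traces = "list",
                 injectionVolume = "numeric", dilutionFactor = "numeric",
                 temperature = "numeric", angles = "numeric",
                 lsCalibrated = "logical", metadata = "list"),
  prototype(sampleId = "sample", injectionVolume = 100, dilutionFactor = 1,
            temperature = NA_real_, angles = numeric(0), lsCalibrated = TRUE,
            metadata = list()))

setValidity("Chromatogram", function(object) {
  msg <- character()
  chs <- vapply(object@traces, function(tr) tr@channel, character(1))
  if (length(object@traces) &&
      (is.null(names(object@traces)) || !identical(unname(chs), names(object@traces))))
    msg <- c(msg, "traces must be named by their channel")
  if (anyDuplicated(chs))
    msg <- c(msg, "at most one trace per channel")
  ok <- vapply(object@traces, function(tr) isTRUE(validObject(tr, test = TRUE)),
               logical(1))
  if (length(ok) && !all(ok)) msg <- c(msg, "invalid trace(s)")
  if (object@dilutionFactor < 1)
    msg <- c(msg, "dilutionFactor must be >= 1")
  if (object@injectionVolume <= 0)
    msg <- c(msg, "injectionVolume must be positive")
  ls <- chs[.isLsChannel(chs)]
  if (length(ls) && !all(ls %in% names(object@angles)))
    msg <- c(msg, "every LS channel needs an entry in angles")
  if (length(msg)) msg else TRUE
})

#' Capsid composition parameters
#'
#' Stoichiometry and optical composition of an AAV capsid: VP1/VP2/VP3 copy
#' numbers per 60-mer (default 5:5:50, the canonical 1:1:10 ratio), aromatic
#' residue counts (Trp, Tyr, cystine) per VP monomer or pre-computed per-VP
#' molar extinction at 280 nm, the vector-genome molecular weight, the empty
#' capsid (protein shell) mass, and the particle-to-genome ratio vp/vg.
#'
#' @slot vpCounts integer(3), copies of VP1, VP2, VP3; must sum to 60.
#' @slot aromatics 3x3 numeric matrix (rows VP1..VP3, cols Trp, Tyr, Cystine)
#'   of residue counts, or a 0x0 matrix when `perVpE280` is supplied.
#' @slot perVpE280 numeric(3) molar e280 per VP monomer (M^-1 cm^-1), or
#'   length 0 when `aromatics` is supplied.
#' @slot genomeMw numeric(1), Da.
#' @slot emptyCapsidMw numeric(1), Da.
#' @slot vpVg numeric(1), >= 1.
#'
#' @exportClass CapsidComposition
setClass("CapsidComposition",
  representation(vpCounts = "integer", aromatics = "matrix",
                 perVpE280 = "numeric", genomeMw = "numeric",
                 emptyCapsidMw = "numeric", vpVg = "numeric"))

setValidity("CapsidComposition", function(object) {
  msg <- character()
  if (length(object@vpCounts) != 3L || sum(object@vpCounts) != 60L)
    msg <- c(msg, "vpCounts must be three integers summing to 60")
  if (!length(object@perVpE280) && !length(object@aromatics))
    msg <- c(msg, "provide aromatic counts or per-VP e280 coefficients")
  if (length(object@aromatics) && !identical(dim(object@aromatics), c(3L, 3L)))
    msg <- c(msg, "aromatics must be a 3x3 matrix (VP x {Trp,Tyr,Cystine})")
  if (length(object@perVpE280) && length(object@perVpE280) != 3L)
    msg <- c(msg, "perVpE280 must have length 3")
  if (object@genomeMw < 0 || object@emptyCapsidMw <= 0)
    msg <- c(msg, "masses must be positive (genomeMw may be 0)")
  if (object@vpVg < 1) msg <- c(msg, "vpVg must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Extinction coefficients of one capsid species
#'
#' Molar (M^-1 cm^-1) and mass ((mg/mL)^-1 cm^-1) extinction coefficients at
#' 260 and 280 nm, tied together by the species molecular weight:
#' e_mass = e_molar / MW.
#'
#' @slot e260Molar,e280Molar numeric(1), M^-1 cm^-1.
#' @slot e260Mass,e280Mass numeric(1), (mg/mL)^-1 cm^-1.
#' @slot speciesMw numeric(1), Da.
#'
#' @exportClass ExtinctionSet
setClass("ExtinctionSet",
  representation(e260Molar = "numeric", e280Molar = "numeric",
                 e260Mass = "numeric", e280Mass = "numeric",
                 speciesMw = "numeric"))

setValidity("ExtinctionSet", function(object) {
  msg <- character()
  vals <- c(object@e260Molar, object@e280Molar, object@e260Mass,
            object@e280Mass, object@speciesMw)
  if (any(vals <= 0)) msg <- c(msg, "all coefficients and the mass must be > 0")
  rel <- function(mass, molar)
    abs(mass * object@speciesMw - molar) > 1e-9 * abs(molar)
  if (rel(object@e260Mass, object@e260Molar) ||
      rel(object@e280Mass, object@e280Molar))
    msg <- c(msg, "e_mass * speciesMw must equal e_molar to 1 part in 1e9")
  if (length(msg)) msg else TRUE
})

#' Full/empty extinction-coefficient model
#'
#' Pairs the empty-capsid and full-capsid [ExtinctionSet-class]s and fixes how
#' coefficients are interpolated between them as a function of the fill
#' fraction f: `linear_in_fill` interpolates each wavelength linearly in f
#' (the construction behind the published e(f) plots); `mass_weighted`
#' weights the endpoints by species mass, which is exactly equivalent to
#' mixing the protein and DNA optical components.  The defining asymmetry —
#' full capsids absorb more at 260 than 280 nm, empty capsids the reverse —
#' is enforced by the validity method.
#'
#' @slot empty,full [ExtinctionSet-class].
#' @slot interpolation character(1), "linear_in_fill" or "mass_weighted".
#'
#' @exportClass FillModel
setClass("FillModel",
  representation(empty = "ExtinctionSet", full = "ExtinctionSet",
                 interpolation = "character"))

setValidity("FillModel", function(object) {
  msg <- character()
  if (!(object@interpolation %in% c("linear_in_fill", "mass_weighted")))
    msg <- c(msg, "interpolation must be 'linear_in_fill' or 'mass_weighted'")
  if (!(object@full@e260Mass > object@full@e280Mass))
    msg <- c(msg, "full capsid must have e260Mass > e280Mass")
  if (!(object@empty@e280Mass > object@empty@e260Mass))
    msg <- c(msg, "empty capsid must have e280Mass > e260Mass")
  if (length(msg)) msg else TRUE
})

#' Integrated peak table
#'
#' Result of integrating detected peaks over every channel of an aligned
#' chromatogram.  `peaks` holds one row per peak (start/apex/end in minutes,
#' height on the detection channel, class label); `areas` and `percentArea`
#' are peak x channel matrices (trapezoidal signal.min and percent of the
#' summed detected-peak area per channel).
#'
#' @slot peaks data.frame with columns start, apex, end, height, label.
#' @slot areas,percentArea numeric matrices, peaks x channels.
#' @slot totalArea named numeric, per-channel sum of detected-peak areas.
#' @slot detectionChannel character(1).
#'
#' @exportClass PeakTable
setClass("PeakTable",
  representation(peaks = "data.frame", areas = "matrix",
                 percentArea = "matrix", totalArea = "numeric",
                 detectionChannel = "character"))

setValidity("PeakTable", function(object) {
  msg <- character()
  p <- object@peaks
  need <- c("start", "apex", "end", "height", "label")
  if (!all(need %in% names(p)))
    msg <- c(msg, "peaks must have columns start, apex, end, height, label")
  else if (nrow(p)) {
    if (any(!(p$start < p$apex & p$apex < p$end)))
      msg <- c(msg, "each peak needs start < apex < end")
    if (nrow(object@areas) != nrow(p))
      msg <- c(msg, "areas must have one row per peak")
    if (any(object@areas < 0)) msg <- c(msg, "areas must be >= 0")
    sums <- colSums(object@percentArea)
    if (any(abs(sums - 100) > 1e-6))
      msg <- c(msg, "percent areas must sum to 100 per channel")
  }
  if (length(msg)) msg else TRUE
})

#' Calibration curve for titer quantitation
#'
#' Ordinary least-squares line of detector peak area against nominal titer,
#' with fit statistics and limits of detection/quantitation (3.3 and 10 times
#' residual SD over slope).
#'
#' @slot levels numeric, nominal titer (vp/mL or vg/mL).
#' @slot responses numeric, peak areas.
#' @slot slope,intercept,rSquared,residualSd numeric(1).
#' @slot lod,loq numeric(1), titer units.
#' @slot valid logical(1), FALSE when slope <= 0.
#'
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(levels = "numeric", responses = "numeric",
                 slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", residualSd = "numeric",
                 lod = "numeric", loq = "numeric", valid = "logical"))

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (length(object@levels) < 3L)
    msg <- c(msg, "a calibration curve needs at least 3 levels")
  if (length(object@levels) != length(object@responses))
    msg <- c(msg, "levels and responses must have the same length")
  if (isTRUE(object@valid)) {
    if (object@slope <= 0) msg <- c(msg, "a valid curve needs slope > 0")
    if (!(object@lod < object@loq)) msg <- c(msg, "lod must be < loq")
  }
  if (!is.na(object@rSquared) &&
      (object@rSquared < 0 || object@rSquared > 1))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "Trace", function(object) {
  cat(sprintf("Trace '%s': %d points, %.3f-%.3f min, delay %.3f min\n",
              object@channel, length(object@times), min(object@times),
              max(object@times), object@delayOffset))
})

setMethod("show", "Chromatogram", function(object) {
  cat(sprintf("Chromatogram '%s' (%d channel%s: %s)\n", object@sampleId,
              length(object@traces),
              if (length(object@traces) == 1L) "" else "s",
              paste(names(object@traces), collapse = ", ")))
  cat(sprintf("  injection %.0f uL, dilution %.3g", object@injectionVolume,
              object@dilutionFactor))
  if (!is.na(object@temperature))
    cat(sprintf(", %.0f degC", object@temperature))
  cat("\n")
  if (length(object@metadata))
    cat("  metadata keys:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "ExtinctionSet", function(object) {
  cat(sprintf(paste0("ExtinctionSet: e260 %.4g, e280 %.4g (mg/mL)^-1 cm^-1 ",
                     "(MW %.4g Da)\n"),
              object@e260Mass, object@e280Mass, object@speciesMw))
})

setMethod("show", "FillModel", function(object) {
  cat(sprintf("FillModel (%s)\n  empty: e260 %.3g / e280 %.3g\n  full:  e260 %.3g / e280 %.3g\n",
              object@interpolation, object@empty@e260Mass,
              object@empty@e280Mass, object@full@e260Mass,
              object@full@e280Mass))
})

setMethod("show", "PeakTable", function(object) {
  cat(sprintf("PeakTable: %d peak(s), channels %s (detection on %s)\n",
              nrow(object@peaks), paste(colnames(object@areas), collapse = ", "),
              object@detectionChannel))
  if (nrow(object@peaks)) print(peakData(object))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(paste0("CalibrationCurve: %d levels, slope %.4g, R^2 %.4f\n",
                     "  LOD %.3g, LOQ %.3g%s\n"),
              length(object@levels), object@slope, object@rSquared,
              object@lod, object@loq,
              if (object@valid) "" else "  [INVALID: non-positive slope]"))
})
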