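#' @include AllClasses.R
NULL

#' Fit a titer calibration curve
#'
#' Ordinary least squares of response (peak area) on nominal level (titer),
#' on raw scales; an optional `weights = "1/x2"` mode performs
#' inverse-variance-in-level weighting.  Residual SD uses the n-2
#' denominator.  LOD and LOQ follow the 3.3 and 10 times residual-SD-over-
#' slope convention, so LOQ/LOD = 10/3.3 identically.  A non-positive slope
#' marks the curve invalid rather than erroring.
#'
#' @param levels numeric, >= 3 distinct nominal titers.
#' @param responses numeric peak areas, same length.
#' @param weights `NULL` (unweighted, default) or `"1/x2"`.
#' @return a [CalibrationCurve-class].
#' @export
#' @examples
#' fitCalibration(c(1, 2, 3), c(3, 5, 7))   # y = 2x + 1, R^2 = 1
fitCalibration <- function(levels, responses, weights = NULL) {
  if (length(levels) < 3L || length(unique(levels)) < 3L)
    stop("at least 3 distinct calibration levels are required")
  if (length(levels) != length(responses))
    stop("levels and responses must have the same length")
  w <- if (identical(weights, "1/x2")) 1 / levels^2 else rep(1, length(levels))
  fit <- stats::lm(responses ~ levels, weights = w)
  co <- stats::coef(fit)
  res <- stats::residuals(fit)
  rsd <- sqrt(sum(w * res^2) / (length(levels) - 2L))
  ybar <- sum(w * responses) / sum(w)
  ss <- sum(w * (responses - ybar)^2)
  r2 <- if (ss > 0) 1 - sum(w * res^2) / ss else NA_real_
  slope <- unname(co[2L]); intercept <- unname(co[1L])
  valid <- is.finite(slope) && slope > 0
  lodv <- if (valid) 3.3 * rsd / slope else NA_real_
  loqv <- if (valid) 10 * rsd / slope else NA_real_
  new("CalibrationCurve", levels = as.numeric(levels),
      responses = as.numeric(responses), slope = slope,
      intercept = intercept, rSquared = r2, residualSd = rsd,
      lod = lodv, loq = loqv, valid = valid)
}

#' Limits of detection and quantitation of a curve
#'
#' LOD = 3.3 sigma / slope, LOQ = 10 sigma / slope with sigma the residual
#' SD, so the LOQ/LOD ratio is 10/3.3 for every valid curve.
#'
#' @param curve a valid [CalibrationCurve-class].
#' @return named numeric `c(lod, loq)` in titer units.
#' @export
lodLoq <- function(curve) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (!curve@valid) stop("curve is invalid (non-positive slope)")
  c(lod = curve@lod, loq = curve@loq)
}

#' Predict a titer from a response
#'
#' Inverts the calibration line, titer = dilutionFactor * (response -
#' intercept) / slope.  Negative back-calculated titers are clamped to 0 and
#' flagged; results below the (dilution-corrected) LOQ are flagged, never
#' suppressed.
#'
#' @param curve a valid [CalibrationCurve-class].
#' @param response observed peak area(s), >= 0.
#' @param dilutionFactor sample dilution factor(s), >= 1.
#' @return data.frame with columns `titer`, `belowLoq`, `clamped`.
#' @export
predictTiter <- function(curve, response, dilutionFactor = 1) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (!curve@valid) stop("curve is invalid (non-positive slope)")
  if (any(response < 0)) stop("response must be >= 0")
  atDetector <- (response - curve@intercept) / curve@slope
  titer <- dilutionFactor * atDetector
  clamped <- titer < 0
  titer[clamped] <- 0
  data.frame(titer = titer, belowLoq = atDetector < curve@loq,
             clamped = clamped)
}

#' Percent difference against a reference value
#'
#' 100 * |candidate - reference| / |reference| — the reference-denominator
#' convention used for theoretical-vs-experimental and cross-method
#' comparisons.
#'
#' @param candidate measured value(s).
#' @param reference reference value(s), nonzero.
#' @return percent difference(s).
#' @export
#' @examples
#' percentDifference(1.78, 1.68)   # 5.95
percentDifference <- function(candidate, reference) {
  if (any(reference == 0)) stop("reference must be nonzero")
  100 * abs(candidate - reference) / abs(reference)
}

#' Recovery and precision of an aggregate-spiking series
#'
#' For samples mixed volumetrically from an aggregated stock (known %HMW)
#' and an aggregate-free reference of equal nominal total concentration, the
#' expected %HMW at aggregated-stock volume fraction phi is
#' `phi * stockHmwPct`.  Recovery is 100 * measured/expected per level (not
#' defined at phi = 0, where the absolute %HMW is reported instead), RSD is
#' the percent relative standard deviation over replicates, and a linear fit
#' of mean measured %HMW against phi summarises linearity.
#'
#' @param measurements data.frame with columns `phi` (volume fraction of the
#'   aggregated stock) and `hmwPct` (measured %HMW), one row per injection.
#' @param stockHmwPct %HMW of the aggregated stock (e.g. 45).
#' @return list with `perLevel` (data.frame: phi, expected, meanMeasured,
#'   recoveryPct, rsdPct, n) and `fit` (named numeric: slope, intercept,
#'   rSquared).
#' @export
spikingRecovery <- function(measurements, stockHmwPct) {
  stopifnot(all(c("phi", "hmwPct") %in% names(measurements)))
  phis <- sort(unique(measurements$phi))
  if (length(phis) < 2L) stop("at least 2 spike levels are required")
  perLevel <- do.call(rbind, lapply(phis, function(p) {
    x <- measurements$hmwPct[measurements$phi == p]
    expected <- p * stockHmwPct
    m <- mean(x)
    data.frame(phi = p, expected = expected, meanMeasured = m,
               recoveryPct = if (expected > 0) 100 * m / expected else NA_real_,
               rsdPct = if (length(x) >= 2L && m != 0)
                 100 * stats::sd(x) / m else NA_real_,
               n = length(x))
  }))
  fit <- stats::lm(meanMeasured ~ phi, data = perLevel)
  list(perLevel = perLevel,
       fit = c(slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               rSquared = summary(fit)$r.squared))
}
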