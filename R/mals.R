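#' @include AllClasses.R
NULL

.avogadro <- 6.02214076e23

#' Default 18-angle detector geometry
#'
#' Angles evenly spaced in sin^2(theta/2) from 15 to 160 degrees, mirroring
#' an 18-photodiode static light-scattering detector.
#'
#' @return named numeric vector of angles (degrees) for channels LS00..LS17.
#' @export
defaultMalsAngles <- function() {
  s <- seq(sin(15 / 2 * pi / 180)^2, sin(160 / 2 * pi / 180)^2, length.out = 18)
  ang <- 2 * asin(sqrt(s)) * 180 / pi
  names(ang) <- sprintf("LS%02d", 0:17)
  ang
}

#' Optical constants of the detector train
#'
#' @param wavelength vacuum laser wavelength, nm.
#' @param solventRI refractive index of the mobile phase.
#' @param angles named numeric vector of scattering angles (degrees) per LS
#'   channel.
#' @param pathLength UV cell path length, cm.
#' @return list with class `OpticalConstants`.
#' @export
opticalConstants <- function(wavelength = 690, solventRI = 1.331,
                             angles = defaultMalsAngles(), pathLength = 1.0) {
  stopifnot(wavelength > 0, all(angles > 0 & angles < 180), pathLength > 0)
  structure(list(wavelength = wavelength, solventRI = solventRI,
                 angles = angles, pathLength = pathLength),
            class = "OpticalConstants")
}

#' Optical properties of the protein and DNA components
#'
#' Specific refractive-index increments (dn/dc, mL/g) and mass extinction
#' coefficients ((mg/mL)^-1 cm^-1) of the two components of the capsid
#' conjugate.  Defaults: dn/dc 0.185 (protein shell) and 0.170 (nucleic
#' acid); protein ECs from the empty-capsid fixture (0.98 / 1.68) and DNA
#' ECs from the large-genome limit of the DNA-containing-capsid equations
#' per unit mass (20.0 / 11.1).
#'
#' @param dndcProtein,dndcDna mL/g, each in (0.05, 0.30).
#' @param proteinE260,proteinE280,dnaE260,dnaE280 mass extinction
#'   coefficients, (mg/mL)^-1 cm^-1.
#' @return list with class `ComponentOptics`.
#' @export
componentOptics <- function(dndcProtein = 0.185, dndcDna = 0.170,
                            proteinE260 = 0.98, proteinE280 = 1.68,
                            dnaE260 = 20.0, dnaE280 = 11.1) {
  dd <- c(dndcProtein, dndcDna)
  stopifnot(all(dd > 0.05 & dd < 0.30))
  structure(list(dndcProtein = dndcProtein, dndcDna = dndcDna,
                 proteinE260 = proteinE260, proteinE280 = proteinE280,
                 dnaE260 = dnaE260, dnaE280 = dnaE280),
            class = "ComponentOptics")
}

#' Protein and DNA concentrations from UV and RI signals
#'
#' Solves, per slice and in the least-squares sense, the conjugate system
#' \preformatted{
#'   A260 = l (e260p cp + e260d cd)
#'   A280 = l (e280p cp + e280d cd)
#'   S_RI =    dndc_p cp + dndc_d cd
#' }
#' for the protein and DNA mass concentrations (mg/mL).  `S_RI` is the
#' package RI convention: dn/dc (mL/g) times concentration (mg/mL), i.e.
#' 1e3 times the refractive-index increment.  A negative solution component
#' is clamped to zero and the remaining component refitted.
#'
#' @param a260,a280 absorbances (AU), scalars or vectors (slices).
#' @param ri RI signal in package units, same length.
#' @param optics a [componentOptics()] list.
#' @param pathLength UV cell path length, cm.
#' @return list with vectors `cProtein`, `cDna`, `cTotal`, `dndcConjugate`
#'   (the composition-weighted dn/dc; `NA` where the total is zero).
#' @export
conjugateConcentrations <- function(a260, a280, ri, optics = componentOptics(),
                                    pathLength = 1.0) {
  A <- rbind(c(pathLength * optics$proteinE260, pathLength * optics$dnaE260),
             c(pathLength * optics$proteinE280, pathLength * optics$dnaE280),
             c(optics$dndcProtein, optics$dndcDna))
  if (abs(det(crossprod(A))) < 1e-12 * sum(A^2)^2)
    stop("component spectra are proportional; the conjugate system is singular")
  B <- rbind(a260, a280, ri)
  X <- solve(crossprod(A), crossprod(A, B))        # 2 x m
  cp <- X[1L, ]; cd <- X[2L, ]
  refit <- function(col, keep) sum(A[, keep] * B[, col]) / sum(A[, keep]^2)
  neg <- which(cp < 0)
  for (i in neg) { cp[i] <- 0; cd[i] <- max(refit(i, 2L), 0) }
  neg <- which(cd < 0)
  for (i in neg) { cd[i] <- 0; cp[i] <- max(refit(i, 1L), 0) }
  total <- cp + cd
  dndc <- ifelse(total > 0,
                 (optics$dndcProtein * cp + optics$dndcDna * cd) / total,
                 NA_real_)
  list(cProtein = unname(cp), cDna = unname(cd), cTotal = unname(total),
       dndcConjugate = unname(dndc))
}

## K* = 4 pi^2 n0^2 (dn/dc)^2 / (lambda^4 N_A), lambda in cm, dn/dc in mL/g,
## c in g/mL, R(theta) in cm^-1 -> K*c/R in mol/g
.kStar <- function(dndc, constants) {
  lam <- constants$wavelength * 1e-7   # nm -> cm
  4 * pi^2 * constants$solventRI^2 * dndc^2 / (lam^4 * .avogadro)
}

#' Molar mass and RMS radius from slice-wise angular scattering
#'
#' Zimm reduction: a straight line is fitted to K*c/R(theta) against
#' sin^2(theta/2); the intercept is 1/M and slope/intercept equals
#' (16 pi^2 n0^2 / 3 lambda^2) Rg^2.  A non-positive intercept flags the
#' slice invalid; a non-positive slope reports Rg = 0 (isotropic scatterer
#' within noise).
#'
#' @param rayleigh excess Rayleigh ratios (cm^-1): a numeric vector (one
#'   slice) or a slices x angles matrix.
#' @param cTotal conjugate mass concentration(s), mg/mL.
#' @param dndc conjugate dn/dc value(s), mL/g.
#' @param constants an [opticalConstants()] list.
#' @param angleMask optional logical or integer vector selecting usable
#'   angles (low-angle flow noise is conventionally masked).
#' @return data.frame with columns `molarMass` (g/mol), `rg` (nm),
#'   `fitResidual` (RMS relative residual of the Zimm line) and `valid`.
#' @export
sliceMolarMass <- function(rayleigh, cTotal, dndc,
                           constants = opticalConstants(), angleMask = NULL) {
  if (is.null(dim(rayleigh))) rayleigh <- matrix(rayleigh, nrow = 1L)
  angles <- constants$angles
  if (ncol(rayleigh) != length(angles))
    stop("rayleigh must have one column per configured angle")
  if (!is.null(angleMask)) {
    rayleigh <- rayleigh[, angleMask, drop = FALSE]
    angles <- angles[angleMask]
  }
  if (length(angles) < 3L) stop("at least 3 usable angles are required")
  s2 <- sin(angles / 2 * pi / 180)^2
  cg <- cTotal * 1e-3                        # mg/mL -> g/mL
  y <- sweep(1 / rayleigh, 1L, .kStar(dndc, constants) * cg, "*")
  ## per-slice OLS of y on s2, closed form
  mx <- mean(s2)
  sxx <- sum((s2 - mx)^2)
  my <- rowMeans(y)
  slope <- as.numeric((y - my) %*% (s2 - mx)) / sxx
  intercept <- my - slope * mx
  pred <- outer(slope, s2) + intercept
  fitRes <- sqrt(rowMeans((y - pred)^2)) / abs(my)
  valid <- is.finite(intercept) & intercept > 0
  m <- ifelse(valid, 1 / intercept, NA_real_)
  n0 <- constants$solventRI
  lam <- constants$wavelength                 # nm; Rg comes out in nm
  rg2 <- 3 * lam^2 * slope / (16 * pi^2 * n0^2 * intercept)
  rg <- ifelse(valid & slope > 0, sqrt(pmax(rg2, 0)), 0)
  data.frame(molarMass = m, rg = rg, fitResidual = fitRes, valid = valid)
}

#' Slice-wise conjugate MALS analysis of a chromatogram
#'
#' Runs the full reduction over an aligned run with UV260, UV280, RI and LS
#' channels: per elution slice, protein/DNA concentrations from UV+RI
#' ([conjugateConcentrations()]), then molar mass and Rg from the angular
#' scattering ([sliceMolarMass()]) using the slice's composition-weighted
#' dn/dc.  Slices below the concentration floor are skipped (`valid =
#' FALSE`).  Refuses runs whose LS traces are not in excess Rayleigh units.
#'
#' @param chrom an aligned [Chromatogram-class]; UV traces in mAU.
#' @param constants an [opticalConstants()] list; angles default to the
#'   chromatogram's `angles` metadata.
#' @param optics a [componentOptics()] list.
#' @param concFloor minimum conjugate concentration analysed, mg/mL.
#' @param baseline correct baselines with [correctBaseline()] first.
#' @param quietWindows for the baseline fit.
#' @param angleMask passed to [sliceMolarMass()].
#' @return data.frame with one row per slice: `time`, `cProtein`, `cDna`,
#'   `cTotal` (mg/mL), `dndcConjugate`, `molarMass`, `rg`, `fitResidual`,
#'   `valid`.
#' @export
analyzeMALSRun <- function(chrom, constants = NULL, optics = componentOptics(),
                           concFloor = 1e-4, baseline = TRUE,
                           quietWindows = defaultQuietWindows(),
                           angleMask = NULL) {
  stopifnot(is(chrom, "Chromatogram"))
  if (!chrom@lsCalibrated)
    stop("LS traces are flagged uncalibrated (raw volts); ",
         "normalise to excess Rayleigh units before MALS analysis")
  lsCh <- intersect(names(chrom@traces), .lsChannels)
  need <- c("UV260", "UV280", "RI")
  if (!all(need %in% names(chrom@traces)) || length(lsCh) < 3L)
    stop("MALS analysis needs UV260, UV280, RI and >= 3 LS channels")
  if (is.null(constants))
    constants <- opticalConstants(angles = chrom@angles[lsCh])
  grab <- function(ch) {
    tr <- chrom@traces[[ch]]
    if (baseline) tr <- correctBaseline(tr, quietWindows)
    tr@values
  }
  times <- chrom@traces[[1L]]@times
  a260 <- grab("UV260") / 1000      # mAU -> AU
  a280 <- grab("UV280") / 1000
  ri <- grab("RI")
  conj <- conjugateConcentrations(a260, a280, ri, optics,
                                  pathLength = constants$pathLength)
  R <- vapply(lsCh, grab, numeric(length(times)))
  out <- data.frame(time = times, cProtein = conj$cProtein,
                    cDna = conj$cDna, cTotal = conj$cTotal,
                    dndcConjugate = conj$dndcConjugate,
                    molarMass = NA_real_, rg = NA_real_,
                    fitResidual = NA_real_, valid = FALSE)
  use <- which(conj$cTotal >= concFloor)
  if (length(use)) {
    sl <- sliceMolarMass(R[use, , drop = FALSE], conj$cTotal[use],
                         conj$dndcConjugate[use], constants, angleMask)
    out$molarMass[use] <- sl$molarMass
    out$rg[use] <- sl$rg
    out$fitResidual[use] <- sl$fitResidual
    out$valid[use] <- sl$valid
  }
  out
}

#' Weight-average molar mass and monodispersity over a peak
#'
#' Mw = sum(c_i M_i) / sum(c_i) over the valid slices inside the peak; the
#' average Rg is concentration-weighted the same way.  Flatness is
#' (max M - min M)/Mw over the central 80% of the peak by cumulative
#' concentration-area, and the peak is called monodisperse when flatness
#' < 0.05 — a flat molar-mass profile across the peak.
#'
#' Slices whose Zimm line fits poorly (relative RMS residual above
#' `maxResidual`, typically near-floor concentrations where 1/R noise
#' dominates) are excluded from the averages — the standard peak-limit
#' practice of discarding slices without usable scattering statistics.
#'
#' @param slices output of [analyzeMALSRun()].
#' @param peak list or one-row data.frame with `start` and `end` (minutes).
#' @param maxResidual largest acceptable relative Zimm-fit residual.
#' @return list: `mw` (g/mol), `rg` (nm), `flatness`, `monodisperse`,
#'   `nSlices`.
#' @export
peakMALSSummary <- function(slices, peak, maxResidual = 0.5) {
  sel <- slices$valid & slices$time >= peak$start & slices$time <= peak$end &
    is.finite(slices$fitResidual) & slices$fitResidual <= maxResidual
  if (sum(sel) < 3L) stop("fewer than 3 valid slices inside the peak")
  s <- slices[sel, ]
  mw <- sum(s$cTotal * s$molarMass) / sum(s$cTotal)
  rg <- sum(s$cTotal * s$rg) / sum(s$cTotal)
  cum <- cumsum(s$cTotal) / sum(s$cTotal)
  central <- s[cum >= 0.10 & cum <= 0.90, ]
  if (!nrow(central)) central <- s
  flatness <- (max(central$molarMass) - min(central$molarMass)) / mw
  list(mw = mw, rg = rg, flatness = flatness,
       monodisperse = flatness < 0.05, nSlices = sum(sel))
}

#' Experimental mass extinction coefficient over a peak
#'
#' e = integral(A dt) / (l * integral(c_total dt)) over the peak window,
#' with A the absorbance (AU) of the chosen UV channel and c_total the
#' conjugate concentration from the slice analysis — the SEC-UV-RI-MALS
#' route to an experimental EC.
#'
#' @param chrom the aligned [Chromatogram-class] that was analysed (UV in
#'   mAU).
#' @param slices output of [analyzeMALSRun()] on the same run.
#' @param peak list with `start`, `end` (minutes).
#' @param channel `"UV280"` (default) or `"UV260"`.
#' @param pathLength cm.
#' @param baseline,quietWindows as in [analyzeMALSRun()].
#' @return mass extinction coefficient, (mg/mL)^-1 cm^-1.
#' @export
experimentalMassEC <- function(chrom, slices, peak, channel = "UV280",
                               pathLength = 1.0, baseline = TRUE,
                               quietWindows = defaultQuietWindows()) {
  tr <- getTrace(chrom, channel)
  if (baseline) tr <- correctBaseline(tr, quietWindows)
  sel <- tr@times >= peak$start & tr@times <= peak$end
  if (sum(sel) < 2L) stop("peak window contains fewer than 2 grid points")
  aInt <- .trapz(tr@times[sel], tr@values[sel] / 1000)
  ssel <- slices$time >= peak$start & slices$time <= peak$end
  cInt <- .trapz(slices$time[ssel], slices$cTotal[ssel])
  if (cInt <= 0) stop("concentration integral over the peak is not positive")
  aInt / (pathLength * cInt)
}

#' Fill fraction from a weight-average molar mass
#'
#' f = (Mw - M_empty) / M_genome, clamped to \[0, 1\] — the molar-mass route
#' to the full/empty ratio.
#'
#' @param mw weight-average molar mass, g/mol.
#' @param emptyCapsidMw empty-capsid (protein shell) mass, Da.
#' @param genomeMw vector-genome mass, Da (> 0).
#' @return fill fraction in \[0, 1\].
#' @export
feFromMolarMass <- function(mw, emptyCapsidMw = defaultEmptyCapsidMw(),
                            genomeMw = defaultGenomeMw()) {
  if (any(genomeMw <= 0)) stop("genomeMw must be > 0")
  pmin(pmax((mw - emptyCapsidMw) / genomeMw, 0), 1)
}
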