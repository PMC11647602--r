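#' @include AllClasses.R
NULL

#' Exponentially modified Gaussian elution profile
#'
#' Unit-area EMG density (Gaussian of width `sigma` convolved with an
#' exponential tail of time constant `tau`), evaluated with the scaled
#' complementary error function for numerical stability; `tau = 0` reduces
#' to the pure Gaussian.  Units: minutes in, 1/min out.
#'
#' @param t times, minutes.
#' @param mu Gaussian centre, minutes.
#' @param sigma Gaussian SD, minutes (> 0).
#' @param tau exponential tail constant, minutes (>= 0).
#' @return profile values; integrates to 1 over the real line.
#' @export
emgProfile <- function(t, mu, sigma, tau = 0) {
  stopifnot(sigma > 0, tau >= 0)
  if (tau < 1e-12) return(stats::dnorm(t, mu, sigma))
  z <- (t - mu) / sigma
  a <- sigma / tau
  out <- numeric(length(z))
  ## Gaussian-dominated side: f = exp(-z^2/2) erfcx((a-z)/sqrt(2)) / (2 tau)
  left <- z <= a
  out[left] <- exp(-z[left]^2 / 2) *
    .erfcxPos((a - z[left]) / sqrt(2)) / (2 * tau)
  ## exponential tail: f = exp(a^2/2 - a z) Phi(z - a) / tau
  zr <- z[!left]
  out[!left] <- exp(a^2 / 2 - a * zr) * stats::pnorm(zr - a) / tau
  out
}

## erfcx on [0, Inf): pracma below 25, asymptotic series above (pracma's
## exp(x^2)*erfc(x) form returns Inf*0 there)
.erfcxPos <- function(u) {
  r <- numeric(length(u))
  big <- u > 25
  if (any(!big)) r[!big] <- pracma::erfcx(u[!big])
  if (any(big)) {
    ub <- u[big]
    r[big] <- (1 - 1 / (2 * ub^2) + 3 / (4 * ub^4)) / (ub * sqrt(pi))
  }
  r
}

#' Describe one eluting species
#'
#' @param kind `"capsid"`, `"free_dna"` or `"protein_impurity"`.
#' @param fill fill fraction in \[0, 1\] (capsid only).
#' @param concentration mass concentration in the injected sample, mg/mL
#'   (give this or `titer`).
#' @param titer particle titer, particles/mL; converted through
#'   c = titer * M / N_A * 1e3.
#' @param molarMass species molar mass, g/mol; defaults per kind (capsid:
#'   empty shell + fill x genome; free DNA: the genome; impurity: 1e5).
#' @param radius equivalent sphere radius for the scattering form factor,
#'   nm (0 = point scatterer).
#' @param apex,sigma,tau EMG elution parameters, minutes.
#' @param e260Mass,e280Mass optional per-species mass extinction overrides,
#'   (mg/mL)^-1 cm^-1 (used for non-capsid kinds and spectral variants).
#' @param id species identifier, must be unique within a chromatogram.
#' @return list with class `SpeciesSpec`.
#' @export
speciesSpec <- function(kind = c("capsid", "free_dna", "protein_impurity"),
                        fill = 0, concentration = NULL, titer = NULL,
                        molarMass = NULL, radius = 0, apex = 6.5,
                        sigma = 0.05, tau = 0.03, e260Mass = NULL,
                        e280Mass = NULL, id = NULL) {
  kind <- match.arg(kind)
  stopifnot(fill >= 0, fill <= 1, sigma > 0, tau >= 0, radius >= 0)
  if (is.null(concentration) && is.null(titer))
    stop("give concentration (mg/mL) or titer (particles/mL)")
  if (!is.null(concentration) && concentration < 0)
    stop("concentration must be >= 0")
  structure(list(kind = kind, fill = fill, concentration = concentration,
                 titer = titer, molarMass = molarMass, radius = radius,
                 apex = apex, sigma = sigma, tau = tau, e260Mass = e260Mass,
                 e280Mass = e280Mass,
                 id = if (is.null(id)) paste0(kind, "@", apex) else id),
            class = "SpeciesSpec")
}

#' Describe the detector noise model
#'
#' Additive Gaussian noise per channel (SD as a fraction of that channel's
#' clean maximum), one lognormal injection-to-injection scale factor shared
#' by all channels (injection-volume variability, so in-run ratios are
#' unaffected), and an optional linear baseline drift.  Only the noise layer
#' consumes the seed; the clean signal is deterministic.
#'
#' @param additive additive SD as a fraction of the clean channel maximum.
#' @param multiplicative SD of log injection scale factor.
#' @param drift baseline drift slope, signal units per minute (applied as a
#'   fraction of the channel maximum).
#' @param seed integer RNG seed.
#' @return list with class `NoiseSpec`.
#' @export
noiseSpec <- function(additive = 0.002, multiplicative = 0.02, drift = 0,
                      seed = 1L) {
  stopifnot(additive >= 0, multiplicative >= 0)
  structure(list(additive = additive, multiplicative = multiplicative,
                 drift = drift, seed = as.integer(seed)),
            class = "NoiseSpec")
}

## sphere form factor P(qR); P(0) = 1
.sphereP <- function(q, radius) {
  x <- q * radius
  p <- rep(1, length(x))
  nz <- x > 1e-8
  p[nz] <- (3 * (sin(x[nz]) - x[nz] * cos(x[nz])) / x[nz]^3)^2
  p
}

.speciesComposition <- function(sp, emptyCapsidMw, genomeMw) {
  switch(sp$kind,
    capsid = {
      wp <- emptyCapsidMw / (emptyCapsidMw + sp$fill * genomeMw)
      c(wp = wp, wd = 1 - wp)
    },
    free_dna = c(wp = 0, wd = 1),
    protein_impurity = c(wp = 1, wd = 0))
}

.speciesMolarMass <- function(sp, emptyCapsidMw, genomeMw) {
  if (!is.null(sp$molarMass)) return(sp$molarMass)
  switch(sp$kind,
    capsid = emptyCapsidMw + sp$fill * genomeMw,
    free_dna = genomeMw,
    protein_impurity = 1e5)
}

#' Simulate a multi-detector SEC chromatogram
#'
#' Physical forward model: each species contributes a unit-area EMG elution
#' profile scaled per channel by its detection response — Beer-Lambert UV
#' (A = e c l, traces stored in mAU), intrinsic protein fluorescence
#' (proportional to protein mass concentration; free DNA is dark),
#' refractive index (dn/dc times concentration, package RI units) and
#' excess Rayleigh scattering (K* c M P(theta) with a sphere form factor).
#' Capsid UV coefficients come from [ecAtFill()] of the supplied fill model
#' unless a species carries explicit overrides.  Noise-free generation is
#' deterministic and seed-independent; the optional noise layer is
#' deterministic for a fixed [noiseSpec()] seed.
#'
#' @param species list of [speciesSpec()] objects with unique ids.
#' @param noise a [noiseSpec()], or `NULL` for a noise-free run.
#' @param fillModel [FillModel-class] used for capsid UV responses.
#' @param optics [componentOptics()] for RI/LS composition responses and
#'   non-capsid UV defaults.
#' @param constants [opticalConstants()] (wavelength, solvent RI, angles).
#' @param channels channels to generate; LS channels take their angles from
#'   `constants`.
#' @param gridStart,gridEnd,dt time grid, minutes (defaults 0..30 by 0.01).
#' @param sampleId,injectionVolume,dilutionFactor,temperature sample
#'   metadata.
#' @param flowRate mL/min; converts injected concentration to elution-
#'   coordinate concentration.
#' @param fldResponse fluorescence response factor, signal units per
#'   (mg/mL) of protein.
#' @param emptyCapsidMw,genomeMw capsid component masses, Da.
#' @param delays named per-channel delay offsets, minutes (default 0).
#' @param truth named numeric list recorded as `true_*` metadata.
#' @return a [Chromatogram-class].
#' @export
generateChromatogram <- function(species, noise = NULL,
                                 fillModel = defaultFillModel(),
                                 optics = componentOptics(),
                                 constants = opticalConstants(),
                                 channels = c("UV260", "UV280", "FLD"),
                                 gridStart = 0, gridEnd = 30, dt = 0.01,
                                 sampleId = "synthetic",
                                 injectionVolume = 100, dilutionFactor = 1,
                                 temperature = NA_real_, flowRate = 1.0,
                                 fldResponse = 1000,
                                 emptyCapsidMw = defaultEmptyCapsidMw(),
                                 genomeMw = defaultGenomeMw(),
                                 delays = NULL, truth = list()) {
  ids <- vapply(species, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("species ids must be unique")
  apexes <- vapply(species, `[[`, numeric(1), "apex")
  if (any(apexes <= gridStart | apexes >= gridEnd))
    stop("all species must elute inside the run window")
  times <- seq(gridStart, gridEnd, by = dt)
  if (is.null(delays)) delays <- stats::setNames(rep(0, length(channels)), channels)

  lsCh <- channels[.isLsChannel(channels)]
  angles <- constants$angles[lsCh]
  if (length(lsCh) && anyNA(angles))
    stop("opticalConstants does not define angles for all requested LS channels")
  q <- 4 * pi * constants$solventRI * sin(angles / 2 * pi / 180) /
    constants$wavelength                        # nm^-1
  l <- constants$pathLength

  clean <- matrix(0, length(times), length(channels),
                  dimnames = list(NULL, channels))
  for (sp in species) {
    M <- .speciesMolarMass(sp, emptyCapsidMw, genomeMw)
    conc <- if (!is.null(sp$concentration)) sp$concentration
            else sp$titer * M / .avogadro * 1e3
    S <- conc * injectionVolume * 1e-3 / flowRate   # mg/mL . min
    w <- .speciesComposition(sp, emptyCapsidMw, genomeMw)
    if (sp$kind == "capsid" && is.null(sp$e260Mass)) {
      e <- ecAtFill(sp$fill, fillModel)
      e260 <- e[["e260"]]; e280 <- e[["e280"]]
    } else {
      e260 <- if (!is.null(sp$e260Mass)) sp$e260Mass else
        if (sp$kind == "free_dna") optics$dnaE260 else 0.59 * 1.0
      e280 <- if (!is.null(sp$e280Mass)) sp$e280Mass else
        if (sp$kind == "free_dna") optics$dnaE280 else 1.0
    }
    dndcSp <- w[["wp"]] * optics$dndcProtein + w[["wd"]] * optics$dndcDna
    for (j in seq_along(channels)) {
      ch <- channels[j]
      d <- if (is.null(delays[[ch]])) 0 else delays[[ch]]
      p <- emgProfile(times - d, sp$apex, sp$sigma, sp$tau)
      cS <- S * p                                  # mg/mL along elution
      clean[, j] <- clean[, j] + switch(
        substr(ch, 1, 2),
        UV = if (ch == "UV260") 1000 * e260 * cS * l else 1000 * e280 * cS * l,
        FL = fldResponse * w[["wp"]] * cS,
        RI = dndcSp * cS,
        LS = .kStar(dndcSp, constants) * (cS * 1e-3) * M *
          .sphereP(q[[ch]], sp$radius))
    }
  }

  values <- clean
  if (!is.null(noise)) {
    if (exists(".Random.seed", envir = globalenv())) {
      oldSeed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
    }
    set.seed(noise$seed)
    scale <- exp(stats::rnorm(1, 0, noise$multiplicative))
    for (j in seq_along(channels)) {
      mx <- max(abs(clean[, j]))
      values[, j] <- clean[, j] * scale +
        stats::rnorm(length(times), 0, noise$additive * mx) +
        noise$drift * mx * (times - times[1L])
    }
  }

  traces <- lapply(seq_along(channels), function(j) {
    d <- if (is.null(delays[[channels[j]]])) 0 else delays[[channels[j]]]
    Trace(channels[j], times, values[, j], delayOffset = d)
  })
  meta <- truth
  if (length(meta)) names(meta) <- paste0("true_", names(meta))
  Chromatogram(traces, sampleId = sampleId,
               injectionVolume = injectionVolume,
               dilutionFactor = dilutionFactor, temperature = temperature,
               angles = angles, lsCalibrated = TRUE, metadata = meta)
}

.subSeed <- function(seed, i) as.integer((as.numeric(seed) * 1009 + i) %%
                                           .Machine$integer.max)

#' Simulate a complete experiment
#'
#' Scenario generators mirroring the validation experiments of a
#' multi-attribute SEC assay.  Every member chromatogram carries its ground
#' truth as `true_*` metadata for closed-loop recovery testing.
#'
#' Scenarios and their main `params` (all have sensible defaults):
#' \describe{
#' \item{dilution_series}{`nPoints` (7) two-fold (`fold`) dilutions from
#'   `topTiter` (7.5e13 vp/mL, genome titer `topGenomeTiter` 1.83e13 vg/mL);
#'   `replicates` (1).  FLD areas are exactly geometric when noise-free.}
#' \item{aggregate_spiking}{volume fractions `phi` (0, 0.25, 0.5, 1) of an
#'   aggregated stock with `stockHmwPct` (45) %HMW mixed into an
#'   aggregate-free reference of equal total concentration; `replicates`
#'   (3).}
#' \item{fe_spiking}{capsid samples at `fills` (0, 0.25, 0.5, 0.75, 1).}
#' \item{thermal_series}{`temperatures` (30..80 by 10): fill `f0` (0.6)
#'   constant to 40 degC then declining linearly to 0 at 80; monomer
#'   amplitude likewise collapsing to 0 at 80; the ejected DNA reappears as
#'   a free-DNA peak at 5.5 min (spectral ratio `dnaRatio`, 1.85) with the
#'   total DNA mass conserved.}
#' \item{mals_run}{a monodisperse `monomerMw` (4.2e6 g/mol) monomer with
#'   sphere radius `monomerRadius` (15.5 nm) plus heterogeneous HMW
#'   oligomers (8.4, 25.2, 100 MDa), with UV/RI/18-angle LS channels and a
#'   component-consistent (mass-weighted) fill model.}
#' \item{inprocess_panel}{five downstream-process members (cell lysate,
#'   clarified lysate, affinity eluate, mixed-mode flow-through, purified
#'   product); lysates carry abundant 8-16 min impurity peaks, the purified
#'   product is >= 98% monomer.}
#' }
#'
#' @param name scenario name.
#' @param params named list overriding scenario defaults; `noise = FALSE`
#'   disables the noise layer in any scenario.
#' @param seed integer; injection-level noise seeds are derived from it.
#' @return a named list of [Chromatogram-class] objects.
#' @export
generateScenario <- function(name = c("dilution_series", "aggregate_spiking",
                                      "fe_spiking", "thermal_series",
                                      "mals_run", "inprocess_panel"),
                             params = list(), seed = 1L) {
  name <- match.arg(name)
  p <- function(key, default)
    if (is.null(params[[key]])) default else params[[key]]
  noisy <- !identical(p("noise", TRUE), FALSE)
  mkNoise <- function(i) if (noisy)
    noiseSpec(additive = p("additiveNoise", 0.002),
              multiplicative = p("multiplicativeNoise", 0.02),
              seed = .subSeed(seed, i)) else NULL
  me <- p("emptyCapsidMw", defaultEmptyCapsidMw())
  mg <- p("genomeMw", defaultGenomeMw())

  switch(name,
    dilution_series = {
      n <- p("nPoints", 7); fold <- p("fold", 2)
      top <- p("topTiter", 7.5e13)
      topVg <- p("topGenomeTiter", 1.83e13)
      reps <- p("replicates", 1)
      fill <- topVg / top
      titers <- top / fold^(seq_len(n) - 1L)
      out <- list(); k <- 0L
      for (i in seq_len(n)) for (r in seq_len(reps)) {
        k <- k + 1L
        out[[sprintf("level%02d_rep%d", i, r)]] <- generateChromatogram(
          list(speciesSpec("capsid", fill = fill, titer = titers[i],
                           apex = 6.5, id = "monomer")),
          noise = mkNoise(k), emptyCapsidMw = me, genomeMw = mg,
          sampleId = sprintf("dilution_%02d_rep%d", i, r),
          truth = list(titer_vp = titers[i], titer_vg = titers[i] * fill,
                       fill = fill))
      }
      out
    },
    aggregate_spiking = {
      phi <- p("phi", c(0, 0.25, 0.5, 1.0))
      stock <- p("stockHmwPct", 45)
      reps <- p("replicates", 3)
      titer <- p("titer", 2e13)
      fill <- p("fill", 0.5)
      conc <- titer * (me + fill * mg) / .avogadro * 1e3
      out <- list(); k <- 0L
      for (i in seq_along(phi)) for (r in seq_len(reps)) {
        k <- k + 1L
        hmwFrac <- phi[i] * stock / 100
        sp <- list(speciesSpec("capsid", fill = fill,
                               concentration = conc * (1 - hmwFrac),
                               apex = 6.5, id = "monomer"))
        if (hmwFrac > 0)
          sp <- c(sp, list(speciesSpec("capsid", fill = fill,
                                       concentration = conc * hmwFrac,
                                       molarMass = 2 * (me + fill * mg),
                                       radius = 19.5, apex = 5.5,
                                       sigma = 0.07, id = "dimer")))
        out[[sprintf("phi%03.0f_rep%d", 100 * phi[i], r)]] <-
          generateChromatogram(sp, noise = mkNoise(k),
                               emptyCapsidMw = me, genomeMw = mg,
                               sampleId = sprintf("spike_phi%.2f_rep%d",
                                                  phi[i], r),
                               truth = list(phi = phi[i],
                                            hmw_pct = phi[i] * stock))
      }
      out
    },
    fe_spiking = {
      fills <- p("fills", c(0, 0.25, 0.5, 0.75, 1))
      titer <- p("titer", 2e13)
      fm <- p("fillModel", defaultFillModel())
      out <- list()
      for (i in seq_along(fills)) {
        out[[sprintf("fill%03.0f", 100 * fills[i])]] <- generateChromatogram(
          list(speciesSpec("capsid", fill = fills[i], titer = titer,
                           apex = 6.5, id = "monomer")),
          noise = mkNoise(i), fillModel = fm,
          emptyCapsidMw = me, genomeMw = mg,
          sampleId = sprintf("fe_fill%.2f", fills[i]),
          truth = list(fill = fills[i]))
      }
      out
    },
    thermal_series = {
      temps <- p("temperatures", seq(30, 80, by = 10))
      f0 <- p("f0", 0.6)
      titer <- p("titer", 2e13)
      dnaRatio <- p("dnaRatio", 1.85)
      fm <- p("fillModel", componentFillModel(emptyCapsidMw = me,
                                              genomeMw = mg))
      dna0 <- titer * f0 * mg / .avogadro * 1e3
      out <- list()
      for (i in seq_along(temps)) {
        Tc <- temps[i]
        amp <- if (Tc <= 40) 1 else max(0, 1 - (Tc - 40) / 40)
        fT <- if (Tc <= 40) f0 else f0 * max(0, (80 - Tc) / 40)
        bound <- titer * amp * fT * mg / .avogadro * 1e3
        free <- dna0 - bound
        sp <- list()
        monConc <- titer * amp * (me + fT * mg) / .avogadro * 1e3
        if (monConc > 0)
          sp <- c(sp, list(speciesSpec("capsid", fill = fT,
                                       concentration = monConc,
                                       apex = 6.9, id = "monomer")))
        if (free > 0)
          sp <- c(sp, list(speciesSpec("free_dna", concentration = free,
                                       molarMass = mg, apex = 5.5,
                                       sigma = 0.06,
                                       e260Mass = 20.0,
                                       e280Mass = 20.0 / dnaRatio,
                                       id = "free_dna")))
        out[[sprintf("T%02d", Tc)]] <- generateChromatogram(
          sp, noise = mkNoise(i), fillModel = fm,
          channels = c("UV260", "UV280"),
          emptyCapsidMw = me, genomeMw = mg,
          sampleId = sprintf("thermal_%02dC", Tc), temperature = Tc,
          truth = list(fill = fT, amp = amp, bound_dna = bound,
                       free_dna = free, total_dna = dna0))
      }
      out
    },
    mals_run = {
      mwMono <- p("monomerMw", 4.2e6)
      rMono <- p("monomerRadius", 15.5)
      concMono <- p("monomerConc", 0.3)
      fill <- min(max((mwMono - me) / mg, 0), 1)
      fm <- componentFillModel(emptyCapsidMw = me, genomeMw = mg)
      constants <- p("constants", opticalConstants())
      hmw <- p("hmw", list(
        list(mw = 2 * mwMono, radius = 19.5, apex = 5.6, conc = 0.05),
        list(mw = 6 * mwMono, radius = 28, apex = 5.0, conc = 0.03),
        list(mw = 1.0e8, radius = 45, apex = 4.4, conc = 0.02)))
      sp <- list(speciesSpec("capsid", fill = fill, concentration = concMono,
                             molarMass = mwMono, radius = rMono, apex = 6.5,
                             id = "monomer"))
      for (i in seq_along(hmw)) {
        h <- hmw[[i]]
        sp <- c(sp, list(speciesSpec("capsid", fill = fill,
                                     concentration = h$conc,
                                     molarMass = h$mw, radius = h$radius,
                                     apex = h$apex, sigma = 0.08,
                                     id = sprintf("hmw%d", i))))
      }
      list(run = generateChromatogram(
        sp, noise = mkNoise(1L), fillModel = fm,
        optics = p("optics", componentOptics()), constants = constants,
        channels = c("UV260", "UV280", "FLD", "RI", names(constants$angles)),
        emptyCapsidMw = me, genomeMw = mg, sampleId = "mals_run",
        truth = list(mw_monomer = mwMono,
                     rg_monomer = sqrt(3 / 5) * rMono,
                     fill = fill)))
    },
    inprocess_panel = {
      fill <- p("fill", 0.5)
      imp <- function(apex, sigma, conc, id)
        speciesSpec("protein_impurity", concentration = conc, apex = apex,
                    sigma = sigma, tau = 0.05, id = id)
      mono <- function(conc) speciesSpec("capsid", fill = fill,
                                         concentration = conc, apex = 6.5,
                                         id = "monomer")
      hmw <- function(conc) speciesSpec("capsid", fill = fill,
                                        concentration = conc,
                                        molarMass = 2 * (me + fill * mg),
                                        radius = 19.5, apex = 5.5,
                                        sigma = 0.07, id = "dimer")
      dna <- function(conc) speciesSpec("free_dna", concentration = conc,
                                        molarMass = mg, apex = 10.5,
                                        sigma = 0.6, id = "hc_dna")
      members <- list(
        cell_lysate = list(mono(0.05), hmw(0.01), imp(9.0, 0.5, 0.8, "hcp1"),
                           imp(12.5, 0.8, 1.0, "hcp2"), dna(0.5)),
        clarified_lysate = list(mono(0.05), hmw(0.008),
                                imp(9.0, 0.5, 0.5, "hcp1"),
                                imp(12.5, 0.8, 0.6, "hcp2"), dna(0.3)),
        affinity_eluate = list(mono(0.25), hmw(0.015),
                               imp(11.0, 0.6, 0.02, "hcp1")),
        mixed_mode_ft = list(mono(0.01), imp(10.0, 0.6, 0.12, "hcp1"),
                             imp(13.0, 0.7, 0.10, "hcp2")),
        purified_product = list(mono(0.3), hmw(0.003)))
      out <- list()
      for (i in seq_along(members)) {
        nm <- names(members)[i]
        truePurity <- {
          concs <- vapply(members[[i]], function(s)
            if (s$kind == "free_dna") 0 else s$concentration, numeric(1))
          isMono <- vapply(members[[i]], function(s)
            identical(s$id, "monomer"), logical(1))
          100 * sum(concs[isMono]) / sum(concs)
        }
        out[[nm]] <- generateChromatogram(
          members[[i]], noise = mkNoise(i), emptyCapsidMw = me,
          genomeMw = mg, sampleId = nm,
          truth = list(purity = truePurity))
      }
      out
    })
}
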