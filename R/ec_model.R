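#' @include AllClasses.R
NULL

## 280-nm absorptivities of the aromatic chromophores (M^-1 cm^-1), the
## standard set used for protein extinction estimates.
.aromaticE280 <- c(Trp = 5500, Tyr = 1490, Cystine = 125)

## Eq. coefficients of the DNA-containing-capsid molar extinction model:
## e260 = 20.0 * MW_DNA + 3.72e6 * vp/vg
## e280 = 11.1 * MW_DNA + 6.31e6 * vp/vg
.dnaCoef260 <- 20.0
.dnaCoef280 <- 11.1
.capsidConst260 <- 3.72e6
.capsidConst280 <- 6.31e6

#' Construct an ExtinctionSet
#'
#' Give either the molar or the mass coefficients (plus the species mass);
#' the missing basis is derived through e_mass = e_molar / MW.
#'
#' @param e260Mass,e280Mass mass coefficients, (mg/mL)^-1 cm^-1.
#' @param speciesMw species molecular weight, Da.
#' @param e260Molar,e280Molar molar coefficients, M^-1 cm^-1.
#' @return an [ExtinctionSet-class].
#' @export
#' @examples
#' ExtinctionSet(e260Mass = 0.98, e280Mass = 1.68, speciesMw = 3.756e6)
ExtinctionSet <- function(e260Mass = NULL, e280Mass = NULL, speciesMw,
                          e260Molar = NULL, e280Molar = NULL) {
  if (is.null(e260Molar)) e260Molar <- e260Mass * speciesMw
  if (is.null(e280Molar)) e280Molar <- e280Mass * speciesMw
  if (is.null(e260Mass)) e260Mass <- e260Molar / speciesMw
  if (is.null(e280Mass)) e280Mass <- e280Molar / speciesMw
  new("ExtinctionSet", e260Molar = e260Molar, e280Molar = e280Molar,
      e260Mass = e260Mass, e280Mass = e280Mass, speciesMw = speciesMw)
}

#' Construct a FillModel
#'
#' @param empty,full [ExtinctionSet-class] for the empty and full capsid.
#' @param interpolation `"linear_in_fill"` (default) or `"mass_weighted"`.
#' @return a [FillModel-class].
#' @export
FillModel <- function(empty, full, interpolation = "linear_in_fill") {
  new("FillModel", empty = empty, full = full, interpolation = interpolation)
}

#' Default AAV capsid masses
#'
#' The packaged fixture is anchored to the published mass extinction
#' coefficients (empty capsid e280 1.68, e260 0.98; full capsid e280 4.0,
#' e260 5.65 (mg/mL)^-1 cm^-1): the empty-capsid mass is the one that turns
#' the DNA-free molar e280 (6.31e6 M^-1 cm^-1) into 1.68, and the genome mass
#' is the one for which the DNA-containing-capsid equations reproduce the
#' printed full-capsid coefficients.  This makes the whole default model
#' internally consistent.
#'
#' @return mass in Da.
#' @export
defaultEmptyCapsidMw <- function() .capsidConst280 / 1.68

#' @rdname defaultEmptyCapsidMw
#' @export
defaultGenomeMw <- function() {
  me <- defaultEmptyCapsidMw()
  (4.0 * me - .capsidConst280) / (.dnaCoef280 - 4.0)
}

#' @rdname defaultEmptyCapsidMw
#' @export
defaultFullCapsidMw <- function() defaultEmptyCapsidMw() + defaultGenomeMw()

#' The default full/empty extinction model
#'
#' Linear-in-fill interpolation between the published empty (e260 0.98, e280
#' 1.68) and full (e260 5.65, e280 4.0) mass coefficient sets.  Its 260/280
#' crossover sits near 30% full capsid and its ratio endpoints are ~0.58 and
#' ~1.41.
#'
#' @param interpolation `"linear_in_fill"` (default) or `"mass_weighted"`.
#' @return a [FillModel-class].
#' @export
defaultFillModel <- function(interpolation = "linear_in_fill") {
  FillModel(
    empty = ExtinctionSet(e260Mass = 0.98, e280Mass = 1.68,
                          speciesMw = defaultEmptyCapsidMw()),
    full = ExtinctionSet(e260Mass = 5.65, e280Mass = 4.0,
                         speciesMw = defaultFullCapsidMw()),
    interpolation = interpolation)
}

#' Component-consistent full/empty extinction model
#'
#' Builds a mass-weighted [FillModel-class] whose endpoints are exact
#' mixtures of a protein component and a DNA component, so that interpolated
#' coefficients at any fill equal the protein/DNA conjugate decomposition
#' used by the MALS reduction.  Mass-weighted interpolation between such
#' endpoints is algebraically identical to component mixing, both for
#' mixtures of full and empty particles and for uniformly part-filled
#' particles.
#'
#' @param optics a [componentOptics()] list with the component mass ECs.
#' @param emptyCapsidMw,genomeMw masses in Da.
#' @return a [FillModel-class] with `mass_weighted` interpolation.
#' @export
componentFillModel <- function(optics = componentOptics(),
                               emptyCapsidMw = defaultEmptyCapsidMw(),
                               genomeMw = defaultGenomeMw()) {
  me <- emptyCapsidMw; mg <- genomeMw; mf <- me + mg
  FillModel(
    empty = ExtinctionSet(e260Mass = optics$proteinE260,
                          e280Mass = optics$proteinE280, speciesMw = me),
    full = ExtinctionSet(
      e260Mass = (me * optics$proteinE260 + mg * optics$dnaE260) / mf,
      e280Mass = (me * optics$proteinE280 + mg * optics$dnaE280) / mf,
      speciesMw = mf),
    interpolation = "mass_weighted")
}

#' Molar extinction coefficients of a DNA-containing capsid
#'
#' Combined protein+DNA molar coefficients of the full (DNA-containing)
#' capsid as a linear function of the packaged genome mass:
#' `e260 = 20.0 * mwDna + 3.72e6 * vpVg` and
#' `e280 = 11.1 * mwDna + 6.31e6 * vpVg` (M^-1 cm^-1).  `vpVg` is the
#' particle-to-genome ratio, a plain multiplicative correction on the capsid
#' (protein) term; 1 corresponds to a fully packaged preparation.
#'
#' @param mwDna vector-genome molecular weight, Da (>= 0).
#' @param vpVg particle-to-genome ratio, >= 1.
#' @return named numeric `c(e260, e280)` in M^-1 cm^-1.
#' @export
#' @examples
#' molarECFullCapsid(0, 1)        # DNA-free limit: the capsid constants
#' molarECFullCapsid(1.2e6, 1)
molarECFullCapsid <- function(mwDna, vpVg = 1) {
  if (any(mwDna < 0)) stop("mwDna must be >= 0")
  if (any(vpVg < 1)) stop("vpVg must be >= 1")
  c(e260 = .dnaCoef260 * mwDna + .capsidConst260 * vpVg,
    e280 = .dnaCoef280 * mwDna + .capsidConst280 * vpVg)
}

#' Construct a CapsidComposition
#'
#' @param vpCounts integer(3), VP1/VP2/VP3 copies per 60-mer (default 5:5:50,
#'   i.e. the canonical 1:1:10 stoichiometry).
#' @param aromatics 3x3 matrix of residue counts per VP monomer, columns
#'   Trp, Tyr, Cystine; or `NULL` when `perVpE280` is given.
#' @param perVpE280 numeric(3), molar e280 per VP monomer (M^-1 cm^-1); or
#'   `NULL` when `aromatics` is given.
#' @param genomeMw,emptyCapsidMw masses in Da.
#' @param vpVg particle-to-genome ratio, >= 1.
#' @return a [CapsidComposition-class].
#' @export
CapsidComposition <- function(vpCounts = c(5L, 5L, 50L), aromatics = NULL,
                              perVpE280 = NULL,
                              genomeMw = defaultGenomeMw(),
                              emptyCapsidMw = defaultEmptyCapsidMw(),
                              vpVg = 1) {
  if (is.null(aromatics) && is.null(perVpE280))
    stop("provide aromatic counts or per-VP e280 coefficients")
  if (!is.null(aromatics)) {
    aromatics <- as.matrix(aromatics)
    colnames(aromatics) <- c("Trp", "Tyr", "Cystine")
  } else aromatics <- matrix(numeric(0), 0, 0)
  new("CapsidComposition", vpCounts = as.integer(vpCounts),
      aromatics = aromatics,
      perVpE280 = if (is.null(perVpE280)) numeric(0) else perVpE280,
      genomeMw = genomeMw, emptyCapsidMw = emptyCapsidMw, vpVg = vpVg)
}

#' Empty-capsid molar extinction at 280 nm from composition
#'
#' Sums the aromatic absorptivities (Trp 5500, Tyr 1490, cystine 125
#' M^-1 cm^-1) over the residues of all 60 VP monomers, or — when per-VP
#' coefficients are supplied — the count-weighted per-VP coefficients.
#'
#' @param composition a [CapsidComposition-class].
#' @param coefficients named absorptivity set; the cystine contribution can
#'   be disabled by setting it to 0.
#' @return per-capsid molar e280, M^-1 cm^-1.
#' @export
emptyCapsidE280 <- function(composition, coefficients = .aromaticE280) {
  stopifnot(is(composition, "CapsidComposition"))
  if (length(composition@perVpE280))
    return(sum(composition@vpCounts * composition@perVpE280))
  perVp <- as.numeric(composition@aromatics %*%
                        coefficients[colnames(composition@aromatics)])
  sum(composition@vpCounts * perVp)
}

#' Empty-capsid extinction at 260 nm via the conversion factor
#'
#' For the protein-only (empty) capsid the 260-nm coefficient is taken as a
#' published fixed fraction of the 280-nm one (default 0.59); units follow
#' the input.
#'
#' @param e280 coefficient at 280 nm, > 0 (molar or mass basis).
#' @param factor conversion factor in (0, 1).
#' @return coefficient at 260 nm, same basis as the input.
#' @export
emptyCapsidE260 <- function(e280, factor = 0.59) {
  if (any(e280 <= 0)) stop("e280 must be > 0")
  if (factor <= 0 || factor >= 1) stop("factor must lie in (0, 1)")
  factor * e280
}

#' Convert a molar extinction coefficient to a mass basis
#'
#' e_mass = e_molar / MW; the result is in (mg/mL)^-1 cm^-1 (numerically
#' equal to L g^-1 cm^-1).
#'
#' @param eMolar molar coefficient, M^-1 cm^-1.
#' @param mw molecular weight, Da (> 0).
#' @return mass coefficient, (mg/mL)^-1 cm^-1.
#' @export
massFromMolar <- function(eMolar, mw) {
  if (any(mw <= 0)) stop("mw must be > 0")
  eMolar / mw
}

.checkFill <- function(f) {
  if (any(f < 0 | f > 1)) stop("fill fraction must lie in [0, 1]")
  f
}

#' Mass extinction coefficients at a given fill fraction
#'
#' `linear_in_fill`: e(f) = (1-f) e_empty + f e_full per wavelength.
#' `mass_weighted`: endpoints weighted by species mass,
#' e(f) = \[(1-f) Me e_empty + f Mf e_full\] / \[(1-f) Me + f Mf\].
#'
#' @param f fill fraction(s) in \[0, 1\].
#' @param model a [FillModel-class].
#' @return for scalar `f` a named numeric `c(e260, e280)`; for vector `f` a
#'   two-column matrix.
#' @export
#' @examples
#' ecAtFill(0, defaultFillModel())   # the empty-capsid set
#' ecAtFill(1, defaultFillModel())   # the full-capsid set
ecAtFill <- function(f, model = defaultFillModel()) {
  .checkFill(f)
  em <- model@empty; fu <- model@full
  if (model@interpolation == "linear_in_fill") {
    w <- f
  } else {
    w <- f * fu@speciesMw / ((1 - f) * em@speciesMw + f * fu@speciesMw)
  }
  e260 <- (1 - w) * em@e260Mass + w * fu@e260Mass
  e280 <- (1 - w) * em@e280Mass + w * fu@e280Mass
  if (length(f) == 1L) c(e260 = e260, e280 = e280)
  else cbind(e260 = e260, e280 = e280)
}

#' Fill fraction at which the 260- and 280-nm curves cross
#'
#' Solves e260(f) = e280(f).  The crossing is unique because the ratio is
#' strictly increasing; closed form for `linear_in_fill`, root bracketing to
#' 1e-10 otherwise.  With the published coefficient sets it falls near 30%
#' full capsid.
#'
#' @param model a [FillModel-class].
#' @return the crossover fill fraction f* in \[0, 1\].
#' @export
crossoverFill <- function(model = defaultFillModel()) {
  em <- model@empty; fu <- model@full
  g <- function(f) {
    e <- ecAtFill(f, model)
    e[["e260"]] - e[["e280"]]
  }
  if (g(0) > 0 || g(1) < 0)
    stop("the 260/280 curves do not cross in [0, 1]")
  if (model@interpolation == "linear_in_fill") {
    d0 <- em@e280Mass - em@e260Mass
    d1 <- fu@e260Mass - fu@e280Mass
    return(d0 / (d0 + d1))
  }
  stats::uniroot(g, c(0, 1), tol = 1e-10)$root
}

#' A260/A280 ratio as a function of fill, and its inverse
#'
#' `ratioAtFill` returns r(f) = e260(f)/e280(f), which is strictly increasing
#' in f for both interpolation modes.  `fillFromRatio` inverts it (closed
#' form for `linear_in_fill`, bisection to 1e-10 otherwise); ratios outside
#' the attainable band \[r(0), r(1)\] raise an error reporting that band.
#'
#' @param f fill fraction(s) in \[0, 1\].
#' @param r observed A260/A280 ratio(s).
#' @param model a [FillModel-class].
#' @return `ratioAtFill`: the ratio(s); `fillFromRatio`: the fill
#'   fraction(s).
#' @export
ratioAtFill <- function(f, model = defaultFillModel()) {
  e <- ecAtFill(f, model)
  if (is.matrix(e)) unname(e[, "e260"] / e[, "e280"])
  else unname(e[["e260"]] / e[["e280"]])
}

#' @rdname ratioAtFill
#' @export
fillFromRatio <- function(r, model = defaultFillModel()) {
  r0 <- ratioAtFill(0, model); r1 <- ratioAtFill(1, model)
  if (any(r < r0 - 1e-12 | r > r1 + 1e-12))
    stop(sprintf("ratio outside the attainable band [%.4f, %.4f]", r0, r1))
  r <- pmin(pmax(r, r0), r1)
  em <- model@empty; fu <- model@full
  if (model@interpolation == "linear_in_fill") {
    ## r = (e260e + f*(e260f - e260e)) / (e280e + f*(e280f - e280e))
    num <- r * em@e280Mass - em@e260Mass
    den <- (fu@e260Mass - em@e260Mass) - r * (fu@e280Mass - em@e280Mass)
    return(pmin(pmax(num / den, 0), 1))
  }
  vapply(r, function(ri) {
    stats::uniroot(function(f) ratioAtFill(f, model) - ri, c(0, 1),
                   tol = 1e-10)$root
  }, numeric(1))
}

#' Read a capsid composition / extinction fixture from a YAML config
#'
#' Schema (all keys optional unless noted):
#' \preformatted{
#' composition:
#'   vp_counts: [5, 5, 50]
#'   aromatics:            # per-VP rows [Trp, Tyr, Cystine]; or per_vp_e280
#'     VP1: [9, 55, 6]
#'     VP2: [8, 48, 6]
#'     VP3: [7, 44, 6]
#'   genome_mw: 1.227e6
#'   empty_capsid_mw: 3.756e6
#'   vp_vg: 1
#' fill_model:             # omit to use the packaged default
#'   empty: {e260_mass: 0.98, e280_mass: 1.68, mw: 3.756e6}
#'   full:  {e260_mass: 5.65, e280_mass: 4.0,  mw: 4.983e6}
#'   interpolation: linear_in_fill
#' }
#'
#' @param path YAML file path.
#' @return list with elements `composition` ([CapsidComposition-class] or
#'   `NULL`) and `fillModel` ([FillModel-class]).
#' @export
readCapsidConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  comp <- NULL
  if (!is.null(cfg$composition)) {
    cc <- cfg$composition
    aromatics <- if (!is.null(cc$aromatics))
      do.call(rbind, cc$aromatics[c("VP1", "VP2", "VP3")])
    comp <- CapsidComposition(
      vpCounts = if (is.null(cc$vp_counts)) c(5L, 5L, 50L) else cc$vp_counts,
      aromatics = aromatics,
      perVpE280 = cc$per_vp_e280,
      genomeMw = if (is.null(cc$genome_mw)) defaultGenomeMw() else cc$genome_mw,
      emptyCapsidMw = if (is.null(cc$empty_capsid_mw)) defaultEmptyCapsidMw()
                      else cc$empty_capsid_mw,
      vpVg = if (is.null(cc$vp_vg)) 1 else cc$vp_vg)
  }
  fm <- if (is.null(cfg$fill_model)) defaultFillModel() else {
    fmArgs <- cfg$fill_model
    mk <- function(side) ExtinctionSet(e260Mass = side$e260_mass,
                                       e280Mass = side$e280_mass,
                                       speciesMw = side$mw)
    FillModel(mk(fmArgs$empty), mk(fmArgs$full),
              interpolation = if (is.null(fmArgs$interpolation))
                "linear_in_fill" else fmArgs$interpolation)
  }
  list(composition = comp, fillModel = fm)
}
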