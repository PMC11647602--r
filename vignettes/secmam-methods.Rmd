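---
title: "Multi-attribute SEC analytics for AAV: models and methods"
author: "secmam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-attribute SEC analytics for AAV: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secmam)
```

## The problem

A recombinant AAV preparation is a mixture of ~25 nm icosahedral protein
capsids (60 VP monomers, roughly 3.7 MDa of protein) that either package a
single-stranded DNA genome ("full") or do not ("empty"), plus aggregates of
those capsids and, upstream in the process, host-cell protein and DNA
impurities.  A single size-exclusion injection monitored by four in-line
detectors — UV absorbance at 260 and 280 nm, intrinsic protein fluorescence
(FLD), a differential refractometer (RI) and an 18-angle static
light-scattering photometer (MALS) — carries enough information to report,
in one assay: purity and aggregation, total-capsid and genome titer, the
full/empty fraction, absolute molar mass and RMS radius, and (across a
temperature series) the onset and completion of thermal genome ejection.
`secmam` implements the data reduction for all of these attributes and a
physical forward simulator used to validate every step in closed loop.

## The extinction-coefficient model

The core model links UV absorbance to genome content.  A DNA-containing
capsid absorbs like a protein/DNA conjugate; its molar extinction
coefficients (M^-1 cm^-1) are linear in the packaged genome mass
$M_\mathrm{DNA}$ (Da):

$$\epsilon_{260} = 20.0\,M_\mathrm{DNA} + 3.72\times10^6\,(vp/vg), \qquad
  \epsilon_{280} = 11.1\,M_\mathrm{DNA} + 6.31\times10^6\,(vp/vg),$$

where $vp/vg$ is a particle-to-genome correction held at 1 for fully
packaged material (`molarECFullCapsid()`).  Dividing by the species mass
gives mass coefficients in (mg/mL)^-1 cm^-1 (`massFromMolar()`).  For the
protein-only empty capsid, $\epsilon_{280}$ follows from the aromatic
residue content of VP1/VP2/VP3 (Trp 5500, Tyr 1490, cystine 125
M^-1 cm^-1 — the cystine term is configurable and on by default), and
$\epsilon_{260}$ is a fixed published fraction of it, 0.59
(`emptyCapsidE280()`, `emptyCapsidE260()`).

The packaged default fixture (`defaultFillModel()`) is anchored directly to
the published mass-coefficient sets — empty 0.98/1.68 and full 5.65/4.0
(mg/mL)^-1 cm^-1 at 260/280 nm — and the default masses are derived
backwards from them so the whole fixture is self-consistent: the
empty-shell mass $6.31\times10^6/1.68 = 3.756$ MDa and the genome mass
$1.227$ MDa, the unique value for which the molar equations reproduce the
printed full-capsid set.  Note the fixture keeps the printed empty
$\epsilon_{260} = 0.98$ even though $1.68 \times 0.59 = 0.9912$; the two
constructions differ in the second decimal and both are exposed.

Between the endpoints the model interpolates in the fill fraction $f$ (the
proportion of full particles).  Two rules are provided:

* `linear_in_fill` (default): $\epsilon(f) = (1-f)\,\epsilon_e + f\,\epsilon_s$
  per wavelength.  This is the construction behind the published
  coefficient-versus-%full plots and puts the 260/280 crossover at
  `r round(100 * crossoverFill(defaultFillModel()), 1)`% full capsid.
* `mass_weighted`: endpoints weighted by species mass.  This rule is
  algebraically identical to mixing a protein component and a DNA component
  with their own coefficients — both for mixtures of full and empty
  particles and for uniformly part-filled particles — and is therefore the
  rule consistent with the conjugate (UV/RI) decomposition used by the MALS
  reduction (`componentFillModel()`).

The A260/A280 ratio $r(f) = \epsilon_{260}(f)/\epsilon_{280}(f)$ is strictly
increasing under both rules, from `r round(ratioAtFill(0), 3)` (empty) to
`r round(ratioAtFill(1), 4)` (full), so it inverts uniquely
(`fillFromRatio()`; closed form for the linear rule, bisection to 1e-10
otherwise).  Because peak areas at the two wavelengths are proportional to
the coefficients (Beer–Lambert), the same inversion applied to the
monomer-peak area ratio yields the full/empty fraction
(`feFromPeakAreas()`).  Two caveats are surfaced as flags, never refusals:
ratios outside the attainable band clamp to the nearest endpoint with
`inRange = FALSE`, and fractions above 0.8 are flagged because the ratio
method loses discrimination in the 80–100% range.  A monomer ratio of 1.20
maps to ≈0.55 under the linear rule; empirical spiked-standard calibrations
have read the same ratio as ≈0.60, so a user-supplied `FillModel` built
from spiked standards can replace the theoretical curve throughout.

## Chromatogram model and peak processing

Traces live on a strictly increasing uniform grid (minutes; default
0–30 min at 0.01 min, i.e. 3001 points for a 30-min, 1 mL/min method).
Inter-detector dead volumes are per-channel constant `delayOffset`s
supplied in metadata (default 0, since the instrument train's dead volumes
are configuration-specific); `alignTraces()` shifts and linearly
interpolates every trace onto the first detector's grid over the common
window.  Cross-correlation delay estimation is deliberately out of scope.

Baseline correction subtracts an ordinary least-squares line fitted to
quiet windows (default 0–2 and 25–30 min), so constant offsets and linear
drift are removed exactly and the operation is exactly testable.
Asymmetric-least-squares smoothing was considered and rejected: it has no
closed-form oracle and the simulated baselines are linear.  Peak detection
takes local maxima above a height threshold (default five times the robust
quiet-window noise, MAD × 1.4826) with at least that prominence; boundaries
are valley minima between adjacent peaks and a 0.1%-of-apex threshold
crossing at the outer flanks.  Integration is trapezoidal, always over the
*same* time boundaries on every channel — required so that 260/280 area
ratios refer to identical windows.  Class labels are assigned by apex
retention time: monomer 6.0–7.0 min, HMW aggregates 4.0–5.8 min, late
process impurities 8–16 min; thermal analysis carves a free-DNA window
(5.3–5.7 min) out of the HMW region.  The boundary and baseline rules are
documented package defaults, not claims about any vendor integrator.

## Titer calibration

Calibration is unweighted ordinary least squares of peak area on nominal
titer on raw scales (a `1/x^2`-weighted option exists), with residual SD on
the n−2 denominator.  Detection and quantitation limits use the 3.3σ/slope
and 10σ/slope conventions, so LOQ/LOD = 10/3.3 ≈ 3.03 for every curve —
the ratio both published LOQ/LOD pairs sit at, which is what pins the
convention choice.  Back-calculated titers below the LOQ are flagged and
reported, never suppressed; negative back-calculations clamp to zero with a
flag.

## Conjugate MALS reduction

Per elution slice, protein and DNA mass concentrations come from the
least-squares solution of

$$A_{260} = l(\epsilon_{260,p} c_p + \epsilon_{260,d} c_d),\quad
  A_{280} = l(\epsilon_{280,p} c_p + \epsilon_{280,d} c_d),\quad
  S_{RI} = (dn/dc)_p c_p + (dn/dc)_d c_d,$$

with dn/dc 0.185 mL/g for the protein shell and 0.170 mL/g for nucleic
acid, protein mass coefficients from the empty-capsid fixture and DNA mass
coefficients 20.0/11.1 (mg/mL)^-1 cm^-1 — the per-unit-mass limit of the
molar equations, an interpretation documented here.  A negative component
clamps to zero with a refit of the other.  The package RI convention is
dn/dc (mL/g) × concentration (mg/mL), i.e. 10^3 × the refractive-index
increment, which keeps the three equations at comparable magnitude.

Molar mass and radius use the Zimm relation
$K^* c / R(\theta) = 1/M + (16\pi^2 n_0^2 / 3\lambda_0^2) R_g^2
\sin^2(\theta/2) / M$ with
$K^* = 4\pi^2 n_0^2 (dn/dc)^2 / (\lambda^4 N_A)$, fitted linearly in
$\sin^2(\theta/2)$ per slice using the slice's composition-weighted dn/dc.
For 25 nm particles at 690 nm the maximum $qR_g$ is ≈0.3, where the Zimm
linearisation of the sphere form factor is accurate to well under 5% in
$R_g$ and under 0.1% in $M$ — the reason Zimm was chosen over Berry/Debye.
The "sphere" reading of the result is $R = R_g\sqrt{5/3}$.  Wavelength
(690 nm), solvent index (1.331) and the 18 angles (evenly spaced in
$\sin^2(\theta/2)$ from 15° to 160°) are instrument constants that the
source instrument does not publish; all are configurable
(`opticalConstants()`), and results are invariant to the wavelength as long
as generation and analysis agree (tested).  Low-angle channels can be
masked (`angleMask`), the usual treatment for flow noise.  BSA-based
detector normalisation is out of scope: synthetic LS traces are generated
already in excess Rayleigh units, and a `lsCalibrated = FALSE` flag makes
the reduction refuse raw-signal input.

Peak summaries report the weight-average $M_w = \sum c_i M_i / \sum c_i$, a
concentration-weighted $R_g$, and a flatness metric (mass range over the
central 80% of the peak by area, relative to $M_w$; flat ⇒ monodisperse at
threshold 0.05).  Slices whose Zimm line fits poorly (relative RMS residual
above 0.5) are excluded: they are near-floor concentrations where noise on
$1/R(\theta)$ makes the intercept — and hence $M$ — unbounded, and
excluding statistically unusable slices is the standard peak-limit
practice.  The molar-mass route to the fill fraction is
$f = (M_w - M_{empty})/M_{DNA}$, clamped to [0, 1]
(`feFromMolarMass()`).

## Thermal genome-ejection analysis

For each temperature the monomer peak (280 nm boundaries shared with
260 nm) yields a percent area and an A260/A280 ratio; the free-DNA window
is tracked alongside.  Ejection onset is the lowest temperature whose
monomer ratio falls >5% (relative) below the baseline-temperature ratio
*or* whose monomer percent area falls >10% below baseline — two
signatures, either of which may trigger first, because genome loss first
depresses the 260 nm signal and later the particle count.  Completion is
the lowest temperature with monomer percent area below 5% of baseline.  A
free-DNA peak ratio at or above 1.8 (the DNA limit 20.0/11.1 of the molar
equations) is classified nucleic-acid-like by `uvSpectrumCheck()`.

## The synthetic-data generator

`generateChromatogram()` is a physical forward model: each species
contributes a unit-area exponentially modified Gaussian elution profile
(default σ = 0.05 min, τ = 0.03 min — mild tailing; τ = 0 gives a pure
Gaussian) scaled per channel by its detection response: Beer–Lambert UV
with coefficients from `ecAtFill()` of the chosen fill model, fluorescence
proportional to protein mass concentration (free DNA is dark),
RI = dn/dc × c, and Rayleigh scattering $K^* c M P(\theta)$ with a uniform-
sphere form factor.  Titer-mode concentrations convert through
$c = \mathrm{titer} \times M / N_A \times 10^3$ mg/mL.  Noise defaults are
reverse-engineered from the published precision claims (purity RSD ≤ 5%,
titer RSD ≤ 10%): additive Gaussian noise at 0.2% of each channel's clean
maximum, plus one lognormal injection-scale factor (σ = 2%) shared by all
channels, emulating injection-volume variability — which is why
within-injection ratios (percent areas, 260/280 ratios) are much more
precise than absolute areas, as observed.  Only the noise layer consumes
the seed (R's default Mersenne–Twister, restored after use); noise-free
generation is deterministic and seed-independent.

`generateScenario()` packages the validation experiments, embedding ground
truth as `true_*` metadata:

* **dilution_series** — 7 two-fold dilutions from 7.5×10^13 vp/mL
  (1.83×10^13 vg/mL).  The published dilution span (0.29–75 ×10^12, a
  258-fold range) is slightly inconsistent with 7 two-fold steps (64-fold);
  both the number of points and the fold are parameters, with 7 × 2-fold as
  the default reading.
* **aggregate_spiking** — an aggregated stock with 45% HMW mixed
  volumetrically (φ = 0, 0.25, 0.5, 1.0; triplicates) into an
  aggregate-free reference.  The source description is ambiguous about
  which stock is spiked into which; the generator parameterises by the
  volume fraction φ of aggregated stock, and expected %HMW = 45φ assumes
  equal total particle concentration of the two stocks.
* **fe_spiking** — single-capsid samples at fill 0, 0.25, 0.5, 0.75, 1.0,
  generated with the linear-in-fill model so the UV-ratio closed loop is
  exact up to noise.
* **thermal_series** — 30–80 °C by 10 °C: fill constant at f₀ = 0.6 up to
  40 °C then declining linearly to 0 at 80 °C, monomer amplitude likewise
  collapsing to 0 at 80 °C, with the ejected DNA reappearing as a free-DNA
  peak at 5.5 min under exact mass conservation.  The free-DNA spectral
  ratio defaults to 1.85 — a realistic ssDNA value that sits safely above
  the 1.8 classification threshold; the exact model limit 20.0/11.1 ≈ 1.802
  is available via `dnaRatio`.  This scenario uses the component-consistent
  (mass-weighted) fill model so the generated UV traces admit an exact
  protein/DNA decomposition.
* **mals_run** — a monodisperse 4.2 MDa monomer (sphere radius 15.5 nm,
  $R_g$ = 12.0 nm) with 8.4/25/100 MDa oligomer aggregates, full
  UV+RI+18-angle LS channel set, component-consistent fill model.
* **inprocess_panel** — five downstream-process members; lysates carry
  abundant 8–16 min impurity peaks, the purified product is ≥98% monomer.

What the generator does *not* emulate — nonlinear detector response,
band-broadening differences between detectors, retention drift, column
interactions, partially resolved empty/full subpopulations — bounds what
passing closed-loop tests show about real data: they validate the
*reduction*, not the chromatography.

## Problem sizes and numerics

All simulations run on the 3001-point default grid.  The test suite uses
single runs for deterministic checks, 10–20 seeds for stochastic recovery
claims (e.g. molar mass within 2% at 1% detector noise in ≥90% of 20
seeds), and the acceptance script medians a 60-injection spiking study over
5 sub-seeds; the full suite completes in well under a minute on one CPU.
Numerical choices worth knowing: the EMG uses a scaled-complementary-error
formulation with an asymptotic branch, stable over the whole grid;
`fillFromRatio`/`crossoverFill` use closed forms for the linear rule and
bisection to 1e-10 otherwise; ties in peak classification cannot occur
because windows must be disjoint; degenerate inputs (flat traces, zero
areas, missing channels, monomer-free baselines, raw LS signals) raise
typed errors or flagged absences as documented on each function.

## Known limitations

The UV-ratio full/empty method is insensitive above ~80% full (flagged,
per the published caveat) and cannot distinguish partially filled capsids
from mixtures of full and empty ones.  LOD/LOQ values depend on the
calibration design through the residual SD.  The MALS reduction assumes
constant inter-detector delays and excess-Rayleigh-calibrated LS input.
Aggregates larger than ~100 nm are outside the method's (and simulator's)
remit.
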