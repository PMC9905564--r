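---
title: "Carbonate budgets, bioerosion, and reef-accretion potential: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbonate budgets, bioerosion, and reef-accretion potential: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefcarb)
```

## The scientific problem

Eastern tropical Pacific reefs are built almost entirely by branching
*Pocillopora* growing under marginal conditions: seasonal upwelling, low
aragonite saturation, recurrent ENSO heat stress, and bioerosion pressure
several times higher than in the Caribbean or Indo-Pacific. Whether a
given reef accretes or erodes is the balance of two census-scale sums:
carbonate fixed by calcifiers, and carbonate removed by borers and
grazers. This package implements that balance as a per-transect budget
and converts it into reef-accretion potential (RAP), the maximum vertical
growth rate the budget can sustain, for comparison against local
sea-level rise.

Two gulfs anchor the analysis. The Gulf of Panamá (GoP) experiences
strong seasonal upwelling that today buffers thermal stress; the Gulf of
Chiriquí (GoC) is warmer, more stable, and bleached harder in 2015–2016.
The package's defaults encode this contrast.

## The budget model

All covers are proportions in [0, 1] internally; percentages exist only
at I/O edges and in the threshold models (where slopes per percent cover
are the field convention).

**Gross production.** For each transect, cover of each calcifying taxon
times its calcification rate (g CaCO₃ cm⁻² yr⁻¹), times 10 to convert to
kg CaCO₃ m⁻² yr⁻¹. Production is planar: rugosity was not surveyed, so
gross production and bioerosion are both per unit horizontal area and the
budget is internally consistent, though both are conservative in absolute
terms.

**Calcification rates.** *Pocillopora* rates come from out-planted
fragments weighed hydrostatically at ~6-month intervals. Dry weight
follows from buoyant weight via
$W_d = W_b/(1 - \rho_{sw}/\rho_{arag})$ with defaults
$\rho_{sw} = 1.023$, $\rho_{arag} = 2.93$ g cm⁻³ (the conventional
hydrostatic-weighing constants; both configurable). An interval's rate is
the dry-weight change divided by the mean planar area and the interval
length. Note the physics: dry weight is *decreasing* in the assumed
aragonite density, because denser skeleton displaces less water per gram.
Seasons are assigned by interval midpoint; the month mapping is
configurable because regional studies disagree on labels, and the default
(March–September = non-upwelling, carrying the higher rates) follows the
convention in which upwelling suppresses calcification. Intervals longer
than 9 months are labelled "annual". Minor taxa (*Porites*, *Pavona*,
*Gardineroseris*) and CCA carry literature-scale rates in the
configuration; they average ≤ 2% of cover and are immaterial to the
gulf contrasts.

**Bioerosion.** Six components, each a positive magnitude; the
conventional minus sign is cosmetic and applied only when formatting.
Components are linear in their cover/density arguments, so the budget
identity `net = gross − Σ components` is exact to machine precision (a
tested invariant):

- *Macroborers*: `L·ml + T·mt + D·md`, with gulf-specific rates per unit
  cover of live coral, thick algal turf, and dead substrate. These rates
  are literature-derived configuration values (the nutrient-rich GoP
  carries the higher live-coral rate).
- *Microborers*: a flat 0.233 kg m⁻² yr⁻¹ per transect — the
  Indo-Pacific database average, used verbatim because no regional
  estimates exist. Whether the constant should apply to the whole
  transect or only its dead substrate is genuinely open; the default is
  the flat reading, and a dead-scaled mode is provided for sensitivity
  analysis.
- *Boring sponges*: chemical dissolution 0.85 kg m⁻² yr⁻¹ weighted by
  infestation prevalence on live coral (0.46), rubble (0.46) and standing
  framework (0.56). Mechanical sponge erosion is assumed to be inside the
  macroborer rates and is not double-counted.
- *Urchins*: per-individual substrate-specific rates (g ind⁻¹ day⁻¹)
  times density and cover, times 365/1000.
- *Parrotfish*: per-capita = bite rate × feeding hours × 365 × scar
  proportion × scar volume × substrate density / 1000, times species
  density. Parameters are configuration, in the ReefBudget structure.
- *Pufferfish*: destruction rate × 365/1000 × density × 0.6, the 0.6
  being the fraction of fish actively feeding.

**Category mapping.** The point-intercept vocabulary does not name "dead
substrate" directly. The default mapping takes D = dead framework + fine
turf (turf-veneered bare carbonate), keeps rubble out of D (it enters
only the sponge term), and uses dead framework as the standing-framework
term FC. The mapping is a config object because the composition of "dead
substrate" is a genuine judgment call.

**Fish broadcast.** Fish were surveyed only in the final period; the
model assumes stable assemblages and broadcasts those densities to all
periods. The step is explicit (`broadcast_fish_densities()`) and flagged
per row, so the provenance of extrapolated densities survives into the
output table.

## Accretion potential

Net mass converts to vertical growth through the density of what the
reef actually accretes: porous framework packed in matrix. Per site,
cores give a compaction fraction $C_x$ (top 2 m excluded as open,
contemporary framework; the package consumes already-summarised values),
porosity $\phi_x = 1 - C_x$, and
$\rho_x = C_x D_f + \phi_x D_w$ with $D_f = 1.84$ g cm⁻³ measured on
waxed *Pocillopora* skeletons and $D_w = 1.03$ g cm⁻³ for the pore
water.

$$RAP = G/\rho_x + S \quad \text{(mm yr}^{-1}\text{)}$$

**Units.** With $G$ in kg CaCO₃ m⁻² yr⁻¹ and $\rho_x$ in g cm⁻³, the
quotient is *already* in mm yr⁻¹: 1 kg m⁻² of solid at 1 g cm⁻³ is a
1-mm slab. Formulations that state an explicit ×1000 factor are
converting a metres-based intermediate; carrying that factor literally on
top of these units would be off by three orders of magnitude. This
package fixes the unit convention above and documents it here
prominently. Sanity anchor: $7.8/1.84 + 0.46 \approx 4.7$ mm yr⁻¹ —
net production over skeletal density plus sediment, at the scale
observed for upwelling-gulf reefs.

The *millennial* variant substitutes $D_f$ for $\rho_x$, approximating
long-term accretion of fully compacted framework; it is never above the
full RAP when $\rho_x \le D_f$ and the budget is positive. The sediment
contribution $S$ (mm yr⁻¹) is a per-site configuration value (its
derivation needs sedimentation data outside this package's scope);
site tables default it to 0 and the synthetic generator uses 0.4 mm yr⁻¹,
a plausible matrix contribution for these reef settings.

## Thresholds and sea level

Net production and RAP are modelled as affine functions of coral cover
(percent) and gulf with a site random intercept, via `nlme::lme` — the
standard tool for this design. With noiseless or site-homogeneous data
the random effect is degenerate and the fit falls back to OLS on the same
fixed effects; thresholds always use fixed effects only (population-level
prediction), so the two routes agree. Inverting the affine prediction
gives the cover needed to reach a target: 0 for a net-positive budget, or
a sea-level-rise rate for a keep-up threshold. Covers above 100% are
flagged unattainable rather than clipped. The keep-up boundary is
inclusive (RAP equal to the rise rate counts as keeping up) —
documented, arbitrary.

Global RCP rates (2.6: 4, 4.5: 7, 8.5: 15 mm yr⁻¹) are localized by the
ratio of the observed local trend to the observed global-mean rise,
default 1.7 mm yr⁻¹ (the 20th-century convention). The local trend is
the OLS slope of the PSMSL-style monthly series on decimal year, with
missing months omitted, never interpolated — with a ~1.4 mm yr⁻¹ Balboa
trend the correction factor is ≈ 0.82 and the localized rates ≈ 3.3,
5.7 and 12.3 mm yr⁻¹.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which the pipeline is validated.

- **Survey**: per site × period, six multinomial draws of 100 points
  over per-gulf, per-period category means calibrated to the observed
  cover trajectories (GoP 81→75%, GoC 51→39%), with thick turf declining
  in the GoP and dead substrate expanding in the GoC.
- **Out-plants**: 20 corals per site with fixed planar area
  (mean 30 cm²); dry-weight increments are true seasonal rate × area ×
  Δt plus Gaussian noise (SD 3 g), emitted as buoyant weights so the
  analysis must invert the hydrostatic relation. Seasonal truths are
  GoP 3.1/2.0 and GoC 2.9/2.3 g cm⁻² yr⁻¹; the final annual interval
  grows at the seasonal mean. Holding area constant makes the noise-free
  inversion exact, which is what makes it a useful oracle.
- **Grazers**: Poisson counts over 25 m² urchin belts around linear
  trajectories (GoP 0.5→1.7, GoC 0.4→4.9 ind m⁻²; in the source
  material the labelling of these two trajectories is ambiguous in one
  sentence, so both are plain config) and 100 m² fish belts around
  fixed species densities, fish in the final period only.
- **Cores**: Gaussian compaction around 0.62 (SD 0.05), clamped to
  (0, 1]; porosity is the exact complement by construction. The 0.62
  default puts $\rho_x \approx 1.53$ g cm⁻³, consistent with RAP ≈ 5.5
  mm yr⁻¹ at a GoP-scale net budget.
- **Tide gauge**: 50 years of monthly levels = intercept + 1.4 mm yr⁻¹
  trend + a 60-mm annual harmonic + 25-mm noise, with 2% of months
  missing. Because the trend fit omits the seasonal term, the harmonic
  inflates residuals; the trend SE is ≈ 0.14 mm yr⁻¹, which the tests
  respect by pooling across seed sweeps rather than asserting each seed
  at the noise-only SE.

One integer seed drives all channels through fixed sub-streams, so any
table is reproducible in isolation. What the generator does *not*
emulate: spatial autocorrelation among transects, ENSO events, observer
error in category assignment, coral area growth over the experiment, and
non-stationary fish assemblages. Passing tests therefore demonstrate
correctness of the estimators under the declared statistical structure,
not robustness to survey artefacts in real data.

## Numerical and design choices

- Percent change is reported as 100 × (old − new)/old, rounded half
  away from zero — the convention that reproduces standard report
  tables. (Not every published percentage follows a single convention;
  this one is applied uniformly.)
- Bioerosion components are magnitudes; no signs inside the model.
- The budget identity and additivity are asserted at 1e−12, threshold
  inverse-consistency at 1e−9.
- Transect problem sizes throughout the tests and the acceptance script
  (180 transects, 120 corals, 600 tide months, 100-seed ordering sweeps)
  match the full study design; they run in seconds and were chosen to
  keep the sampling error of gulf contrasts well below the effect sizes.
- Gulf-specific borer and urchin rates, fish parameters, and minor-taxon
  calcification rates are configuration with literature-scale defaults;
  they shape magnitudes, not the structure of any equation, and every
  equation is tested against independent arithmetic oracles on random
  inputs.

## Known limitations

Planar (rugosity-free) production; no physical or chemical erosion; fish
assemblages assumed stable across periods; sediment contribution taken
as config rather than derived; thresholds assume the bioeroder
assemblage stays at its contemporary state while cover varies. All are
properties of the census-based budget approach, not implementation
shortcuts.
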