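---
title: "Attributing land-use emissions to crops: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing land-use emissions to crops: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lucattr)
```

## The accounting problem

Agricultural land use emits greenhouse gases through two broad channels:
the one-off carbon released when natural vegetation is converted to
farmland (land-use change, LUC), and the recurring emissions of managing
that farmland (peat drainage, fertilizer and manure N2O, residue
decomposition, waste burning, methane from flooded rice). Attributing
both channels to individual crops, per region and per time step, is what
this package does. It is a bookkeeping exercise on gridded inputs, not a
process model: vegetation dynamics, yield formation and land allocation
are upstream of the package and consumed as data.

The pipeline operates on a regular latitude/longitude grid (nominally
5 arc-min cells, about 85 km2 at the equator) with a 5-year time step,
and on a fixed vocabulary of 20 land-use classes, of which three are
agricultural (cropland, intensive grassland, biofuel cropland). Each
cell carries a single dominant class; the composition of agricultural
cells across the 17 attribution categories (16 crop categories plus
pastureland) is a separate fraction stack.

## Procedure

1. **Carbon stocks.** Aboveground carbon density (Mg C/km2) times cell
   area gives the per-cell stock; differencing consecutive steps gives
   the stock change, with the sign convention *positive = loss*, so
   emission events have positive CO2 after the 44/12 conversion.
2. **Transitions.** Any cell whose dominant class changes between
   consecutive steps produces one transition event carrying the whole
   cell's stock change (no sub-cell apportionment — a direct consequence
   of the one-dominant-class representation). Events are classified by a
   taxonomy table into six categories: (1) natural vegetation
   transitions, (2) natural vegetation to agriculture, (3) natural
   vegetation to biofuel, (4) natural vegetation to extensive grassland,
   (5) agricultural transitions, (6) abandonment to natural vegetation.
   Only categories 2 and 5 are attributable to crops; only *emission*
   events (positive stock loss) ever enter the attribution.
3. **Management sources.** Seven gridded sources are integrated per
   step: (1) land-clearing N2O, (2) peatland-drainage CO2/N2O/CH4,
   (3) manure N2O, (4) residue N2O, (5) synthetic-fertilizer N2O,
   (6) waste-burning N2O/CH4, (7) wetland-rice CH4. CH4 and N2O are
   converted to CO2-eq with configurable GWP factors. Sources 1-3 join
   the LUC attribution pool; source 4 is split across crops proportional
   to their aboveground residue; sources 5-7 arrive crop-specific and
   pass through (rice CH4 is asserted to stay on the rice category).
4. **Attribution.** In each cell and step, attributable CO2-eq is
   allocated proportional to the *increase* in crop-area fraction,
   w_i = max(f_i(t) - f_i(t-1), 0) / sum, then aggregated to reporting
   regions into the ledger (region x crop x step x source). Allocation
   has no memory: land converted in step t is existing cropland from
   t+1 on.
5. **Metrics.** Marginal footprint = natural-to-agriculture emissions /
   newly converted area (t CO2/ha); total footprint = all emissions /
   total crop area (t CO2-eq/ha); emission intensity = all emissions /
   production (t CO2-eq/ton); land requirement = harvested area /
   production (ha/ton, the inverse of yield). Production is smoothed
   with a centered 5-year moving average before use. Crop-region
   pairings are classified into three clusters by footprint and land
   requirement bands.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `co2PerC` | 44/12 | stoichiometric C→CO2 mass ratio |
| `gwp` | CH4 28, N2O 265 | CO2-eq factors, AR5 100-yr horizon |
| `earthRadius` | 6371.0072 km | authalic radius for cell areas |
| `resolution` | 1/12° | 5 arc-min grid |
| moving-average window | 5 yr | production smoothing, odd, truncated at edges |
| cluster thresholds | footprint (5, 50) t CO2-eq/ha; land (0.15, 0.5) ha/ton | band edges for clusters i/ii/iii |

The GWP horizon label travels into all run metadata so CO2-eq totals are
always interpretable. The AR5 100-year defaults are a package choice —
gridded-model CO2-eq totals elsewhere may rest on other factors, which
is why both are fully configurable.

## Design decisions taken where the method is open

* **Extensive grassland.** The six category names leave transitions out
  of extensive grassland unnamed. The shipped taxonomy treats extensive
  grassland as semi-natural: conversion *into* cropland/pasture counts
  as category 2 (so its carbon loss is attributable), conversion into
  biofuel as category 3, and all flows from agriculture back into
  extensive grassland or natural classes as abandonment (category 6).
  The taxonomy is data (`inst/extdata/default_taxonomy.csv`, 380 ordered
  pairs), so a different reading is a one-file change.
* **Fallback weights (conservation first).** When no category's fraction
  increased in an emitting cell, weights fall back to the current
  fractions — the crops actually present; if those are zero too, the
  mass is booked to an explicit `unallocated` pseudo-category. Emissions
  are never silently dropped, and the ledger-vs-input conservation check
  runs on every call, not only in tests.
* **Category-5 transitions** (agricultural transitions, e.g. pasture to
  cropland) use the same increase-proportional rule, so the expanding
  crop is charged. An alternative — charging the destination class —
  would break down when several crops expand at once.
* **Area bases.** The total footprint uses physical crop area (prior
  area plus newly established area); the land requirement uses harvested
  area, which differs under multi-cropping. The decomposition identity
  *intensity = footprint x land requirement* is therefore checked on a
  harmonized harvested-area basis (`cropAreaTable()` vs. the
  harvested-area table share one interface).
* **Weighted period averages** use the weights that make each mean equal
  the corresponding global ratio: converted area for marginal
  footprints, total area for total footprints, production for
  intensities. This is the only choice with that consistency property.
* **Management step convention.** Management layers hold 5-year sums
  (rate x area x 5 when synthesized from annual rates), indexed by the
  interval's end year; the convention is recorded in layer metadata.
* **Ocean / no-data** cells are the fill value -9999 in the NetCDF
  layout; this is the package's format convention, not a claim about
  any external archive's dialect.

## The synthetic world

The generator emulates the *structure* of the real inputs — a gridded
multi-decade series with class-typical carbon-density contrasts,
fractional crop composition inside agricultural cells, per-source
management rates, and region-level production trajectories — under a
scripted transition schedule that makes every downstream number
computable in closed form (`expectedLedger()`). The default world is
12 x 12 cells x 11 steps (1970-2020), 3 regions, 5 active crops plus
pasture, with a nine-entry schedule covering all six transition
categories; equivalence sweeps use scripted worlds up to 24 x 24, and
conservation sweeps run 100 random seeded worlds. These sizes exercise
every code path of the accounting at comfortably interactive speed;
the math is identical at any grid size.

Densities are class-typical (tropical forest 15,000 Mg C/km2, i.e.
150 Mg C/ha; cropland 500), and management rates have realistic
magnitudes (synthetic fertilizer ~1.6 kg N2O/ha/yr, wetland rice
~0.3 Mg CH4/ha/yr, peat CO2 0.5 Mg/ha/yr as a region-average over
agricultural land). The soil pool responds with a one-step lag of
class-typical soil densities, so a conversion's soil flux falls in the
5-year period after it — exactly the window of the first-order soil
estimate.

What the generator does *not* emulate: the spatial autocorrelation,
class mosaic statistics, or empirical density distributions of real
land-use model output; multi-step transition chains driven by land
markets; trade-driven production shifts. A green test suite therefore
demonstrates that the accounting is exact and conserving on structurally
faithful inputs — not that any real-world emission total is reproduced.

## Numerical choices

* Cell areas use the spherical-band formula
  A = R² Δλ (sin φ_top − sin φ_bottom) with the authalic radius; a full
  global grid closes to 4πR² to rounding error.
* Conservation and identity checks use a 1e-9 relative tolerance;
  observed errors are at machine precision (~1e-16).
* Fractions may sum to at most 1 + 1e-9 per cell to absorb float noise;
  class vocabularies and region ids are validated on construction *and*
  on file read, with errors naming the offending cell and step.
* Zero denominators yield missing metrics (never 0 or Inf); missing
  values are excluded from weighted averages with weight
  renormalization. A stock change of exactly zero is labelled an
  emission event of zero CO2 and drops out of all totals.
* Ties in the moving average do not arise (plain truncated mean); the
  window must be odd so the average is centered.

## First-order soil-carbon extension

Soil carbon is excluded from the core stocks because its flux is slow
and assigning it to a conversion year is ambiguous. As a bounded
estimate of what that exclusion omits, `soilCarbonFirstOrder()` takes
the soil-stock change of the 5-year period *after* each attributable
conversion, allocates it with the same weights as the aboveground
carbon, and reports soil / (soil + aboveground). On the default demo
world this is about 19%. Conversions in the final step have no
post-conversion window and are excluded, making the figure a
lower-bound style approximation.

## Worked demo

```{r demo, eval = FALSE}
res <- runPipeline(runConfig(seed = 1, world = "synthetic"))
head(res$ledger)
res$metadata$conservation
res$metrics$summary
```

The same run is scripted in `scripts/acceptance.R`, which regenerates
the demo world from scratch and writes the headline quantities
(totals, shares, conservation and identity errors, cell-area checks,
cluster counts) to JSON.

## Known limitations

* Whole-cell events: a cell's full stock change rides on its single
  dominant-class transition, which over- or under-states emissions in
  mixed cells.
* No amortization of conversion emissions over later years and no
  multi-step chains (forest → pasture → crop books two independent
  events).
* No reprojection: all layers must share one grid; no trade or
  consumption-based reallocation.
* The ledger cannot distinguish management-driven density change from
  transition-driven change inside a converting cell; the whole change is
  booked to the transition.
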