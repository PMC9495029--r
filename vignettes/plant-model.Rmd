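---
title: "Modelling a black soldier fly larvae fatty-acid plant: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a black soldier fly larvae fatty-acid plant: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsfrefinery)
```

This vignette explains the model behind `bsfrefinery`: what is simulated,
under which assumptions, which parameters matter, and where we made design
choices that another modeller could legitimately make differently.

## The process in one paragraph

Ten tonnes of wet black soldier fly larvae enter per batch. A cold-water wash
removes part of the ash and fiber; a grinder homogenizes the suspension; an
alcalase (serine endopeptidase) incubation at 60 °C hydrolyzes the tissue
protein so the lipids release cleanly; two microfiltration steps reject
cellulose and ash as waste; a disc centrifuge splits the slurry into a crude
oil phase, a wet protein cake and an aqueous stream; three sharp-split
distillation towers fractionate the oil by boiling point (lauric 298.8 °C,
myristic 326.2 °C, palmitic 348 °C, stearic above); condensers liquefy the
overheads, an adsorption column strips residual water off the lauric product,
the protein cake is freeze-dried into a saleable meal and an ultrafilter
recovers reusable water. The plant runs ~2,878 staggered batches a year, and
a 20-year discounted cash flow decides feasibility per rearing-feed scenario.

## Mass-balance philosophy

Every unit is a *split-fraction* model: each output component mass is a fixed
fraction of the corresponding input mass. There is no thermodynamics in the
mass balance — temperatures, pressures and phases are carried as stream
metadata and checked for plausibility, but they never alter a split. This is
the right level of abstraction for a feasibility study: the published
operating parameters *are* split fractions (66% ash and 38% cellulose removal
in the washer, 0.999 membrane rejection, a sharp distillation cut), and it
makes the whole plant exactly linear in the feed, so conservation can be
demanded to numerical precision (1e-9 relative, per unit and plant-wide)
rather than "approximately".

Two consequences worth knowing:

* **Distillation is idealized.** A component boils entirely overhead or
  entirely to the bottoms depending on its boiling point versus the cut
  temperature. Real columns leak; the reflux ratios (14.404, 1.186, 0.984)
  and stage counts (22, 43, 43) only drive the shortcut condenser/reboiler
  duty estimate `(R+1) · D · λ̄`, not the split.
* **Energy is config-dependent.** Latent heats (water 2,257 kJ/kg, fatty
  acids 200 kJ/kg) and heat capacities (4.18 / 2.1 kJ/kg·K) are registry
  defaults, not measured values; duty numbers are therefore indicative and
  deliberately excluded from any verified quantity.

## From proximate analysis to simulation components

A scenario's proximate rows overlap: organic matter subsumes protein, fiber
and fat, and acid detergent fiber is contained in neutral detergent fiber. We
therefore use only {ash, crude protein, NDF, ether extract} as dry-matter
components, renormalized to fill the dry matter exactly, with NDF standing in
for the "cellulose" simulation component and ether extract for crude fat; OM
and ADF ride along as reporting metadata. The chicken-manure scenario's OM
value (59.8%) is inconsistent with its other rows — flagged, not corrected,
and harmless because OM never enters the conversion. The spent-grain rows sum
to 112.5% of dry matter before renormalization; the validator's soft sanity
warning therefore triggers only above 115%.

The fatty-acid profile of the crude fat is **not** a measured input; no
numeric profile is published. The default (0.50 lauric / 0.20 myristic /
0.20 palmitic / 0.10 stearic) encodes lauric dominance — the lead product,
with the first and most expensive tower dedicated to it — and is overridable
per scenario. Any conclusion about *absolute* product masses inherits this
choice; conclusions about *between-scenario ordering* do not, because the
profile multiplies all scenarios alike.

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| batch mass | 10,000 | kg larvae | published per-batch feed |
| wash removals | 0.66 ash, 0.38 cellulose | – | published washer spec |
| grinder throughput | 9,174 | kg/h | published; sets a 1 h-scale occupancy |
| enzyme charge | 100 | kg/batch | published bulk material |
| hydrolysis conversion | 0.9 | – | book-keeping split; mass-neutral |
| membrane rejection | 0.999 | – | published for cellulose/ash/UF |
| denaturation | 0.05 | – | published; relabels permeating protein |
| flux | 20 | L/m²·h | published; drives membrane area |
| max retentate density | 1,100 (MF), 1,200 (UF) | g/L | published cap; sets retained water |
| distillation cuts | 310 / 337 / 354.5 | °C | chosen strictly between boiling points |
| freeze-dryer | 10 mm/h, 10 mm tray, 5% moisture | | published rate; depth/moisture are ours |
| schedule | 7919 / 7.25 / 2.75 | h | published timing set |
| tax, horizon | 6%, 20 yr | | published economics settings |

Utility water (wash 10,000 kg, enzyme dilution 900 kg, backwash 500 kg per
batch) and the per-batch steam/cooling/electricity demands are plausible
magnitudes chosen once so the cost arithmetic is exercised; they are not
published values.

## Design choices where the sources underdetermine the model

* **Unit order.** The narrative order wash → grind → incubate was kept even
  though one stream listing implies grinding after incubation; the flow
  labels were reconciled to the narrative order.
* **Annual operating time.** The text says 7920 h, the results table 7919 h.
  We use 7919: it is the value under which `floor((7919 − 7.25)/2.75) + 1`
  returns the published 2,878 batches.
* **Per-batch water demand.** The 36,058.03 kg/batch water row is a
  simulator-side aggregate (process water plus thermal-jacket and other
  utility water) that cannot be derived from the printed unit parameters; the
  plant fixture stores the annual demand (103,775,015 kg over the 2,878-batch
  campaign) and derives the per-batch figure from it. The flowsheet's own
  explicit water inputs are tracked separately at stream level.
* **Centrifuge water routing.** A component-to-outlet map cannot put water in
  three places at once, yet the wet protein cake, the aqueous stream and the
  oil phase all carry water downstream. Two physical parameters resolve
  this: cake moisture (1 kg water per kg cake solids → a 50%-moisture cake,
  matching what a freeze-dryer feed should look like) and oil-phase water
  entrainment (0.02 kg/kg, which is what the first tower then strips).
* **Condense-then-adsorb.** The lauric overhead leaves as vapor with its
  entrained water, is condensed at 80 °C, and only then water-stripped in the
  adsorber. The stearic product leaves the last tower as *bottoms* (liquid),
  so its heat exchanger is a sensible-heat cooler, not a condenser.
* **Membrane water retention.** The density cap (g/L) is read as the maximum
  solids concentration of the retentate slurry; the retentate then carries
  the *minimum* water meeting the cap, `W = ρ_w · S · (1/C_max − 1/ρ_s)` with
  ρ_s = 1,500 kg/m³ for solids. If the feed cannot supply that water the unit
  records an infeasibility warning rather than failing.
* **Empty batches draw no utilities.** Wash water, enzyme and backwash are
  per-batch charges applied only when material is processed, so a zero feed
  propagates to an all-empty, still-conserving plant.
* **Stearic boiling point.** Not printed (its registry entry came from the
  simulator's database); set to 361.1 °C from standard property tables, which
  preserves the required lauric < myristic < palmitic < stearic ordering.
* **Economics.** No prices, equipment costs or waste fees are published, and
  the published IRR/NPV table is internally inconsistent (two different feed
  scenarios print identical panels). We therefore treat the numeric IRR/NPV
  values as non-reproducible and verify the economics *structurally*: NPV at
  the solved IRR vanishes, NPV decreases in the rate for conventional series,
  the flat tax can only lower the IRR, all-negative series report −100%, and
  the fat-rich kitchen-waste scenario out-earns the fat-poor control at any
  common non-negative price set. Default prices (fatty acids 1.0–1.8 /kg,
  protein meal 0.7 /kg, enzyme 25 /kg, capital 8e7) are round commodity
  magnitudes chosen once. Depreciation is omitted — the only published fiscal
  instrument is the 6% flat tax on gross profit.

## The synthetic-scenario generator

`sample_composition()` draws each proximate field independently from a normal
with the scenario's mean and SD, truncated to [0, 100] ("±" values are read
as SDs). `generate_scenario_set()` adds mean-preserving log-normal price
perturbations (σ² = log(1 + CV²), with the −σ²/2 correction) so that price
sensitivity can be studied without biasing the mean.

What it emulates: measurement spread in larval composition between rearing
batches, and market noise on prices. What it does **not** emulate:
covariance between proximate fields (fat and fiber are anti-correlated in
real larvae; no covariance data exists, so fields are independent),
within-batch heterogeneity, seasonal feed variation, or any biological
substrate-to-composition model. A passing sensitivity suite therefore shows
the *pipeline* responds monotonically and reproducibly to composition and
price inputs — not that the sampled distributions are biologically complete.

## Numerical choices

* Mass closure is enforced at 1e-9 relative per unit and plant-wide;
  violations are errors, not warnings, because any closure failure in a
  linear split model is a programming bug.
* `n_batches` adds 1e-9 before flooring so that exact multiples of the cycle
  time (7919 − 7.25 is exactly 2,877 cycles) are not lost to floating-point
  division.
* The crude-fat split forces its last component to the exact remainder so the
  four fatty acids sum to the fat mass bit-exactly.
* IRR: deterministic sign-change scan on (−0.999, 10] (step 0.01 up to 1,
  then 0.1) followed by bisection to an interval of 1e-12; a root is accepted
  only if |NPV| < 1e-6 × |capital|. No derivatives, no dependence on initial
  guesses.
* A cut temperature within 1e-9 of a component boiling point is an
  "ambiguous cut" error; an empty distillate or bottoms is a degenerate-cut
  warning, and an empty distillation feed is handled as a degenerate case so
  an empty plant simulates cleanly.
* Report CSVs write kg at fixed 2-decimal precision and the in-memory report
  stores the same rounded values, so a written table re-reads bit-exactly;
  the material-balance Total row is computed as the sum of the already-
  rounded rows, which is what makes the published totals exact sums.

## Problem sizes used in the checks

The test-suite and reproduction script run the full plant on the four
scenario feeds plus 1,000 random feeds, solve 1,000 random cash-flow series,
build the full 2,878-batch Gantt (23,024 intervals), draw 10,000 composition
samples for mean recovery and push 200 sampled scenarios through the whole
pipeline for the fat-monotonicity regression. These sizes keep every suite
in the seconds-to-a-minute range while being comfortably large enough for
the 3-standard-error and sign checks they support.

## Known limitations

* Sharp splits mean zero product cross-contamination by construction;
  product purities are not informative outputs of this model.
* Energy and utility figures are configuration, not prediction.
* The economics module compares scenarios under one price set; it does not
  model price dynamics, working capital, or depreciation.
* Stream temperatures/pressures are carried, not solved; no vapor–liquid
  equilibrium exists anywhere.
* The Gantt model checks single-equipment occupancy only; it does not model
  shared operators, CIP turnarounds or buffer tanks.
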