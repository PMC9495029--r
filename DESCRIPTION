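Package: bsfrefinery
Title: Flowsheet Simulation and Techno-Economic Assessment of a Black
    Soldier Fly Larvae Fatty-Acid Extraction Plant
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch flowsheet simulator for an insect-biorefinery plant that
    extracts and fractionates fatty acids from black soldier fly
    (Hermetia illucens) larvae. Converts proximate larval compositions per
    feed scenario into simulation component streams, solves the full plant
    mass balance (washer, grinder, enzymatic hydrolysis reactor, membrane
    filters, disc centrifuge, sharp-split distillation train, condensers,
    water adsorber, freeze dryer) by topological evaluation, reproduces the
    staggered-batch recipe schedule and Gantt chart, annualizes per-batch
    material balances, and assesses 20-year discounted-cash-flow feasibility
    (NPV, IRR, flat tax) across feed scenarios. Includes a synthetic-scenario
    generator for composition and price sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
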