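# Default plant: black soldier fly larvae fatty-acid extraction and
# fractionation flowsheet. Mechanical pre-treatment (wash, grind), enzymatic
# hydrolysis, membrane waste separation, centrifugal phase split, a three-tower
# sharp-split fatty-acid distillation train with product condensers, water
# adsorption on the lauric product, and freeze drying of the protein byproduct.
batch_mass_kg: 10000

# Per-batch bulk material demands. The water demand is the plant-wide figure
# (process water plus utility/jacket water computed by the scheduler), stored
# as the annual demand over the default campaign of 2878 batches.
bulk_materials:
  alcalase_kg_per_batch: 100
  larvae_kg_per_batch: 10000
  water_kg_per_year: 103775015
  batches_per_year_basis: 2878

feed_streams: [Larvae feed]

units:
  WSH-101:
    kind: washer
    inputs: [Larvae feed]
    outputs: {washed: Crude suspension, waste: Wastes 1}
    params: {wash_water_kg: 10000, ash_removal: 0.66, cellulose_removal: 0.38}
  GR-101:
    kind: grinder
    inputs: [Crude suspension]
    outputs: {product: S-104}
    params: {throughput_kg_h: 9174}
  BR-101:
    kind: reactor
    inputs: [S-104]
    outputs: {slurry: Sludge}
    params: {enzyme_kg: 100, dilution_water_kg: 900, conversion: 0.9, temperature_c: 60}
  MF-101:
    kind: membrane_filter
    inputs: [Sludge]
    outputs: {permeate: S-108, retentate: Cellulose waste}
    params: {rejected_component: cellulose, rejection: 0.999, denaturation: 0.05,
             flux_lm2h: 20, max_density_gl: 1100}
  MF-102:
    kind: membrane_filter
    inputs: [S-108]
    outputs: {permeate: Slurry, retentate: Ash waste}
    params: {rejected_component: ash, rejection: 0.999, denaturation: 0.05,
             flux_lm2h: 20, max_density_gl: 1100}
  DC-101:
    kind: centrifuge
    inputs: [Slurry]
    outputs: {oil_feed: Oil feed, wet_protein: Wet protein meals, water_cellulose: S-112}
    params: {carryover: 0, cake_moisture_ratio: 1.0, oil_entrained_water_ratio: 0.02}
  C-101:
    kind: distillation
    inputs: [Oil feed]
    outputs: {distillate: Impure product 1, bottoms: S-103}
    params: {heavy_key_cut_c: 310, reflux_ratio: 14.404, stages: 22}
  HX-101:
    kind: condenser
    inputs: [Impure product 1]
    outputs: {liquid: S-110}
    params: {outlet_temp_c: 80}
  GAC-101:
    kind: adsorber
    inputs: [S-110]
    outputs: {dry_product: Lauric acid product, reusable_water: Reusable water 2}
    params: {backwash_water_kg: 500}
  C-102:
    kind: distillation
    inputs: [S-103]
    outputs: {distillate: S-105, bottoms: S-107}
    params: {heavy_key_cut_c: 337, reflux_ratio: 1.186, stages: 43}
  HX-104:
    kind: condenser
    inputs: [S-105]
    outputs: {liquid: Myristic acid product}
    params: {outlet_temp_c: 80}
  C-103:
    kind: distillation
    inputs: [S-107]
    outputs: {distillate: Impure product 2, bottoms: S-111}
    params: {heavy_key_cut_c: 354.5, reflux_ratio: 0.984, stages: 43}
  HX-102:
    kind: condenser
    inputs: [Impure product 2]
    outputs: {liquid: Palmitic acid product}
    params: {outlet_temp_c: 80}
  HX-103:
    kind: cooler
    inputs: [S-111]
    outputs: {liquid: Stearic acid product}
    params: {outlet_temp_c: 80}
  FDR-101:
    kind: freeze_dryer
    inputs: [Wet protein meals]
    outputs: {meal: Protein meal, exhaust: FD exhaust}
    params: {final_moisture: 0.05, sublimation_rate_mm_h: 10, tray_depth_mm: 10}
  P-11:
    kind: transport
    inputs: [Protein meal]
    outputs: {product: Protein product}
    params: {shipment_size_kg: 20000}
  UF-101:
    kind: membrane_filter
    inputs: [S-112]
    outputs: {permeate: Reusable water 1, retentate: Wastes 2}
    params: {rejected_component: cellulose, rejection: 0.999, denaturation: 0.05,
             flux_lm2h: 20, max_density_gl: 1200}
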