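test_that("washer removes the configured ash and cellulose fractions", {
  f <- stream("feed", c(ash = 100, cellulose = 200, water = 700))
  r <- wash(f, wash_water = 500, ash_removal = 0.66, cellulose_removal = 0.38)
  expect_equal(component_mass(r$waste, "ash"), 66)
  expect_equal(component_mass(r$washed, "ash"), 34)
  expect_equal(component_mass(r$waste, "cellulose"), 0.38 * 200)
  expect_equal(component_mass(r$waste, "water"), 500)
  expect_equal(total_mass(r$washed) + total_mass(r$waste),
               total_mass(f) + 500, tolerance = 1e-12)

  # identity washer
  r0 <- wash(f, wash_water = 0, ash_removal = 0, cellulose_removal = 0)
  expect_equal(sort(r0$washed$masses), sort(f$masses))
  expect_equal(total_mass(r0$waste), 0)

  expect_error(wash(f, 0, ash_removal = 1.2), "fraction")
})

test_that("grinder preserves composition and computes occupancy from throughput", {
  f <- stream("feed", c(water = 9174))
  expect_equal(grind(f, 9174)$duration, 1)
  expect_equal(grind(stream("empty"), 9174)$duration, 0)
  f2 <- random_feed(11)
  r <- grind(f2, 5000)
  expect_equal(total_mass(r$product), total_mass(f2))
  expect_equal(sort(r$product$masses), sort(f2$masses))
  expect_error(grind(f2, 0), "> 0")
})

test_that("hydrolysis adds the enzyme charge and relabels converted protein", {
  f <- stream("feed", c(protein = 2894, water = 7106))
  s <- hydrolyze(f, enzyme = 100, conversion = 1)
  expect_equal(component_mass(s, "hydrolyzed_protein"), 2894)
  expect_equal(component_mass(s, "protein"), 0)
  expect_equal(total_mass(s), 10100)
  expect_equal(s$temperature, 60)

  # zero conversion only adds the enzyme
  s0 <- hydrolyze(f, enzyme = 100, conversion = 0)
  expect_equal(component_mass(s0, "protein"), 2894)
  expect_equal(component_mass(s0, "hydrolyzed_protein"), 0)

  expect_error(hydrolyze(f, 100, conversion = 1.5), "fraction")
})

test_that("membrane filter rejects solids, sizes area, and conserves mass", {
  f <- stream("feed", c(cellulose = 1000, water = 9000))
  r <- membrane_filter(f, "cellulose", rejection = 0.999, denaturation = 0)
  expect_equal(component_mass(r$retentate, "cellulose"), 999)
  expect_equal(component_mass(r$permeate, "cellulose"), 1, tolerance = 1e-9)
  expect_equal(total_mass(r$permeate) + total_mass(r$retentate),
               total_mass(f), tolerance = 1e-9)

  # retained water is the minimum meeting the density cap:
  # W = rho_w * S * (1/C_max - 1/rho_s)
  expect_equal(component_mass(r$retentate, "water"),
               1000 * 999 * (1 / 1100 - 1 / 1500), tolerance = 1e-9)

  # rejection 0: all solids permeate
  r0 <- membrane_filter(f, "cellulose", rejection = 0, denaturation = 0)
  expect_equal(component_mass(r0$permeate, "cellulose"), 1000)
  expect_equal(total_mass(r0$retentate), 0)

  # area: 20 m3/h at 20 L/m2/h -> 1000 m2 (water density 1000 kg/m3)
  fa <- stream("feed", c(water = 20000))
  ra <- membrane_filter(fa, "cellulose", rejection = 0.999)
  expect_equal(ra$area, 1000)

  # density infeasibility: not enough water to carry the solids
  fd <- stream("feed", c(cellulose = 1000, water = 10))
  rd <- membrane_filter(fd, "cellulose", rejection = 0.999)
  expect_match(rd$warnings, "max density")
  expect_equal(total_mass(rd$permeate) + total_mass(rd$retentate),
               total_mass(fd), tolerance = 1e-9)

  expect_error(membrane_filter(f, "unobtainium"), "unknown")
})

test_that("membrane denaturation relabels permeating protein mass-conservingly", {
  f <- stream("feed", c(cellulose = 100, protein = 1000, water = 5000))
  r <- membrane_filter(f, "cellulose", rejection = 0.999, denaturation = 0.05)
  expect_equal(component_mass(r$permeate, "protein"), 950)
  expect_equal(component_mass(r$permeate, "denatured_protein"), 50)
  expect_equal(total_mass(r$permeate) + total_mass(r$retentate),
               total_mass(f), tolerance = 1e-9)
})

test_that("centrifuge routes components per the phase map and closes its balance", {
  f <- stream("feed", c(lauric = 3000, protein = 2000, cellulose = 300,
                        water = 5000))
  pm <- default_phase_map()
  r <- centrifuge(f, pm, carryover = 0, cake_moisture_ratio = 0,
                  oil_entrained_water_ratio = 0)
  expect_equal(component_mass(r$oil_feed, "lauric"), 3000)
  expect_equal(component_mass(r$wet_protein, "protein"), 2000)
  expect_equal(component_mass(r$water_cellulose, "cellulose"), 300)
  expect_equal(component_mass(r$water_cellulose, "water"), 5000)

  # mass closure with moisture and entrainment active
  r2 <- centrifuge(f, pm, carryover = 0.02)
  expect_equal(total_mass(r2$oil_feed) + total_mass(r2$wet_protein) +
                 total_mass(r2$water_cellulose), total_mass(f),
               tolerance = 1e-9)
  # fat carryover leaks into the cake
  expect_equal(component_mass(r2$wet_protein, "lauric"), 60)

  expect_error(centrifuge(f, pm[names(pm) != "protein"]), "phase_map")
  expect_error(centrifuge(f, c(pm, bogus = "sideways")[c(names(pm), "bogus")]),
               "invalid")
})

test_that("sharp split partitions strictly by boiling point against the cut", {
  f <- stream("oil", c(water = 10, lauric = 20, myristic = 30, palmitic = 15,
                       stearic = 25), phase = "liquid")
  d <- distill_sharp(f, heavy_key_cut = 310, reflux_ratio = 14.404)
  expect_setequal(names(d$distillate$masses), c("water", "lauric"))
  expect_setequal(names(d$bottoms$masses), c("myristic", "palmitic", "stearic"))
  expect_equal(total_mass(d$distillate) + total_mass(d$bottoms), 100)
  expect_equal(d$distillate$phase, "vapor")
  expect_equal(d$bottoms$phase, "liquid")

  # single component below the cut: empty distillate, degenerate warning
  s1 <- distill_sharp(stream("one", c(stearic = 10), phase = "liquid"),
                      heavy_key_cut = 310, reflux_ratio = 1)
  expect_equal(total_mass(s1$distillate), 0)
  expect_match(s1$warnings, "degenerate")

  # reflux 0: condenser duty = distillate mass x latent heat
  s2 <- distill_sharp(stream("one", c(lauric = 100), phase = "liquid"),
                      heavy_key_cut = 310, reflux_ratio = 0)
  expect_equal(s2$condenser_duty, 100 * 200)
  expect_equal(s2$reboiler_duty, s2$condenser_duty)

  expect_error(distill_sharp(f, heavy_key_cut = 298.8, reflux_ratio = 1),
               "ambiguous")
})

test_that("sharp-split ordering holds on randomized feeds", {
  reg <- default_components()
  volatile <- reg$name[!is.na(reg$boiling_point)]
  for (seed in 1:40) {
    set.seed(seed)
    comps <- sample(volatile, sample(2:length(volatile), 1))
    masses <- setNames(stats::runif(length(comps), 1, 100), comps)
    bp <- reg$boiling_point[match(comps, reg$name)]
    cut <- stats::runif(1, min(bp) + 0.1, max(bp) - 0.1)
    if (any(abs(bp - cut) < 0.5)) cut <- cut + 0.51  # avoid ambiguous cuts
    d <- distill_sharp(stream("r", masses, phase = "liquid"),
                       heavy_key_cut = cut, reflux_ratio = 1)
    bp_d <- reg$boiling_point[match(names(d$distillate$masses), reg$name)]
    bp_b <- reg$boiling_point[match(names(d$bottoms$masses), reg$name)]
    expect_true(all(bp_d < cut))
    expect_true(all(bp_b > cut))
    expect_equal(total_mass(d$distillate) + total_mass(d$bottoms),
                 sum(masses), tolerance = 1e-9)
  }
})

test_that("condenser computes latent plus sensible duty and demands vapor", {
  v <- stream("Impure product 1", c(lauric = 1000), temperature = 298.8,
              phase = "vapor")
  r <- condense(v, outlet_temp = 80)
  expect_equal(r$cooling_duty, 1000 * 200 + 1000 * 2.1 * (298.8 - 80))
  expect_equal(r$liquid$phase, "liquid")
  expect_equal(r$liquid$masses, v$masses)
  expect_equal(r$liquid$temperature, 80)

  expect_equal(condense(stream("e", phase = "vapor"))$cooling_duty, 0)
  expect_error(condense(stream("l", c(lauric = 1), phase = "liquid")), "vapor")
})

test_that("water adsorber strips all water into the reusable stream", {
  f <- stream("S-110", c(lauric = 500, water = 50), phase = "liquid")
  r <- adsorb_water(f, backwash_water = 100)
  expect_equal(r$dry_product$masses, c(lauric = 500))
  expect_equal(component_mass(r$reusable_water, "water"), 150)
  expect_equal(total_mass(r$dry_product) + total_mass(r$reusable_water),
               total_mass(f) + 100, tolerance = 1e-12)

  dryf <- stream("dry", c(lauric = 500), phase = "liquid")
  expect_equal(adsorb_water(dryf)$dry_product$masses, dryf$masses)
})

test_that("freeze dryer hits the target moisture with a layer-model duration", {
  r <- freeze_dry(stream("cake", c(protein = 900, water = 1100)),
                  final_moisture = 0)
  expect_equal(r$meal$masses, c(protein = 900))
  expect_equal(component_mass(r$exhaust, "water"), 1100)

  r2 <- freeze_dry(stream("cake", c(protein = 950, water = 950)),
                   final_moisture = 0.05)
  expect_equal(component_mass(r2$meal, "water"), 50, tolerance = 1e-9)
  expect_equal(total_mass(r2$meal) + total_mass(r2$exhaust), 1900,
               tolerance = 1e-9)

  expect_equal(freeze_dry(stream("c", c(water = 1, protein = 1)),
                          sublimation_rate = 10, tray_depth = 10)$duration, 1)

  # already dry: no-op with warning
  r3 <- freeze_dry(stream("c", c(protein = 99, water = 1)),
                   final_moisture = 0.5)
  expect_match(r3$warnings, "no-op")
  expect_equal(total_mass(r3$exhaust), 0)
  expect_error(freeze_dry(stream("c", c(water = 1)), final_moisture = 1),
               "final_moisture")
})
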