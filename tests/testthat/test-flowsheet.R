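test_that("flowsheet validation catches topology and parameter defects", {
  units <- list(
    "A-1" = list(kind = "grinder", inputs = "Larvae feed",
                 outputs = list(product = "s1"),
                 params = list(throughput_kg_h = 1000)),
    "B-1" = list(kind = "grinder", inputs = "s1",
                 outputs = list(product = "s2"),
                 params = list(throughput_kg_h = 1000))
  )
  expect_s3_class(flowsheet(units), "flowsheet")

  # cycle: B feeds A
  cyc <- units
  cyc[["A-1"]]$inputs <- c("Larvae feed", "s2")
  expect_error(flowsheet(cyc), "cycle")

  # missing producer
  orphan <- units
  orphan[["B-1"]]$inputs <- "nowhere"
  expect_error(flowsheet(orphan), "no producer")

  # two producers of one stream
  dup <- units
  dup[["B-1"]]$outputs <- list(product = "s1")
  expect_error(flowsheet(dup), "two producers")

  # incomplete parameters for the kind
  nopar <- units
  nopar[["A-1"]]$params <- list()
  expect_error(flowsheet(nopar), "missing parameter")

  expect_error(flowsheet(list("X" = list(kind = "teleporter", inputs = "Larvae feed",
                                         outputs = list(product = "s"), params = list()))),
               "unknown kind")
})

test_that("three-unit toy flowsheet matches hand-composed split matrices", {
  fs <- flowsheet(list(
    "WSH-1" = list(kind = "washer", inputs = "Larvae feed",
                   outputs = list(washed = "washed", waste = "w1"),
                   params = list(wash_water_kg = 50, ash_removal = 0.66,
                                 cellulose_removal = 0.38)),
    "MF-1" = list(kind = "membrane_filter", inputs = "washed",
                  outputs = list(permeate = "perm", retentate = "ret"),
                  params = list(rejected_component = "cellulose",
                                rejection = 0.9, denaturation = 0)),
    "GR-1" = list(kind = "grinder", inputs = "perm",
                  outputs = list(product = "out"),
                  params = list(throughput_kg_h = 1000))
  ))
  feed <- stream("Larvae feed", c(ash = 100, cellulose = 200, water = 700))
  sim <- simulate_flowsheet(fs, feed)

  # hand-composed oracle, factor by factor
  ash_washed <- 100 * (1 - 0.66)              # 34
  cel_washed <- 200 * (1 - 0.38)              # 124
  cel_ret <- 0.9 * cel_washed                 # 111.6
  w_ret <- 1000 * cel_ret * (1 / 1100 - 1 / 1500)
  expect_equal(component_mass(sim$streams$w1, "ash"), 66)
  expect_equal(component_mass(sim$streams$w1, "water"), 50)
  expect_equal(component_mass(sim$streams$ret, "cellulose"), cel_ret)
  expect_equal(component_mass(sim$streams$ret, "water"), w_ret)
  expect_equal(component_mass(sim$streams$out, "ash"), ash_washed)
  expect_equal(component_mass(sim$streams$out, "cellulose"),
               cel_washed - cel_ret)
  expect_equal(component_mass(sim$streams$out, "water"), 700 - w_ret)
  expect_equal(sim$closure$residual_rel, 0, tolerance = 1e-12)
})

test_that("default plant closes plant-wide mass balance on scenario and random feeds", {
  fs <- plant_cfg$flowsheet
  for (pc in feed_scenarios()) {
    feed <- larvae_feed_stream(10000, wet_basis_fractions(pc))
    sim <- simulate_flowsheet(fs, feed)
    expect_lt(sim$closure$residual_rel, 1e-9)
  }
  for (seed in 1:50) {
    sim <- simulate_flowsheet(fs, random_feed(seed))
    expect_lt(sim$closure$residual_rel, 1e-9)
  }
})

test_that("empty feed simulates cleanly to empty products", {
  sim <- simulate_flowsheet(plant_cfg$flowsheet, stream("Larvae feed"))
  expect_lt(sim$closure$residual_rel, 1e-9)
  for (lab in c("Lauric acid product", "Myristic acid product",
                "Palmitic acid product", "Stearic acid product",
                "Protein product"))
    expect_equal(total_mass(sim$streams[[lab]]), 0)
})

test_that("simulated stream contents match the plant's flow-content contract", {
  feed <- larvae_feed_stream(10000,
                             wet_basis_fractions(feed_scenarios()$control))
  sim <- simulate_flowsheet(plant_cfg$flowsheet, feed)
  violations <- check_stream_contents(sim)
  expect_identical(nrow(violations), 0L)
  # spot checks of the contract itself
  expect_setequal(names(sim$streams[["Ash waste"]]$masses), c("ash", "water"))
  expect_setequal(names(sim$streams[["Lauric acid product"]]$masses), "lauric")
  # reusable water is essentially pure; only finite-rejection trace leaks ride along
  rw <- sim$streams[["Reusable water 1"]]
  expect_gt(component_mass(rw, "water") / total_mass(rw), 0.999)
})

test_that("lauric product tracks the analytic composition of split factors", {
  pc <- feed_scenarios()$kitchen_waste
  cf <- wet_basis_fractions(pc)
  profile <- fatty_acid_profile()
  feed <- larvae_feed_stream(10000, cf, profile)
  sim <- simulate_flowsheet(plant_cfg$flowsheet, feed)
  # no fat is removed by the washer or membranes and carryover is 0, so the
  # lauric product equals feed fat x lauric profile fraction exactly
  expect_equal(total_mass(sim$streams[["Lauric acid product"]]),
               10000 * cf$crude_fat * profile[["lauric"]], tolerance = 1e-9)
  # with filter fat carryover the product shrinks accordingly
  fs2 <- plant_cfg$flowsheet
  fs2$units[["DC-101"]]$params$carryover <- 0.1
  sim2 <- simulate_flowsheet(fs2, feed)
  expect_equal(total_mass(sim2$streams[["Lauric acid product"]]),
               0.9 * 10000 * cf$crude_fat * profile[["lauric"]],
               tolerance = 1e-9)
})

test_that("unit failures surface with the unit id", {
  fs <- plant_cfg$flowsheet
  fs$units[["C-101"]]$params$heavy_key_cut_c <- 298.8  # a boiling point
  feed <- larvae_feed_stream(10000,
                             wet_basis_fractions(feed_scenarios()$control))
  expect_error(simulate_flowsheet(fs, feed), "\\[C-101\\].*ambiguous")
})

test_that("stream table export is long-format with metadata", {
  sim <- simulate_flowsheet(plant_cfg$flowsheet,
                            larvae_feed_stream(10000,
                              wet_basis_fractions(feed_scenarios()$control)))
  st <- stream_table(sim$streams)
  expect_true(all(c("label", "component", "kg_per_batch", "temperature_c",
                    "pressure_bar", "phase") %in% names(st)))
  expect_true(all(st$kg_per_batch >= 0))
  expect_true("Oil feed" %in% st$label)
})
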